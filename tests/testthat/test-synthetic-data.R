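test_that("noise generation is seeded, sized and filterable", {
  tr <- time_series(rep(0, 1e5), dt = 0.03)
  # rms = 0 is the identity
  expect_identical(add_noise(tr, noise_spec(0, seed = 1))$values, tr$values)
  # same seed twice -> bitwise identical
  a <- add_noise(tr, noise_spec(0.005, seed = 5, cutoff_khz = Inf))
  b <- add_noise(tr, noise_spec(0.005, seed = 5, cutoff_khz = Inf))
  expect_identical(a$values, b$values)
  # unfiltered sample sd within 1% of the requested rms
  expect_lt(abs(sd(a$values) - 0.005) / 0.005, 0.01)
  # the low-pass reduces the white-noise variance but keeps DC gain 1
  f <- add_noise(tr, noise_spec(0.005, seed = 5, cutoff_khz = 2))
  expect_lt(sd(f$values), sd(a$values))
  step <- caflux:::bessel4_lowpass(rep(1, 2000), 0.03, 2)
  expect_equal(step[2000], 1, tolerance = 1e-6)
  # the generators leave the global RNG state alone
  set.seed(123); r1 <- rnorm(1)
  set.seed(123); invisible(make_gaussian_population(0, 1, 10, seed = 99))
  expect_identical(rnorm(1), r1)
})

test_that("flux waveforms honor their analytic peak and width", {
  # zero peak -> zero trace
  z <- make_flux_waveform(flux_shape(0), duration = 10)
  expect_true(all(z$values == 0))
  # alpha shape tuned for FDHM 2 ms
  rt <- alpha_rise_for_fdhm(2)
  sh <- flux_shape(260, latency = 1, rise_tau = rt)
  expect_equal(flux_fdhm(sh), 2, tolerance = 1e-9)
  fl <- make_flux_waveform(sh, duration = 15, dt = 0.03)
  expect_lt(abs(max(fl$values) - 260) / 260, 5e-4)
  expect_lt(abs(caflux:::fdhm_of(fl$values, fl$dt) - 2), 0.03)
  # dual-exponential: normalized so the sampled maximum hits the peak
  sh2 <- flux_shape(100, 0, rise_tau = 0.4, decay_tau = 5, "dual-exponential")
  fl2 <- make_flux_waveform(sh2, duration = 30, dt = 0.03)
  expect_lt(abs(max(fl2$values) - 100) / 100, 1e-4)
})

test_that("AP waveform meets its programmed amplitude and width", {
  shp <- ap_shape(fdhm = 2.3)
  ap <- make_ap_waveform(shp, duration = 20, dt = 0.03, onset = 2)
  expect_equal(min(ap$values), -90, tolerance = 1e-9)
  expect_lt(abs(max(ap$values) - 40) / 130, 5e-4)
  expect_equal(caflux:::fdhm_of(ap$values + 90, 0.03), 2.3, tolerance = 0.02)
})

test_that("transient kernel solves its morphology constraints exactly", {
  ker <- make_transient_kernel(peak = 0.63, latency = 1.4, time_to_peak = 3,
                               fdhm = 2)
  tr <- attr(ker, "truth")
  expect_equal(max(ker$values), 0.63, tolerance = 1e-9)
  expect_equal(caflux:::fdhm_of(ker$values, ker$dt), 2, tolerance = 0.03)
  i5 <- which(ker$values >= 0.05 * 0.63)[1]
  expect_equal((i5 - 1) * ker$dt, 1.4, tolerance = 0.031)
  expect_gt(tr$tau1, 0)
})

test_that("a single-pulse train reproduces the kernel", {
  pr <- train_protocol(10, duration_ms = 100, start_ms = 21)
  ker <- make_transient_kernel(duration = 30)
  tr <- make_train(pr, per_pulse_scale = 1, kernel = ker)
  i0 <- round(21 / 0.03) + 1
  seg <- tr$dfof$values[i0:(i0 + length(ker$values) - 1)]
  expect_equal(seg, ker$values, tolerance = 1e-12)
})

test_that("clamp families carry their ground truth and degenerate cleanly", {
  fam <- make_clamp_family(voltage_clamp_protocol(),
                           boltzmann_fit(0.77, 7, 13),
                           boltzmann_fit(0.37, 6, 11))
  expect_equal(nrow(fam$truth), 21)
  ext <- vapply(seq_along(fam$sweeps), function(i)
    extract_peak_and_steady(fam$sweeps[[i]], fam$pulse_window)$peak, 0)
  expect_lt(max(abs(ext - fam$truth$peak)), 1e-6)
  # zero-amplitude family is flat
  flat <- make_clamp_family(voltage_clamp_protocol(),
                            boltzmann_fit(0, 7, 13), boltzmann_fit(0, 6, 11))
  expect_true(all(vapply(flat$sweeps, function(s) max(abs(s$values)), 0) == 0))
  # noisy family at the same seed is reproducible
  n1 <- make_clamp_family(voltage_clamp_protocol(), boltzmann_fit(0.77, 7, 13),
                          boltzmann_fit(0.37, 6, 11), noise = noise_spec(0.02, 4))
  n2 <- make_clamp_family(voltage_clamp_protocol(), boltzmann_fit(0.77, 7, 13),
                          boltzmann_fit(0.37, 6, 11), noise = noise_spec(0.02, 4))
  expect_identical(n1$sweeps[[5]]$values, n2$sweeps[[5]]$values)
})

test_that("line-scan geometry: six triad maxima and exact anchor passage", {
  scan <- make_linescan(n_sarcomeres = 3)
  P <- scan$truth$profile
  expect_equal(sum(diff(sign(diff(P))) == -2), 6)
  # the solved observed profile passes through the programmed anchors at
  # the canonical site positions, for the default PSF and for no PSF
  for (fwhm in c(0.8, 0)) {
    sc <- make_linescan(psf_fwhm = fwhm, step = 0.05, phase = 0.5,
                        triad_offset = 0.5)
    near <- function(x) which.min(abs(sc$positions - x))
    s <- sc$truth$sites
    tin <- s$t_all[s$t_all > 0.3 & s$t_all < max(sc$positions) - 0.3]
    zin <- s$z_all[s$z_all > 0.3 & s$z_all < max(sc$positions) - 0.3]
    min_ <- s$m_all[s$m_all > 0.3 & s$m_all < max(sc$positions) - 0.3]
    expect_lt(max(abs(sc$truth$profile[vapply(tin, near, 0L)] - 0.6)), 2e-3)
    expect_lt(max(abs(sc$truth$profile[vapply(zin, near, 0L)] - 0.45)), 2e-3)
    expect_lt(max(abs(sc$truth$profile[vapply(min_, near, 0L)] - 0.35)), 2e-3)
  }
  # violating the amplitude ordering warns
  expect_warning(make_linescan(amplitudes = c(T = 0.3, Z = 0.45, M = 0.35),
                               profile_type = "plateau"), "T > Z > M")
})
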