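test_that("noise-free scans are classified perfectly with T > Z > M means", {
  scan <- make_linescan()
  lab <- classify_sites(scan)
  expect_equal(mean(lab$labels == scan$truth$labels), 1)
  cm <- lab$class_means
  expect_true(cm["T"] > cm["Z"] && cm["Z"] > cm["M"])
  # estimated period within one position step
  expect_lt(abs(lab$period - 2.1), 0.2)
  # two triads per sarcomere: T twice as frequent as Z among label classes
  expect_equal(sum(lab$labels == "T") > sum(lab$labels == "Z"), TRUE)
})

test_that("a spatially flat scan raises a periodicity failure", {
  scan <- make_linescan()
  scan$dfof <- matrix(0.5, nrow(scan$dfof), ncol(scan$dfof))
  expect_error(classify_sites(scan), "periodicity")
})

test_that("classification stays above 95% under 0.02 rms noise", {
  acc <- vapply(1:25, function(s) {
    scan <- make_linescan(noise = noise_spec(0.02, seed = s))
    mean(classify_sites(scan)$labels == scan$truth$labels)
  }, 0)
  expect_gte(mean(acc), 0.95)
})

test_that("longer scans refine the period estimate to within one step", {
  for (n in c(3, 5)) {
    scan <- make_linescan(n_sarcomeres = n)
    lab <- classify_sites(scan)
    expect_lt(abs(lab$period - 2.1), 0.2 + 1e-9)
  }
})

test_that("site averaging recovers identical and plateau-programmed transients", {
  # identical transients at every position: class means equal the input
  scan <- make_linescan(profile_type = "plateau",
                        amplitudes = c(T = 0.5, Z = 0.5 - 1e-9, M = 0.5 - 2e-9))
  lab <- list(labels = scan$truth$labels)
  av <- average_by_site(list(scan), list(lab))
  ker <- scan$truth$kernel
  expect_equal(av$T$mean$values, 0.5 * ker$values, tolerance = 1e-6)
  expect_equal(av$M$mean$values, 0.5 * ker$values, tolerance = 1e-6)
  expect_true(attr(av, "single_fiber"))
  expect_true(all(is.na(av$T$sem)))
  # plateau profile with noise: class mean peaks recover programmed values
  scans <- lapply(1:4, function(s)
    make_linescan(profile_type = "plateau", noise = noise_spec(0.02, seed = s)))
  labs <- lapply(scans, function(s) list(labels = s$truth$labels))
  av2 <- average_by_site(scans, labs)
  expect_lt(abs(max(av2$T$mean$values) - 0.6) / 0.6, 0.02)
  expect_lt(abs(max(av2$Z$mean$values) - 0.45) / 0.45, 0.02)
  expect_lt(abs(max(av2$M$mean$values) - 0.35) / 0.35, 0.02)
  expect_false(all(is.na(av2$T$sem)))
})

test_that("T > Z > M ordering is statistically detectable across 6 fibers", {
  scans <- lapply(1:6, function(s)
    make_linescan(noise = noise_spec(0.02, seed = 200 + s)))
  labs <- lapply(scans, classify_sites)
  peak_by_class <- function(cl) vapply(seq_along(scans), function(i) {
    idx <- labs[[i]]$labels == cl
    max(colMeans(scans[[i]]$dfof[idx, , drop = FALSE]))
  }, 0)
  pk <- lapply(c(T = "T", Z = "Z", M = "M"), peak_by_class)
  t_tz <- stats::t.test(pk$T, pk$Z, alternative = "greater", var.equal = TRUE)
  t_zm <- stats::t.test(pk$Z, pk$M, alternative = "greater", var.equal = TRUE)
  expect_lt(t_tz$p.value, 0.05)
  expect_lt(t_zm$p.value, 0.05)
})

test_that("triad-site flux recovery and triad > global ordering hold", {
  p <- default_params()
  fl <- wt_alpha_flux(peak = 300, duration = 15)
  tr <- simulate_forward(p, fl)
  ker <- dfof_from_trajectory(tr)
  # plateau profile: every T position carries the triad-local transient, so
  # the T-class mean is exactly the simulated record
  scan <- make_linescan(amplitudes = c(T = 1, Z = 0.75, M = 0.583),
                        kernel = ker, profile_type = "plateau")
  lab <- classify_sites(scan)
  av <- average_by_site(list(scan), list(lab))
  Rt <- triad_flux(av$T$mean, p)
  expect_lt(abs(peak_flux(Rt) - 300) / 300, 0.03)
  # PSF-blurred microdomain scan: triad-site flux beats the space average
  scan2 <- make_linescan(amplitudes = c(T = 1, Z = 0.75, M = 0.583),
                         kernel = ker)
  lab2 <- classify_sites(scan2)
  av2 <- average_by_site(list(scan2), list(lab2))
  Rt2 <- triad_flux(av2$T$mean, p)
  glob <- time_series(colMeans(scan2$dfof), scan2$dt, units = "dfof")
  Rg <- flux_from_dfof(glob, p)
  expect_gt(peak_flux(Rt2), peak_flux(Rg))
  # zero scan -> zero flux
  z <- time_series(rep(0, length(ker$values)), ker$dt, units = "dfof")
  expect_lt(max(abs(flux_from_dfof(z, p)$values)), 0.1)
})
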