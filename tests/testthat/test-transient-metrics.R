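test_that("dF/F normalization uses the pre-stimulus baseline", {
  f <- time_series(rep(100, 400), dt = 0.03)
  d <- compute_dfof(f, c(0, 5))
  expect_equal(d$values, rep(0, 400))
  # F0 = 100, peak F = 163 -> peak dF/F = 0.63
  v <- rep(100, 400); v[250] <- 163
  d2 <- compute_dfof(time_series(v, dt = 0.03), c(0, 5))
  expect_equal(max(d2$values), 0.63)
  # injected DC offset is recovered from a noisy baseline
  set.seed(42)
  v3 <- 80 + rnorm(1000, 0, 0.5)
  d3 <- compute_dfof(time_series(v3, dt = 0.03), c(0, 10))
  expect_lt(abs(mean(d3$values[1:333])), 1e-3)
  expect_error(compute_dfof(time_series(rep(-1, 100), dt = 1), c(0, 10)),
               "baseline")
})

test_that("transient metrics recover the generator's programmed morphology", {
  ker <- make_transient_kernel(peak = 0.63, latency = 1.4, time_to_peak = 3,
                               fdhm = 2)
  pre <- round(5 / 0.03)
  dfof <- time_series(c(numeric(pre), ker$values), 0.03, units = "dfof")
  ap <- make_ap_waveform(ap_shape(), duration = 0.03 * (pre + length(ker) - 1),
                         onset = 5)
  m <- measure_transient(dfof, ap)
  expect_equal(m$peak, 0.63, tolerance = 1e-6)
  expect_equal(m$latency, 1.4, tolerance = 0.03 / 1.4)
  expect_equal(m$time_to_peak, 3, tolerance = 0.031 / 3)
  expect_equal(m$fdhm, 2, tolerance = 0.03 / 2)
  # decay fit on the same record recovers the WT double exponential shape
  expect_false(m$decay$degenerate)
  expect_equal(m$decay$tau2, 19, tolerance = 0.05)
})

test_that("FDHM has its closed-form value on canonical shapes", {
  # symmetric triangle of half-width w
  up <- seq(0, 1, length.out = 101)
  tri <- time_series(c(up, rev(up)[-1]), dt = 0.05)   # half-width 5 ms
  expect_equal(caflux:::fdhm_of(tri$values, tri$dt), 5, tolerance = 1e-9)
  # Gaussian bump of SD sigma -> fdhm = 2.3548 sigma
  t <- seq(0, 40, by = 0.03)
  g <- time_series(exp(-(t - 20)^2 / (2 * 2.5^2)), dt = 0.03)
  expect_equal(caflux:::fdhm_of(g$values, g$dt), 2 * sqrt(2 * log(2)) * 2.5,
               tolerance = 0.01)
})

test_that("FDHM and peak are invariant to time shift and resampling", {
  ker <- make_transient_kernel()
  base <- caflux:::fdhm_of(ker$values, ker$dt)
  shifted <- c(numeric(500), ker$values)
  expect_equal(caflux:::fdhm_of(shifted, ker$dt), base, tolerance = 1e-9)
  fine <- make_transient_kernel(dt = 0.01)
  expect_lt(abs(caflux:::fdhm_of(fine$values, fine$dt) - base), 0.03)
})

test_that("double-exponential fit recovers printed WT and mutant decays", {
  t <- seq(0, 60, by = 0.03)
  for (par in list(c(0.63, 1, 0.04, 19),      # WT example
                   c(0.57, 1, 0.03, 18))) {   # knockout example
    y <- par[1] * exp(-t / par[2]) + par[3] * exp(-t / par[4])
    f <- fit_double_exponential(time_series(y, dt = 0.03))
    expect_equal(f$a1, par[1], tolerance = 1e-4)
    expect_equal(f$tau1, par[2], tolerance = 1e-4)
    expect_equal(f$a2, par[3], tolerance = 1e-4)
    expect_equal(f$tau2, par[4], tolerance = 1e-4)
    expect_equal(f$offset, 0, tolerance = 1e-6)
    expect_true(f$tau1 <= f$tau2)
  }
})

test_that("a pure single exponential yields a vanishing second component", {
  t <- seq(0, 60, by = 0.03)
  f <- fit_double_exponential(time_series(0.5 * exp(-t / 2), dt = 0.03))
  expect_equal(f$a1 + f$a2, 0.5, tolerance = 1e-6)
  expect_lt(min(f$a1, f$a2), 1e-6)
  tau_main <- if (f$a1 >= f$a2) f$tau1 else f$tau2
  expect_equal(tau_main, 2, tolerance = 1e-5)
})

test_that("noise-free recovery holds across random parameter draws", {
  set.seed(11)
  n_draw <- 40
  t <- seq(0, 60, by = 0.12)
  for (i in seq_len(n_draw)) {
    tau1 <- runif(1, 0.5, 3); tau2 <- runif(1, 10, 30)
    a2 <- runif(1, 0.02, 0.1); a1 <- a2 * runif(1, 5, 30)
    y <- a1 * exp(-t / tau1) + a2 * exp(-t / tau2)
    f <- fit_double_exponential(time_series(y, dt = 0.12))
    expect_lt(abs(f$tau1 - tau1) / tau1, 1e-3)
    expect_lt(abs(f$tau2 - tau2) / tau2, 1e-3)
    expect_lt(abs(f$a1 - a1) / a1, 1e-3)
    expect_lt(abs(f$a2 - a2) / a2, 1e-3)
  }
})

test_that("fast tau is stable under realistic noise at the WT point", {
  t <- seq(0, 60, by = 0.12)
  y0 <- 0.63 * exp(-t / 1) + 0.04 * exp(-t / 19)
  ok <- vapply(1:40, function(s) {
    set.seed(s)
    y <- y0 + rnorm(length(t), 0, 0.005)
    f <- fit_double_exponential(time_series(y, dt = 0.12))
    abs(f$tau1 - 1) < 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("fast_fraction reduces to the printed ~95% for the WT decay", {
  f <- list(a1 = 0.63, a2 = 0.04)
  class(f) <- "double_exp_fit"
  expect_equal(fast_fraction(f), 0.63 / 0.67)
  expect_equal(round(fast_fraction(f), 2), 0.94)
  f$a2 <- 0
  expect_equal(fast_fraction(f), 1)
  f$a2 <- f$a1
  expect_equal(fast_fraction(f), 0.5)
})
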