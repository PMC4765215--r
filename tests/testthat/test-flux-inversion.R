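wt_dfof <- function(peak = 260, fdhm = 2, phi = 40, duration = 25) {
  p <- default_params()
  fl <- wt_alpha_flux(peak, fdhm, duration = duration)
  tr <- simulate_forward(p, fl)
  list(dfof = dfof_from_trajectory(tr, fluorescence_params(phi)),
       flux = fl, params = p)
}

test_that("dye occupancy transform is the exact inverse of the dF/F model", {
  fl <- fluorescence_params(phi = 5)
  dye <- buffer_spec("dye", 250, ca = rate_constants(0.157, 9.42))
  dfof0 <- time_series(rep(0, 10), dt = 0.03)
  expect_equal(cad_from_dfof(dfof0, fl, dye, 0.3)$values, rep(0.3, 10))
  # inverse of the hand example
  d <- time_series(c(0, 4 * 39.7 / 251.2), dt = 0.03)
  cad <- cad_from_dfof(d, fl, dye, 0.3)
  expect_equal(cad$values[2], 40, tolerance = 1e-12)
  # full round trip through a simulated trajectory is machine precision
  w <- wt_dfof()
  rest <- equilibrium_state(w$params, "clamped")
  cad2 <- cad_from_dfof(w$dfof, fluorescence_params(40),
                        w$params$buffers$dye, rest[["dye.ca"]])
  tr <- simulate_forward(w$params, w$flux)
  expect_equal(cad2$values, unname(tr$states[, "dye.ca"]), tolerance = 1e-9)
  # saturation guard
  expect_error(cad_from_dfof(time_series(c(0, 99), dt = 1), fl, dye, 0.3),
               "saturation")
})

test_that("free Ca recovery inverts the dye reaction kinetics", {
  dye <- rate_constants(0.157, 9.42)
  d_total <- 250
  # constant CaD at the equilibrium of Ca* returns Ca*
  ca_star <- 2.5
  cad_eq <- d_total * ca_star / (ca_star + dye$kd)
  cad <- time_series(rep(cad_eq, 200), dt = 0.03)
  ca <- free_ca_from_cad(cad, dye, d_total)
  expect_equal(ca$values, rep(ca_star, 200), tolerance = 1e-10)
  # analytic single-reaction relaxation toward a clamped Ca level
  ca_c <- 5
  tau <- 1 / (dye$kon * ca_c + dye$koff)
  cad_inf <- d_total * ca_c / (ca_c + dye$kd)
  t <- seq(0, 6, by = 0.03)
  cadv <- cad_inf + (0.3 - cad_inf) * exp(-t / tau)
  ca2 <- free_ca_from_cad(time_series(cadv, dt = 0.03), dye, d_total)
  valid <- attr(ca2, "valid")
  expect_lt(max(abs(ca2$values[valid] - ca_c)) / ca_c, 1e-3)
})

test_that("free Ca from a forward simulation tracks the true trajectory", {
  w <- wt_dfof()
  tr <- simulate_forward(w$params, w$flux)
  rest <- equilibrium_state(w$params, "clamped")
  cad <- cad_from_dfof(w$dfof, fluorescence_params(40),
                       w$params$buffers$dye, rest[["dye.ca"]])
  ca <- free_ca_from_cad(cad, w$params$buffers$dye$ca, 250)
  truth <- tr$states[, "ca"]
  # the local-polynomial derivative is biased within one window of the flux
  # onset (a slope discontinuity); judge recovery away from it and edges
  sel <- attr(ca, "valid") & truth > 0.05 * max(truth) & ts_time(ca) > 2.3
  expect_lt(max(abs(ca$values[sel] - truth[sel]) / truth[sel]), 0.01)
})

test_that("zero dF/F inverts to zero flux", {
  R <- flux_from_dfof(time_series(rep(0, 500), dt = 0.03), default_params())
  expect_lt(max(abs(R$values)), 0.1)
})

test_that("flux round trip recovers an AP-like release waveform", {
  w <- wt_dfof()
  R <- flux_from_dfof(w$dfof, w$params)
  expect_s3_class(R, "flux_trace")
  expect_equal(length(R), length(w$dfof))
  pk <- peak_flux(R)
  expect_lt(abs(pk - 260) / 260, 0.02)
  # peak time within one sample of the programmed peak
  expect_lt(abs(ts_time(R)[which.max(R$values)] -
                  ts_time(w$flux)[which.max(w$flux$values)]), 0.03 + 1e-9)
  v <- attr(R, "valid")
  expect_lt(abs(sum(R$values[v]) - sum(w$flux$values[v])) /
              sum(w$flux$values[v]), 0.02)
})

test_that("round trip is phi-invariant when forward and inverse share phi", {
  errs <- vapply(c(5, 40, 100), function(phi) {
    w <- wt_dfof(phi = phi)
    pk <- peak_flux(flux_from_dfof(w$dfof, w$params, fluorescence_params(phi)))
    abs(pk - 260) / 260
  }, 0)
  expect_lt(max(abs(errs - errs[2])), 1e-3)
})

test_that("small-signal inversion is linear in the input amplitude", {
  w1 <- wt_dfof(peak = 0.5)
  w2 <- wt_dfof(peak = 1)
  p1 <- peak_flux(flux_from_dfof(w1$dfof, w1$params))
  p2 <- peak_flux(flux_from_dfof(w2$dfof, w2$params))
  expect_lt(abs(p2 / p1 - 2), 2 * 0.005)
})

test_that("recovered peak flux is unbiased under realistic optical noise", {
  w <- wt_dfof()
  pks <- vapply(1:5, function(s) {
    noisy <- add_noise(w$dfof, noise_spec(0.005, seed = 100 + s))
    peak_flux(flux_from_dfof(noisy, w$params))
  }, 0)
  expect_lt(abs(mean(pks) - 260) / 260, 0.05)
})

test_that("peak_flux respects windows and validity flags", {
  x <- time_series(rep(3.5, 100), dt = 1)
  expect_equal(peak_flux(x), 3.5)
  sh <- flux_shape(120, 1, alpha_rise_for_fdhm(2))
  fl <- make_flux_waveform(sh, 20, dt = 0.03)
  # analytic peak falls between samples: interpolation error only
  expect_lt(abs(peak_flux(fl) - 120) / 120, 5e-4)
  expect_error(peak_flux(x, c(500, 600)), "empty window")
  expect_equal(peak_flux(x, c(10, 20)), 3.5)
})

test_that("negative-flux handling warns but does not clamp by default", {
  # a dF/F decay only slightly slower than the dye off-rate implies a tiny
  # positive free Ca but a strongly negative total-Ca rate
  t <- seq(0, 12, by = 0.03)
  rise <- exp(-pmax(3 - t, 0)^2)
  fall <- ifelse(t > 3, exp(-(t - 3) * 7.5), 1)
  d <- time_series(0.4 * rise * fall, dt = 0.03)
  expect_warning(R <- flux_from_dfof(d, default_params(), negative_tol = 5),
                 "flux")
  expect_lt(min(R$values), 0)
  Rc <- suppressWarnings(flux_from_dfof(d, default_params(),
                                        clamp_negative = TRUE, negative_tol = 5))
  expect_gte(min(Rc$values), 0)
})
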