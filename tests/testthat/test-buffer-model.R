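test_that("default parameter set carries the printed buffer constants", {
  p <- default_params()
  eg <- p$buffers$egta
  expect_equal(eg$total, 30000)
  expect_equal(eg$ca$kon, 0.0105)
  expect_equal(eg$ca$koff, 0.00075)
  expect_equal(eg$ca$kd, 0.0714, tolerance = 1e-3)
  dye <- p$buffers$dye
  expect_equal(dye$total, 250)
  expect_equal(dye$ca$kon, 0.157)
  expect_equal(dye$ca$koff, 9.42)
  pv <- p$buffers$parvalbumin
  expect_equal(pv$total, 900)
  expect_equal(pv$mg$kon, 1.5e-5)
  expect_equal(pv$mg$koff, 0.003)
  expect_equal(p$buffers$troponin$ca$kon, 0.15)
  expect_equal(p$buffers$atp$mg$koff, 0.15)
  expect_null(p$buffers$atp$ca)       # ATP binds Mg only
  expect_null(p$buffers$egta$mg)
  expect_equal(p$ca_total, 15000)
  expect_equal(p$mg_total, 5000)
  expect_equal(p$ca_free_rest, 0.075)
  expect_equal(p$mg_free_rest, 150)
})

test_that("clamped equilibrium pins the resting free concentrations", {
  p <- default_params()
  eq <- equilibrium_state(p, "clamped")
  expect_equal(eq[["ca"]], 0.075)
  expect_equal(eq[["mg"]], 150)
  # detailed balance: every reaction individually at rest
  rates <- caflux:::reaction_rates(p, eq)
  expect_lt(max(abs(rates)), 1e-9)
  # implied totals are reported (they differ from the nominal totals)
  expect_true(is.list(attr(eq, "implied")))
})

test_that("EGTA-only system equilibrates at free Ca = Kd for 2:1 loading", {
  p <- compartment_params(
    list(egta = buffer_spec("egta", 30000, ca = rate_constants(0.0105, 0.00075))),
    ca_total = 15000, mg_total = 0, ca_free_rest = 0.075, mg_free_rest = 0)
  eq <- equilibrium_state(p, "solved")
  # bound:free EGTA is 1:1 up to the ~0.07 uM held free, so free Ca sits at
  # Kd to ~1e-5 relative
  expect_equal(eq[["ca"]], 0.00075 / 0.0105, tolerance = 1e-4)
})

test_that("solved equilibrium matches a grid-refinement oracle and brackets", {
  p <- default_params()
  eq <- equilibrium_state(p, "solved")
  expect_gt(eq[["ca"]], 0.060)
  expect_lt(eq[["ca"]], 0.080)
  expect_lt(attr(eq, "residual"), 1e-6)
  expect_lt(max(abs(caflux:::reaction_rates(p, eq))), 1e-9)
  orc <- grid_equilibrium_oracle(p)
  expect_equal(eq[["ca"]], orc$ca, tolerance = 1e-6)
  expect_equal(eq[["mg"]], orc$mg, tolerance = 1e-6)
})

test_that("equilibrium is a fixed point of the forward model over 1 s", {
  p <- default_params()
  eq <- equilibrium_state(p, "clamped")
  fl <- time_series(rep(0, 33334), dt = 0.03, units = "uM_per_ms")  # 1 s
  tr <- simulate_forward(p, fl, dt_out = 50)
  rel <- abs(sweep(tr$states, 2, as.numeric(eq)) /
               matrix(as.numeric(eq), nrow(tr$states), ncol(tr$states), byrow = TRUE))
  expect_lt(max(rel), 1e-6)
  d <- dfof_from_trajectory(tr)
  expect_lt(max(abs(d$values)), 1e-9)
})

test_that("a rectangular flux injects exactly its integral and conserves mass", {
  p <- default_params()
  v <- numeric(334)
  v[1:67] <- 260                         # ~2 ms at 260 uM/ms
  fl <- time_series(v, dt = 0.03, units = "uM_per_ms")
  tr <- simulate_forward(p, fl)
  nm <- colnames(tr$states)
  ca_tot <- tr$states[, "ca"] + rowSums(tr$states[, grepl("\\.ca$", nm)])
  mg_tot <- tr$states[, "mg"] + rowSums(tr$states[, grepl("\\.mg$", nm)])
  n <- length(tr$time)
  # injected Ca equals the flux integral at every sample, Mg is untouched
  expect_equal(ca_tot - ca_tot[1], tr$injected, tolerance = 1e-9)
  expect_lt(max(abs(ca_tot - ca_tot[1] - tr$injected)) / p$ca_total, 1e-6)
  expect_lt(max(abs(mg_tot - mg_tot[1])) / p$mg_total, 1e-6)
  # the sampled 2-ms rectangle carries ~520 uM
  expect_equal(tr$injected[n], 520, tolerance = 0.01)
})

test_that("stiff trajectory matches a micro-step explicit-Euler oracle", {
  p <- default_params()
  fl <- wt_alpha_flux(duration = 10)
  init <- equilibrium_state(p, "clamped")
  tr <- simulate_forward(p, fl, dt_out = 0.5)
  orc <- euler_oracle(p, fl$values, fl$dt, unclass(init), h = 1e-4, dt_out = 0.5)
  for (cn in colnames(tr$states)) {
    scale <- max(abs(orc[, cn]))
    expect_lt(max(abs(tr$states[, cn] - orc[, cn])) / scale, 1e-4)
  }
})

test_that("negative or inconsistent inputs are rejected", {
  expect_error(rate_constants(-1, 1), "kon")
  expect_error(buffer_spec("x", 100), "at least one")
  expect_error(fluorescence_params(phi = 1), "phi")
  p <- default_params()
  init <- equilibrium_state(p, "clamped")
  # a huge negative flux drives free Ca negative -> diagnostic abort
  fl <- time_series(rep(-5000, 200), dt = 0.03)
  expect_error(simulate_forward(p, fl, init), "negative state")
})

test_that("dye brightness model evaluates and inverts exactly", {
  # hand example: phi 5, D 250, CaD_rest 0.3, CaD 40 -> 4*39.7/251.2
  fl <- fluorescence_params(phi = 5)
  dye <- buffer_spec("dye", 250, ca = rate_constants(0.157, 9.42))
  traj <- structure(list(
    time = c(0, 1),
    states = cbind(ca = c(0.075, 1), mg = c(150, 150),
                   dye.ca = c(0.3, 40)),
    params = compartment_params(list(dye = dye), 15000, 5000, 0.075, 150)),
    class = "compartment_trajectory")
  d <- dfof_from_trajectory(traj, fl)
  expect_equal(d$values[2], 4 * 39.7 / (250 + 4 * 0.3), tolerance = 1e-12)
  expect_equal(d$values[1], 0)
  # phi -> 1+ kills the signal
  d1 <- dfof_from_trajectory(traj, fluorescence_params(phi = 1 + 1e-9))
  expect_lt(max(abs(d1$values)), 1e-9)
})
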