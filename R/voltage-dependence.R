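#' Voltage-clamp step protocol
#'
#' @param holding holding potential, mV (default -90).
#' @param step_amplitudes step amplitudes relative to holding, mV (default
#'   -20 to 180 in 10-mV increments, i.e. absolute potentials -110 to +90).
#' @param pulse_ms pulse duration, ms (default 20).
#' @param pre_ms,post_ms pre- and post-pulse record time, ms.
#' @param dt sampling interval, ms.
#' @return list of class `voltage_clamp_protocol`.
#' @export
voltage_clamp_protocol <- function(holding = -90,
                                   step_amplitudes = seq(-20, 180, by = 10),
                                   pulse_ms = 20, pre_ms = 10, post_ms = 30,
                                   dt = 0.03) {
  stopifnot(pulse_ms > 0, length(step_amplitudes) >= 1)
  if (length(step_amplitudes) > 1 &&
      stats::var(diff(step_amplitudes)) > 1e-12)
    stop("step amplitudes must be uniformly spaced")
  structure(list(holding = holding, step_amplitudes = step_amplitudes,
                 pulse_ms = pulse_ms, pre_ms = pre_ms, post_ms = post_ms,
                 dt = dt), class = "voltage_clamp_protocol")
}

#' Boltzmann activation parameters
#'
#' The increasing two-state sigmoid
#' \deqn{\Delta F/F(V) = \Delta F/F_{max} / (1 + e^{(V_{1/2} - V)/k}),}
#' i.e. release grows with depolarization, is half-maximal at `v_half` and
#' changes e-fold over `k` millivolts. (The decreasing-sign variant
#' sometimes printed, with `(V - V_half)/k` in the exponent, describes the
#' same data only after flipping the sign of k; the increasing convention
#' is used throughout this package so that `k > 0`.)
#'
#' @param dfof_max maximal dF/F (>= 0; zero describes a flat family and is
#'   accepted for curve generation, while [fit_boltzmann()] always returns
#'   a positive amplitude).
#' @param v_half midpoint voltage, mV.
#' @param k slope factor, mV (> 0).
#' @param rss residual sum of squares of a fit (optional).
#' @return list of class `boltzmann_fit`.
#' @export
boltzmann_fit <- function(dfof_max, v_half, k, rss = NA_real_) {
  stopifnot(dfof_max >= 0, k > 0)
  structure(list(dfof_max = dfof_max, v_half = v_half, k = k, rss = rss),
            class = "boltzmann_fit")
}

#' Evaluate a Boltzmann curve
#'
#' @param fit [boltzmann_fit()].
#' @param v voltages, mV.
#' @return dF/F values.
#' @export
boltzmann_value <- function(fit, v) {
  fit$dfof_max / (1 + exp((fit$v_half - v) / fit$k))
}

#' Peak and steady-state dF/F of one voltage-clamp sweep
#'
#' Peak = maximum dF/F within the pulse; steady = mean over the final 25%
#' of the pulse (the sweep has relaxed to its maintained level there).
#'
#' @param dfof [time_series()] of one sweep.
#' @param pulse_window numeric `c(start, end)` of the pulse, ms.
#' @return list `peak`, `steady`, `peak_time` (ms), `edge_peak` (`TRUE` if
#'   the maximum sits on the first/last sample of the window, which usually
#'   means the pulse window is wrong).
#' @export
extract_peak_and_steady <- function(dfof, pulse_window) {
  stopifnot(inherits(dfof, "time_series"), length(pulse_window) == 2)
  tt <- ts_time(dfof)
  w <- tt > pulse_window[1] & tt <= pulse_window[2]
  if (!any(w)) stop("pulse window outside trace")
  iw <- which(w)
  ipk <- iw[which.max(dfof$values[iw])]
  steady_from <- pulse_window[2] - 0.25 * diff(pulse_window)
  ws <- tt > steady_from & tt <= pulse_window[2]
  list(peak = dfof$values[ipk],
       steady = mean(dfof$values[ws]),
       peak_time = tt[ipk],
       edge_peak = ipk == iw[1] || ipk == iw[length(iw)])
}

# variable projection: dfof_max is linear given (v_half, k)
boltz_rss <- function(par, v, y, wts) {
  vh <- par[1]; k <- exp(par[2])
  b <- 1 / (1 + exp((vh - v) / k))
  amp <- sum(wts * y * b) / sum(wts * b^2)
  sum(wts * (y - amp * b)^2)
}

#' Fit a Boltzmann activation curve
#'
#' Least-squares fit of the increasing sigmoid
#' `y = dfof_max / (1 + exp((v_half - V)/k))`. The amplitude enters
#' linearly and is projected out; the optimization runs over
#' `(v_half, log k)` from a deterministic multi-start grid of `v_half`
#' values spanning the sampled voltage range.
#'
#' @param v voltages, mV (>= 4 distinct values spanning the transition).
#' @param y dF/F values (same length).
#' @param weights optional nonnegative weights.
#' @return [boltzmann_fit()] with `rss`, plus attribute `saturated`
#'   (`FALSE` if the data do not approach the fitted maximum, flagging an
#'   unconstrained `dfof_max`).
#' @export
fit_boltzmann <- function(v, y, weights = NULL) {
  stopifnot(length(v) == length(y))
  if (length(unique(v)) < 4) stop("need >= 4 distinct voltages")
  wts <- if (is.null(weights)) rep(1, length(v)) else weights
  ks <- c(2, 5, 10, 20, 40)
  vhs <- seq(min(v), max(v), length.out = 7)
  best <- NULL
  for (k0 in ks) for (vh0 in vhs) {
    op <- stats::optim(c(vh0, log(k0)), boltz_rss, v = v, y = y, wts = wts,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || op$value < best$value) best <- op
  }
  vh <- best$par[1]; k <- exp(best$par[2])
  b <- 1 / (1 + exp((vh - v) / k))
  amp <- sum(wts * y * b) / sum(wts * b^2)
  if (amp <= 0) stop("fit converged to a nonpositive amplitude")
  fit <- boltzmann_fit(amp, vh, k, rss = best$value)
  # saturation: the largest sampled voltage should reach >= 90% of max
  attr(fit, "saturated") <- max(b) >= 0.90
  fit
}

#' Compare two populations of Boltzmann fits
#'
#' Per-parameter mean, SEM and pooled-variance two-sample t test between
#' two groups of fits (e.g. genotypes), plus normalized curves
#' (`y/dfof_max`) for overlay plots.
#'
#' @param fits_a,fits_b lists of [boltzmann_fit()] (>= 2 each).
#' @param v_grid voltages at which normalized overlay curves are evaluated.
#' @return list of class `boltzmann_comparison`: `table` (data.frame with
#'   mean/SEM per group and t/p per parameter), `normalized` (data.frame
#'   `v`, `mean_a`, `mean_b` of the normalized curves).
#' @export
compare_populations <- function(fits_a, fits_b,
                                v_grid = seq(-110, 90, by = 2)) {
  stopifnot(length(fits_a) >= 2, length(fits_b) >= 2)
  get <- function(fits, f) vapply(fits, `[[`, 0, f)
  pars <- c("dfof_max", "v_half", "k")
  rows <- lapply(pars, function(p) {
    a <- get(fits_a, p); b <- get(fits_b, p)
    tst <- two_sample_t(a, b)
    data.frame(parameter = p,
               mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)),
               mean_b = mean(b), sem_b = sd(b) / sqrt(length(b)),
               t = tst$t, p = tst$p)
  })
  norm_curves <- function(fits) {
    rowMeans(vapply(fits, function(f)
      boltzmann_value(f, v_grid) / f$dfof_max, numeric(length(v_grid))))
  }
  structure(list(table = do.call(rbind, rows),
                 normalized = data.frame(v = v_grid,
                                         mean_a = norm_curves(fits_a),
                                         mean_b = norm_curves(fits_b))),
            class = "boltzmann_comparison")
}
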