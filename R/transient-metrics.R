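#' Fractional fluorescence change from a raw fluorescence record
#'
#' dF/F(t) = (F(t) - F0)/F0 with F0 the mean over a pre-stimulus baseline
#' window.
#'
#' @param raw_f [time_series()] of raw fluorescence (arbitrary units > 0).
#' @param baseline_window numeric `c(from, to)` in ms; must precede the
#'   stimulus.
#' @return [time_series()] of dF/F.
#' @export
compute_dfof <- function(raw_f, baseline_window) {
  stopifnot(inherits(raw_f, "time_series"), length(baseline_window) == 2)
  f0 <- mean(ts_window(raw_f, baseline_window[1], baseline_window[2])$values)
  if (!is.finite(f0) || f0 <= 0) stop("nonpositive baseline fluorescence")
  time_series((raw_f$values - f0) / f0, raw_f$dt, raw_f$t0, units = "dfof")
}

# full duration at half maximum by linear interpolation, baseline 0
fdhm_of <- function(values, dt, t0 = 0) {
  ipk <- which.max(values)
  half <- values[ipk] / 2
  if (ipk == 1L || ipk == length(values)) stop("peak at trace edge")
  below_l <- which(values[seq_len(ipk)] < half)
  below_r <- which(values[ipk:length(values)] < half)
  if (!length(below_l) || !length(below_r))
    stop("half-maximum level not crossed on both sides")
  i <- rev(below_l)[1]                    # last sample below half before peak
  tl <- i + (half - values[i]) / (values[i + 1] - values[i])
  j <- ipk + below_r[1] - 1L              # first sample below half after peak
  tr <- (j - 1) + (half - values[j - 1]) / (values[j] - values[j - 1])
  (tr - tl) * dt
}

#' Morphological metrics of a single AP-evoked transient
#'
#' @param dfof [time_series()] of baseline-corrected dF/F.
#' @param ap [time_series()] of membrane potential (mV) on the same time
#'   base (action potential that triggered the transient).
#' @param onset_threshold AP onset criterion: first crossing of
#'   dV/dt >= this many mV/ms (default 10).
#' @param signal_frac latency criterion: dF/F exceeding this fraction of its
#'   peak (default 0.05) marks signal onset.
#' @param fit_decay if `TRUE` (default) a double-exponential is fitted to
#'   the decay (from the sample after the peak to the end of the sweep).
#' @return list of class `transient_metrics`: `peak` (dF/F), `time_to_peak`
#'   and `latency` (ms from AP onset), `fdhm` (ms), `ap_onset` (ms), `decay`
#'   ([fit_double_exponential()] result or `NULL`).
#' @export
measure_transient <- function(dfof, ap, onset_threshold = 10,
                              signal_frac = 0.05, fit_decay = TRUE) {
  stopifnot_same_base(dfof, ap)
  dvdt <- diff(ap$values) / ap$dt
  icross <- which(dvdt >= onset_threshold)
  if (!length(icross)) stop("no AP onset found (dV/dt never reached ",
                            onset_threshold, " mV/ms)")
  t_onset <- ts_time(ap)[icross[1]]

  tt <- ts_time(dfof)
  ipk <- which.max(dfof$values)
  if (ipk == 1L || ipk == length(dfof$values)) stop("dF/F peak at trace edge")
  peak <- dfof$values[ipk]
  after <- which(tt >= t_onset & dfof$values >= signal_frac * peak)
  if (!length(after)) stop("signal never exceeded the onset fraction")
  i <- after[1]
  # linear interpolation of the threshold crossing
  thr <- signal_frac * peak
  t_sig <- if (i > 1 && dfof$values[i] > dfof$values[i - 1])
    tt[i - 1] + dfof$dt * (thr - dfof$values[i - 1]) /
      (dfof$values[i] - dfof$values[i - 1])
  else tt[i]

  decay <- NULL
  if (fit_decay && length(dfof$values) - ipk >= 50)
    decay <- fit_double_exponential(
      time_series(dfof$values[(ipk + 1):length(dfof$values)], dfof$dt,
                  t0 = 0, units = dfof$units))
  structure(list(peak = peak,
                 time_to_peak = tt[ipk] - t_onset,
                 latency = t_sig - t_onset,
                 fdhm = fdhm_of(dfof$values, dfof$dt),
                 ap_onset = t_onset,
                 decay = decay),
            class = "transient_metrics")
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf("<transient_metrics> peak dF/F %.3f, latency %.2f ms, time-to-peak %.2f ms, FDHM %.2f ms\n",
              x$peak, x$latency, x$time_to_peak, x$fdhm))
  if (!is.null(x$decay))
    cat(sprintf("  decay: A1 %.3f tau1 %.2f ms | A2 %.3f tau2 %.2f ms (offset %.4f)\n",
                x$decay$a1, x$decay$tau1, x$decay$a2, x$decay$tau2, x$decay$offset))
  invisible(x)
}

# variable-projection residual: amplitudes (and offset) are linear given taus
dblexp_rss <- function(ltau, t, y, fix_offset) {
  B <- cbind(exp(-t / exp(ltau[1])), exp(-t / exp(ltau[2])))
  if (!fix_offset) B <- cbind(B, 1)
  fit <- stats::lm.fit(B, y)
  sum(fit$residuals^2)
}

#' Double-exponential fit of a transient decay
#'
#' Fits \eqn{y(t) = y_0 + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}} by
#' nonlinear least squares. The amplitudes and offset enter linearly, so the
#' optimization runs over \eqn{(\log\tau_1, \log\tau_2)} only (variable
#' projection), started from a fixed, deterministic log-spaced grid of tau
#' pairs to avoid the well-known local minima of sums of exponentials.
#' Components are returned fast-first (`tau1 <= tau2`).
#'
#' @param decay [time_series()] beginning at/after the transient peak;
#'   needs >= 50 samples. Time is measured from the first sample.
#' @param fix_offset if `TRUE` the offset is fixed at 0.
#' @return list of class `double_exp_fit`: `a1`, `tau1` (ms), `a2`, `tau2`
#'   (ms), `offset`, `rss`, `degenerate` (`TRUE` if the two taus agree
#'   within 1%, i.e. the fit collapsed to a single exponential).
#' @export
fit_double_exponential <- function(decay, fix_offset = FALSE) {
  stopifnot(inherits(decay, "time_series"))
  y <- decay$values
  n <- length(y)
  if (n < 50) stop("decay segment too short (need >= 50 samples)")
  t <- decay$dt * (seq_len(n) - 1)
  span <- t[n]

  grid <- exp(seq(log(max(2 * decay$dt, span / 2000)), log(span), length.out = 6))
  starts <- expand.grid(t1 = grid, t2 = grid)
  starts <- starts[starts$t1 < starts$t2, ]
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    op <- stats::optim(log(c(starts$t1[k], starts$t2[k])), dblexp_rss,
                       t = t, y = y, fix_offset = fix_offset,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 3000))
    if (is.null(best) || op$value < best$value) best <- op
  }
  ltau <- best$par
  taus <- exp(ltau)
  B <- cbind(exp(-t / taus[1]), exp(-t / taus[2]))
  if (!fix_offset) B <- cbind(B, 1)
  cf <- stats::lm.fit(B, y)$coefficients
  ord <- order(taus)
  out <- list(a1 = unname(cf[ord[1]]), tau1 = taus[ord[1]],
              a2 = unname(cf[ord[2]]), tau2 = taus[ord[2]],
              offset = if (fix_offset) 0 else unname(cf[3]),
              rss = best$value,
              degenerate = abs(taus[1] / taus[2] - 1) < 0.01)
  class(out) <- "double_exp_fit"
  out
}

#' Fraction of the decay carried by the fast component
#'
#' @param fit a [fit_double_exponential()] result.
#' @return `a1 / (a1 + a2)`, dimensionless.
#' @export
fast_fraction <- function(fit) {
  stopifnot(inherits(fit, "double_exp_fit"))
  tot <- fit$a1 + fit$a2
  if (tot <= 0) stop("zero total amplitude")
  fit$a1 / tot
}
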