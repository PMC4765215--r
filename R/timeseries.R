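#' Uniformly sampled time series
#'
#' The backbone container for every signal handled by caflux: fluorescence
#' (dF/F), membrane potential (mV), free concentrations (uM) and release
#' fluxes (uM/ms). Sampling is uniform; the package-wide default sampling
#' interval is 0.03 ms (30 us per point, the digitization rate of the
#' acquisition chain the synthetic generator emulates).
#'
#' @param values numeric vector of samples (length >= 2).
#' @param dt sampling interval in ms (> 0).
#' @param t0 time of the first sample in ms.
#' @param units unit tag, one of `"dfof"`, `"mV"`, `"uM"`, `"uM_per_ms"` or
#'   any other short label; purely descriptive but preserved by I/O.
#' @return An object of class `time_series`: a list with elements `values`,
#'   `dt`, `t0`, `units`.
#' @examples
#' ts <- time_series(sin(seq(0, 1, length.out = 100)), dt = 0.03)
#' head(ts_time(ts))
#' @export
time_series <- function(values, dt, t0 = 0, units = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("time_series needs at least 2 samples")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number (ms)")
  structure(list(values = values, dt = dt, t0 = t0, units = units),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples, dt = %g ms, t0 = %g ms, units = '%s'\n",
              length(x$values), x$dt, x$t0, x$units))
  cat(sprintf("  range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

#' Time axis of a time series
#'
#' @param ts a [time_series()].
#' @return numeric vector of sample times in ms.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$t0 + ts$dt * (seq_along(ts$values) - 1)
}

#' Extract a sub-window of a time series
#'
#' @param ts a [time_series()].
#' @param from,to window limits in ms (inclusive).
#' @return a [time_series()] restricted to samples with `from <= t <= to`.
#' @export
ts_window <- function(ts, from = -Inf, to = Inf) {
  tt <- ts_time(ts)
  keep <- tt >= from - 1e-12 & tt <= to + 1e-12
  if (!any(keep)) stop("empty window [", from, ", ", to, "] ms")
  time_series(ts$values[keep], ts$dt, t0 = tt[which(keep)[1]], units = ts$units)
}

stopifnot_same_base <- function(a, b) {
  if (abs(a$dt - b$dt) > 1e-12 || abs(a$t0 - b$t0) > 1e-9 ||
      length(a$values) != length(b$values))
    stop("time series do not share a time base")
  invisible(TRUE)
}
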