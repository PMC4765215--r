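#' Tetanic stimulation protocol
#'
#' @param frequency stimulation frequency, Hz (10/20/50/100 typical).
#' @param duration_ms train duration, ms (default 1000 = the standard 1-s
#'   train). Pulse count is `round(frequency * duration_ms / 1000)`.
#' @param pulse_width_ms current pulse width, ms (metadata; default 0.5).
#' @param start_ms time of the first stimulus, ms (default 20, leaving a
#'   pre-train baseline).
#' @param dt sampling interval of generated records, ms.
#' @param tail_ms record time kept after the last stimulus, ms.
#' @return list of class `train_protocol` with `stimulus_times` (ms,
#'   strictly increasing).
#' @export
train_protocol <- function(frequency, duration_ms = 1000,
                           pulse_width_ms = 0.5, start_ms = 20, dt = 0.03,
                           tail_ms = 60) {
  stopifnot(frequency > 0, duration_ms > 0)
  n <- round(frequency * duration_ms / 1000)
  if (n < 1) stop("protocol contains no stimuli")
  structure(list(frequency = frequency, duration_ms = duration_ms,
                 pulse_width_ms = pulse_width_ms,
                 stimulus_times = start_ms + (seq_len(n) - 1) * 1000 / frequency,
                 start_ms = start_ms, dt = dt, tail_ms = tail_ms),
            class = "train_protocol")
}

#' Peak and inter-pulse envelopes of a tetanic dF/F record
#'
#' For each stimulus i: the *peak* value is the maximum dF/F within
#' `(t_i, t_i + min(inter-pulse interval, 10 ms)]`; the *inter-pulse* value
#' is the minimum dF/F in the 1-ms window ending at `t_i` (the pre-stimulus
#' fluorescence the next transient rides on). Envelopes are
#' monotonicity-preserving piecewise-cubic interpolants through these
#' anchor points, and the per-pulse amplitude is their difference at each
#' stimulus: `amp[i] = peak[i] - inter[i]`.
#'
#' @param dfof [time_series()] covering the whole train plus a pre-train
#'   baseline.
#' @param protocol [train_protocol()].
#' @return list of class `train_envelopes`: `peak_env`, `interpulse_env`
#'   ([time_series()] spanning the train), `per_pulse_amp`, `peak_values`,
#'   `interpulse_values`, `stimulus_times`.
#' @export
compute_envelopes <- function(dfof, protocol) {
  stopifnot(inherits(dfof, "time_series"), inherits(protocol, "train_protocol"))
  st <- protocol$stimulus_times
  tt <- ts_time(dfof)
  if (st[1] < tt[1] + 1 || max(st) > max(tt))
    stop("stimulus times outside trace (need >= 1 ms pre-train baseline)")
  ipi <- if (length(st) > 1) min(diff(st)) else Inf
  win <- min(ipi, 10)
  n <- length(st)
  peak_v <- inter_v <- numeric(n)
  for (i in seq_len(n)) {
    in_peak <- tt > st[i] & tt <= st[i] + win
    in_pre  <- tt >= st[i] - 1 & tt <= st[i]
    if (!any(in_peak) || !any(in_pre)) stop("empty measurement window at pulse ", i)
    peak_v[i]  <- max(dfof$values[in_peak])
    inter_v[i] <- min(dfof$values[in_pre])
  }
  span <- tt >= st[1] - 1 & tt <= max(st) + win
  tspan <- tt[span]
  pe <- stats::splinefun(st, peak_v, method = "monoH.FC")(tspan)
  ie <- stats::splinefun(st, inter_v, method = "monoH.FC")(tspan)
  structure(list(
    peak_env = time_series(pe, dfof$dt, t0 = tspan[1], units = dfof$units),
    interpulse_env = time_series(ie, dfof$dt, t0 = tspan[1], units = dfof$units),
    per_pulse_amp = peak_v - inter_v,
    peak_values = peak_v, interpulse_values = inter_v,
    stimulus_times = st), class = "train_envelopes")
}

#' Last-to-first per-pulse amplitude ratio of a train
#'
#' Quantifies how well release is sustained along a tetanus: 1 means no
#' depression, values < 1 a depressing train. Invariant to uniform scaling
#' of the fluorescence and to DC offsets (both envelopes shift together).
#'
#' @param env [compute_envelopes()] result.
#' @return `per_pulse_amp[last] / per_pulse_amp[first]`.
#' @export
first_last_ratio <- function(env) {
  stopifnot(inherits(env, "train_envelopes"))
  amp <- env$per_pulse_amp
  if (length(amp) < 2) stop("need >= 2 pulses")
  if (amp[1] <= 0) stop("zero first-pulse amplitude")
  amp[length(amp)] / amp[1]
}

#' Electrical metrics of a tetanic voltage record
#'
#' AP amplitudes are spike peaks minus the pre-train baseline (mean of the
#' 5 ms before the first stimulus); the end-of-train depolarization is the
#' minimum potential in the final inter-pulse interval minus that baseline.
#' One spike per stimulus is enforced: a local maximum above `spike_floor`
#' must exist in each stimulus window.
#'
#' @param vm [time_series()] of membrane potential, mV.
#' @param protocol [train_protocol()].
#' @param spike_floor minimum potential (mV) a spike peak must exceed
#'   (default -20).
#' @return list of class `train_electrical_metrics`: `first_ap_amp`,
#'   `last_ap_amp`, `end_depolarization` (mV), `baseline` (mV),
#'   `ap_amplitudes` (all pulses).
#' @export
train_electrical_metrics <- function(vm, protocol, spike_floor = -20) {
  stopifnot(inherits(vm, "time_series"), inherits(protocol, "train_protocol"))
  st <- protocol$stimulus_times
  tt <- ts_time(vm)
  base_win <- tt >= st[1] - 5 & tt < st[1]
  if (!any(base_win)) stop("no pre-train baseline available")
  baseline <- mean(vm$values[base_win])
  ipi <- if (length(st) > 1) min(diff(st)) else 10
  amps <- numeric(length(st))
  missing <- integer(0)
  for (i in seq_along(st)) {
    w <- tt >= st[i] & tt < st[i] + ipi
    pk <- max(vm$values[w])
    if (!is.finite(pk) || pk < spike_floor) missing <- c(missing, i)
    amps[i] <- pk - baseline
  }
  if (length(missing))
    stop("missing spikes at stimuli: ", paste(missing, collapse = ", "))
  n <- length(st)
  final_ipi <- tt >= st[n] - ipi & tt < st[n]
  structure(list(first_ap_amp = amps[1], last_ap_amp = amps[n],
                 end_depolarization = min(vm$values[final_ipi]) - baseline,
                 baseline = baseline, ap_amplitudes = amps),
            class = "train_electrical_metrics")
}
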