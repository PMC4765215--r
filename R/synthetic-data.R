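#' Noise specification for synthetic traces
#'
#' Additive Gaussian noise, optionally low-pass filtered to mimic the
#' analog signal conditioning of the acquisition chain (optical channels
#' 2 kHz, voltage 10 kHz). `rms` is the standard deviation of the white
#' noise before filtering.
#'
#' @param rms noise SD in trace units (>= 0).
#' @param seed integer seed; all generator randomness flows through
#'   explicit seeds and never touches the global RNG state.
#' @param cutoff_khz low-pass cutoff in kHz; `Inf` for unfiltered noise.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(rms, seed = 1L, cutoff_khz = 2) {
  stopifnot(rms >= 0, cutoff_khz > 0)
  structure(list(rms = rms, seed = as.integer(seed), cutoff_khz = cutoff_khz),
            class = "noise_spec")
}

# 4th-order Bessel low-pass (two biquads via bilinear transform with
# prewarping). Poles of the 3dB-normalized analog prototype.
bessel4_lowpass <- function(x, dt, cutoff_khz) {
  if (!is.finite(cutoff_khz)) return(x)
  wc <- 2 * pi * cutoff_khz                      # rad/ms
  if (wc * dt / 2 >= pi / 2 * 0.999) return(x)   # at/above Nyquist: no-op
  K <- 2 / dt
  wa <- K * tan(wc * dt / 2)                     # prewarped analog cutoff
  poles <- list(complex(real = -1.3700678305514764, imaginary = 0.41024971749375255),
                complex(real = -0.9952087643502621, imaginary = 1.2571057394546674))
  for (p in poles) {
    b1 <- -2 * Re(p) * wa
    b0 <- Mod(p)^2 * wa^2
    a0 <- K^2 + b1 * K + b0
    a1 <- 2 * (b0 - K^2)
    a2 <- K^2 - b1 * K + b0
    num <- b0 * (x + 2 * c(x[1], x[-length(x)]) +
                   c(x[1], x[1], x[-((length(x) - 1):length(x))])) / a0
    x <- as.numeric(stats::filter(num, c(-a1 / a0, -a2 / a0), method = "recursive",
                                  init = c(x[1], x[1])))
  }
  x
}

#' Add (filtered) Gaussian noise to a trace
#'
#' @param trace [time_series()].
#' @param spec [noise_spec()].
#' @return [time_series()] with noise added; bitwise-reproducible for a
#'   given seed, identity for `rms = 0`.
#' @export
add_noise <- function(trace, spec) {
  stopifnot(inherits(trace, "time_series"), inherits(spec, "noise_spec"))
  if (spec$rms == 0) return(trace)
  eps <- with_seed(spec$seed, function() rnorm(length(trace$values), 0, spec$rms))
  eps <- bessel4_lowpass(eps, trace$dt, spec$cutoff_khz)
  time_series(trace$values + eps, trace$dt, trace$t0, trace$units)
}

#' Seeded draws from a normal law
#'
#' @param mean,sd population parameters.
#' @param n sample size.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
make_gaussian_population <- function(mean, sd, n, seed) {
  with_seed(seed, function() rnorm(n, mean, sd))
}

# ---- release flux waveforms ----------------------------------------------

#' Parametric SR release flux waveform
#'
#' @param peak peak flux, uM/ms.
#' @param latency delay before the waveform starts, ms.
#' @param rise_tau rise time constant, ms. For the alpha shape this is also
#'   the time from onset to peak.
#' @param decay_tau decay time constant, ms (dual-exponential shape only).
#' @param shape `"alpha"` (\eqn{x e^{1-x}}, x = t/rise_tau) or
#'   `"dual-exponential"` (difference of exponentials, normalized so the
#'   analytic maximum equals `peak` exactly).
#' @return list of class `flux_shape`.
#' @export
flux_shape <- function(peak, latency = 0, rise_tau = 0.8175,
                       decay_tau = 1.5, shape = c("alpha", "dual-exponential")) {
  shape <- match.arg(shape)
  stopifnot(peak >= 0, latency >= 0, rise_tau > 0, decay_tau > 0)
  if (shape == "dual-exponential" && decay_tau <= rise_tau)
    stop("dual-exponential shape needs decay_tau > rise_tau")
  structure(list(peak = peak, latency = latency, rise_tau = rise_tau,
                 decay_tau = decay_tau, shape = shape), class = "flux_shape")
}

# unit-peak waveform evaluated at times s >= 0 from onset
flux_unit <- function(shape, s) {
  switch(shape$shape,
    "alpha" = {
      x <- s / shape$rise_tau
      ifelse(s <= 0, 0, x * exp(1 - x))
    },
    "dual-exponential" = {
      tr <- shape$rise_tau; td <- shape$decay_tau
      tpk <- log(td / tr) * tr * td / (td - tr)
      norm <- exp(-tpk / td) - exp(-tpk / tr)
      ifelse(s <= 0, 0, (exp(-s / td) - exp(-s / tr)) / norm)
    })
}

#' Closed-form FDHM of a parametric flux waveform
#'
#' Solves the half-maximum crossings of the unit shape analytically (1-D
#' root finds on the exact expression, not on samples).
#'
#' @param shape [flux_shape()].
#' @return full duration at half maximum, ms.
#' @export
flux_fdhm <- function(shape) {
  tpk <- switch(shape$shape,
    "alpha" = shape$rise_tau,
    "dual-exponential" = with(shape, log(decay_tau / rise_tau) *
                                rise_tau * decay_tau / (decay_tau - rise_tau)))
  f <- function(s) flux_unit(shape, s) - 0.5
  left  <- stats::uniroot(f, c(1e-12, tpk), tol = 1e-13)$root
  hi <- tpk * 2
  while (f(hi) > 0) hi <- hi * 2
  right <- stats::uniroot(f, c(tpk, hi), tol = 1e-13)$root
  right - left
}

#' Alpha-shape rise time for a requested FDHM
#'
#' The alpha function \eqn{x e^{1-x}} crosses half-maximum at fixed
#' abscissae x1, x2 (roots of \eqn{x e^{1-x} = 1/2}), so
#' `rise_tau = fdhm / (x2 - x1)`.
#'
#' @param fdhm requested full duration at half maximum, ms.
#' @return rise_tau in ms.
#' @export
alpha_rise_for_fdhm <- function(fdhm) {
  f <- function(x) x * exp(1 - x) - 0.5
  x1 <- stats::uniroot(f, c(1e-12, 1), tol = 1e-14)$root
  x2 <- stats::uniroot(f, c(1, 20), tol = 1e-14)$root
  fdhm / (x2 - x1)
}

#' Sampled release-flux waveform
#'
#' @param shape [flux_shape()].
#' @param duration record length, ms (must exceed the latency).
#' @param dt sampling interval, ms (default 0.03).
#' @return [time_series()] in uM/ms whose maximum equals `shape$peak` at
#'   the analytic peak time (the peak sample hits it exactly when the peak
#'   time is a multiple of dt).
#' @export
make_flux_waveform <- function(shape, duration, dt = 0.03) {
  stopifnot(inherits(shape, "flux_shape"), duration > shape$latency)
  t <- seq(0, duration, by = dt)
  time_series(shape$peak * flux_unit(shape, t - shape$latency), dt,
              units = "uM_per_ms")
}

# ---- action potentials and dF/F transient kernels ------------------------

#' Parametric action potential waveform
#'
#' A dual-exponential spike: fast rise, slower repolarization, no
#' biophysical channel model (the metrics operations only need the
#' morphology).
#'
#' @param baseline resting potential, mV (default -90).
#' @param amplitude spike amplitude above baseline, mV (default 130).
#' @param rise_tau rise time constant, ms.
#' @param fdhm requested spike FDHM, ms (default 2.3); the decay time
#'   constant is solved to match it.
#' @return list of class `ap_shape` (with the solved `decay_tau`).
#' @export
ap_shape <- function(baseline = -90, amplitude = 130, rise_tau = 0.3,
                     fdhm = 2.3) {
  stopifnot(amplitude > 0, rise_tau > 0, fdhm > 0)
  f <- function(td) flux_fdhm(flux_shape(1, 0, rise_tau, td,
                                         "dual-exponential")) - fdhm
  lo <- rise_tau * 1.05; hi <- rise_tau * 2
  while (f(hi) < 0) hi <- hi * 2
  decay_tau <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  structure(list(baseline = baseline, amplitude = amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau, fdhm = fdhm),
            class = "ap_shape")
}

# unit AP spike at time s from onset: dual-exponential with a quartic
# taper so repolarization is complete (< 1e-3) by ~10 ms, letting spikes
# in 100-Hz trains return to baseline between stimuli
ap_unit <- function(shape, s) {
  fs <- flux_shape(1, 0, shape$rise_tau, shape$decay_tau, "dual-exponential")
  flux_unit(fs, s) * ifelse(s > 0, exp(-(s / 7)^4), 1)
}

#' Sampled action potential waveform
#'
#' @param shape [ap_shape()].
#' @param duration record length, ms.
#' @param dt sampling interval, ms.
#' @param onset spike onset time, ms.
#' @return [time_series()] in mV.
#' @export
make_ap_waveform <- function(shape, duration, dt = 0.03, onset = 0) {
  t <- seq(0, duration, by = dt)
  v <- shape$baseline + shape$amplitude * ap_unit(shape, t - onset)
  time_series(v, dt, units = "mV")
}

#' dF/F transient kernel with prescribed morphology
#'
#' A parametric single-transient shape: quartic-exponential rise (so the
#' signal leaves baseline sharply, as AP-evoked transients do) and a
#' double-exponential decay. The internal rise width and fast decay time
#' are solved so that the kernel's 5%-of-peak onset, peak time and FDHM
#' match the requested values exactly.
#'
#' @param peak peak dF/F.
#' @param latency time from t = 0 (the AP onset) to the 5%-of-peak
#'   crossing, ms.
#' @param time_to_peak time from t = 0 to the peak, ms.
#' @param fdhm full duration at half maximum, ms.
#' @param a1,a2 relative amplitudes of the fast and slow decay components
#'   (only their ratio matters for the shape).
#' @param tau2 slow decay time constant, ms.
#' @param duration,dt record length and sampling interval, ms.
#' @return [time_series()] of dF/F with attribute `truth` (the solved
#'   internal parameters: `sigma_rise`, `tau1`, plus all inputs).
#' @export
make_transient_kernel <- function(peak = 0.63, latency = 1.4,
                                  time_to_peak = 3, fdhm = 2,
                                  a1 = 0.63, a2 = 0.04, tau2 = 19,
                                  duration = 60, dt = 0.03) {
  stopifnot(latency < time_to_peak, fdhm > 0, a1 > 0, a2 >= 0, tau2 > 0)
  w1 <- a1 / (a1 + a2); w2 <- 1 - w1
  sigma <- (time_to_peak - latency) / log(20)^(1 / 4)
  left <- sigma * log(2)^(1 / 4)          # rise half-width
  right <- fdhm - left
  if (right <= 0)
    stop("fdhm too short for the requested latency/time_to_peak geometry")
  # solve fast tau so the decay crosses half-maximum at `right`
  g <- function(tau1) w1 * exp(-right / tau1) + w2 * exp(-right / tau2) - 0.5
  if (g(1e-4) > 0 || g(tau2) < 0)
    stop("no fast decay constant matches the requested fdhm")
  tau1 <- stats::uniroot(g, c(1e-4, tau2), tol = 1e-12)$root
  t <- seq(0, duration, by = dt)
  y <- ifelse(t <= time_to_peak,
              exp(-((time_to_peak - t) / sigma)^4),
              w1 * exp(-(t - time_to_peak) / tau1) +
                w2 * exp(-(t - time_to_peak) / tau2))
  out <- time_series(peak * y, dt, units = "dfof")
  attr(out, "truth") <- list(peak = peak, latency = latency,
                             time_to_peak = time_to_peak, fdhm = fdhm,
                             sigma_rise = sigma, tau1 = tau1, tau2 = tau2,
                             w1 = w1, w2 = w2)
  out
}

# ---- tetanic trains ------------------------------------------------------

#' Synthetic tetanic train (membrane potential + dF/F)
#'
#' The dF/F train is built by superposing a single-transient kernel scaled
#' per pulse, plus an explicit inter-pulse buildup term (fast path; a slow
#' path through [simulate_forward()] is available by inverting/re-simulating
#' but is not needed for envelope analysis). The membrane potential is a
#' spike train over a baseline that may drift by a programmed end-of-train
#' depolarization. The generator returns its ground truth.
#'
#' @param protocol [train_protocol()].
#' @param per_pulse_scale numeric vector (length = pulse count) of kernel
#'   scale factors; defaults to geometric depression `depression^(i-1)`.
#' @param depression geometric per-pulse factor used when `per_pulse_scale`
#'   is `NULL` (default 0.95).
#' @param buildup inter-pulse fluorescence level at each stimulus time
#'   (length = pulse count, starting at 0); default no buildup.
#' @param end_depolarization programmed baseline shift at the end of the
#'   train, mV (approached with time constant duration/6, so it is
#'   saturated to < 0.3% by the final inter-pulse interval).
#' @param kernel dF/F single-transient kernel ([make_transient_kernel()]);
#'   a default WT-like kernel is used if `NULL`.
#' @param ap [ap_shape()] for the spikes.
#' @param noise optional [noise_spec()] applied to the dF/F trace (the
#'   voltage trace gets the same rms at 10 kHz cutoff, seed offset by 1).
#' @return list of class `synthetic_train`: `vm`, `dfof` ([time_series()]),
#'   `protocol`, and `truth` (per-pulse amplitudes, buildup levels,
#'   end-of-train depolarization, AP peak amplitudes).
#' @export
make_train <- function(protocol, per_pulse_scale = NULL, depression = 0.95,
                       buildup = NULL, end_depolarization = 0,
                       kernel = NULL, ap = ap_shape(), noise = NULL) {
  stopifnot(inherits(protocol, "train_protocol"))
  st <- protocol$stimulus_times
  n <- length(st)
  if (is.null(per_pulse_scale)) per_pulse_scale <- depression^(seq_len(n) - 1)
  if (is.null(buildup)) buildup <- numeric(n)
  stopifnot(length(per_pulse_scale) == n, length(buildup) == n)
  dt <- protocol$dt
  duration <- max(st) + protocol$tail_ms
  t <- seq(0, duration, by = dt)

  if (is.null(kernel))
    kernel <- make_transient_kernel(duration = min(60, duration), dt = dt)
  kv <- kernel$values
  dfof <- numeric(length(t))
  for (i in seq_len(n)) {
    i0 <- round(st[i] / dt) + 1L
    idx <- i0:min(length(t), i0 + length(kv) - 1L)
    dfof[idx] <- dfof[idx] + per_pulse_scale[i] * kv[seq_along(idx)]
  }
  # inter-pulse buildup: monotone interpolant through (stimulus, level),
  # zero before the train, exponential relaxation (tau 30 ms) after it
  if (any(buildup != 0)) {
    bu_fun <- stats::splinefun(c(0, st), c(0, buildup), method = "monoH.FC")
    bu <- ifelse(t <= max(st), pmax(0, bu_fun(t)), 0)
    after <- t > max(st)
    bu[after] <- buildup[n] * exp(-(t[after] - max(st)) / 30)
    bu[t < st[1]] <- 0
    dfof <- dfof + bu
  }

  tau_dep <- protocol$duration_ms / 6
  dep <- end_depolarization * (1 - exp(-pmax(0, t - st[1]) / tau_dep))
  vm <- ap$baseline + dep
  for (i in seq_len(n))
    vm <- vm + ap$amplitude * ap_unit(ap, t - st[i])

  dfof_ts <- time_series(dfof, dt, units = "dfof")
  vm_ts <- time_series(vm, dt, units = "mV")
  if (!is.null(noise)) {
    dfof_ts <- add_noise(dfof_ts, noise)
    vm_ts <- add_noise(vm_ts, noise_spec(noise$rms, noise$seed + 1L, 10))
  }
  structure(list(vm = vm_ts, dfof = dfof_ts, protocol = protocol,
                 truth = list(per_pulse_amp = per_pulse_scale * max(kernel$values),
                              per_pulse_scale = per_pulse_scale,
                              buildup = buildup,
                              end_depolarization = end_depolarization,
                              ap_amplitude = ap$amplitude + dep[round(st / dt) + 1L])),
            class = "synthetic_train")
}

# ---- voltage-clamp families ----------------------------------------------

#' Synthetic voltage-clamp dF/F family
#'
#' For each test potential V the sweep rises to the Boltzmann-programmed
#' peak p(V), relaxes during the pulse to the programmed steady level s(V),
#' and decays back to baseline afterwards. The within-pulse shape is
#' \deqn{y(t) = s(V) A(t) + (p(V) - s(V)) K(t)}
#' where A is a saturating activation (exactly 1 from 1.2 ms onwards) and K
#' a unit-peak transient (quartic rise peaking at `t_peak`, exponential
#' relaxation with `tau_relax`), so the sweep maximum equals p(V) to
#' rounding error and the final 25% of the pulse averages s(V) to ~1e-4.
#'
#' @param protocol [voltage_clamp_protocol()].
#' @param peak_fit,steady_fit [boltzmann_fit()] parameter triples
#'   generating p(V) and s(V).
#' @param t_peak time-to-peak within the pulse, ms.
#' @param tau_relax peak-to-steady relaxation time constant, ms.
#' @param noise optional [noise_spec()]; sweep i uses `seed + i`.
#' @return list of class `clamp_family`: `sweeps` (list of [time_series()],
#'   named by test potential), `truth` (data.frame `v_mV`, `peak`,
#'   `steady`), `protocol`, `pulse_window` (c(start, end) ms).
#' @export
make_clamp_family <- function(protocol, peak_fit, steady_fit,
                              t_peak = 2, tau_relax = 1.8, noise = NULL) {
  stopifnot(inherits(protocol, "voltage_clamp_protocol"))
  v <- protocol$holding + protocol$step_amplitudes
  pre <- protocol$pre_ms; dur <- protocol$pulse_ms
  dt <- protocol$dt
  t <- seq(0, pre + dur + protocol$post_ms, by = dt)
  tp <- t - pre                       # time from pulse start
  sigA <- 0.55; tA <- 1.2; sigK <- 0.8
  A <- ifelse(tp <= 0, 0, ifelse(tp >= tA, 1, exp(-((tA - tp) / sigA)^4)))
  K <- ifelse(tp <= 0, 0, ifelse(tp <= t_peak,
                                 exp(-((t_peak - tp) / sigK)^4),
                                 exp(-(tp - t_peak) / tau_relax)))
  in_pulse <- tp > 0 & tp <= dur
  sweeps <- list()
  truth <- data.frame(v_mV = v,
                      peak = boltzmann_value(peak_fit, v),
                      steady = boltzmann_value(steady_fit, v))
  for (i in seq_along(v)) {
    p <- truth$peak[i]; s <- truth$steady[i]
    y <- numeric(length(t))
    y[in_pulse] <- s * A[in_pulse] + (p - s) * K[in_pulse]
    yend <- y[max(which(in_pulse))]
    post <- tp > dur
    y[post] <- yend * exp(-(tp[post] - dur) / 10)
    sw <- time_series(y, dt, units = "dfof")
    if (!is.null(noise)) sw <- add_noise(sw, noise_spec(noise$rms,
                                                        noise$seed + i,
                                                        noise$cutoff_khz))
    sweeps[[sprintf("%+d_mV", round(v[i]))]] <- sw
  }
  structure(list(sweeps = sweeps, truth = truth, protocol = protocol,
                 pulse_window = c(pre, pre + dur)),
            class = "clamp_family")
}

# ---- confocal line scans -------------------------------------------------

#' Synthetic sarcomeric line scan
#'
#' Positions along the fiber axis are scanned at `step` resolution across
#' `n_sarcomeres` sarcomeres of the given period. Ca2+ microdomains are
#' Gaussian bumps centered on the two triads per sarcomere (at
#' `triad_offset` on either side of each Z line); the confocal spot is a
#' 1-D Gaussian PSF of `psf_fwhm`. Because a Gaussian domain blurred by a
#' Gaussian PSF is again Gaussian, the observed profile is computed in
#' closed form, and the generator *solves* the domain width, amplitude and
#' offset so that the observed (post-PSF) profile passes exactly through
#' the programmed T, Z and M amplitudes. With `psf_fwhm = 0` the profile
#' equals the unblurred site template, whose anchors are then the
#' programmed amplitudes directly.
#'
#' @param n_sarcomeres number of sarcomeres scanned (>= 2 for
#'   classification).
#' @param period sarcomere length, um (default 2.1).
#' @param amplitudes named or ordered numeric `c(T, Z, M)` observed peak
#'   dF/F at triad, Z-line and M-line positions. Must satisfy T > Z > M
#'   (warning otherwise).
#' @param triad_offset distance of each triad from its Z line, um.
#' @param psf_fwhm confocal spot FWHM, um (default 0.8).
#' @param step scan step, um (default 0.2).
#' @param phase position of the first Z line, um (default 0.17, which keeps
#'   all triads away from the scan edges for the default 3-sarcomere scan).
#' @param profile_type `"microdomain"` (default; Gaussian triad-centered
#'   domains solved to hit the programmed post-PSF anchors) or `"plateau"`
#'   (every position carries exactly its class amplitude — an idealized
#'   profile useful for testing class-average recovery, where the PSF is
#'   not applied).
#' @param kernel unit-normalized transient [time_series()]; defaults to a
#'   WT-like [make_transient_kernel()] scaled to peak 1.
#' @param noise optional [noise_spec()]; row j uses `seed + j`.
#' @return list of class `line_scan`: `positions` (um), `dt`, `dfof`
#'   (position x time matrix), `period`, and `truth` (labels, phase,
#'   site positions, observed profile, programmed amplitudes, kernel).
#' @export
make_linescan <- function(n_sarcomeres = 3, period = 2.1,
                          amplitudes = c(T = 0.6, Z = 0.45, M = 0.35),
                          triad_offset = 0.5, psf_fwhm = 0.8, step = 0.2,
                          phase = 0.17, kernel = NULL, noise = NULL,
                          profile_type = c("microdomain", "plateau")) {
  profile_type <- match.arg(profile_type)
  amplitudes <- unname(amplitudes)
  aT <- amplitudes[1]; aZ <- amplitudes[2]; aM <- amplitudes[3]
  if (!(aT > aZ && aZ > aM))
    warning("programmed amplitudes do not honor T > Z > M")
  L <- n_sarcomeres * period
  positions <- seq(0, L, by = step)
  sites <- canonical_sites(period, triad_offset, phase, L)
  labels <- nearest_site_labels(positions, sites)
  sig_psf <- psf_fwhm / (2 * sqrt(2 * log(2)))

  if (profile_type == "plateau") {
    profile <- amplitudes[as.integer(labels)]
    sig_obs <- NA_real_
  } else {
    # observed bump sum at x for domain sd `sig`
    comb <- function(x, sig) {
      vapply(x, function(xx) sum(exp(-(xx - sites$t_all)^2 / (2 * sig^2))), 0)
    }
    # anchor the solve on sites near the scan center so every anchor has a
    # full neighborhood of flanking triads
    xT <- sites$t_all[which.min(abs(sites$t_all - L / 2))]
    xZ <- sites$z_all[which.min(abs(sites$z_all - L / 2))]
    xM <- sites$m_all[which.min(abs(sites$m_all - L / 2))]
    ratio_target <- (aT - aZ) / (aZ - aM)
    f <- function(sig) {
      s <- comb(c(xT, xZ, xM), sig)
      (s[1] - s[2]) / (s[2] - s[3]) - ratio_target
    }
    # bracket the domain width by grid scan (narrow widths underflow)
    grid <- seq(0.15, 3, by = 0.01)
    fg <- vapply(grid, f, 0)
    ok <- which(is.finite(fg))
    flip <- ok[which(diff(sign(fg[ok])) != 0)[1]]
    if (is.na(flip)) stop("requested T/Z/M amplitude pattern unobtainable")
    sig_obs <- stats::uniroot(f, grid[c(flip, flip + 1)], tol = 1e-10)$root
    if (sig_obs <= sig_psf)
      stop("PSF (sigma ", signif(sig_psf, 3), " um) too wide for the requested ",
           "T/Z/M contrast (needs observed domain sigma ", signif(sig_obs, 3), " um)")
    s3 <- comb(c(xT, xZ, xM), sig_obs)
    b <- (aT - aZ) / (s3[1] - s3[2])       # observed bump height
    c0 <- aT - b * s3[1]
    profile <- c0 + b * comb(positions, sig_obs)
  }

  if (is.null(kernel)) {
    kernel <- make_transient_kernel(duration = 15)
    kernel <- time_series(kernel$values / max(kernel$values), kernel$dt,
                          units = "dfof")
  }
  dfof <- outer(profile, kernel$values)
  if (!is.null(noise) && noise$rms > 0) {
    for (j in seq_along(positions)) {
      row <- add_noise(time_series(dfof[j, ], kernel$dt, units = "dfof"),
                       noise_spec(noise$rms, noise$seed + j, noise$cutoff_khz))
      dfof[j, ] <- row$values
    }
  }
  structure(list(positions = positions, dt = kernel$dt, dfof = dfof,
                 period = period,
                 truth = list(labels = labels, phase = phase,
                              triad_offset = triad_offset,
                              sites = sites, profile = profile,
                              amplitudes = c(T = aT, Z = aZ, M = aM),
                              sigma_observed = sig_obs, kernel = kernel)),
            class = "line_scan")
}

# canonical site positions covering [-period, L + period]
canonical_sites <- function(period, triad_offset, phase, L) {
  z <- seq(phase - 2 * period, L + 2 * period, by = period)
  list(z_all = z,
       m_all = z + period / 2,
       t_all = sort(c(z - triad_offset, z + triad_offset)))
}

nearest_site_labels <- function(positions, sites) {
  lab <- character(length(positions))
  for (j in seq_along(positions)) {
    dists <- c(T = min(abs(positions[j] - sites$t_all)),
               Z = min(abs(positions[j] - sites$z_all)),
               M = min(abs(positions[j] - sites$m_all)))
    lab[j] <- names(which.min(dists))
  }
  factor(lab, levels = c("T", "Z", "M"))
}
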