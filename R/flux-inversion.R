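#' Smoothing / differentiation settings for kinetic inversion
#'
#' Derivatives of measured signals are estimated by local-polynomial
#' (Savitzky-Golay) filtering: a polynomial of order `order` is fit by least
#' squares in a sliding window and its analytic derivative is read at the
#' window center. Edge samples where the window does not fit are flagged
#' invalid, not extrapolated.
#'
#' @param window_ms window length in ms; rounded to an odd number of samples
#'   (>= 3) at the trace's dt. Default 0.21 ms = 7 samples at 30 us.
#' @param order polynomial order (must be < window length in samples).
#' @return list of class `smoothing_spec`.
#' @export
smoothing_spec <- function(window_ms = 0.21, order = 3) {
  stopifnot(window_ms > 0, order >= 1)
  structure(list(window_ms = window_ms, order = order), class = "smoothing_spec")
}

# Savitzky-Golay convolution coefficients for the d-th derivative at the
# window center; window of 2m+1 samples, polynomial order p.
sg_coefficients <- function(m, p, deriv = 0) {
  x <- (-m):m
  A <- outer(x, 0:p, `^`)
  # row `deriv` of the pseudo-inverse, times deriv!
  G <- solve(crossprod(A), t(A))
  G[deriv + 1, ] * factorial(deriv)
}

# centered SG filter; returns list(values, valid)
sg_filter <- function(values, dt, smooth, deriv = 0) {
  n <- length(values)
  w <- max(3L, round(smooth$window_ms / dt))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > n) stop("smoothing window (", w, " samples) exceeds trace length")
  ord <- min(smooth$order, w - 1L)
  m <- (w - 1L) %/% 2L
  cf <- sg_coefficients(m, ord, deriv) / dt^deriv
  # stats::filter computes sum(cf[k] * x[i + m + 1 - k]); reverse for convolution
  out <- as.numeric(stats::filter(values, rev(cf), sides = 2))
  valid <- !is.na(out)
  # fill flagged edges with nearest interior estimate so downstream code
  # never sees NA; validity travels alongside
  first <- which(valid)[1]; last <- rev(which(valid))[1]
  out[seq_len(first - 1)] <- out[first]
  if (last < n) out[(last + 1):n] <- out[last]
  list(values = out, valid = valid)
}

#' Ca-bound dye concentration from a dF/F record
#'
#' Exact algebraic inverse of the brightness model used by
#' [dfof_from_trajectory()]:
#' \deqn{CaD(t) = CaD_{rest} + \Delta F/F(t)
#'       (D_{total} + (\phi - 1) CaD_{rest}) / (\phi - 1).}
#'
#' @param dfof [time_series()] of baseline-corrected dF/F.
#' @param fluor [fluorescence_params()].
#' @param dye [buffer_spec()] of the indicator.
#' @param cad_rest resting Ca-bound dye concentration (uM).
#' @return [time_series()] of CaD(t) in uM. Errors if the implied CaD
#'   exceeds the total dye (saturation exceeded) or falls below zero.
#' @export
cad_from_dfof <- function(dfof, fluor, dye, cad_rest) {
  stopifnot(inherits(dfof, "time_series"))
  phi <- fluor$phi
  cad <- cad_rest + dfof$values * (dye$total + (phi - 1) * cad_rest) / (phi - 1)
  bad <- which(cad > dye$total)
  if (length(bad))
    stop("dye saturation exceeded (CaD > ", dye$total, " uM) at ",
         length(bad), " samples, first at index ", bad[1])
  if (any(cad < 0))
    stop("dF/F below the physical floor (implied CaD < 0) at ",
         sum(cad < 0), " samples")
  time_series(cad, dfof$dt, dfof$t0, units = "uM")
}

#' Free calcium from the dye-binding kinetics
#'
#' Inverts the single dye reaction
#' \eqn{dCaD/dt = k_{on} [Ca] (D_{total} - CaD) - k_{off} CaD} for the free
#' calcium transient:
#' \deqn{[Ca](t) = (dCaD/dt + k_{off} CaD) / (k_{on} (D_{total} - CaD)),}
#' with the derivative estimated by Savitzky-Golay filtering. This is the
#' step that turns a low-affinity-dye fluorescence record into a signal that
#' tracks release rather than equilibrium calcium.
#'
#' @param cad [time_series()] of CaD(t), uM (strictly below `d_total`).
#' @param dye [rate_constants()] of the dye's Ca2+ reaction.
#' @param d_total total dye concentration, uM.
#' @param smooth [smoothing_spec()].
#' @return [time_series()] of free Ca2+ (uM) with attribute `valid` marking
#'   samples whose derivative window fit inside the trace.
#' @export
free_ca_from_cad <- function(cad, dye, d_total, smooth = smoothing_spec()) {
  stopifnot(inherits(cad, "time_series"))
  if (any(cad$values >= d_total))
    stop("CaD reaches total dye; kinetic inversion undefined at saturation")
  dcad <- sg_filter(cad$values, cad$dt, smooth, deriv = 1)
  ca <- (dcad$values + dye$koff * cad$values) /
        (dye$kon * (d_total - cad$values))
  out <- time_series(ca, cad$dt, cad$t0, units = "uM")
  attr(out, "valid") <- dcad$valid
  out
}

#' SR calcium release flux underlying a dF/F transient
#'
#' The full kinetic inversion pipeline:
#' 1. [cad_from_dfof()] — dye occupancy from the fluorescence record;
#' 2. [free_ca_from_cad()] — free Ca2+ by inverting the dye reaction;
#' 3. forward integration of all *other* buffers' binding ODEs driven by
#'    the recovered free Ca2+ (free Mg2+ integrated alongside);
#' 4. release flux as the total rate of Ca2+ appearance,
#'    \deqn{R(t) = d[Ca]/dt + \sum_B d[CaB]/dt}
#'    over the free pool, the dye, and every Ca-binding buffer.
#'
#' The model contains no SR uptake term: in the high-EGTA regime removal is
#' by buffering, so R(t) is the pure release flux.
#'
#' @param dfof [time_series()] of dF/F. Must be baseline-corrected (resting
#'   level 0); alternatively give `baseline_ms` > 0 to subtract the mean of
#'   that initial pre-stimulus window first.
#' @param params [compartment_params()] including a buffer named `"dye"`.
#' @param fluor [fluorescence_params()].
#' @param smooth [smoothing_spec()].
#' @param baseline_ms length (ms) of a pre-stimulus window used for baseline
#'   subtraction; 0 (default) assumes the record is already corrected.
#' @param clamp_negative if `TRUE`, negative flux samples are clamped to
#'   zero. Default `FALSE`: inversion artifacts are reported as computed.
#' @param negative_tol flux more negative than `-negative_tol` (uM/ms)
#'   triggers a warning (never an error).
#' @return [time_series()] of class `c("flux_trace", "time_series")` with
#'   units uM/ms, same dt and length as the input, and attributes `valid`
#'   (logical; edge samples with incomplete derivative windows are `FALSE`)
#'   and `meta` (parameters and smoothing used).
#' @export
flux_from_dfof <- function(dfof, params = default_params(),
                           fluor = fluorescence_params(),
                           smooth = smoothing_spec(),
                           baseline_ms = 0, clamp_negative = FALSE,
                           negative_tol = 10) {
  stopifnot(inherits(dfof, "time_series"), inherits(params, "compartment_params"))
  dye <- params$buffers[["dye"]]
  if (is.null(dye)) stop("params must contain a buffer named 'dye'")
  if (baseline_ms > 0) {
    base <- mean(ts_window(dfof, dfof$t0, dfof$t0 + baseline_ms)$values)
    dfof <- time_series(dfof$values - base, dfof$dt, dfof$t0, dfof$units)
  }
  rest <- equilibrium_state(params, "clamped")
  cad_rest <- rest[[paste0(dye$name, ".ca")]]

  cad <- cad_from_dfof(dfof, fluor, dye, cad_rest)
  ca <- free_ca_from_cad(cad, dye$ca, dye$total, smooth)
  valid <- attr(ca, "valid")

  # drive the non-dye buffers with the recovered free Ca (stiff scheme,
  # Ca as exogenous forcing, linear interpolation between samples)
  others <- params$buffers[names(params$buffers) != dye$name]
  pars_o <- pars_matrix(compartment_params(others, params$ca_total,
                                           params$mg_total, params$ca_free_rest,
                                           params$mg_free_rest))
  nm_o <- c("ca", "mg", unlist(lapply(others, function(b)
    c(if (!is.null(b$ca)) paste0(b$name, ".ca"),
      if (!is.null(b$mg)) paste0(b$name, ".mg")))))
  y0 <- as.numeric(rest)[match(nm_o, state_names(params))]
  res <- cpp_simulate(pars_o, y0, ca$values, ca$dt, ca$dt, 1e-8, 0.01, 1.0)
  st <- res$states
  colnames(st) <- nm_o

  # total Ca rate: free pool + dye + driven buffers (mass-action rates)
  dca  <- sg_filter(ca$values, ca$dt, smooth, deriv = 1)
  dcad <- sg_filter(cad$values, cad$dt, smooth, deriv = 1)
  R <- dca$values + dcad$values
  for (b in others) {
    if (is.null(b$ca)) next
    cab <- st[, paste0(b$name, ".ca")]
    mgb <- if (!is.null(b$mg)) st[, paste0(b$name, ".mg")] else 0
    R <- R + b$ca$kon * ca$values * (b$total - cab - mgb) - b$ca$koff * cab
  }
  valid <- valid & dca$valid & dcad$valid
  if (min(R[valid]) < -negative_tol)
    warning("inversion produced flux < -", negative_tol,
            " uM/ms (min ", signif(min(R[valid]), 3),
            "); check smoothing/baseline")
  if (clamp_negative) R <- pmax(R, 0)
  out <- time_series(R, dfof$dt, dfof$t0, units = "uM_per_ms")
  class(out) <- c("flux_trace", "time_series")
  attr(out, "valid") <- valid
  attr(out, "meta") <- list(phi = fluor$phi, smooth = smooth,
                            clamp_negative = clamp_negative,
                            params_hash = params_hash(params))
  out
}

# short stable hash of the parameter set for provenance logging
params_hash <- function(params) {
  s <- paste(utils::capture.output(utils::str(params, digits.d = 15)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Peak release flux in a window
#'
#' @param flux a flux trace from [flux_from_dfof()] (any [time_series()]
#'   works). Samples flagged invalid (edge derivative windows) are ignored.
#' @param window numeric `c(from, to)` in ms, or `NULL` for the whole trace.
#' @return maximum flux (uM/ms).
#' @export
peak_flux <- function(flux, window = NULL) {
  stopifnot(inherits(flux, "time_series"))
  valid <- attr(flux, "valid")
  if (is.null(valid)) valid <- rep(TRUE, length(flux$values))
  tt <- ts_time(flux)
  keep <- valid
  if (!is.null(window)) keep <- keep & tt >= window[1] & tt <= window[2]
  if (!any(keep)) stop("empty window")
  max(flux$values[keep])
}
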