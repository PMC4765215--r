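#' Binding rate constants for one ligand on one buffer
#'
#' @param kon second-order on-rate in uM^-1 ms^-1 (> 0). Printed on-rates of
#'   the form "uM ms^-1" in the source literature are interpreted as
#'   uM^-1 ms^-1, the only dimensionally consistent reading for a
#'   second-order rate.
#' @param koff off-rate in ms^-1 (>= 0).
#' @return list of class `rate_constants` with `kon`, `koff` and the derived
#'   dissociation constant `kd = koff/kon` (uM).
#' @export
rate_constants <- function(kon, koff) {
  if (!is.finite(kon) || kon <= 0) stop("kon must be > 0 (uM^-1 ms^-1)")
  if (!is.finite(koff) || koff < 0) stop("koff must be >= 0 (ms^-1)")
  structure(list(kon = kon, koff = koff, kd = koff / kon),
            class = "rate_constants")
}

#' Specification of one intracellular buffer
#'
#' A buffer is a single pool of sites that can bind Ca2+, Mg2+, or both
#' competitively (one site per molecule; a site holds at most one ion).
#'
#' @param name label, e.g. `"parvalbumin"`.
#' @param total total site concentration in uM (> 0).
#' @param ca [rate_constants()] for Ca2+ binding, or `NULL` if the buffer
#'   does not bind Ca2+.
#' @param mg [rate_constants()] for Mg2+ binding, or `NULL`.
#' @return list of class `buffer_spec`.
#' @export
buffer_spec <- function(name, total, ca = NULL, mg = NULL) {
  if (!is.finite(total) || total <= 0) stop("total must be > 0 (uM)")
  if (is.null(ca) && is.null(mg)) stop("buffer must bind at least one of Ca/Mg")
  if (!is.null(ca)) stopifnot(inherits(ca, "rate_constants"))
  if (!is.null(mg)) stopifnot(inherits(mg, "rate_constants"))
  structure(list(name = name, total = total, ca = ca, mg = mg),
            class = "buffer_spec")
}

#' Default single-compartment model parameters
#'
#' The myoplasmic buffer set of a muscle fiber equilibrated with a
#' high-EGTA, low-affinity-dye pipette solution:
#'
#' * parvalbumin, 900 uM, competitive Ca2+ (kon 0.025, koff 0.7) and Mg2+
#'   (kon 1.5e-5, koff 0.003) binding on a single site;
#' * troponin, 240 uM, Ca2+ only (kon 0.15, koff 0.45);
#' * ATP, 5 mM, Mg2+ only (kon 0.013, koff 0.15);
#' * EGTA, 30 mM, Ca2+ only (kon 0.0105, koff 0.00075);
#' * indicator dye (OGB-5N), 250 uM, Ca2+ only (kon 0.157, koff 9.42);
#'
#' with 15 mM total Ca2+ (resting free 0.075 uM) and 5 mM total Mg2+
#' (resting free 150 uM). All on-rates in uM^-1 ms^-1, off-rates in ms^-1,
#' concentrations in uM.
#'
#' There is deliberately no SR uptake/pump term: removal of released Ca2+ is
#' entirely by buffering, which is the regime the high-EGTA internal
#' solution creates.
#'
#' @return list of class `compartment_params` with fields `buffers` (named
#'   list of [buffer_spec()]), `ca_total`, `mg_total`, `ca_free_rest`,
#'   `mg_free_rest` (uM).
#' @seealso [equilibrium_state()], [simulate_forward()]
#' @export
default_params <- function() {
  buffers <- list(
    parvalbumin = buffer_spec("parvalbumin", 900,
                              ca = rate_constants(0.025, 0.7),
                              mg = rate_constants(1.5e-5, 0.003)),
    troponin    = buffer_spec("troponin", 240,
                              ca = rate_constants(0.15, 0.45)),
    atp         = buffer_spec("atp", 5000,
                              mg = rate_constants(0.013, 0.15)),
    egta        = buffer_spec("egta", 30000,
                              ca = rate_constants(0.0105, 0.00075)),
    dye         = buffer_spec("dye", 250,
                              ca = rate_constants(0.157, 9.42))
  )
  compartment_params(buffers, ca_total = 15000, mg_total = 5000,
                     ca_free_rest = 0.075, mg_free_rest = 150)
}

#' Assemble compartment parameters
#'
#' @param buffers named list of [buffer_spec()] objects. The buffer named
#'   `"dye"` (if present) is treated as the fluorescence indicator.
#' @param ca_total,mg_total total ion content, uM.
#' @param ca_free_rest,mg_free_rest nominal resting free concentrations, uM.
#' @return list of class `compartment_params`.
#' @export
compartment_params <- function(buffers, ca_total, mg_total,
                               ca_free_rest, mg_free_rest) {
  stopifnot(length(buffers) >= 1, all(vapply(buffers, inherits, TRUE, "buffer_spec")))
  if (is.null(names(buffers)) || any(names(buffers) == ""))
    names(buffers) <- vapply(buffers, `[[`, "", "name")
  stopifnot(ca_total > 0, mg_total >= 0, ca_free_rest > 0, mg_free_rest >= 0)
  structure(list(buffers = buffers, ca_total = ca_total, mg_total = mg_total,
                 ca_free_rest = ca_free_rest, mg_free_rest = mg_free_rest),
            class = "compartment_params")
}

#' @export
print.compartment_params <- function(x, ...) {
  cat("<compartment_params>\n")
  cat(sprintf("  ca_total %g uM (resting free %g), mg_total %g uM (resting free %g)\n",
              x$ca_total, x$ca_free_rest, x$mg_total, x$mg_free_rest))
  for (b in x$buffers) {
    sites <- c(if (!is.null(b$ca)) sprintf("Ca kon %g koff %g", b$ca$kon, b$ca$koff),
               if (!is.null(b$mg)) sprintf("Mg kon %g koff %g", b$mg$kon, b$mg$koff))
    cat(sprintf("  %-12s %7g uM  [%s]\n", b$name, b$total, paste(sites, collapse = "; ")))
  }
  invisible(x)
}

#' Fluorescence model parameters
#'
#' The dye signal model assumes the Ca-bound dye is `phi` times brighter
#' than the free dye, so that with resting occupancy `CaD_rest`,
#' \deqn{\Delta F/F(t) = (\phi - 1)(CaD(t) - CaD_{rest}) /
#'       (D_{total} + (\phi - 1) CaD_{rest}).}
#' dF/F is referenced to the resting state (baseline convention).
#'
#' @param phi brightness ratio of Ca-bound to free dye, > 1. Default 40.
#'   Round-trip analyses are phi-invariant as long as the forward and
#'   inverse transforms share the value.
#' @return list of class `fluorescence_params`.
#' @export
fluorescence_params <- function(phi = 40) {
  if (!is.finite(phi) || phi <= 1) stop("phi must be > 1")
  structure(list(phi = phi, baseline_convention = "rest"),
            class = "fluorescence_params")
}

# ---- internal: state layout and parameter matrix -------------------------

# One row per buffer; NA marks an absent reaction. Used by both the C++
# integrator and the R-side equilibrium/rate helpers.
pars_matrix <- function(params) {
  m <- t(vapply(params$buffers, function(b) c(
    total   = b$total,
    kon_ca  = if (is.null(b$ca)) NA_real_ else b$ca$kon,
    koff_ca = if (is.null(b$ca)) NA_real_ else b$ca$koff,
    kon_mg  = if (is.null(b$mg)) NA_real_ else b$mg$kon,
    koff_mg = if (is.null(b$mg)) NA_real_ else b$mg$koff), numeric(5)))
  rownames(m) <- names(params$buffers)
  m
}

# state vector layout: ca, mg, then <buf>.ca / <buf>.mg per reaction
state_names <- function(params) {
  nm <- c("ca", "mg")
  for (b in params$buffers) {
    if (!is.null(b$ca)) nm <- c(nm, paste0(b$name, ".ca"))
    if (!is.null(b$mg)) nm <- c(nm, paste0(b$name, ".mg"))
  }
  nm
}

# bound concentrations of one buffer at fixed free ca/mg (single shared site)
bound_at_free <- function(b, ca, mg) {
  xca <- if (is.null(b$ca)) 0 else ca / b$ca$kd
  xmg <- if (is.null(b$mg)) 0 else mg / b$mg$kd
  denom <- 1 + xca + xmg
  c(ca = b$total * xca / denom, mg = b$total * xmg / denom)
}

#' Compartment state as a named vector
#'
#' @param params [compartment_params()].
#' @param ca_free,mg_free free concentrations, uM.
#' @param bound named numeric vector of bound species (`"<buffer>.ca"`,
#'   `"<buffer>.mg"`); missing entries are an error.
#' @return named numeric vector of class `compartment_state` in the
#'   canonical layout `ca, mg, <buffer>.ca, <buffer>.mg, ...`.
#' @export
compartment_state <- function(params, ca_free, mg_free, bound) {
  nm <- state_names(params)
  y <- c(ca = ca_free, mg = mg_free, bound[setdiff(nm, c("ca", "mg"))])
  if (any(is.na(y))) stop("missing bound species: ",
                          paste(setdiff(nm, names(bound))[-(1:2)], collapse = ", "))
  if (any(y < 0)) stop("negative concentration in state")
  names(y) <- nm
  structure(y, class = "compartment_state")
}

# net binding rates (uM/ms) for every reaction at a state vector
reaction_rates <- function(params, y) {
  ca <- y[["ca"]]; mg <- y[["mg"]]
  out <- c()
  for (b in params$buffers) {
    cab <- if (!is.null(b$ca)) y[[paste0(b$name, ".ca")]] else 0
    mgb <- if (!is.null(b$mg)) y[[paste0(b$name, ".mg")]] else 0
    free <- b$total - cab - mgb
    if (!is.null(b$ca))
      out[paste0(b$name, ".ca")] <- b$ca$kon * ca * free - b$ca$koff * cab
    if (!is.null(b$mg))
      out[paste0(b$name, ".mg")] <- b$mg$kon * mg * free - b$mg$koff * mgb
  }
  out
}

#' Resting (equilibrium) state of the compartment
#'
#' Two initialization conventions are provided:
#'
#' * `"clamped"` (default): the free concentrations are fixed at the stated
#'   resting values (`ca_free_rest`, `mg_free_rest`) and every buffer is set
#'   to its binding equilibrium at those values. The implied totals
#'   (free + bound) are reported in the `implied` attribute; they need not
#'   equal the nominal `ca_total`/`mg_total`.
#' * `"solved"`: the free concentrations are found by a two-dimensional
#'   root-find (nested monotone bisection via [stats::uniroot()]) so that
#'   mass conservation holds exactly for the nominal totals.
#'
#' In both modes every reaction is individually at equilibrium (detailed
#' balance; net rates < 1e-9 uM/ms), which is checked before returning.
#'
#' @param params [compartment_params()].
#' @param mode `"clamped"` or `"solved"`.
#' @return [compartment_state()] with attribute `implied` = list of implied
#'   totals (clamped mode) or `residual` = conservation residual (solved).
#' @export
equilibrium_state <- function(params, mode = c("clamped", "solved")) {
  mode <- match.arg(mode)
  if (mode == "clamped") {
    ca <- params$ca_free_rest; mg <- params$mg_free_rest
  } else {
    has_mg <- any(vapply(params$buffers, function(b) !is.null(b$mg), TRUE))
    ca_resid <- function(ca, mg) {
      tot <- ca
      for (b in params$buffers) tot <- tot + bound_at_free(b, ca, mg)[["ca"]]
      tot - params$ca_total
    }
    mg_resid <- function(mg) {
      ca <- stats::uniroot(ca_resid, c(1e-12, params$ca_total), mg = mg,
                           tol = 1e-15)$root
      tot <- mg
      for (b in params$buffers) tot <- tot + bound_at_free(b, ca, mg)[["mg"]]
      tot - params$mg_total
    }
    mg <- if (has_mg && params$mg_total > 0)
      stats::uniroot(mg_resid, c(1e-9, params$mg_total), tol = 1e-13)$root
    else params$mg_total
    ca <- stats::uniroot(ca_resid, c(1e-12, params$ca_total), mg = mg,
                         tol = 1e-15)$root
  }
  bound <- numeric(0)
  for (b in params$buffers) {
    bb <- bound_at_free(b, ca, mg)
    if (!is.null(b$ca)) bound[paste0(b$name, ".ca")] <- bb[["ca"]]
    if (!is.null(b$mg)) bound[paste0(b$name, ".mg")] <- bb[["mg"]]
  }
  y <- compartment_state(params, ca, mg, bound)
  rates <- reaction_rates(params, y)
  if (max(abs(rates)) > 1e-9)
    stop("equilibrium did not converge; max |rate| = ", max(abs(rates)), " uM/ms")
  if (mode == "clamped") {
    attr(y, "implied") <- list(
      ca_total = ca + sum(bound[grepl("\\.ca$", names(bound))]),
      mg_total = mg + sum(bound[grepl("\\.mg$", names(bound))]))
  } else {
    attr(y, "residual") <- max(abs(c(
      y[["ca"]] + sum(y[grepl("\\.ca$", names(y))]) - params$ca_total,
      y[["mg"]] + sum(y[grepl("\\.mg$", names(y))]) - params$mg_total)))
  }
  y
}

#' Forward simulation of the buffering network driven by a release flux
#'
#' Integrates the mass-action ODE system
#' \deqn{d[XB]/dt = k_{on} [X] (B_{tot} - [CaB] - [MgB]) - k_{off} [XB]}
#' for every buffer/ion reaction, with
#' \deqn{d[Ca]/dt = R(t) - \sum \text{Ca net rates}, \quad
#'       d[Mg]/dt = -\sum \text{Mg net rates},}
#' where R(t) is the SR release flux (uM/ms), linearly interpolated between
#' the samples of `flux`. EGTA and dye binding have sub-10-us time constants
#' so the system is stiff; integration uses an L-stable SDIRK2 scheme with
#' analytic Jacobian, relative tolerance 1e-8 and a 10-us cap on the
#' internal step (compiled code).
#'
#' @param params [compartment_params()].
#' @param flux [time_series()] of release flux R(t), units uM/ms. The
#'   simulated interval is the flux's time span (t0 is taken as time zero).
#' @param init initial [compartment_state()]; defaults to the clamped
#'   equilibrium.
#' @param dt_out output sampling interval in ms; defaults to `flux$dt`.
#' @param rtol relative tolerance of the step-doubling error control.
#' @param hmax maximum internal step (ms).
#' @return object of class `compartment_trajectory`: list with `time` (ms),
#'   `states` (matrix, one row per output time, canonical state columns),
#'   `injected` (cumulative integral of R up to each output time, uM),
#'   `params`, `flux`. Mass conservation holds to < 1e-6 relative at every
#'   output sample (checked; violation is an error).
#' @export
simulate_forward <- function(params, flux, init = NULL, dt_out = NULL,
                             rtol = 1e-8, hmax = 0.01) {
  stopifnot(inherits(params, "compartment_params"), inherits(flux, "time_series"))
  if (is.null(init)) init <- equilibrium_state(params, "clamped")
  if (is.null(dt_out)) dt_out <- flux$dt
  nm <- state_names(params)
  if (!identical(names(unclass(init)), nm)) stop("init inconsistent with params")
  res <- cpp_simulate(pars_matrix(params), as.numeric(init), flux$values,
                      flux$dt, dt_out, rtol, hmax, -1.0)
  states <- res$states
  colnames(states) <- nm
  time <- res$time
  # exact integral of the piecewise-linear flux at the output times (the
  # integrator sees the same piecewise-linear forcing)
  cumR <- c(0, cumsum((utils::head(flux$values, -1) + utils::tail(flux$values, -1)) / 2 * flux$dt))
  injected <- vapply(time, function(tt) {
    i <- max(0, min(floor(tt / flux$dt + 1e-9), length(flux$values) - 2))
    frac <- tt - i * flux$dt
    Ri <- flux$values[i + 1]
    Rt <- Ri + (flux$values[i + 2] - Ri) * frac / flux$dt
    cumR[i + 1] + (Ri + Rt) / 2 * frac
  }, 0)
  ca0 <- init[["ca"]] + sum(init[grepl("\\.ca$", nm)])
  mg0 <- init[["mg"]] + sum(init[grepl("\\.mg$", nm)])
  ca_t <- states[, "ca"] + rowSums(states[, grepl("\\.ca$", nm), drop = FALSE])
  mg_t <- states[, "mg"] + rowSums(states[, grepl("\\.mg$", nm), drop = FALSE])
  resid <- max(abs(ca_t - (ca0 + injected)) / ca0, abs(mg_t - mg0) / max(mg0, 1))
  if (resid > 1e-6)
    stop("conservation violated in forward simulation (residual ", signif(resid, 3), ")")
  structure(list(time = time, states = states, injected = injected,
                 params = params, flux = flux, conservation_residual = resid),
            class = "compartment_trajectory")
}

#' @export
print.compartment_trajectory <- function(x, ...) {
  cat(sprintf("<compartment_trajectory> %d samples over %g ms, %d species\n",
              length(x$time), max(x$time), ncol(x$states)))
  cat(sprintf("  conservation residual %.2e (relative)\n", x$conservation_residual))
  invisible(x)
}

#' Dye fluorescence signal of a simulated trajectory
#'
#' Maps the Ca-bound dye concentration of a trajectory to the reported
#' dimensionless dF/F under the linear brightness model of
#' [fluorescence_params()]. Exact algebraic inverse of [cad_from_dfof()].
#'
#' @param traj `compartment_trajectory` from [simulate_forward()].
#' @param fluor [fluorescence_params()].
#' @param dye [buffer_spec()] of the indicator; defaults to the buffer named
#'   `"dye"` in the trajectory's params.
#' @param cad_rest resting Ca-bound dye (uM); defaults to the first sample.
#' @return [time_series()] of dF/F.
#' @export
dfof_from_trajectory <- function(traj, fluor = fluorescence_params(),
                                 dye = NULL, cad_rest = NULL) {
  stopifnot(inherits(traj, "compartment_trajectory"))
  if (is.null(dye)) dye <- traj$params$buffers[["dye"]]
  if (is.null(dye)) stop("trajectory has no dye buffer")
  cad <- traj$states[, paste0(dye$name, ".ca")]
  if (is.null(cad_rest)) cad_rest <- cad[1]
  phi <- fluor$phi
  dfof <- (phi - 1) * (cad - cad_rest) / (dye$total + (phi - 1) * cad_rest)
  time_series(dfof, dt = traj$time[2] - traj$time[1], t0 = traj$time[1],
              units = "dfof")
}
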