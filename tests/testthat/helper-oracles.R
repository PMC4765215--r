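# Independent reference implementations used as oracles. Deliberately
# naive: plain-R explicit Euler at a micro step, and grid-refinement search
# for the resting equilibrium. They share no code with the package paths
# they check.

# explicit Euler at fixed step h (ms); forcing linearly interpolated.
# mirrors the canonical state layout: ca, mg, <buf>.ca, <buf>.mg
euler_oracle <- function(params, flux_values, dt_in, y0, h, dt_out) {
  nm <- names(y0)
  bufs <- params$buffers
  tmax <- dt_in * (length(flux_values) - 1)
  nout <- floor(tmax / dt_out + 1e-9) + 1
  out <- matrix(NA_real_, nout, length(y0), dimnames = list(NULL, nm))
  out[1, ] <- y0
  y <- y0
  t <- 0
  Rof <- function(t) {
    x <- t / dt_in
    i <- floor(x)
    if (i >= length(flux_values) - 1) return(flux_values[length(flux_values)])
    w <- x - i
    flux_values[i + 1] * (1 - w) + flux_values[i + 2] * w
  }
  io <- 2
  nstep <- round(tmax / h)
  for (s in seq_len(nstep)) {
    dy <- setNames(numeric(length(y)), nm)
    sca <- smg <- 0
    for (b in bufs) {
      cab <- if (!is.null(b$ca)) y[[paste0(b$name, ".ca")]] else 0
      mgb <- if (!is.null(b$mg)) y[[paste0(b$name, ".mg")]] else 0
      free <- b$total - cab - mgb
      if (!is.null(b$ca)) {
        r <- b$ca$kon * y[["ca"]] * free - b$ca$koff * cab
        dy[[paste0(b$name, ".ca")]] <- r; sca <- sca + r
      }
      if (!is.null(b$mg)) {
        r <- b$mg$kon * y[["mg"]] * free - b$mg$koff * mgb
        dy[[paste0(b$name, ".mg")]] <- r; smg <- smg + r
      }
    }
    dy[["ca"]] <- Rof(t) - sca
    dy[["mg"]] <- -smg
    y <- y + h * dy
    t <- s * h
    if (io <= nout && t >= (io - 1) * dt_out - h / 2 - 1e-12) {
      out[io, ] <- y
      io <- io + 1
    }
  }
  out
}

# resting equilibrium by nested grid refinement on the two conservation
# equations (no root-finder shared with the implementation)
grid_equilibrium_oracle <- function(params, iters = 60) {
  bound_tot <- function(ca, mg, which) {
    tot <- 0
    for (b in params$buffers) {
      xca <- if (is.null(b$ca)) 0 else ca / b$ca$kd
      xmg <- if (is.null(b$mg)) 0 else mg / b$mg$kd
      den <- 1 + xca + xmg
      tot <- tot + b$total * (if (which == "ca") xca else xmg) / den
    }
    tot
  }
  ca_for_mg <- function(mg) {
    lo <- 1e-12; hi <- params$ca_total
    for (i in 1:iters) {
      mid <- (lo + hi) / 2
      if (mid + bound_tot(mid, mg, "ca") > params$ca_total) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- 1e-9; hi <- max(params$mg_total, 1e-6)
  for (i in 1:iters) {
    mid <- (lo + hi) / 2
    ca <- ca_for_mg(mid)
    if (mid + bound_tot(ca, mid, "mg") > params$mg_total) hi <- mid else lo <- mid
  }
  mg <- (lo + hi) / 2
  list(ca = ca_for_mg(mg), mg = mg)
}

# WT-like defaults used across tests
wt_alpha_flux <- function(peak = 260, fdhm = 2, latency = 2, duration = 25,
                          dt = 0.03) {
  make_flux_waveform(flux_shape(peak, latency, alpha_rise_for_fdhm(fdhm)),
                     duration, dt)
}
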