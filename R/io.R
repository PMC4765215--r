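#' Write / read a trace as CSV
#'
#' Format: two columns, `time_ms` and the unit tag as the second column
#' name (e.g. `dfof`, `mV`, `uM_per_ms`). Values are written at full
#' double precision so `read_trace(write_trace(x))` is exact. Reading
#' enforces a uniform time column (relative tolerance 1e-9).
#'
#' @param trace [time_series()].
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   [time_series()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "time_series"))
  unit <- if (nzchar(trace$units)) trace$units else "value"
  df <- data.frame(time_ms = sprintf("%.17g", ts_time(trace)),
                   v = sprintf("%.17g", trace$values))
  names(df)[2] <- unit
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != 2 || names(df)[1] != "time_ms")
    stop("malformed trace file: expected columns time_ms,<units>")
  tt <- as.numeric(df[[1]])
  dts <- diff(tt)
  dt <- stats::median(dts)
  if (dt <= 0 || max(abs(dts - dt)) > 1e-9 * max(abs(tt), 1))
    stop("non-uniform time column in ", path)
  # snap dt to 12 significant digits: the time column is written as
  # t0 + k*dt, so re-deriving dt from differences picks up 1-ulp noise
  time_series(as.numeric(df[[2]]), dt = signif(dt, 12), t0 = tt[1],
              units = names(df)[2])
}

#' Write / read a line scan as wide CSV
#'
#' First column `position_um`, remaining columns one per time point named
#' `t<ms>`; the sampling interval is recovered from the column names on
#' read, the sarcomere period is supplied by the caller (it is protocol
#' metadata, not data).
#'
#' @param scan a `line_scan`.
#' @param path file path.
#' @param period sarcomere period (um) recorded in the object on read.
#' @return `read_linescan` returns a `line_scan` (without ground truth).
#' @export
write_linescan <- function(scan, path) {
  stopifnot(inherits(scan, "line_scan"))
  tcols <- sprintf("t%.6g", scan$dt * (seq_len(ncol(scan$dfof)) - 1))
  df <- cbind(data.frame(position_um = scan$positions),
              as.data.frame(scan$dfof))
  names(df) <- c("position_um", tcols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_linescan
#' @export
read_linescan <- function(path, period = 2.1) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "position_um") stop("malformed line-scan file")
  tt <- as.numeric(sub("^t", "", names(df)[-1]))
  dts <- diff(tt)
  if (max(abs(dts - dts[1])) > 1e-6) stop("non-uniform time columns")
  structure(list(positions = as.numeric(df[[1]]),
                 dt = dts[1],
                 dfof = as.matrix(df[, -1, drop = FALSE]),
                 period = period, truth = NULL),
            class = "line_scan")
}

#' Serialize model parameters to JSON (units in field names)
#'
#' @param params [compartment_params()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "compartment_params"))
  enc_rc <- function(rc) if (is.null(rc)) NULL else
    list(kon_per_uM_ms = rc$kon, koff_per_ms = rc$koff)
  obj <- list(
    buffers = lapply(params$buffers, function(b) list(
      total_uM = b$total, ca = enc_rc(b$ca), mg = enc_rc(b$mg))),
    ca_total_uM = params$ca_total, mg_total_uM = params$mg_total,
    ca_free_rest_uM = params$ca_free_rest, mg_free_rest_uM = params$mg_free_rest)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname params_to_json
#' @param json JSON string or file path.
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  dec_rc <- function(x) if (is.null(x) || !length(x)) NULL else
    rate_constants(x$kon_per_uM_ms, x$koff_per_ms)
  buffers <- lapply(names(obj$buffers), function(nm) {
    b <- obj$buffers[[nm]]
    buffer_spec(nm, b$total_uM, ca = dec_rc(b$ca), mg = dec_rc(b$mg))
  })
  names(buffers) <- names(obj$buffers)
  compartment_params(buffers, obj$ca_total_uM, obj$mg_total_uM,
                     obj$ca_free_rest_uM, obj$mg_free_rest_uM)
}

#' Run a synthesize-then-analyze pipeline from a config
#'
#' The config is a named list (or path to a JSON file) with fields:
#' * `stage`: one of `"transient"`, `"train"`, `"clamp"`, `"linescan"`;
#' * `seed`: integer controlling all randomness (required);
#' * `noise_rms`: optional dF/F noise level (default 0);
#' * `out_dir`: optional output directory; results (JSON) and traces (CSV)
#'   are written there when given;
#' * stage-specific settings: `frequency` (train), `n_sarcomeres`
#'   (linescan).
#'
#' Every artifact is a pure function of the config: identical configs give
#' byte-identical JSON results.
#'
#' @param config named list or path to a JSON config file.
#' @return list of class `pipeline_result`: `metrics` (stage-dependent,
#'   JSON-serializable), `traces` (list of [time_series()]), `log`
#'   (character vector recording stage, seed and parameter hash).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  stopifnot(is.list(config))
  stages <- c("transient", "train", "clamp", "linescan")
  if (is.null(config$stage) || !config$stage %in% stages)
    stop("config$stage must be one of: ", paste(stages, collapse = ", "))
  if (is.null(config$seed)) stop("config$seed is required (explicit seeding)")
  seed <- as.integer(config$seed)
  rms <- if (is.null(config$noise_rms)) 0 else config$noise_rms
  params <- default_params()
  log <- c(sprintf("caflux %s", as.character(utils::packageVersion("caflux"))),
           sprintf("stage=%s seed=%d noise_rms=%g", config$stage, seed, rms),
           sprintf("params_hash=%s", params_hash(params)))
  ns <- if (rms > 0) noise_spec(rms, seed) else NULL

  metrics <- list(); traces <- list()
  if (config$stage == "transient") {
    ker <- make_transient_kernel(dt = 0.03, duration = 60)
    dfof <- time_series(c(numeric(round(5 / 0.03)), ker$values), ker$dt, units = "dfof")
    if (!is.null(ns)) dfof <- add_noise(dfof, ns)
    ap <- make_ap_waveform(ap_shape(), duration = max(ts_time(dfof)) + 0.03,
                           onset = 5)
    ap <- time_series(ap$values[seq_along(dfof$values)], ap$dt, units = "mV")
    met <- measure_transient(dfof, ap)
    flux <- flux_from_dfof(dfof, params)
    metrics <- list(peak_dfof = met$peak, latency_ms = met$latency,
                    time_to_peak_ms = met$time_to_peak, fdhm_ms = met$fdhm,
                    decay = met$decay[c("a1", "tau1", "a2", "tau2")],
                    peak_flux_uM_per_ms = peak_flux(flux))
    traces <- list(dfof = dfof, vm = ap, flux = flux)
  } else if (config$stage == "train") {
    freq <- if (is.null(config$frequency)) 50 else config$frequency
    pr <- train_protocol(freq)
    tr <- make_train(pr, noise = ns)
    env <- compute_envelopes(tr$dfof, pr)
    el <- train_electrical_metrics(tr$vm, pr)
    metrics <- list(frequency_Hz = freq,
                    first_last_ratio = first_last_ratio(env),
                    per_pulse_amp = env$per_pulse_amp,
                    first_ap_amp_mV = el$first_ap_amp,
                    last_ap_amp_mV = el$last_ap_amp,
                    end_depolarization_mV = el$end_depolarization)
    traces <- list(dfof = tr$dfof, vm = tr$vm)
  } else if (config$stage == "clamp") {
    fam <- make_clamp_family(voltage_clamp_protocol(),
                             boltzmann_fit(0.77, 7, 13),
                             boltzmann_fit(0.37, 6, 11), noise = ns)
    ps <- t(vapply(fam$sweeps, function(s) {
      e <- extract_peak_and_steady(s, fam$pulse_window)
      c(e$peak, e$steady)
    }, numeric(2)))
    fit_p <- fit_boltzmann(fam$truth$v_mV, ps[, 1])
    fit_s <- fit_boltzmann(fam$truth$v_mV, ps[, 2])
    metrics <- list(peak = fit_p[c("dfof_max", "v_half", "k")],
                    steady = fit_s[c("dfof_max", "v_half", "k")])
    traces <- fam$sweeps
  } else {
    nsarc <- if (is.null(config$n_sarcomeres)) 3 else config$n_sarcomeres
    scan <- make_linescan(n_sarcomeres = nsarc, noise = ns)
    lab <- classify_sites(scan)
    av <- average_by_site(list(scan), list(lab))
    metrics <- list(period_um = lab$period, phase_um = lab$phase,
                    class_mean_peak = as.list(lab$class_means),
                    label_counts = as.list(table(lab$labels)))
    traces <- list(T_mean = av$T$mean, Z_mean = av$Z$mean, M_mean = av$M$mean)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(traces))
      write_trace(traces[[nm]], file.path(config$out_dir, paste0(nm, ".csv")))
    writeLines(log, file.path(config$out_dir, "run.log"))
  }
  structure(list(metrics = metrics, traces = traces, log = log),
            class = "pipeline_result")
}
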