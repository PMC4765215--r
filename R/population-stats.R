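#' Single-Gaussian fit to a histogram of values
#'
#' Bins the values (Freedman-Diaconis width by default) and fits
#' `amplitude * exp(-(x - center)^2 / (2 sd^2))` to the bin counts by
#' least squares, initialized from the sample moments. The sample mean and
#' SEM are reported alongside, since whether a published distribution
#' center came from binned least squares or from the raw moments is often
#' unknowable; for anything close to a single Gaussian the two agree.
#'
#' @param values numeric vector (n >= 10).
#' @param bin_width histogram bin width in data units; `NULL` (default) for
#'   the Freedman-Diaconis rule.
#' @return list of class `gaussian_fit`: `center`, `sd`, `amplitude`
#'   (counts), `se_center` (standard error of the fitted center),
#'   `sample_mean`, `sample_sem`, `n`, `bin_width`.
#' @export
fit_gaussian_hist <- function(values, bin_width = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 10) stop("need >= 10 values")
  if (stats::sd(values) == 0) stop("degenerate input: all values equal")
  if (is.null(bin_width)) {
    iqr <- stats::IQR(values)
    bin_width <- if (iqr > 0) 2 * iqr / n^(1 / 3) else diff(range(values)) / 10
  }
  stopifnot(bin_width > 0)
  breaks <- seq(min(values) - bin_width, max(values) + bin_width,
                by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  x <- h$mids; cnt <- h$counts
  if (sum(cnt > 0) < 4) stop("fewer than 4 nonempty bins; widen the sample or bins")
  start <- list(amplitude = max(cnt), center = mean(values), sdev = stats::sd(values))
  fit <- stats::nls(cnt ~ amplitude * exp(-(x - center)^2 / (2 * sdev^2)),
                    start = start,
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["center", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(center = unname(cf["center"]), sd = abs(unname(cf["sdev"])),
                 amplitude = unname(cf["amplitude"]), se_center = se,
                 sample_mean = mean(values),
                 sample_sem = stats::sd(values) / sqrt(n),
                 n = n, bin_width = bin_width),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> center %.4g (se %.2g), sd %.4g, n = %d\n",
              x$center, x$se_center, x$sd, x$n))
  cat(sprintf("  sample mean %.4g +/- %.2g (SEM)\n", x$sample_mean, x$sample_sem))
  invisible(x)
}

#' Two-sample Student's t test
#'
#' Pooled-variance Student's t with two-sided p by default (the classical
#' "Student's test"); set `welch = TRUE` for the unequal-variance variant.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param welch use the Welch correction instead of pooled variance.
#' @return list of class `two_sample_t`: `t`, `df`, `p`, `mean_a`, `sem_a`,
#'   `mean_b`, `sem_b`, `significant` (p < 0.05).
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                            mean_a = mean(a), sem_a = 0,
                            mean_b = mean(b), sem_b = 0, significant = FALSE),
                       class = "two_sample_t"))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
                 mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)),
                 significant = ht$p.value < 0.05),
            class = "two_sample_t")
}

#' @export
print.two_sample_t <- function(x, ...) {
  cat(sprintf("<two_sample_t> t = %.3f (df %.1f), p = %.4g%s\n",
              x$t, x$df, x$p, if (x$significant) " *" else ""))
  cat(sprintf("  group a: %.4g +/- %.2g; group b: %.4g +/- %.2g (mean +/- SEM)\n",
              x$mean_a, x$sem_a, x$mean_b, x$sem_b))
  invisible(x)
}
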