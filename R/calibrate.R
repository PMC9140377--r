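# Linear divergence-to-time calibration (through the origin: zero time means
# zero divergence) and the ancestral-population-size counterargument.

#' Fit a linear divergence-vs-time calibration through the origin
#'
#' Least-squares slope of % divergence on split time with intercept fixed at
#' zero: `slope = sum(t*d) / sum(t^2)`.
#'
#' @param points Data frame (or 2-column matrix) whose first column is split
#'   time in Myr and second is % divergence; extra columns ignored. Columns
#'   named `time`/`split_myr` and `divergence` are picked up by name when
#'   present.
#' @return Object of class `numt_calibration`: list with `slope`
#'   (% divergence per Myr), `fit_points`, `residuals`, `rmse`.
#' @examples
#' fit_calibration(data.frame(time = c(2, 6), divergence = c(2.2, 5.8)))
#' @export
fit_calibration <- function(points) {
  pts <- as.data.frame(points)
  tcol <- intersect(c("time", "split_myr", "split_time"), names(pts))
  dcol <- intersect(c("divergence", "divergence_pct", "div"), names(pts))
  t <- if (length(tcol)) pts[[tcol[1]]] else pts[[1]]
  d <- if (length(dcol)) pts[[dcol[1]]] else pts[[2]]
  if (length(t) < 1L) stop("need at least one calibration point")
  if (any(t < 0)) stop("split times must be positive")
  if (all(t == 0)) stop("all split times are zero; slope undefined")
  slope <- sum(t * d) / sum(t^2)
  resid <- d - slope * t
  structure(list(slope = slope,
                 fit_points = data.frame(time = t, divergence = d),
                 residuals = resid,
                 rmse = sqrt(mean(resid^2))),
            class = "numt_calibration")
}

#' @export
print.numt_calibration <- function(x, ...) {
  cat(sprintf("numt_calibration: %.4f %% divergence per Myr (%d points, rmse %.3f)\n",
              x$slope, nrow(x$fit_points), x$rmse))
  invisible(x)
}

#' @export
coef.numt_calibration <- function(object, ...) c(slope = object$slope)

#' @export
predict.numt_calibration <- function(object, newdata, ...) {
  t <- if (is.list(newdata)) newdata[[1]] else newdata
  object$slope * t
}

#' Convert a divergence (with uncertainty) to time
#'
#' Inverts the linear calibration: `time = d / slope`, with the standard
#' deviation propagated linearly (`sd_time = sd_d / slope`).
#'
#' @param d Divergence in % (>= 0).
#' @param cal A [fit_calibration()] model.
#' @param sd Standard deviation of `d` (same units), default 0.
#' @return Object of class `time_estimate`: list with `time` (Myr), `sd`.
#' @examples
#' cal <- fit_calibration(data.frame(time = c(2, 9), divergence = c(2, 9)))
#' divergence_to_time(4.5, cal, sd = 0.8)  # 4.5 +/- 0.8 Myr
#' @export
divergence_to_time <- function(d, cal, sd = 0) {
  stopifnot(inherits(cal, "numt_calibration"))
  if (d < 0) stop("divergence must be >= 0")
  if (cal$slope <= 0) stop("calibration slope must be positive")
  structure(list(time = d / cal$slope, sd = sd / cal$slope),
            class = "time_estimate")
}

#' @export
print.time_estimate <- function(x, ...) {
  cat(sprintf("time estimate: %.2f +/- %.2f Myr\n", x$time, x$sd))
  invisible(x)
}

#' Does a large ancestral population explain the stem divergence?
#'
#' Regresses maximum intra-taxon mtDNA divergence on nuclear effective
#' population size across present-day populations, extrapolates to the
#' (larger) ancestral `Ne_nuc` with a 95% t-based prediction interval, and
#' asks whether the observed stem divergence could be mere standing
#' variation: the verdict is `does_not_explain` iff the observed value
#' exceeds the interval's upper bound. The `Ne_nuc`/`Ne_mit` ratio is assumed
#' stable across the extrapolation and carried as metadata only.
#'
#' @param points Data frame with columns `taxon`, `Ne_nuc`,
#'   `max_mtdna_divergence` (in %); at least 3 rows.
#' @param ancestral_ne Nuclear effective size of the ancestral population.
#' @param observed_stem Observed (corrected) stem divergence, %.
#' @return Object of class `ne_extrapolation`: list with `predicted`,
#'   `pi_lower`, `pi_upper` (95% prediction interval at `ancestral_ne`),
#'   `correlation` (Pearson r), `p_value`, `verdict`, `model` (the `lm` fit).
#' @export
ne_extrapolation <- function(points, ancestral_ne, observed_stem) {
  pts <- as.data.frame(points)
  need <- c("Ne_nuc", "max_mtdna_divergence")
  if (!all(need %in% names(pts))) {
    stop("points needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(pts) < 3L) {
    stop("need at least 3 population points for a prediction interval")
  }
  if (ancestral_ne <= 0) stop("ancestral_ne must be positive")
  if (any(pts$Ne_nuc <= 0) || any(pts$max_mtdna_divergence < 0)) {
    stop("Ne_nuc must be positive and divergences non-negative")
  }
  fit <- stats::lm(max_mtdna_divergence ~ Ne_nuc, data = pts)
  pred <- stats::predict(fit, newdata = data.frame(Ne_nuc = ancestral_ne),
                         interval = "prediction", level = 0.95)
  ct <- if (stats::sd(pts$max_mtdna_divergence) == 0) {
    list(estimate = c(cor = NA_real_), p.value = 1)  # flat response
  } else {
    stats::cor.test(pts$Ne_nuc, pts$max_mtdna_divergence)
  }
  verdict <- if (observed_stem > pred[1, "upr"]) "does_not_explain"
             else "explains"
  structure(list(predicted = unname(pred[1, "fit"]),
                 pi_lower = unname(pred[1, "lwr"]),
                 pi_upper = unname(pred[1, "upr"]),
                 correlation = unname(ct$estimate),
                 p_value = ct$p.value,
                 observed_stem = observed_stem,
                 ancestral_ne = ancestral_ne,
                 verdict = verdict,
                 model = fit),
            class = "ne_extrapolation")
}

#' @export
print.ne_extrapolation <- function(x, ...) {
  cat("Ne extrapolation (intra-population mtDNA divergence ~ Ne_nuc)\n")
  cat(sprintf("  correlation r = %.3f (p = %.3g)\n", x$correlation, x$p_value))
  cat(sprintf("  predicted divergence at Ne_nuc = %g: %.2f%% (95%% PI %.2f-%.2f)\n",
              x$ancestral_ne, x$predicted, x$pi_lower, x$pi_upper))
  cat(sprintf("  observed stem: %.2f%% -> verdict: %s\n",
              x$observed_stem, x$verdict))
  invisible(x)
}

#' Read a TSV table of labelled points
#'
#' Header-required tab-separated reader for calibration and population
#' tables.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv_points <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("TSV '", path, "' needs a header and >= 2 columns")
  df
}
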