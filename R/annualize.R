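#' Season-adjusted annual values
#'
#' Adjusts each measured concentration for seasonal variation by adding
#' the individual's deviation from the fitted seasonal curve to the annual
#' mean of the study sample: `annual = annual_mean + (measured - fitted)`.
#' For an unadjusted cosinor model the annual mean is the intercept; for
#' covariate-adjusted models it is the cohort average of the fitted values
#' with the sine/cosine (and interaction) terms zeroed, which reduces to
#' the intercept when no covariates are present.
#'
#' @param fit a [cosinor_fit()] (or [fit_season_dummy()]) object fitted to
#'   the same data.
#' @param data the cohort data frame the model was fitted to.
#' @return A data frame with one row per record used in the fit:
#'   `patient_id` (if present), `month`, `measured`, `fitted`, `annual`,
#'   plus attribute `annual_mean`. Records outside the model's
#'   complete-case set are omitted.
#' @export
annualize <- function(fit, data) {
  UseMethod("annualize")
}

#' @export
annualize.cosinor_fit <- function(fit, data) {
  rows <- fit$rows_used
  d <- data[rows, , drop = FALSE]
  measured <- fit$frame$.y
  seasonal_cols <- c("sin_m", "cos_m",
                     grep("\\.(sin|cos)$", fit$terms, value = TRUE))
  X_level <- cbind(intercept = 1,
                   as.matrix(fit$frame[, setdiff(fit$terms, seasonal_cols),
                                       drop = FALSE]))
  annual_mean <- mean(X_level %*% fit$beta[colnames(X_level)])
  out <- data.frame(
    month = d[[fit$month]],
    measured = measured,
    fitted = fit$fitted,
    annual = annual_mean + (measured - fit$fitted)
  )
  if (!is.null(d$patient_id)) out <- cbind(patient_id = d$patient_id, out)
  attr(out, "annual_mean") <- annual_mean
  out
}

#' @export
annualize.season_dummy_fit <- function(fit, data) {
  d <- data[fit$rows_used, , drop = FALSE]
  measured <- d[[fit$value]]
  fitted <- as.numeric(stats::fitted(fit$lm))
  # the step model has no seasonal-free level term; its annual mean is the
  # cohort average fitted value
  annual_mean <- mean(fitted)
  out <- data.frame(
    month = d[[fit$month]],
    measured = measured,
    fitted = fitted,
    annual = annual_mean + (measured - fitted)
  )
  if (!is.null(d$patient_id)) out <- cbind(patient_id = d$patient_id, out)
  attr(out, "annual_mean") <- annual_mean
  out
}

#' Classify vitamin D status against a sufficiency threshold
#'
#' @param value 25OHD concentration(s), nmol/l.
#' @param threshold sufficiency threshold (default 50 nmol/l); a value
#'   exactly at the threshold is sufficient.
#' @return Factor with levels `sufficient`, `insufficient`.
#' @export
#' @examples
#' classify_status(c(50, 49.999))
classify_status <- function(value, threshold = 50) {
  stopifnot(threshold > 0)
  factor(ifelse(value >= threshold, "sufficient", "insufficient"),
         levels = c("sufficient", "insufficient"))
}

# internal: percentages for one 2x2 status table
# counts: matrix [measured status x annual status], sufficient first
reclass_percentages <- function(counts) {
  n <- sum(counts)
  off <- counts[1, 2] + counts[2, 1]
  list(
    row_reclassified_pct = c(
      sufficient = 100 * counts[1, 2] / sum(counts[1, ]),
      insufficient = 100 * counts[2, 1] / sum(counts[2, ])
    ),
    total_reclassified_pct = 100 * off / n,
    n_reclassified = off,
    n = n,
    measured_insufficient_pct = 100 * sum(counts[2, ]) / n,
    annual_insufficient_pct = 100 * sum(counts[, 2]) / n
  )
}

#' Reclassification summary from printed 2x2 counts
#'
#' Computes row-wise and total reclassification percentages (and the
#' marginal insufficiency proportions) from a 2x2 cross-classification of
#' measured versus annual vitamin D status, with `sufficient` first in
#' both dimensions.
#'
#' @param counts 2x2 numeric matrix (rows: measured status, columns:
#'   annual status) or a length-4 vector in row-major order
#'   (suff/suff, suff/insuff, insuff/suff, insuff/insuff).
#' @return A list with `counts`, `row_reclassified_pct` (per measured
#'   status row), `total_reclassified_pct`, `n_reclassified`, `n`, and the
#'   marginal percentages `measured_insufficient_pct`,
#'   `annual_insufficient_pct`.
#' @export
#' @examples
#' reclassification_from_counts(c(2531, 183, 246, 1156))
reclassification_from_counts <- function(counts) {
  if (!is.matrix(counts)) {
    stopifnot(length(counts) == 4)
    counts <- matrix(counts, 2, 2, byrow = TRUE)
  }
  dimnames(counts) <- list(measured = c("sufficient", "insufficient"),
                           annual = c("sufficient", "insufficient"))
  c(list(counts = counts), reclass_percentages(counts))
}

#' Reclassification across the sufficiency threshold
#'
#' Cross-classifies measured versus season-adjusted (annual) vitamin D
#' status overall and within the dark (October--March) and bright
#' (April--September) periods, counting participants whose status changes
#' when the annual value replaces the measured one.
#'
#' @param measured,annual 25OHD concentrations (nmol/l), aligned per
#'   participant.
#' @param month calendar month of the measured sample (1--12); rows with
#'   missing month are kept in the all-year table but excluded from the
#'   period strata, with a warning.
#' @param threshold sufficiency threshold (default 50 nmol/l).
#' @return An object of class `reclassification`: a named list of strata
#'   (`all_year`, `dark`, `bright`), each as returned by
#'   [reclassification_from_counts()].
#' @export
reclassification <- function(measured, annual, month, threshold = 50) {
  stopifnot(length(measured) == length(annual),
            length(month) == length(measured))
  ms <- classify_status(measured, threshold)
  as_ <- classify_status(annual, threshold)
  if (anyNA(month))
    warning(sum(is.na(month)),
            " record(s) without month excluded from period strata")
  period <- rep(NA_character_, length(month))
  ok <- !is.na(month)
  period[ok] <- as.character(assign_calendar(month[ok])$period)
  strata <- list(all_year = rep(TRUE, length(month)),
                 dark = !is.na(period) & period == "dark",
                 bright = !is.na(period) & period == "bright")
  out <- lapply(strata, function(idx) {
    counts <- table(measured = ms[idx], annual = as_[idx])
    counts <- unclass(counts)[c("sufficient", "insufficient"),
                              c("sufficient", "insufficient")]
    c(list(counts = counts), reclass_percentages(counts))
  })
  structure(out, class = "reclassification", threshold = threshold)
}

#' @export
print.reclassification <- function(x, ...) {
  cat("Reclassification across the", attr(x, "threshold"),
      "nmol/l sufficiency threshold\n")
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("\n%s (n = %d)\n", nm, s$n))
    tab <- cbind(s$counts,
                 reclassified_pct = round(s$row_reclassified_pct, 1))
    print(tab)
    cat(sprintf("  total reclassified: %d (%.1f%%)\n", s$n_reclassified,
                s$total_reclassified_pct))
  }
  invisible(x)
}

#' Peak concentration required to remain sufficient at the trough
#'
#' If the seasonal peak-trough difference is `peak_trough`, a participant
#' measured at the seasonal peak must exceed
#' `threshold + peak_trough` to remain above the sufficiency threshold at
#' the trough.
#'
#' @param peak_trough peak-to-trough seasonal difference (nmol/l).
#' @param threshold sufficiency threshold (default 50 nmol/l).
#' @return Required peak concentration (nmol/l).
#' @export
#' @examples
#' required_peak(15.8)  # 65.8
required_peak <- function(peak_trough, threshold = 50) {
  stopifnot(peak_trough >= 0)
  threshold + peak_trough
}

#' Seasonal variation as a percentage of the annual mean
#'
#' @param peak_trough peak-to-trough seasonal difference (nmol/l).
#' @param mesor annual mean (nmol/l).
#' @return `100 * peak_trough / mesor` (percent).
#' @export
#' @examples
#' seasonal_ratio(15.8, 59.6)  # 26.5
seasonal_ratio <- function(peak_trough, mesor) {
  stopifnot(mesor > 0)
  100 * peak_trough / mesor
}

#' Amplitude of a sinusoid from its peak-trough difference
#'
#' @param peak_trough peak-to-trough difference (nmol/l).
#' @return Half the peak-trough difference (nmol/l).
#' @export
peak_trough_to_amplitude <- function(peak_trough) peak_trough / 2
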