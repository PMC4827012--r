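#' Anchored cosinor prediction of a follow-up concentration
#'
#' Predicts a patient's 25OHD concentration at a follow-up month from a
#' single baseline measurement: the fitted seasonal curve (at the
#' patient's covariate values, if the model has covariate interactions) is
#' shifted vertically so that it passes through the observed baseline
#' value, and read off at the follow-up month. Level terms cancel in the
#' construction, so
#' `predicted = baseline + curve(followup_month) - curve(baseline_month)`.
#'
#' @param fit a [cosinor_fit()] object fitted to the baseline cohort.
#' @param baseline_value measured baseline 25OHD (nmol/l).
#' @param baseline_month,followup_month calendar months 1--12 (vectors
#'   recycle against `baseline_value`).
#' @param at covariate setting: either a single named list applied to all
#'   rows, or a data frame with one row per prediction holding the
#'   covariates the fit interacts with.
#' @return Numeric vector of predicted concentrations (nmol/l).
#' @export
#' @examples
#' d <- data.frame(month = rep(1:12, 5))
#' d$ohd <- 60 + 5 * sin(2 * pi * d$month / 12)
#' fit <- cosinor_fit(d)
#' predict_cosinor(fit, 60, baseline_month = 3, followup_month = 9)  # 50
predict_cosinor <- function(fit, baseline_value, baseline_month,
                            followup_month, at = NULL) {
  n <- max(length(baseline_value), length(baseline_month),
           length(followup_month))
  baseline_value <- rep_len(baseline_value, n)
  baseline_month <- rep_len(baseline_month, n)
  followup_month <- rep_len(followup_month, n)
  if (any(c(baseline_month, followup_month) < 1 |
            c(baseline_month, followup_month) > 12, na.rm = TRUE))
    stop("months must lie in 1..12")
  interacted <- names(Filter(function(m) m$interacted, fit$meta))
  if (length(interacted) && is.null(at))
    stop("fit interacts with covariate(s) ",
         paste(interacted, collapse = ", "),
         "; supply them via 'at'")
  if (is.data.frame(at)) {
    missing_cov <- setdiff(interacted, names(at))
    if (length(missing_cov))
      stop("covariate(s) missing from 'at': ",
           paste(missing_cov, collapse = ", "))
    out <- numeric(n)
    for (i in seq_len(n)) {
      setting <- lapply(at[min(i, nrow(at)), interacted, drop = FALSE],
                        as.character)
      if (anyNA(unlist(setting))) { out[i] <- NA_real_; next }
      out[i] <- baseline_value[i] +
        seasonal_component(fit, followup_month[i], setting) -
        seasonal_component(fit, baseline_month[i], setting)
    }
    out
  } else {
    baseline_value +
      seasonal_component(fit, followup_month, at) -
      seasonal_component(fit, baseline_month, at)
  }
}

#' Baseline value carried forward
#'
#' The naive prediction that a future measurement equals the baseline
#' measurement.
#'
#' @param baseline_value measured baseline 25OHD (nmol/l).
#' @return `baseline_value`, unchanged.
#' @export
predict_baseline_carry <- function(baseline_value) baseline_value

#' Fit a season-dummy linear model
#'
#' Linear regression of the outcome on quarterly season indicators
#' (Jan--Mar reference), the step-function counterpart of the cosinor
#' curve.
#'
#' @param data baseline cohort data frame with `month` and outcome columns.
#' @param value,month outcome and month columns.
#' @return A list of class `season_dummy_fit` with `season_means` (fitted
#'   mean per quarter), the `lm` object and `n_used`.
#' @export
fit_season_dummy <- function(data, value = "ohd", month = "month") {
  cc <- stats::complete.cases(data[, c(value, month)])
  d <- data[cc, , drop = FALSE]
  season <- assign_calendar(d[[month]])$season
  lmfit <- stats::lm(d[[value]] ~ season)
  means <- stats::setNames(
    stats::predict(lmfit,
                   newdata = data.frame(season = factor(levels(season),
                                                        levels = levels(season)))),
    levels(season))
  structure(list(season_means = means, lm = lmfit, n_used = sum(cc),
                 rows_used = which(cc), value = value, month = month),
            class = "season_dummy_fit")
}

#' Anchored season-dummy prediction
#'
#' Same anchoring construction as [predict_cosinor()] but with the fitted
#' quarterly step function as the seasonal curve: the predicted follow-up
#' value is the baseline value plus the difference between the fitted
#' season means of the follow-up and baseline quarters. Baseline and
#' follow-up in the same quarter therefore return the baseline value.
#'
#' @param fit a [fit_season_dummy()] object.
#' @inheritParams predict_cosinor
#' @return Numeric vector of predicted concentrations (nmol/l).
#' @export
predict_season_dummy <- function(fit, baseline_value, baseline_month,
                                 followup_month) {
  s_b <- as.character(assign_calendar(baseline_month)$season)
  s_f <- as.character(assign_calendar(followup_month)$season)
  baseline_value + fit$season_means[s_f] - fit$season_means[s_b]
}

#' Compare prediction methods on follow-up data
#'
#' Summarises per-observation predictions of several methods against
#' measured follow-up values: Pearson correlation (Fisher-z 95% CI), mean
#' squared error (MSE), its square root (RMSE), the SD of the predicted
#' values, the proportion of predictions within 10 nmol/l of the
#' measurement, and a paired t-test on per-observation squared errors
#' against a reference method.
#'
#' @param predictions data frame with columns `method`, `measured`,
#'   `predicted`, and an observation identifier `obs` aligning rows across
#'   methods.
#' @param reference name of the reference method for the paired t-tests.
#' @param within margin (nmol/l) for the `prop_within` column (default 10).
#' @return A data frame of class `method_comparison`, one row per method:
#'   `method`, `n`, `pearson_r`, `r_ci_lower`, `r_ci_upper`, `mse`,
#'   `rmse`, `sd_pred`, `prop_within`, `p_vs_reference` (`NA` for the
#'   reference itself).
#' @export
evaluate_predictions <- function(predictions, reference, within = 10) {
  stopifnot(all(c("method", "obs", "measured", "predicted") %in%
                  names(predictions)))
  methods <- unique(predictions$method)
  if (!reference %in% methods) stop("reference method not present")
  split_m <- split(predictions, predictions$method)
  obs_sets <- lapply(split_m, function(d) sort(d$obs))
  if (!all(vapply(obs_sets, identical, logical(1), obs_sets[[1]])))
    stop("methods do not cover the same observation set")
  split_m <- lapply(split_m, function(d) d[order(d$obs), , drop = FALSE])
  ref_se <- with(split_m[[reference]], (predicted - measured)^2)

  rows <- lapply(methods, function(m) {
    d <- split_m[[m]]
    err <- d$predicted - d$measured
    se2 <- err^2
    keep <- !is.na(se2)
    n <- sum(keep)
    r <- stats::cor(d$predicted[keep], d$measured[keep])
    z <- atanh(r)
    zci <- z + c(-1, 1) * 1.96 / sqrt(n - 3)
    p_ref <- if (m == reference) NA_real_ else {
      pair <- keep & !is.na(ref_se)
      d_se <- se2[pair] - ref_se[pair]
      if (all(d_se == 0)) NA_real_ else stats::t.test(d_se)$p.value
    }
    data.frame(
      method = m, n = n,
      pearson_r = r, r_ci_lower = tanh(zci[1]), r_ci_upper = tanh(zci[2]),
      mse = mean(se2[keep]), rmse = sqrt(mean(se2[keep])),
      sd_pred = stats::sd(d$predicted[keep]),
      prop_within = mean(abs(err[keep]) < within),
      p_vs_reference = p_ref,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("method_comparison", "data.frame")
  out
}

#' Predict all follow-up rows of a cohort with the standard methods
#'
#' Runs the full follow-up prediction comparison on a cohort table
#' containing baseline and follow-up visits: fits the baseline cosinor
#' models (unadjusted, plus-age, multivariate) and the season-dummy
#' regression on the baseline rows, then predicts every follow-up
#' measurement from the same patient's baseline value.
#'
#' @param data cohort data frame with a `visit` column (`baseline` vs
#'   follow-up rows), `patient_id`, `month` and the outcome.
#' @param value,month outcome and month columns.
#' @param multivariate covariates of the multivariate cosinor model
#'   (interacting with the seasonal terms).
#' @return A list with `predictions` (long data frame: one row per
#'   follow-up observation and method) and `comparison`
#'   ([evaluate_predictions()] against the unadjusted cosinor model).
#' @export
predict_followups <- function(data, value = "ohd", month = "month",
                              multivariate = c("age_group", "gender",
                                               "smoker", "supplements")) {
  base <- data[data$visit == "baseline", , drop = FALSE]
  fup <- data[data$visit != "baseline", , drop = FALSE]
  if (!nrow(fup)) stop("no follow-up rows in the cohort")
  bl <- base[match(fup$patient_id, base$patient_id), , drop = FALSE]
  if (anyNA(bl$patient_id)) stop("follow-up rows without a baseline row")

  fit0 <- cosinor_fit(base, value = value, month = month)
  fit_age <- cosinor_fit(base, value = value, month = month,
                         covariates = "age_group", interactions = "age_group")
  fit_mv <- cosinor_fit(base, value = value, month = month,
                        covariates = multivariate,
                        interactions = multivariate)
  fit_sd <- fit_season_dummy(base, value = value, month = month)

  obs <- seq_len(nrow(fup))
  mk <- function(method, predicted) data.frame(
    method = method, obs = obs, patient_id = fup$patient_id,
    baseline_month = bl[[month]], followup_month = fup[[month]],
    baseline_value = bl[[value]], measured = fup[[value]],
    predicted = as.numeric(predicted), stringsAsFactors = FALSE)

  preds <- rbind(
    mk("cosinor_unadjusted",
       predict_cosinor(fit0, bl[[value]], bl[[month]], fup[[month]])),
    mk("cosinor_plus_age",
       predict_cosinor(fit_age, bl[[value]], bl[[month]], fup[[month]],
                       at = bl)),
    mk("cosinor_multivariate",
       predict_cosinor(fit_mv, bl[[value]], bl[[month]], fup[[month]],
                       at = bl)),
    mk("baseline_carry", predict_baseline_carry(bl[[value]])),
    mk("season_dummy",
       predict_season_dummy(fit_sd, bl[[value]], bl[[month]], fup[[month]]))
  )
  preds$squared_error <- (preds$predicted - preds$measured)^2
  complete <- !is.na(preds$predicted) & !is.na(preds$measured)
  keep_obs <- Reduce(intersect, split(preds$obs[complete], preds$method[complete]))
  cmp <- evaluate_predictions(preds[preds$obs %in% keep_obs, , drop = FALSE],
                              reference = "cosinor_unadjusted")
  list(predictions = preds, comparison = cmp)
}

#' @export
print.method_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$pearson_r <- sprintf("%.2f (%.2f, %.2f)", df$pearson_r, df$r_ci_lower,
                          df$r_ci_upper)
  df$mse <- round(df$mse); df$rmse <- round(df$rmse, 1)
  df$sd_pred <- round(df$sd_pred, 1)
  df$prop_within <- sprintf("%.0f%%", 100 * df$prop_within)
  df$p_vs_reference <- ifelse(is.na(df$p_vs_reference), "Ref.",
                              format.pval(df$p_vs_reference, digits = 3,
                                          eps = 1e-3))
  print(df[, c("method", "n", "pearson_r", "mse", "rmse", "sd_pred",
               "prop_within", "p_vs_reference")], row.names = FALSE)
  invisible(x)
}
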