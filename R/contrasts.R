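#' Covariate contrasts on the annual mean
#'
#' Fits a cosinor model with level-shift terms for one covariate (plus any
#' adjustment covariates) and reports, for each non-reference level, the
#' difference in annual mean concentration versus the reference level with
#' its Wald z test. Level shifts move the fitted sine curve up or down
#' without changing its shape, so these are differences in MESOR.
#'
#' @param data cohort data frame.
#' @param covariate covariate column to contrast.
#' @param adjust character vector of adjustment covariates entering as
#'   level shifts (e.g. `c("age_group", "gender", "site", "bmi_group",
#'   "smoker")` for the adjusted models).
#' @param value,month outcome and month columns.
#' @param conf_mult Wald interval multiplier (default 1.96).
#' @return A data frame of class `group_contrast` with one row per
#'   non-reference level: `covariate`, `level`, `quantity`
#'   (`annual_mean_diff`), `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `p_value`, `model` (`unadjusted`/`adjusted`), `n_used`.
#' @export
mean_contrast <- function(data, covariate, adjust = character(),
                          value = "ohd", month = "month", conf_mult = 1.96) {
  fit <- cosinor_fit(data, value = value, month = month,
                     covariates = c(covariate, adjust))
  info <- fit$meta[[covariate]]
  est <- fit$beta[info$dummies]
  se <- sqrt(diag(fit$vcov)[info$dummies])
  z <- est / se
  out <- data.frame(
    covariate = covariate,
    level = sub(paste0("^", covariate, "_"), "", info$dummies),
    quantity = "annual_mean_diff",
    estimate = unname(est), se = unname(se),
    ci_lower = unname(est - conf_mult * se),
    ci_upper = unname(est + conf_mult * se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    model = if (length(adjust)) "adjusted" else "unadjusted",
    n_used = fit$n_used,
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_contrast", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Covariate contrasts on seasonal variation (peak-trough)
#'
#' Fits a cosinor model with interactions between one covariate's
#' indicators and the sine and cosine terms (adjustment covariates enter
#' as level shifts only) and reports, per non-reference level, the
#' difference in peak-trough seasonal variation: \eqn{2A_\ell - 2A_{ref}}
#' where \eqn{A_\ell} is the amplitude at level \eqn{\ell}. The standard
#' error comes from the delta method over the joint covariance of the
#' sine, cosine and interaction coefficients; with \eqn{(s, c)} the
#' reference and \eqn{(s_\ell, c_\ell) = (s + \delta_s, c + \delta_c)} the
#' level-specific coefficients, the gradient of the difference is
#' \eqn{2(s_\ell/A_\ell - s/A, \; c_\ell/A_\ell - c/A)} with respect to
#' \eqn{(s, c)} and \eqn{2(s_\ell/A_\ell, \; c_\ell/A_\ell)} with respect
#' to \eqn{(\delta_s, \delta_c)}.
#'
#' @inheritParams mean_contrast
#' @return A `group_contrast` data frame as in [mean_contrast()] with
#'   `quantity = "peak_trough_diff"`.
#' @export
amplitude_contrast <- function(data, covariate, adjust = character(),
                               value = "ohd", month = "month",
                               conf_mult = 1.96) {
  fit <- cosinor_fit(data, value = value, month = month,
                     covariates = c(covariate, adjust),
                     interactions = covariate)
  info <- fit$meta[[covariate]]
  s0 <- fit$beta[["sin_m"]]; c0 <- fit$beta[["cos_m"]]
  A0 <- sqrt(s0^2 + c0^2)
  rows <- lapply(info$dummies, function(cn) {
    ds <- fit$beta[[paste0(cn, ".sin")]]
    dc <- fit$beta[[paste0(cn, ".cos")]]
    sl <- s0 + ds; cl <- c0 + dc
    Al <- sqrt(sl^2 + cl^2)
    est <- 2 * (Al - A0)
    # delta gradient over (sin_m, cos_m, dummy.sin, dummy.cos)
    grad <- 2 * c(sl / Al - s0 / A0, cl / Al - c0 / A0, sl / Al, cl / Al)
    names(grad) <- c("sin_m", "cos_m", paste0(cn, ".sin"), paste0(cn, ".cos"))
    se <- delta_from_gradient(fit, grad)
    z <- est / se
    data.frame(
      covariate = covariate,
      level = sub(paste0("^", covariate, "_"), "", cn),
      quantity = "peak_trough_diff",
      estimate = est, se = se,
      ci_lower = est - conf_mult * se, ci_upper = est + conf_mult * se,
      p_value = 2 * stats::pnorm(-abs(z)),
      model = if (length(adjust)) "adjusted" else "unadjusted",
      n_used = fit$n_used,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_contrast", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Joint Wald test on a coefficient subset
#'
#' Quadratic-form Wald test \eqn{W = \theta' V^{-1} \theta} for the
#' hypothesis that a subset of coefficients is jointly zero, with
#' \eqn{\chi^2} reference distribution on as many degrees of freedom as
#' coefficients tested. For a single coefficient this reduces to the
#' square of the usual z statistic.
#'
#' @param fit a [cosinor_fit()] object.
#' @param coefs character vector of coefficient names (see
#'   `names(coef(fit))`).
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
joint_wald <- function(fit, coefs) {
  missing_coefs <- setdiff(coefs, names(fit$beta))
  if (length(missing_coefs))
    stop("coefficients not in the fit: ", paste(missing_coefs, collapse = ", "))
  theta <- fit$beta[coefs]
  V <- fit$vcov[coefs, coefs, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance submatrix for the requested coefficients"))
  W <- drop(t(theta) %*% Vi %*% theta)
  list(statistic = W, df = length(coefs),
       p_value = stats::pchisq(W, df = length(coefs), lower.tail = FALSE))
}

#' Full covariate association table
#'
#' Convenience wrapper reproducing the structure of a covariate
#' association table: for each covariate, unadjusted and adjusted
#' differences in annual mean and in peak-trough seasonal variation, each
#' with 95% CI and Wald p. No multiplicity correction is applied.
#'
#' @param data cohort data frame.
#' @param covariates covariate columns to contrast (each in turn).
#' @param adjust adjustment set for the adjusted models.
#' @inheritParams mean_contrast
#' @return A `group_contrast` data frame stacking all contrasts.
#' @export
contrast_table <- function(data,
                           covariates = c("gender", "age_group", "site",
                                          "smoker", "bmi_group", "activity",
                                          "egfr_group", "crp_group",
                                          "supplements", "diabetes"),
                           adjust = c("age_group", "gender", "site",
                                      "bmi_group", "smoker"),
                           value = "ohd", month = "month") {
  rows <- list()
  for (cov in covariates) {
    adj <- setdiff(adjust, cov)
    rows[[length(rows) + 1]] <- mean_contrast(data, cov, value = value,
                                              month = month)
    rows[[length(rows) + 1]] <- amplitude_contrast(data, cov, value = value,
                                                   month = month)
    rows[[length(rows) + 1]] <- mean_contrast(data, cov, adjust = adj,
                                              value = value, month = month)
    rows[[length(rows) + 1]] <- amplitude_contrast(data, cov, adjust = adj,
                                                   value = value, month = month)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("group_contrast", "data.frame")
  out
}

#' @export
print.group_contrast <- function(x, ...) {
  df <- as.data.frame(x)
  df$estimate <- sprintf("%.1f (%.1f, %.1f)", df$estimate, df$ci_lower,
                         df$ci_upper)
  df$p_value <- format.pval(df$p_value, digits = 3, eps = 1e-3)
  print(df[, c("covariate", "level", "quantity", "model", "estimate",
               "p_value", "n_used")], row.names = FALSE)
  invisible(x)
}
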