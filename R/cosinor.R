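#' Build the cosinor design matrix
#'
#' Constructs the regression frame for a single-component cosinor model
#' with a fixed period: an intercept, \eqn{\sin(2\pi m/T)} and
#' \eqn{\cos(2\pi m/T)} of the calendar month \eqn{m}, treatment-coded
#' indicator columns for each categorical covariate, and (for covariates in
#' `interactions`) products of each indicator with the sine and cosine
#' terms. Only complete cases for the variables involved are retained.
#'
#' @param data cohort data frame (see [read_cohort()]).
#' @param value name of the outcome column (nmol/l).
#' @param month name of the month column (integer 1--12).
#' @param covariates character vector of covariate columns entering as
#'   level shifts.
#' @param interactions character vector of covariate columns whose
#'   indicators also interact with the sine and cosine terms; implicitly
#'   added to `covariates`.
#' @param period period of the harmonic in months (default 12; fixed, not
#'   estimated).
#' @return A list with the model frame `frame` (outcome `.y`, predictors),
#'   predictor column names `terms`, covariate metadata `meta`
#'   (per covariate: levels, reference, dummy column names), `rows_used`
#'   (row indices of `data` retained) and `n_used`.
#' @export
cosinor_design <- function(data, value = "ohd", month = "month",
                           covariates = character(),
                           interactions = character(), period = 12) {
  stopifnot(period > 0)
  covariates <- union(covariates, interactions)
  needed <- c(value, month, covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))

  cc <- stats::complete.cases(data[, needed, drop = FALSE])
  if (!any(cc)) stop("no complete cases for the requested model")
  d <- data[cc, , drop = FALSE]

  m <- d[[month]]
  if (any(m < 1 | m > 12)) stop("month must lie in 1..12")
  theta <- 2 * pi * m / period
  frame <- data.frame(.y = d[[value]], sin_m = sin(theta), cos_m = cos(theta))
  terms <- c("sin_m", "cos_m")

  meta <- list()
  for (cov in covariates) {
    x <- d[[cov]]
    if (is.logical(x)) x <- factor(x, levels = c(FALSE, TRUE),
                                   labels = c("no", "yes"))
    if (!is.factor(x)) x <- factor(x)
    x <- droplevels(x)
    lev <- levels(x)
    if (length(lev) < 2)
      stop("covariate '", cov, "' has a single level in the complete cases")
    dummy_cols <- character(0)
    for (l in lev[-1]) {
      cn <- paste0(cov, "_", l)
      frame[[cn]] <- as.numeric(x == l)
      dummy_cols <- c(dummy_cols, cn)
    }
    meta[[cov]] <- list(levels = lev, ref = lev[1], dummies = dummy_cols,
                        interacted = cov %in% interactions)
    terms <- c(terms, dummy_cols)
    if (cov %in% interactions) {
      for (cn in dummy_cols) {
        frame[[paste0(cn, ".sin")]] <- frame[[cn]] * frame$sin_m
        frame[[paste0(cn, ".cos")]] <- frame[[cn]] * frame$cos_m
        terms <- c(terms, paste0(cn, ".sin"), paste0(cn, ".cos"))
      }
    }
  }
  list(frame = frame, terms = terms, meta = meta,
       rows_used = which(cc), n_used = nrow(frame), period = period,
       value = value, month = month)
}

#' Fit a single-component cosinor model
#'
#' Ordinary least squares regression of a concentration on
#' \eqn{\sin(2\pi m/T)} and \eqn{\cos(2\pi m/T)} of the calendar month,
#' optionally with categorical covariates as level shifts and with
#' covariate-by-(sine, cosine) interactions so that amplitude and phase may
#' differ between covariate levels. The intercept estimates the annual
#' mean (MESOR) at reference covariate levels; amplitude and phase are
#' derived from the sine/cosine coefficients (see [seasonal_summary()]).
#'
#' @inheritParams cosinor_design
#' @return An object of class `cosinor_fit`: a list with `beta`
#'   (named coefficients), `vcov` (classical OLS covariance
#'   \eqn{\hat\sigma^2 (X'X)^{-1}}), `sigma_hat` (residual SD),
#'   `residuals`, `fitted`, `n_used`, `rows_used`, `meta`, `period`, and
#'   the underlying `lm` object as `lm`.
#' @seealso [seasonal_summary()], [delta_se()], [mean_contrast()],
#'   [amplitude_contrast()]
#' @export
#' @examples
#' d <- data.frame(month = rep(1:12, 4))
#' d$ohd <- 60 + 5 * sin(2 * pi * d$month / 12)
#' coef(cosinor_fit(d))
cosinor_fit <- function(data, value = "ohd", month = "month",
                        covariates = character(),
                        interactions = character(), period = 12) {
  des <- cosinor_design(data, value = value, month = month,
                        covariates = covariates,
                        interactions = interactions, period = period)
  p <- length(des$terms) + 1L
  if (des$n_used <= p)
    stop("need more complete cases (", des$n_used, ") than parameters (", p, ")")
  fml <- stats::as.formula(paste(".y ~", paste(des$terms, collapse = " + ")))
  lmfit <- stats::lm(fml, data = des$frame)
  beta <- stats::coef(lmfit)
  if (anyNA(beta))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  names(beta)[1] <- "intercept"
  V <- stats::vcov(lmfit)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(
    beta = beta, vcov = V,
    sigma_hat = summary(lmfit)$sigma,
    residuals = stats::residuals(lmfit),
    fitted = stats::fitted(lmfit),
    n_used = des$n_used, rows_used = des$rows_used,
    meta = des$meta, period = des$period,
    value = value, month = month,
    frame = des$frame, terms = des$terms, lm = lmfit
  ), class = "cosinor_fit")
}

#' @export
coef.cosinor_fit <- function(object, ...) object$beta

#' @export
vcov.cosinor_fit <- function(object, ...) object$vcov

#' @export
residuals.cosinor_fit <- function(object, ...) object$residuals

#' @export
fitted.cosinor_fit <- function(object, ...) object$fitted

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit (period", x$period, "months), n =", x$n_used, "\n")
  print(round(x$beta, 4))
  cat("Residual SD:", round(x$sigma_hat, 3), "\n")
  invisible(x)
}

# internal: resolve a covariate setting into active dummy / interaction
# columns. `at` is a named list/vector covariate -> level; covariates not
# mentioned sit at their reference level.
active_columns <- function(fit, at = NULL) {
  level_cols <- character(0); sin_cols <- character(0); cos_cols <- character(0)
  at <- as.list(at)
  unknown <- setdiff(names(at), names(fit$meta))
  if (length(unknown))
    stop("covariate(s) not in the fit: ", paste(unknown, collapse = ", "))
  for (cov in names(at)) {
    lev <- as.character(at[[cov]])
    info <- fit$meta[[cov]]
    if (!lev %in% info$levels)
      stop("'", lev, "' is not a level of covariate '", cov, "'")
    if (lev == info$ref) next
    cn <- paste0(cov, "_", lev)
    level_cols <- c(level_cols, cn)
    if (info$interacted) {
      sin_cols <- c(sin_cols, paste0(cn, ".sin"))
      cos_cols <- c(cos_cols, paste0(cn, ".cos"))
    }
  }
  list(level = level_cols,
       sin = c("sin_m", sin_cols), cos = c("cos_m", cos_cols))
}

# internal: delta-method SE of g(beta): sqrt(grad' V grad), grad given as a
# named vector over a subset of coefficients.
delta_from_gradient <- function(fit, grad) {
  V <- fit$vcov[names(grad), names(grad), drop = FALSE]
  as.numeric(sqrt(drop(t(grad) %*% V %*% grad)))
}

#' Delta-method standard error of amplitude or phase
#'
#' First-order (delta method) standard error of a nonlinear function of
#' the cosinor coefficients, at a given covariate setting. Writing
#' \eqn{s} and \eqn{c} for the active sine and cosine coefficients and
#' \eqn{A = \sqrt{s^2 + c^2}}, the gradients are \eqn{(s/A,\; c/A)} for
#' the amplitude and \eqn{(c/A^2,\; -s/A^2)\,T/2\pi} for the peak
#' location in months.
#'
#' @param fit a [cosinor_fit()] object.
#' @param what `"amplitude"`, `"peak_trough"` (twice the amplitude) or
#'   `"phase"` (peak month).
#' @param at named covariate setting (covariate = level); omitted
#'   covariates sit at their reference level.
#' @return The standard error (nmol/l, or months for `"phase"`).
#' @export
delta_se <- function(fit, what = c("amplitude", "peak_trough", "phase"),
                     at = NULL) {
  what <- match.arg(what)
  ac <- active_columns(fit, at)
  s <- sum(fit$beta[ac$sin]); c <- sum(fit$beta[ac$cos])
  A <- sqrt(s^2 + c^2)
  if (A == 0) {
    if (what == "phase") stop("amplitude is zero; phase is undefined")
    return(0)
  }
  if (what == "phase") {
    g <- c(rep(c / A^2, length(ac$sin)), rep(-s / A^2, length(ac$cos))) *
      fit$period / (2 * pi)
  } else {
    scale <- if (what == "peak_trough") 2 else 1
    g <- scale * c(rep(s / A, length(ac$sin)), rep(c / A, length(ac$cos)))
  }
  names(g) <- c(ac$sin, ac$cos)
  delta_from_gradient(fit, g)
}

#' Summarise the fitted seasonal curve
#'
#' Derives the annual mean (MESOR), amplitude, peak-trough difference and
#' the peak and trough months from a fitted cosinor model at a chosen
#' covariate setting, with delta-method standard errors and Wald 95%
#' confidence intervals. With active sine coefficient \eqn{s} and cosine
#' coefficient \eqn{c}, the amplitude is \eqn{A = \sqrt{s^2+c^2}} and the
#' peak sits at \eqn{\mathrm{atan2}(s, c)\cdot T/2\pi} months (mod
#' \eqn{T}); by symmetry the trough is half a period later.
#'
#' @inheritParams delta_se
#' @param conf_mult multiplier for the Wald intervals (default 1.96).
#' @return An object of class `seasonal_summary`: a list with `mesor`,
#'   `amplitude`, `peak_trough`, `peak_month`, `trough_month`, each `se_*`
#'   and `ci_*` (95% Wald), `phase_defined`, `n_used` and the setting `at`.
#'   `peak_month` is a continuous month in [0, 12) with month 1 = January
#'   (so 7.5 means mid July--August). If the amplitude is exactly zero the
#'   phase is undefined and flagged.
#' @export
#' @examples
#' d <- data.frame(month = rep(1:12, 20))
#' set.seed(1)
#' d$ohd <- 60 + 5 * sin(2 * pi * d$month / 12) + rnorm(nrow(d), 0, 2)
#' seasonal_summary(cosinor_fit(d))
seasonal_summary <- function(fit, at = NULL, conf_mult = 1.96) {
  ac <- active_columns(fit, at)
  s <- sum(fit$beta[ac$sin]); c <- sum(fit$beta[ac$cos])
  A <- sqrt(s^2 + c^2)
  mesor_cols <- c("intercept", ac$level)
  mesor <- sum(fit$beta[mesor_cols])
  g_m <- stats::setNames(rep(1, length(mesor_cols)), mesor_cols)
  se_mesor <- delta_from_gradient(fit, g_m)

  phase_defined <- A > 0
  if (phase_defined) {
    peak <- (atan2(s, c) * fit$period / (2 * pi)) %% fit$period
    trough <- (peak + fit$period / 2) %% fit$period
    se_A <- delta_se(fit, "amplitude", at)
    se_peak <- delta_se(fit, "phase", at)
  } else {
    peak <- trough <- NA_real_
    se_A <- NA_real_
    se_peak <- NA_real_
  }
  ci <- function(est, se) est + c(-1, 1) * conf_mult * se
  structure(list(
    mesor = mesor, se_mesor = se_mesor, ci_mesor = ci(mesor, se_mesor),
    amplitude = A, se_amplitude = se_A,
    ci_amplitude = if (phase_defined) ci(A, se_A) else c(NA, NA),
    peak_trough = 2 * A, se_peak_trough = 2 * se_A,
    ci_peak_trough = if (phase_defined) ci(2 * A, 2 * se_A) else c(NA, NA),
    peak_month = peak, trough_month = trough, se_peak_month = se_peak,
    ci_peak_month = if (phase_defined) ci(peak, se_peak) else c(NA, NA),
    phase_defined = phase_defined,
    at = at, n_used = fit$n_used
  ), class = "seasonal_summary")
}

#' @export
print.seasonal_summary <- function(x, ...) {
  fmt <- function(est, ci) sprintf("%.1f (%.1f, %.1f)", est, ci[1], ci[2])
  cat("Seasonal summary (n =", x$n_used, ")\n")
  cat("  Annual mean (MESOR):", fmt(x$mesor, x$ci_mesor), "nmol/l\n")
  if (x$phase_defined) {
    cat("  Amplitude:          ", fmt(x$amplitude, x$ci_amplitude), "nmol/l\n")
    cat("  Peak-trough:        ", fmt(x$peak_trough, x$ci_peak_trough),
        "nmol/l\n")
    cat("  Peak month:         ", fmt(x$peak_month, x$ci_peak_month),
        "(trough", sprintf("%.1f", x$trough_month), ")\n")
  } else {
    cat("  Amplitude: 0 -- flat curve, phase undefined\n")
  }
  invisible(x)
}

#' Seasonal curve value at given months
#'
#' Evaluates the seasonal component \eqn{s\,\sin(2\pi m/T) +
#' c\,\cos(2\pi m/T)} of a fitted cosinor model (level terms excluded) at
#' the given months and covariate setting.
#'
#' @inheritParams delta_se
#' @param month numeric vector of months (may be fractional).
#' @return Numeric vector of seasonal deviations from the annual mean
#'   (nmol/l).
#' @export
seasonal_component <- function(fit, month, at = NULL) {
  ac <- active_columns(fit, at)
  s <- sum(fit$beta[ac$sin]); c <- sum(fit$beta[ac$cos])
  theta <- 2 * pi * month / fit$period
  s * sin(theta) + c * cos(theta)
}

#' Export a cosinor fit as JSON
#'
#' Machine-readable summary containing the coefficients, their covariance
#' matrix and the [seasonal_summary()] at reference covariates.
#'
#' @inheritParams delta_se
#' @param path optional file to write to.
#' @return JSON string, invisibly if written to `path`.
#' @export
cosinor_json <- function(fit, path = NULL) {
  ss <- seasonal_summary(fit)
  obj <- list(
    beta = as.list(fit$beta),
    vcov = fit$vcov,
    n_used = fit$n_used,
    sigma_hat = fit$sigma_hat,
    summary = ss[c("mesor", "se_mesor", "amplitude", "se_amplitude",
                   "peak_trough", "peak_month", "trough_month",
                   "se_peak_month")]
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
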