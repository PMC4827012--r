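#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: a
#' Norwegian cardiovascular cohort of ~4116 baseline 25OHD measurements
#' with a sinusoidal seasonal mean (cohort annual mean 59.6 nmol/l,
#' amplitude 7.9 nmol/l i.e. peak-trough 15.8 nmol/l, peak at month 7.5 --
#' between July and August), covariate shifts of the annual mean, an
#' age-dependent reduction of the seasonal swing, Gaussian residuals with
#' SD 19 nmol/l, and a nested subgroup of 271 patients with follow-up
#' measurements ~1 and ~12 months after baseline (expected total 528).
#'
#' Covariate effects are expressed as level-versus-reference differences
#' and are centred at their generating prevalences, so `mesor` and
#' `amplitude` are the marginal (cohort-level) parameters; differences
#' between covariate levels are unaffected by the centring.
#' `amplitude_effects` are on the peak-trough scale (a level effect of
#' -6.3 lowers that level's amplitude by 3.15 nmol/l).
#'
#' The residual SD decomposes into a person-level intercept
#' (SD \eqn{\sqrt{residual\_sd^2 - within\_person\_sd^2}}) shared by all of a
#' patient's visits and a within-person component (SD `within_person_sd`)
#' whose correlation between two visits decays as
#' \eqn{\exp(-\Delta/serial\_range)} with the lag \eqn{\Delta} in months, so
#' baseline and 1-month follow-ups correlate more strongly than baseline
#' and 12-month follow-ups.
#'
#' @param n_baseline number of baseline patients.
#' @param n_nested number of patients in the follow-up substudy.
#' @param followup_offsets_months months after baseline of the follow-up
#'   exams (wrapped mod 12).
#' @param followup_attendance probability a nested patient attends each
#'   follow-up exam (default gives 528 expected follow-ups).
#' @param mesor cohort annual mean, nmol/l.
#' @param amplitude cohort seasonal amplitude, nmol/l (peak-trough / 2).
#' @param peak_month continuous month of the seasonal peak (1 = January).
#' @param residual_sd total residual SD around the seasonal mean, nmol/l.
#' @param within_person_sd within-person component of `residual_sd`,
#'   nmol/l; must not exceed `residual_sd`.
#' @param serial_range e-folding time (months) of the within-person
#'   serial correlation.
#' @param covariate_effects named vector of annual-mean shifts, nmol/l,
#'   keyed `covariate.level`.
#' @param amplitude_effects named vector of peak-trough shifts, nmol/l,
#'   keyed `covariate.level`.
#' @param covariate_prevalences named vector of generating probabilities
#'   for the binary covariates.
#' @param missing_rates named vector of per-covariate missingness
#'   probabilities.
#' @param month_distribution probability vector over the 12 calendar
#'   months.
#' @param lloq assay lower limit of quantification, used when splitting
#'   the total into 25OHD2/25OHD3 components.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_baseline = 4116,
    n_nested = 271,
    followup_offsets_months = c(1, 12),
    followup_attendance = 528 / (271 * 2),
    mesor = 59.6,
    amplitude = 7.9,
    peak_month = 7.5,
    residual_sd = 19,
    within_person_sd = 15,
    serial_range = 6,
    covariate_effects = c(
      gender.female = -2.2, age_group.ge62 = 1.9, site.stavanger = -5.3,
      smoker.yes = -3.4, bmi_group.25to30 = -2.3, bmi_group.gt30 = -8.6,
      activity.ge2h_per_week = 4.1, supplements.regular_daily = 8.4,
      diabetes.yes = -1.9
    ),
    amplitude_effects = c(age_group.ge62 = -6.3),
    covariate_prevalences = c(
      gender.female = 0.281, site.stavanger = 0.181, smoker.yes = 0.317,
      activity.ge2h_per_week = 0.688, supplements.regular_daily = 0.336,
      diabetes.yes = 0.119
    ),
    missing_rates = c(activity = 0.247, supplements = 0.127,
                      smoker = 0.0017, bmi = 0.0007),
    month_distribution = rep(1 / 12, 12),
    lloq = 6.6) {
  cfg <- list(
    n_baseline = n_baseline, n_nested = n_nested,
    followup_offsets_months = followup_offsets_months,
    followup_attendance = followup_attendance,
    mesor = mesor, amplitude = amplitude, peak_month = peak_month,
    residual_sd = residual_sd, within_person_sd = within_person_sd,
    serial_range = serial_range,
    covariate_effects = covariate_effects,
    amplitude_effects = amplitude_effects,
    covariate_prevalences = covariate_prevalences,
    missing_rates = missing_rates,
    month_distribution = month_distribution,
    lloq = lloq
  )
  stopifnot(
    n_baseline > 0, n_nested >= 0, n_nested <= n_baseline,
    followup_attendance >= 0, followup_attendance <= 1,
    amplitude >= 0, residual_sd >= 0,
    within_person_sd >= 0, within_person_sd <= residual_sd,
    all(covariate_prevalences >= 0 & covariate_prevalences <= 1),
    length(month_distribution) == 12,
    abs(sum(month_distribution) - 1) < 1e-8
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Read a generator configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [cohort_config()].
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("covariate_effects", "amplitude_effects",
               "covariate_prevalences", "missing_rates"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  do.call(cohort_config, cfg)
}

# internal: continuous covariates with group cut-offs; prevalences of the
# derived levels come from the generating normal distributions so the
# centring below is exact.
continuous_specs <- list(
  age_years = list(mean = 61.8, sd = 10.4),
  bmi = list(mean = 26.8, sd = 4.0),
  egfr = list(mean = 87.8, sd = 17.2)
)

# internal: implied prevalence of each effect key under the config
effect_prevalence <- function(key, config) {
  p <- config$covariate_prevalences
  if (key %in% names(p)) return(p[[key]])
  switch(key,
    age_group.ge62 = stats::pnorm(62, 61.8, 10.4, lower.tail = FALSE),
    bmi_group.25to30 = stats::pnorm(30, 26.8, 4) - stats::pnorm(25, 26.8, 4),
    bmi_group.gt30 = stats::pnorm(30, 26.8, 4, lower.tail = FALSE),
    egfr_group.le60 = stats::pnorm(60, 87.8, 17.2),
    crp_group.gt10 = 0.068,
    stop("no prevalence available for effect key '", key, "'")
  )
}

# internal: indicator matrix (rows = patients) for a set of effect keys
effect_indicators <- function(cov, keys) {
  out <- matrix(0, nrow(cov), length(keys), dimnames = list(NULL, keys))
  for (k in keys) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    x <- cov[[parts[1]]]
    lev <- parts[2]
    ind <- as.numeric((if (is.logical(x)) ifelse(x, "yes", "no")
                       else as.character(x)) == lev)
    ind[is.na(ind)] <- 0  # missing covariate: generate at reference
    out[, k] <- ind
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the conditions of [cohort_config()]: independent
#' covariates at their prevalences, months of blood draw from the month
#' distribution, a sinusoidal seasonal mean with covariate level shifts
#' and amplitude effects, a person-level random intercept shared across
#' visits, and serially correlated within-person noise. Nested patients
#' receive follow-up rows at the configured month offsets. The total
#' 25OHD is split into a 25OHD3 component and a small 25OHD2 component
#' (mostly below the LLOQ, as in the assay data this emulates).
#'
#' Negative concentrations are truncated at zero; the number truncated is
#' recorded in attribute `n_truncated`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the same config and seed give an identical
#'   cohort.
#' @return A cohort data frame in the [cohort_schema()] layout (one row
#'   per measurement, baseline rows first), with derived group and
#'   calendar columns, ready for [cosinor_fit()]. Attributes: `truth`
#'   (the generating parameters) and `n_truncated`.
#' @export
#' @examples
#' cfg <- cohort_config(n_baseline = 200, n_nested = 20)
#' d <- generate_cohort(cfg, seed = 1)
#' nrow(d)
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_baseline

  cov <- data.frame(patient_id = sprintf("P%04d", seq_len(n)))
  for (nm in names(continuous_specs)) {
    sp <- continuous_specs[[nm]]
    cov[[nm]] <- stats::rnorm(n, sp$mean, sp$sd)
  }
  cov$crp <- stats::rlnorm(n, meanlog = log(10) - stats::qnorm(1 - 0.068),
                           sdlog = 1)
  prev <- config$covariate_prevalences
  draw_level <- function(key, lev_yes, lev_no) {
    factor(ifelse(stats::runif(n) < prev[[key]], lev_yes, lev_no),
           levels = c(lev_no, lev_yes))
  }
  cov$gender <- draw_level("gender.female", "female", "male")
  cov$site <- draw_level("site.stavanger", "stavanger", "bergen")
  cov$smoker <- draw_level("smoker.yes", "yes", "no")
  cov$activity <- draw_level("activity.ge2h_per_week", "ge2h_per_week",
                             "le1h_per_week")
  cov$supplements <- draw_level("supplements.regular_daily", "regular_daily",
                                "never_seldom")
  cov$diabetes <- draw_level("diabetes.yes", "yes", "no")
  cov <- derive_groups(cov)

  eff_keys <- names(config$covariate_effects)
  amp_keys <- names(config$amplitude_effects)
  ind_eff <- effect_indicators(cov, eff_keys)
  ind_amp <- effect_indicators(cov, amp_keys)
  prev_eff <- vapply(eff_keys, effect_prevalence, numeric(1), config = config)
  prev_amp <- vapply(amp_keys, effect_prevalence, numeric(1), config = config)

  # centred effects: marginal mean = mesor, marginal amplitude = amplitude
  level_shift <- drop(sweep(ind_eff, 2, prev_eff) %*% config$covariate_effects)
  amp_i <- config$amplitude +
    drop(sweep(ind_amp, 2, prev_amp) %*% (config$amplitude_effects / 2))
  if (any(amp_i < 0))
    stop("config implies a negative amplitude for some stratum")

  sd_between <- sqrt(config$residual_sd^2 - config$within_person_sd^2)
  b_i <- stats::rnorm(n, 0, sd_between)

  month_b <- sample.int(12, n, replace = TRUE,
                        prob = config$month_distribution)
  seasonal <- function(m, amp)
    amp * cos(2 * pi * (m - config$peak_month) / 12)
  w_b <- stats::rnorm(n, 0, config$within_person_sd)
  y_b <- config$mesor + level_shift + seasonal(month_b, amp_i) + b_i + w_b

  rows <- list(data.frame(
    patient_id = cov$patient_id, visit = "baseline", month = month_b,
    total = y_b, stringsAsFactors = FALSE))

  nested <- seq_len(config$n_nested)
  rho <- exp(-1 / config$serial_range)
  for (j in seq_along(config$followup_offsets_months)) {
    off <- config$followup_offsets_months[j]
    attend <- nested[stats::runif(length(nested)) < config$followup_attendance]
    if (!length(attend)) next
    month_f <- ((month_b[attend] + off - 1) %% 12) + 1
    r <- rho^off
    w_f <- r * w_b[attend] +
      sqrt(1 - r^2) * stats::rnorm(length(attend), 0, config$within_person_sd)
    y_f <- config$mesor + level_shift[attend] +
      seasonal(month_f, amp_i[attend]) + b_i[attend] + w_f
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = cov$patient_id[attend], visit = paste0("followup", j),
      month = month_f, total = y_f, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)

  n_truncated <- sum(d$total < 0)
  d$total[d$total < 0] <- 0

  # split into components: 25OHD2 is small and usually below the LLOQ
  ohd2_raw <- stats::rlnorm(nrow(d), meanlog = log(2), sdlog = 0.6)
  d$ohd2 <- round(ohd2_raw, 1)
  quantified2 <- d$ohd2 >= config$lloq
  d$ohd3 <- round(pmax(d$total - ifelse(quantified2, d$ohd2, 0),
                       config$lloq), 1)
  d$total <- NULL

  d <- merge(d, cov, by = "patient_id", sort = FALSE)
  for (nm in names(config$missing_rates)) {
    if (!nm %in% names(d)) next
    miss <- stats::runif(nrow(d)) < config$missing_rates[[nm]]
    d[[nm]][miss] <- NA
  }
  d <- derive_groups(d)  # refresh groups after missingness
  d <- apply_lloq(d, lloq = config$lloq)
  d$usable <- NULL
  d <- cbind(d, assign_calendar(d$month))
  d <- d[order(match(d$visit, c("baseline", "followup1", "followup2")),
               d$patient_id), ]
  rownames(d) <- NULL
  if (n_truncated > 0)
    message("generate_cohort: ", n_truncated,
            " negative concentration(s) truncated at 0")
  attr(d, "truth") <- config
  attr(d, "n_truncated") <- n_truncated
  d
}

#' Write a deterministic cohort fixture
#'
#' Writes a CSV fixture in the [cohort_schema()] layout: `"tiny"` is a
#' 24-row hand-checkable table (two patients per month, no noise beyond a
#' fixed pattern), `"full_scale"` is a full default cohort from
#' [generate_cohort()]. The same seed always yields byte-identical files.
#'
#' @param size `"tiny"` or `"full_scale"`.
#' @param path output CSV path.
#' @param seed integer seed (used by `"full_scale"`).
#' @return `path`, invisibly.
#' @export
make_fixture <- function(size = c("tiny", "full_scale"),
                         path = tempfile(fileext = ".csv"), seed = 1) {
  size <- match.arg(size)
  if (size == "tiny") {
    month <- rep(1:12, each = 2)
    curve <- 60 + 8 * cos(2 * pi * (month - 7.5) / 12)
    dev <- rep(c(-5, 5), 12)
    d <- data.frame(
      patient_id = sprintf("T%02d", seq_along(month)),
      visit = "baseline", month = month,
      ohd2 = 2, ohd3 = round(curve + dev, 1),
      age_years = rep(c(55, 70), 12), gender = rep(c("male", "female"), 12),
      site = "bergen", smoker = "no", bmi = 25,
      activity = "ge2h_per_week", supplements = "never_seldom",
      diabetes = "no", egfr = 90, crp = 2
    )
  } else {
    d <- generate_cohort(cohort_config(), seed = seed)
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) round(x, 2))
  }
  write_cohort(d, path)
  invisible(path)
}
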