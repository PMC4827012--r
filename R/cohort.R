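#' Default cohort table schema
#'
#' Column mapping, delimiter, lower limit of quantification (LLOQ) and
#' sufficiency threshold used by [read_cohort()] and [write_cohort()].
#' Any entry can be overridden, either programmatically or from a YAML
#' configuration file (see [read_schema()]).
#'
#' The default columns are: `patient_id`, `visit` (one of `baseline`,
#' `followup1`, `followup2`), `month` (calendar month 1--12 of the blood
#' draw), `ohd2` and `ohd3` (25-hydroxyvitamin D2 and D3, nmol/l), and the
#' covariate columns `age_years`, `gender`, `site`, `smoker`, `bmi`,
#' `activity`, `supplements`, `diabetes`, `egfr`, `crp`.
#'
#' @param ... named overrides of individual schema entries.
#' @return A named list with entries `columns` (named character vector
#'   mapping internal names to file column names), `sep`, `lloq` (nmol/l)
#'   and `threshold` (nmol/l).
#' @export
#' @examples
#' s <- cohort_schema(lloq = 10)
#' s$lloq
cohort_schema <- function(...) {
  schema <- list(
    columns = c(
      patient_id = "patient_id", visit = "visit", month = "month",
      ohd2 = "ohd2", ohd3 = "ohd3",
      age_years = "age_years", gender = "gender", site = "site",
      smoker = "smoker", bmi = "bmi", activity = "activity",
      supplements = "supplements", diabetes = "diabetes",
      egfr = "egfr", crp = "crp"
    ),
    sep = ",",
    lloq = 6.6,
    threshold = 50
  )
  dots <- list(...)
  for (nm in names(dots)) schema[[nm]] <- dots[[nm]]
  schema
}

#' Read a schema configuration from a YAML file
#'
#' @param path path to a YAML file with any of the keys `columns`, `sep`,
#'   `lloq`, `threshold`.
#' @return A schema list as produced by [cohort_schema()].
#' @export
read_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- cohort_schema()
  if (!is.null(cfg$columns)) {
    cols <- unlist(cfg$columns)
    schema$columns[names(cols)] <- cols
  }
  for (nm in c("sep", "lloq", "threshold"))
    if (!is.null(cfg[[nm]])) schema[[nm]] <- cfg[[nm]]
  schema
}

#' Apply the LLOQ rule and sum 25OHD components
#'
#' Component concentrations (25OHD2, 25OHD3) strictly below the assay's
#' lower limit of quantification are set to missing; the total 25OHD is the
#' sum of the remaining components. A record whose 25OHD3 is below the LLOQ
#' (or missing) has no usable total and is flagged.
#'
#' @param data data frame with numeric columns `ohd2` and `ohd3` (nmol/l;
#'   `NA` = not measured).
#' @param lloq lower limit of quantification in nmol/l (default 6.6).
#' @return `data` with `ohd2`/`ohd3` censored below `lloq`, a derived
#'   `ohd` column (total 25OHD) and a logical `usable` column.
#' @export
#' @examples
#' apply_lloq(data.frame(ohd2 = c(3, 10, NA), ohd3 = c(60, 50, 6.5)))
apply_lloq <- function(data, lloq = 6.6) {
  stopifnot(is.data.frame(data), lloq > 0)
  for (col in c("ohd2", "ohd3")) {
    if (is.null(data[[col]])) data[[col]] <- NA_real_
    v <- data[[col]]
    if (any(v < 0, na.rm = TRUE))
      stop("negative concentrations in '", col, "'")
    v[!is.na(v) & v < lloq] <- NA_real_
    data[[col]] <- v
  }
  data$usable <- !is.na(data$ohd3)
  data$ohd <- ifelse(data$usable,
                     data$ohd3 + ifelse(is.na(data$ohd2), 0, data$ohd2),
                     NA_real_)
  data
}

#' Derive smoking status
#'
#' A participant is a smoker if self-reported as such, or stopped smoking
#' at most 90 days ago, or has a plasma cotinine concentration above
#' 85 nmol/l. Returns `NA` where all inputs are missing.
#'
#' @param self_report logical; self-reported current smoker.
#' @param days_since_quit numeric; days since smoking cessation (`NA` if
#'   never smoked or unknown).
#' @param cotinine numeric; plasma cotinine in nmol/l.
#' @return logical vector.
#' @export
derive_smoking <- function(self_report = NA, days_since_quit = NA,
                           cotinine = NA) {
  n <- max(length(self_report), length(days_since_quit), length(cotinine))
  self_report <- rep_len(self_report, n)
  days_since_quit <- rep_len(days_since_quit, n)
  cotinine <- rep_len(cotinine, n)
  out <- (!is.na(self_report) & self_report) |
    (!is.na(days_since_quit) & days_since_quit <= 90) |
    (!is.na(cotinine) & cotinine > 85)
  all_absent <- is.na(self_report) & is.na(days_since_quit) & is.na(cotinine)
  out[all_absent] <- NA
  out
}

#' Derive hypertension status
#'
#' Hypertension is systolic blood pressure above 140 mm Hg, and/or
#' diastolic above 90 mm Hg, and/or use of an antihypertensive drug.
#' Both pressure cut-offs are strict inequalities.
#'
#' @param sbp,dbp systolic/diastolic blood pressure, mm Hg.
#' @param on_drug logical; on antihypertensive medication.
#' @return logical vector; `NA` where all inputs are missing.
#' @export
derive_hypertension <- function(sbp = NA, dbp = NA, on_drug = NA) {
  n <- max(length(sbp), length(dbp), length(on_drug))
  sbp <- rep_len(sbp, n); dbp <- rep_len(dbp, n); on_drug <- rep_len(on_drug, n)
  out <- (!is.na(sbp) & sbp > 140) | (!is.na(dbp) & dbp > 90) |
    (!is.na(on_drug) & on_drug)
  out[is.na(sbp) & is.na(dbp) & is.na(on_drug)] <- NA
  out
}

#' Assign calendar strata to months
#'
#' Quarterly seasons (Jan--Mar, Apr--Jun, Jul--Sep, Oct--Dec) and the
#' dark (October--March) / bright (April--September) halves of the year,
#' reflecting months of negligible versus significant cutaneous vitamin D
#' synthesis at ~60 degrees North.
#'
#' @param month integer vector, calendar months in 1--12.
#' @return data frame with factor columns `season`
#'   (levels `JanMar`, `AprJun`, `JulSep`, `OctDec`) and `period`
#'   (levels `dark`, `bright`).
#' @export
#' @examples
#' assign_calendar(c(3, 4, 10))
assign_calendar <- function(month) {
  ok <- !is.na(month)
  if (any(month[ok] != as.integer(month[ok]) | month[ok] < 1 | month[ok] > 12))
    stop("month must be an integer in 1..12")
  season_levels <- c("JanMar", "AprJun", "JulSep", "OctDec")
  season <- factor(season_levels[ceiling(month / 3)], levels = season_levels)
  period <- factor(ifelse(month %in% c(10, 11, 12, 1, 2, 3), "dark", "bright"),
                   levels = c("dark", "bright"))
  data.frame(season = season, period = period)
}

# internal: canonical factor codings; the contrast reference level comes
# first
canonical_levels <- list(
  visit = c("baseline", "followup1", "followup2"),
  gender = c("male", "female"),
  site = c("bergen", "stavanger"),
  smoker = c("no", "yes"),
  activity = c("le1h_per_week", "ge2h_per_week"),
  supplements = c("never_seldom", "regular_daily"),
  diabetes = c("no", "yes")
)

apply_canonical_levels <- function(data) {
  for (nm in names(canonical_levels)) {
    if (is.null(data[[nm]])) next
    x <- as.character(data[[nm]])
    known <- canonical_levels[[nm]]
    lev <- c(known[known %in% x], setdiff(sort(unique(x[!is.na(x)])), known))
    data[[nm]] <- factor(x, levels = lev)
  }
  data
}

# internal: covariate grouping rules shared by reader and generator
derive_groups <- function(data) {
  if (!is.null(data$age_years))
    data$age_group <- factor(ifelse(data$age_years >= 62, "ge62", "under62"),
                             levels = c("under62", "ge62"))
  if (!is.null(data$bmi))
    data$bmi_group <- factor(
      ifelse(data$bmi > 30, "gt30", ifelse(data$bmi >= 25, "25to30", "lt25")),
      levels = c("lt25", "25to30", "gt30"))
  if (!is.null(data$egfr))
    data$egfr_group <- factor(ifelse(data$egfr <= 60, "le60", "gt60"),
                              levels = c("gt60", "le60"))
  if (!is.null(data$crp))
    data$crp_group <- factor(ifelse(data$crp > 10, "gt10", "le10"),
                             levels = c("le10", "gt10"))
  data
}

#' Read a cohort table from delimited text
#'
#' Reads a delimited cohort file, validates it against the schema, applies
#' the LLOQ rule ([apply_lloq()]), derives grouped covariates (age group at
#' 62 years, BMI classes at 25 and 30 kg/m2, eGFR at 60, CRP at 10 mg/l)
#' and calendar strata ([assign_calendar()]). Rows failing validation
#' (out-of-range month, unparseable numerics, 25OHD3 below the LLOQ) are
#' dropped, with counts reported on stderr.
#'
#' @param path file path.
#' @param schema schema list from [cohort_schema()] or [read_schema()].
#' @param quiet suppress the row-accounting message.
#' @return A data frame of usable measurement records (one row per blood
#'   draw, baseline or follow-up) with attribute `dropped` giving the
#'   number of rows removed per reason and `n_missing` the per-column
#'   missing-value counts.
#' @export
read_cohort <- function(path, schema = cohort_schema(), quiet = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = schema$sep,
                           stringsAsFactors = FALSE)
  cols <- schema$columns
  mandatory <- c("patient_id", "month", "ohd3")
  missing_cols <- setdiff(cols[mandatory], names(raw))
  if (length(missing_cols))
    stop("cohort file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  present <- cols[cols %in% names(raw)]
  data <- raw[, present, drop = FALSE]
  names(data) <- names(present)

  numeric_cols <- intersect(
    c("month", "ohd2", "ohd3", "age_years", "bmi", "egfr", "crp"),
    names(data))
  bad_numeric <- rep(FALSE, nrow(data))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(data[[col]]))
    bad_numeric <- bad_numeric | (!is.na(data[[col]]) & data[[col]] != "" &
                                    is.na(v))
    data[[col]] <- v
  }
  bad_month <- is.na(data$month) | data$month < 1 | data$month > 12 |
    data$month != round(data$month)
  keep <- !bad_numeric & !bad_month
  data <- data[keep, , drop = FALSE]

  data <- apply_lloq(data, lloq = schema$lloq)
  n_lloq <- sum(!data$usable)
  data <- data[data$usable, , drop = FALSE]
  data$usable <- NULL
  data <- apply_canonical_levels(data)
  data <- derive_groups(data)
  data <- cbind(data, assign_calendar(data$month))

  dropped <- c(unparseable = sum(bad_numeric), bad_month = sum(bad_month & !bad_numeric),
               below_lloq = n_lloq)
  n_missing <- vapply(data, function(x) sum(is.na(x)), integer(1))
  if (!quiet)
    message(sprintf("read_cohort: %d usable records (dropped: %s)",
                    nrow(data),
                    paste(names(dropped), dropped, sep = "=", collapse = ", ")))
  attr(data, "dropped") <- dropped
  attr(data, "n_missing") <- n_missing
  rownames(data) <- NULL
  data
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()] on the value columns: writing then reading
#' recovers the same records (derived columns are recomputed on read).
#'
#' @param data cohort data frame.
#' @param path output file path.
#' @param schema schema list; its column mapping and separator are used.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, schema = cohort_schema()) {
  cols <- schema$columns
  out_cols <- names(cols)[names(cols) %in% names(data)]
  out <- data[, out_cols, drop = FALSE]
  names(out) <- cols[out_cols]
  utils::write.table(out, path, sep = schema$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
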