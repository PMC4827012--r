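test_that("anchored cosinor prediction follows the fitted curve", {
  V <- diag(3)
  dimnames(V) <- rep(list(c("intercept", "sin_m", "cos_m")), 2)
  f <- manual_fit(c(intercept = 60, sin_m = 5, cos_m = 0), V)
  # curve at +5 in month 3, -5 in month 9
  expect_equal(predict_cosinor(f, 60, 3, 9), 50)
  expect_equal(predict_cosinor(f, 60, 9, 3), 70)
  # anchoring identity: same month returns the baseline value
  expect_equal(predict_cosinor(f, 47.3, 5, 5), 47.3)
  # flat curve: prediction is the baseline value for any month
  f0 <- manual_fit(c(intercept = 60, sin_m = 0, cos_m = 0), V)
  expect_equal(predict_cosinor(f0, 41, 2, 8), 41)
  expect_error(predict_cosinor(f, 60, 0, 5), "1\\.\\.12")
})

test_that("covariate-specific curves drive the prediction", {
  d <- noiseless_cohort(amplitude = 8, peak_month = 7.5, reps = 4)
  d$grp <- rep(c("a", "b"), each = 24)
  # group b has half the seasonal swing
  half <- 4 * cos(2 * pi * (d$month - 7.5) / 12)
  d$ohd[d$grp == "b"] <- 60 + half[d$grp == "b"]
  f <- suppressWarnings(cosinor_fit(d, covariates = "grp",
                                    interactions = "grp"))
  p_a <- predict_cosinor(f, 60, 1, 7, at = list(grp = "a"))
  p_b <- predict_cosinor(f, 60, 1, 7, at = list(grp = "b"))
  curve <- function(amp, m) amp * cos(2 * pi * (m - 7.5) / 12)
  expect_equal(p_a, 60 + curve(8, 7) - curve(8, 1), tolerance = 1e-9)
  expect_equal(p_b, 60 + curve(4, 7) - curve(4, 1), tolerance = 1e-9)
  # per-row covariates via a data frame
  p_df <- predict_cosinor(f, c(60, 60), c(1, 1), c(7, 7),
                          at = data.frame(grp = c("a", "b")))
  expect_equal(p_df, c(p_a, p_b))
  expect_error(predict_cosinor(f, 60, 1, 7), "supply them")
})

test_that("baseline carried forward is the identity", {
  expect_equal(predict_baseline_carry(60), 60)
  expect_equal(predict_baseline_carry(c(0, 12.5)), c(0, 12.5))
})

test_that("season-dummy prediction uses fitted quarter means", {
  # quarter means 50/60/70/60 by construction
  month <- rep(c(2, 5, 8, 11), each = 6)
  d <- data.frame(month = month,
                  ohd = rep(c(50, 60, 70, 60), each = 6) + rep(c(-1, 1), 12))
  f <- fit_season_dummy(d)
  expect_equal(unname(f$season_means),
               c(50, 60, 70, 60), tolerance = 1e-9)
  # oracle: direct group means on the toy data
  gm <- tapply(d$ohd, assign_calendar(d$month)$season, mean)
  expect_equal(as.numeric(f$season_means), as.numeric(gm), tolerance = 1e-9)
  expect_equal(unname(predict_season_dummy(f, 55, 2, 8)), 75)
  # same season: identity
  expect_equal(unname(predict_season_dummy(f, 55, 1, 3)), 55)
})

test_that("method evaluation computes the comparison statistics", {
  set.seed(12)
  n <- 60
  measured <- rnorm(n, 60, 15)
  perfect <- data.frame(method = "perfect", obs = 1:n, measured = measured,
                        predicted = measured)
  noisy <- data.frame(method = "noisy", obs = 1:n, measured = measured,
                      predicted = measured + rnorm(n, 0, 5))
  cmp <- evaluate_predictions(rbind(perfect, noisy), reference = "perfect")
  perf <- cmp[cmp$method == "perfect", ]
  expect_equal(perf$mse, 0)
  expect_equal(perf$pearson_r, 1)
  expect_equal(perf$prop_within, 1)
  expect_true(is.na(perf$p_vs_reference))
  nz <- cmp[cmp$method == "noisy", ]
  expect_equal(nz$rmse, sqrt(nz$mse))
  expect_true(nz$p_vs_reference < 0.05)

  # a method identical to the reference: zero MSE difference, p undefined
  dup <- transform(perfect, method = "copy")
  cmp2 <- evaluate_predictions(rbind(perfect, dup), reference = "perfect")
  expect_true(is.na(cmp2$p_vs_reference[cmp2$method == "copy"]))

  # mismatched observation sets are rejected
  bad <- rbind(perfect, noisy[-1, ])
  expect_error(evaluate_predictions(bad, reference = "perfect"),
               "observation set")
})

test_that("full follow-up pipeline predicts every method per observation", {
  cfg <- cohort_config(n_baseline = 600, n_nested = 80)
  d <- suppressMessages(generate_cohort(cfg, seed = 9))
  out <- predict_followups(d)
  n_fup <- sum(d$visit != "baseline")
  expect_equal(nrow(out$predictions), 5 * n_fup)
  expect_setequal(unique(out$predictions$method),
                  c("cosinor_unadjusted", "cosinor_plus_age",
                    "cosinor_multivariate", "baseline_carry", "season_dummy"))
  expect_equal(out$predictions$squared_error,
               (out$predictions$predicted - out$predictions$measured)^2)
  # anchoring: same-month follow-ups predicted at the baseline value
  pr <- out$predictions
  same <- pr$method == "cosinor_unadjusted" &
    pr$followup_month == pr$baseline_month
  expect_equal(pr$predicted[same], pr$baseline_value[same])
  expect_true(all(c("mse", "rmse", "p_vs_reference") %in%
                    names(out$comparison)))
})
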