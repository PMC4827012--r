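test_that("design matrix carries exact trig values and interaction columns", {
  d <- data.frame(month = c(3, 12, 6), ohd = c(1, 2, 3),
                  age_group = factor(c("under62", "under62", "ge62"),
                                     levels = c("under62", "ge62")))
  des <- cosinor_design(d, covariates = "age_group",
                        interactions = "age_group")
  expect_equal(des$frame$sin_m, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(des$frame$cos_m, c(0, 1, -1), tolerance = 1e-12)
  expect_equal(des$frame$age_group_ge62, c(0, 0, 1))
  expect_equal(des$frame$age_group_ge62.sin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(des$frame$age_group_ge62.cos, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(des$n_used, 3)
})

test_that("complete-case filtering and error paths behave", {
  d <- data.frame(month = rep(1:12, 3), ohd = rnorm(36))
  d$ohd[1:3] <- NA
  f <- cosinor_fit(d)
  expect_equal(f$n_used, 33)
  expect_error(cosinor_fit(d, covariates = "nope"), "not found")
  d2 <- d
  d2$ohd <- NA_real_
  expect_error(cosinor_fit(d2), "complete cases")
})

test_that("noiseless data are recovered exactly", {
  d <- data.frame(month = rep(1:12, 2))
  d$ohd <- 60 + 5 * sin(2 * pi * d$month / 12)
  f <- suppressWarnings(cosinor_fit(d))
  expect_equal(unname(f$beta), c(60, 5, 0), tolerance = 1e-9)
  expect_equal(sum(f$residuals), 0, tolerance = 1e-9)

  # constant outcome: flat curve
  d$ohd <- 50
  f0 <- suppressWarnings(cosinor_fit(d))
  expect_equal(unname(f0$beta), c(50, 0, 0), tolerance = 1e-9)
  ss <- seasonal_summary(f0)
  expect_lt(ss$amplitude, 1e-9)
})

test_that("OLS fit matches a brute-force (M, A, phi) SSE minimiser", {
  set.seed(101)
  for (i in 1:8) {
    n <- sample(12:50, 1)
    month <- sample(1:12, n, replace = TRUE)
    truth_A <- runif(1, 1, 10)
    truth_phi <- runif(1, 0, 12)
    y <- 55 + truth_A * cos(2 * pi * (month - truth_phi) / 12) + rnorm(n, 0, 5)
    f <- cosinor_fit(data.frame(month = month, ohd = y))
    bf <- brute_force_cosinor(month, y)
    expect_equal(unname(f$fitted), bf$fitted, tolerance = 1e-6)
    ss <- seasonal_summary(f)
    expect_equal(ss$amplitude, bf$amplitude, tolerance = 1e-4)
    expect_equal(ss$mesor, bf$mesor, tolerance = 1e-4)
  }
})

test_that("shift and rotation equivariances hold", {
  set.seed(11)
  month <- sample(1:12, 80, replace = TRUE)
  y <- 60 + 6 * cos(2 * pi * (month - 7.5) / 12) + rnorm(80, 0, 8)
  f <- cosinor_fit(data.frame(month = month, ohd = y))
  s <- seasonal_summary(f)

  # adding a constant shifts the mesor only
  f_k <- cosinor_fit(data.frame(month = month, ohd = y + 13))
  s_k <- seasonal_summary(f_k)
  expect_equal(s_k$mesor, s$mesor + 13, tolerance = 1e-9)
  expect_equal(s_k$amplitude, s$amplitude, tolerance = 1e-9)
  expect_equal(s_k$peak_month, s$peak_month, tolerance = 1e-9)

  # rotating months by +Delta rotates the peak and preserves the amplitude
  for (delta in c(1, 4, 9)) {
    m_rot <- ((month + delta - 1) %% 12) + 1
    f_r <- cosinor_fit(data.frame(month = m_rot, ohd = y))
    s_r <- seasonal_summary(f_r)
    expect_equal(s_r$amplitude, s$amplitude, tolerance = 1e-9)
    expect_equal(s_r$peak_month %% 12, (s$peak_month + delta) %% 12,
                 tolerance = 1e-9)
    expect_equal(s_r$mesor, s$mesor, tolerance = 1e-9)
  }
})

test_that("seasonal summary derives amplitude and peak from coefficients", {
  V <- diag(3)
  dimnames(V) <- rep(list(c("intercept", "sin_m", "cos_m")), 2)
  f <- manual_fit(c(intercept = 60, sin_m = 5, cos_m = 0), V)
  f$n_used <- 99
  ss <- seasonal_summary(f)
  expect_equal(ss$amplitude, 5)
  expect_equal(ss$peak_month, 3)       # sine peaks at month 3
  expect_equal(ss$trough_month, 9)
  expect_equal(ss$peak_trough, 2 * ss$amplitude)

  f2 <- manual_fit(c(intercept = 60, sin_m = 3, cos_m = 4), V)
  f2$n_used <- 99
  ss2 <- seasonal_summary(f2)
  expect_equal(ss2$amplitude, 5)
  expect_equal(ss2$peak_month, grid_peak(3, 4), tolerance = 1e-3)
  expect_equal(abs(ss2$peak_month - ss2$trough_month) %% 12, 6,
               tolerance = 1e-9)
})

test_that("delta-method SEs match known gradients", {
  V <- diag(3)
  dimnames(V) <- rep(list(c("intercept", "sin_m", "cos_m")), 2)
  f <- manual_fit(c(intercept = 60, sin_m = 3, cos_m = 4), V)
  # unit gradient norm: SE = sqrt(0.6^2 + 0.8^2) = 1
  expect_equal(delta_se(f, "amplitude"), 1)
  expect_equal(delta_se(f, "peak_trough"), 2)
  # phase gradient (c/A^2, -s/A^2) * 12/(2*pi)
  expect_equal(delta_se(f, "phase"),
               sqrt((4 / 25)^2 + (3 / 25)^2) * 12 / (2 * pi))

  f0 <- manual_fit(c(intercept = 60, sin_m = 3, cos_m = 4), V * 0)
  expect_equal(delta_se(f0, "amplitude"), 0)

  fflat <- manual_fit(c(intercept = 60, sin_m = 0, cos_m = 0), V)
  expect_error(delta_se(fflat, "phase"), "undefined")
  expect_equal(delta_se(fflat, "amplitude"), 0)
})

test_that("fit summaries serialise to JSON", {
  d <- noiseless_cohort()
  set.seed(3)
  d$ohd <- d$ohd + rnorm(nrow(d), 0, 2)
  f <- cosinor_fit(d)
  path <- tempfile(fileext = ".json")
  cosinor_json(f, path)
  back <- jsonlite::fromJSON(readLines(path))
  expect_equal(back$beta$intercept, unname(f$beta["intercept"]))
  expect_equal(back$summary$amplitude, seasonal_summary(f)$amplitude)
  expect_equal(dim(back$vcov), c(3, 3))
})
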