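# Independent oracles used across the suite. These deliberately avoid the
# package's sine/cosine regression algebra.

# Brute-force least-squares fit of y = M + A*cos(2*pi*(m - phi)/12) by
# direct SSE minimisation over (M, A, phi) from multiple phase starts.
brute_force_cosinor <- function(month, y, period = 12) {
  sse <- function(par) {
    mu <- par[1] + par[2] * cos(2 * pi * (month - par[3]) / period)
    sum((y - mu)^2)
  }
  best <- NULL
  for (phi0 in seq(0.5, period - 0.5, by = 1)) {
    fit <- stats::optim(c(mean(y), stats::sd(y), phi0), sse,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 20000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- best$par
  if (par[2] < 0) {  # normalise: positive amplitude
    par[2] <- -par[2]
    par[3] <- par[3] + period / 2
  }
  par[3] <- par[3] %% period
  list(mesor = par[1], amplitude = par[2], peak_month = par[3],
       fitted = par[1] + par[2] * cos(2 * pi * (month - par[3]) / period),
       sse = best$value)
}

# Grid-search locator of the maximum of the fitted seasonal curve.
grid_peak <- function(beta_sin, beta_cos, period = 12, step = 0.001) {
  t <- seq(0, period, by = step)
  curve <- beta_sin * sin(2 * pi * t / period) +
    beta_cos * cos(2 * pi * t / period)
  t[which.max(curve)] %% period
}

# Noiseless cohort lying exactly on a cosine curve.
noiseless_cohort <- function(mesor = 60, amplitude = 5, peak_month = 7.5,
                             reps = 2) {
  month <- rep(1:12, reps)
  data.frame(
    month = month,
    ohd = mesor + amplitude * cos(2 * pi * (month - peak_month) / 12)
  )
}

# Hand-built cosinor_fit-shaped object with prescribed beta and vcov, for
# exercising the delta-method algebra at known values.
manual_fit <- function(beta, vcov, meta = list(), period = 12) {
  structure(list(beta = beta, vcov = vcov, meta = meta, period = period),
            class = "cosinor_fit")
}

# Small config for fast simulations: seasonal structure only.
simple_config <- function(n, amplitude = 7.9, residual_sd = 19, ...) {
  cohort_config(
    n_baseline = n, n_nested = 0,
    amplitude = amplitude, residual_sd = residual_sd,
    within_person_sd = residual_sd,
    covariate_effects = stats::setNames(numeric(0), character(0)),
    amplitude_effects = stats::setNames(numeric(0), character(0)),
    missing_rates = stats::setNames(numeric(0), character(0)),
    ...
  )
}
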