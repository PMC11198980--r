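# synthetic cohort generator: covariate sampling, latent event times,
# censoring, and the statistical structure they are meant to induce

test_that("covariate sampling follows the declared distributions", {
  spec <- reference_covariate_spec()
  pr <- default_true_params(1)
  # dimension check uses a 1-covariate params object only for config
  # validity; sampling does not touch the event model
  gc <- generator_config(10000, spec, pr, seed = 5)
  X <- sample_covariates(gc)
  expect_equal(nrow(X), 10000)

  # hypertension at its configured reference prevalence, within the exact
  # binomial 99% interval
  p_hyp <- spec$hypertension$prob
  k <- sum(X[, "hypertension"])
  expect_gte(k, qbinom(0.005, 10000, p_hyp))
  expect_lte(k, qbinom(0.995, 10000, p_hyp))

  # categorical encoding drops the reference level and records the map
  em <- attr(X, "encoding_map")
  expect_equal(em$race_ethnicity$ref, "NHW")
  expect_false("race_ethnicity_NHW" %in% colnames(X))
  expect_true(all(rowSums(X[, em$race_ethnicity$columns]) <= 1))

  # deterministic given the seed
  X2 <- sample_covariates(gc)
  expect_identical(X, X2)
})

test_that("degenerate and truncated covariate distributions behave", {
  pr <- default_true_params(1)
  gc0 <- generator_config(500, list(z = list(dist = "bernoulli", prob = 0)),
                          pr, seed = 2)
  expect_true(all(sample_covariates(gc0) == 0))

  # truncated normal mean matches the closed form within 3 SE
  m <- 59.4; s <- 21.2; lo <- 18; hi <- 110
  gct <- generator_config(
    10000, list(age = list(dist = "truncnorm", mean = m, sd = s, lo = lo, hi = hi)),
    pr, seed = 9)
  age <- sample_covariates(gct)[, "age"]
  a <- (lo - m) / s; b <- (hi - m) / s
  mean_trunc <- m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(age) - mean_trunc), 3 * sd(age) / sqrt(10000))
  expect_true(all(age >= lo & age <= hi))

  expect_error(generator_config(100, list(z = list(dist = "cauchy")), pr),
               class = "config_error")
  expect_error(generator_config(0, list(z = list(dist = "bernoulli", prob = .5)), pr),
               class = "config_error")
})

test_that("latent times respect the wedge and the no-death limit", {
  X <- matrix(rnorm(500), ncol = 1)
  # death impossible when both death rates are zero
  pr <- idm_params(0.3, 0, 0, kappa = c(1.2, 1, 1), lambda = c(1e-4, 0, 0), theta = 1)
  lat <- simulate_illness_death(X, pr, seed = 4)
  expect_true(all(lat$T2 == Inf))

  # finite illness always strictly precedes death
  pr2 <- default_true_params(1, beta1 = 0.3, beta2 = 0.2, beta3 = 0.1)
  lat2 <- simulate_illness_death(X, pr2, seed = 5)
  fin <- is.finite(lat2$T1)
  expect_true(any(fin))
  expect_true(all(lat2$T1[fin] < lat2$T2[fin]))

  expect_error(
    idm_params(0, 0, 0, kappa = c(1, 1, 1), lambda = c(1, 1, 1), theta = -1),
    class = "param_error")
})

test_that("symmetric competing exponentials split the race evenly", {
  n <- 20000
  X <- matrix(0, n, 1)
  pr <- idm_params(0, 0, 0, kappa = c(1, 1, 1), lambda = c(2e-4, 2e-4, 2e-4),
                   theta = 0)
  lat <- simulate_illness_death(X, pr, seed = 21)
  frac <- mean(is.finite(lat$T1))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("simulated joint survivor matches the closed-form frailty marginal", {
  n <- 100000
  set.seed(3)
  X <- matrix(rnorm(n), ncol = 1)
  pr <- idm_params(0.4, 0.2, 0.1, kappa = c(1.2, 1, 1),
                   lambda = c(3e-4, 2e-4, 5e-4), theta = 1)
  lat <- simulate_illness_death(X, pr, seed = 11)
  tt <- 365
  emp <- mean(pmin(lat$T1, lat$T2) > tt)
  H12 <- 3e-4 * tt^1.2 * exp(0.4 * X[, 1]) + 2e-4 * tt * exp(0.2 * X[, 1])
  closed <- mean((1 + pr$theta * H12)^(-1 / pr$theta))
  expect_lt(abs(emp - closed), 3 * sqrt(closed * (1 - closed) / n))
})

test_that("censoring produces valid cohorts across many seeds", {
  spec <- list(z = list(dist = "bernoulli", prob = 0.5))
  pr <- default_true_params(1, beta1 = 0.3, beta2 = 0.2, beta3 = 0.1)
  for (seed in 1:50) {
    coh <- simulate_cohort(generator_config(120, spec, pr, seed = seed))
    expect_equal(coh$n_excluded_invalid, 0)
    d <- coh$data
    expect_true(all(d$y1 <= d$y2))
    expect_true(all(d$delta1 == 1 | d$y1 == d$y2))
  }
  # round trip through the reader keeps everything valid
  coh <- simulate_cohort(generator_config(200, spec, pr, seed = 99))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  expect_equal(read_cohort(path)$n_excluded_invalid, 0)
})

test_that("censoring limits behave: no censoring vs immediate censoring", {
  spec <- list(z = list(dist = "bernoulli", prob = 0.5))
  pr <- default_true_params(1)
  gc <- generator_config(300, spec, pr,
                         censoring = list(admin_horizon = Inf, dropout = FALSE),
                         seed = 8)
  coh <- simulate_cohort(gc)
  expect_true(all(coh$data$delta2 == 1))  # every finite death observed

  gc0 <- generator_config(300, spec, pr,
                          censoring = list(admin_horizon = 1e-6, dropout = FALSE),
                          seed = 8)
  coh0 <- simulate_cohort(gc0)
  expect_true(all(coh0$data$delta1 == 0 & coh0$data$delta2 == 0))
  expect_true(all(coh0$data$y1 == 1e-6 & coh0$data$y2 == 1e-6))

  expect_error(generator_config(300, spec, pr,
                                censoring = list(admin_horizon = -1, dropout = FALSE)),
               class = "config_error")
})

test_that("shared frailty induces positive event-indicator dependence", {
  spec <- list(z = list(dist = "bernoulli", prob = 0.5))
  pr2 <- default_true_params(1, theta = 2)
  coh2 <- simulate_cohort(generator_config(5000, spec, pr2, seed = 17))
  ec2 <- event_correlation(coh2)
  expect_gt(ec2$estimate, 0)
  expect_lt(ec2$p_value, 0.05)

  # without frailty (and with illness leaving the death hazard unchanged)
  # there is no positive dependence left: the indicator correlation is
  # slightly negative by construction, since death truncates the window in
  # which illness can be observed
  pr0 <- idm_params(0, 0, 0, kappa = c(1.2, 1.1, 1.1),
                    lambda = c(4e-5, 3.5e-5, 3.5e-5), theta = 0, clock = "markov")
  coh0 <- simulate_cohort(generator_config(
    20000, spec, pr0, seed = 18,
    censoring = list(admin_horizon = 2922, dropout = FALSE), clock = "markov"))
  ec0 <- event_correlation(coh0)
  expect_lt(ec0$estimate, 0.02)
  expect_gt(ec2$estimate, ec0$estimate)
})
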