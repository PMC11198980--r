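# illness-death model: hazards, conditional and marginal likelihood,
# fitting, and cumulative-incidence prediction

test_that("transition hazard evaluates the Weibull-PH form", {
  pr <- idm_params(log(2), 0.1, -0.2, kappa = c(2, 1, 1),
                   lambda = c(0.5, 0.01, 0.02), theta = 0)
  # kappa=2, lambda=0.5, t=1.5, x=1, beta=log 2: 1*2*0.5*1.5*2 = 3
  expect_equal(transition_hazard(1, 1.5, x = 1, alpha = 1, params = pr), 3)
  # exponential baseline: constant hazard at any t
  expect_equal(transition_hazard(2, 7, 0, 1, pr), 0.01)
  expect_equal(transition_hazard(2, 4000, 0, 1, pr), 0.01)
  # frailty is multiplicative
  expect_equal(transition_hazard(3, 2, 1, 2, pr),
               2 * transition_hazard(3, 2, 1, 1, pr))
  expect_error(transition_hazard(1, 0, 0, 1, pr), class = "domain_error")
  expect_error(transition_hazard(4, 1, 0, 1, pr), class = "domain_error")
})

test_that("conditional contributions match the four observation patterns", {
  # (0,1) with exponential baselines: log h2(y2) - A(y2) = log(0.1) - 0.4
  pr <- idm_params(0, 0, 0, kappa = c(1, 1, 1), lambda = c(0.1, 0.1, 0.1),
                   theta = 0)
  ll <- subject_loglik_conditional(
    list(y1 = 2, delta1 = 0, y2 = 2, delta2 = 1, x = 0), alpha = 1, params = pr)
  expect_equal(ll, log(0.1) - 0.4)

  # vanishing rates: censored subject contributes nothing
  pr0 <- idm_params(0, 0, 0, kappa = c(1, 1, 1), lambda = rep(1e-12, 3), theta = 0)
  ll0 <- subject_loglik_conditional(
    list(y1 = 400, delta1 = 0, y2 = 400, delta2 = 0, x = 0), 1, pr0)
  expect_equal(ll0, 0, tolerance = 1e-6)

  # (1,1) semi-Markov equals the density factorisation h1 * S12 * h3 * S3
  pr2 <- idm_params(0.3, -0.2, 0.1, kappa = c(1.3, 0.9, 1.1),
                    lambda = c(2e-4, 1e-4, 5e-4), theta = 0.7)
  x <- 1; a <- 1.4; y1 <- 300; y2 <- 730; s <- y2 - y1
  h1 <- a * 1.3 * 2e-4 * y1^0.3 * exp(0.3 * x)
  S12 <- exp(-a * (2e-4 * y1^1.3 * exp(0.3 * x) + 1e-4 * y1^0.9 * exp(-0.2 * x)))
  h3 <- a * 1.1 * 5e-4 * s^0.1 * exp(0.1 * x)
  S3 <- exp(-a * 5e-4 * s^1.1 * exp(0.1 * x))
  ll2 <- subject_loglik_conditional(
    list(y1 = y1, delta1 = 1, y2 = y2, delta2 = 1, x = x), a, pr2)
  expect_equal(ll2, log(h1) + log(S12) + log(h3) + log(S3))

  # inconsistent pattern is rejected
  expect_error(subject_loglik_conditional(
    list(y1 = 1, delta1 = 0, y2 = 2, delta2 = 1, x = 0), 1, pr2),
    class = "pattern_error")
})

test_that("closed-form frailty marginal equals the quadrature oracle", {
  for (seed in 1:20) {
    pair <- random_subject_param_pair(seed)
    df <- data.frame(id = 1, y1 = pair$subject$y1, delta1 = pair$subject$delta1,
                     y2 = pair$subject$y2, delta2 = pair$subject$delta2,
                     x1 = pair$subject$x[1], x2 = pair$subject$x[2])
    closed <- marginal_loglik(as_cohort(df), pair$params)
    quad <- quadrature_subject_loglik(pair$subject, pair$params)
    expect_equal(closed, quad, tolerance = 1e-8)
  }
})

test_that("single-subject marginal equals the direct gamma-ratio formula", {
  pr <- idm_params(0.4, 0.1, -0.3, kappa = c(1.2, 1.0, 0.9),
                   lambda = c(3e-4, 2e-4, 6e-4), theta = 0.6)
  sub <- list(y1 = 250, delta1 = 1, y2 = 600, delta2 = 1, x = 1)
  df <- data.frame(id = 1, y1 = 250, delta1 = 1, y2 = 600, delta2 = 1, x = 1)
  # independent evaluation straight from lgamma and the conditional pieces
  th <- 0.6; d <- 2
  E <- log(1.2 * 3e-4 * 250^0.2 * exp(0.4)) +
    log(0.9 * 6e-4 * 350^(-0.1) * exp(-0.3))
  H <- 3e-4 * 250^1.2 * exp(0.4) + 2e-4 * 250^1.0 * exp(0.1) +
    6e-4 * 350^0.9 * exp(-0.3)
  direct <- E + lgamma(1 / th + d) - lgamma(1 / th) + d * log(th) -
    (1 / th + d) * log(1 + th * H)
  expect_equal(marginal_loglik(as_cohort(df), pr), direct, tolerance = 1e-10)
})

test_that("marginal likelihood is continuous at the theta = 0 boundary", {
  coh <- random_cohort(100, theta = 0.8, seed = 33)
  pr_eps <- idm_params(c(0.3, 0.3), c(0.2, 0.2), c(0.1, 0.1),
                       kappa = c(1.2, 1.1, 1.0), lambda = c(4e-5, 3.5e-5, 6e-4),
                       theta = 1e-10)
  pr_zero <- pr_eps; pr_zero$theta <- 0
  expect_lt(abs(marginal_loglik(coh, pr_eps) - marginal_loglik(coh, pr_zero)), 1e-6)
})

test_that("analytic gradient matches central finite differences on both clocks", {
  for (clock in c("semi-markov", "markov")) {
    coh <- random_cohort(80, theta = 0.8, seed = 44, clock = clock)
    d <- coh$data; X <- covariate_matrix(coh)
    pr <- idm_params(c(0.5, -0.3), c(0.2, 0.1), c(-0.1, 0.3),
                     kappa = c(1.3, 0.9, 1.1), lambda = c(2e-4, 1e-4, 5e-4),
                     theta = 0.8, clock = clock)
    gr <- semicompete:::marginal_loglik_grad_phi(d$y1, d$delta1, d$y2, d$delta2, X, pr)
    phi <- semicompete:::phi_pack(pr)
    num <- vapply(seq_along(phi), function(j) {
      h <- 1e-6
      up <- semicompete:::phi_unpack(replace(phi, j, phi[j] + h), 2, clock)
      dn <- semicompete:::phi_unpack(replace(phi, j, phi[j] - h), 2, clock)
      (marginal_loglik(coh, up) - marginal_loglik(coh, dn)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(gr), num, tolerance = 1e-5)
  }
})

test_that("markov and semi-markov likelihoods coincide for exponential transition 3", {
  coh <- random_cohort(150, theta = 1, seed = 55)
  base <- list(beta1 = c(0.3, -0.2), beta2 = c(0.1, 0.2), beta3 = c(0.2, 0.1),
               kappa = c(1.2, 1.1, 1.0), lambda = c(4e-5, 3.5e-5, 6e-4))
  pr_semi <- do.call(idm_params, c(base, list(theta = 0.9, clock = "semi-markov")))
  pr_mark <- do.call(idm_params, c(base, list(theta = 0.9, clock = "markov")))
  expect_equal(marginal_loglik(coh, pr_semi), marginal_loglik(coh, pr_mark),
               tolerance = 1e-12)
})

test_that("the fitted optimum dominates the generating parameters", {
  true <- idm_params(c(0.5, -0.3), c(0.3, 0.2), c(-0.2, 0.4),
                     kappa = c(1.2, 1.1, 1.0), lambda = c(4e-5, 3.5e-5, 6e-4),
                     theta = 1)
  spec <- list(x1 = list(dist = "bernoulli", prob = 0.5),
               x2 = list(dist = "truncnorm", mean = 0, sd = 1, lo = -4, hi = 4))
  coh <- simulate_cohort(generator_config(600, spec, true, seed = 77))
  fit <- fit_idm(coh, control = list(n_starts = 1))
  expect_true(fit$converged)
  expect_gte(fit$loglik, marginal_loglik(coh, true))
  # Wald CI brackets the HR
  expect_true(all(fit$hr_table$lo <= fit$hr_table$hr &
                    fit$hr_table$hr <= fit$hr_table$hi, na.rm = TRUE))
})

test_that("fit guards: constant covariates and eventless transitions", {
  coh <- random_cohort(100, seed = 21)
  coh$data$x1 <- 1
  expect_error(fit_idm(coh), class = "identifiability_error")

  coh2 <- random_cohort(400, seed = 22)
  coh2$data$delta2[coh2$data$delta1 == 1] <- 0  # no post-illness deaths
  coh2$data$y2[coh2$data$delta1 == 1] <- pmax(coh2$data$y2[coh2$data$delta1 == 1],
                                              coh2$data$y1[coh2$data$delta1 == 1])
  fit <- fit_idm(coh2, control = list(n_starts = 1))
  expect_match(fit$flags, "transition 3", all = FALSE)
})

test_that("cumulative incidence is a proper, bounded, monotone risk", {
  pr <- default_true_params(1, beta1 = 0.4, beta2 = 0.2, beta3 = 0.1)
  expect_equal(cif_nonterminal(0.5, 0, pr), 0)
  tt <- c(100, 500, 1000, 2000, 2922)
  cif <- cif_nonterminal(0.5, tt, pr)
  expect_true(all(diff(cif) > 0))
  expect_true(all(cif >= 0 & cif <= 1))
  # dominated by the no-competing-risk, no-frailty Weibull bound
  pr_free <- idm_params(0.4, 0.2, 0.1, kappa = pr$kappa,
                        lambda = c(pr$lambda[1], 0, 0), theta = 0)
  bound <- 1 - exp(-pr$lambda[1] * tt^pr$kappa[1] * exp(0.4 * 0.5))
  expect_equal(cif_nonterminal(0.5, tt, pr_free), bound, tolerance = 1e-8)
  expect_true(all(cif <= bound + 1e-12))
  expect_error(cif_nonterminal(0.5, -1, pr), class = "domain_error")
})
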