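# Independent oracles and fixture builders.  Everything here is coded
# separately from the package internals so agreement is evidence, not
# tautology.

# -- fixture: small hand-made semi-competing-risks data.frame ------------
make_cohort_df <- function(n = 10, seed = 1) {
  set.seed(seed)
  y2 <- round(runif(n, 100, 2000), 3)
  d1 <- rbinom(n, 1, 0.4)
  d2 <- rbinom(n, 1, 0.4)
  y1 <- ifelse(d1 == 1, round(y2 * runif(n, 0.2, 0.99), 3), y2)
  data.frame(id = paste0("P", seq_len(n)), y1 = y1, delta1 = d1,
             y2 = y2, delta2 = d2,
             x1 = rbinom(n, 1, 0.5), x2 = round(rnorm(n), 4))
}

random_cohort <- function(n, p = 2, theta = 1, seed = 1,
                          beta1 = rep(0.3, p), beta2 = rep(0.2, p),
                          beta3 = rep(0.1, p), clock = "semi-markov") {
  spec <- stats::setNames(
    rep(list(list(dist = "bernoulli", prob = 0.5)), p), paste0("x", seq_len(p)))
  if (p >= 2) spec[[2]] <- list(dist = "truncnorm", mean = 0, sd = 1, lo = -4, hi = 4)
  pr <- idm_params(beta1, beta2, beta3, kappa = c(1.2, 1.1, 1.0),
                   lambda = c(4e-5, 3.5e-5, 6e-4), theta = theta, clock = clock)
  simulate_cohort(generator_config(n, spec, pr, seed = seed, clock = clock))
}

# -- oracle: marginal likelihood by adaptive quadrature over the frailty --
quadrature_subject_loglik <- function(subject, params) {
  th <- params$theta
  f <- function(a) {
    vapply(a, function(ai) {
      exp(subject_loglik_conditional(subject, ai, params)) *
        stats::dgamma(ai, shape = 1 / th, rate = 1 / th)
    }, numeric(1))
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-11, abs.tol = 0)$value)
}

# -- oracle: independent (no-frailty) Weibull-PH log-likelihood ----------
# Separate, loop-based coding of the three transition likelihoods with
# alpha fixed at 1; sojourn clock for transition 3, same half-day tie rule.
independent_weibull_loglik <- function(cohort, params) {
  d <- cohort$data
  X <- covariate_matrix(cohort)
  k <- params$kappa; l <- params$lambda
  total <- 0
  for (i in seq_len(nrow(d))) {
    x <- X[i, ]
    y1 <- d$y1[i]; y2 <- d$y2[i]
    e1 <- exp(sum(x * params$beta1)); e2 <- exp(sum(x * params$beta2))
    e3 <- exp(sum(x * params$beta3))
    total <- total - l[1] * y1^k[1] * e1 - l[2] * y1^k[2] * e2
    if (d$delta1[i] == 1) {
      total <- total + log(k[1] * l[1] * y1^(k[1] - 1) * e1)
      s <- y2 - y1
      if (s <= 0) s <- 0.5
      if (params$clock == "semi-markov") {
        total <- total - l[3] * s^k[3] * e3
        if (d$delta2[i] == 1)
          total <- total + log(k[3] * l[3] * s^(k[3] - 1) * e3)
      } else {
        y2e <- y1 + s
        total <- total - l[3] * (y2e^k[3] - y1^k[3]) * e3
        if (d$delta2[i] == 1)
          total <- total + log(k[3] * l[3] * y2e^(k[3] - 1) * e3)
      }
    } else if (d$delta2[i] == 1) {
      total <- total + log(k[2] * l[2] * y2^(k[2] - 1) * e2)
    }
  }
  total
}

# -- oracle: hand-written Cox log partial likelihood (single covariate) --
hand_partial_loglik <- function(beta, time, event, x, ties = "breslow") {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    d <- length(dead)
    if (ties == "breslow" || d == 1) {
      ll <- ll + sum(x[dead]) * beta - d * log(sum(exp(beta * x[risk])))
    } else {
      sR <- sum(exp(beta * x[risk])); sD <- sum(exp(beta * x[dead]))
      ll <- ll + sum(x[dead]) * beta
      for (j in 0:(d - 1)) ll <- ll - log(sR - (j / d) * sD)
    }
  }
  ll
}

brute_force_cox_beta <- function(time, event, x, ties = "breslow",
                                 lower = -20, upper = 20) {
  stats::optimize(function(b) hand_partial_loglik(b, time, event, x, ties),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# -- simulators for PH-diagnostic calibration and power ------------------
simulate_ph_respecting <- function(n, beta = 0.5, lam = 0.1, seed = 1) {
  set.seed(seed)
  x <- cbind(z = stats::rbinom(n, 1, 0.5))
  t <- stats::rexp(n, rate = lam * exp(beta * x[, 1]))
  cens <- stats::runif(n, 0, 15)
  list(time = pmin(t, cens), event = as.numeric(t <= cens), X = x)
}

# hazard lam*exp(b*x) before tflip, lam*exp(-b*x) after: a sign-flipping
# covariate effect, generated by piecewise-exponential inversion
simulate_sign_flip <- function(n, b = 1, tflip = 7, lam = 0.1, seed = 1) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  u <- stats::rexp(n)
  h1 <- lam * exp(b * x); h2 <- lam * exp(-b * x)
  t <- ifelse(u < h1 * tflip, u / h1, tflip + (u - h1 * tflip) / h2)
  cens <- stats::runif(n, 0, 3 * tflip)
  list(time = pmin(t, cens), event = as.numeric(t <= cens), X = cbind(z = x))
}

# -- scenario of the naive-vs-joint discordance suite --------------------
# Death-only binary covariate z under strong shared frailty: the naive
# cause-specific analysis picks up a spurious protective association for z
# while the joint model's transition-1 HR stays near 1.
discordance_scenario_params <- function() {
  idm_params(beta1 = c(0, 0.3), beta2 = c(1.8, 0.2), beta3 = c(1.0, 0.1),
             kappa = c(1.2, 1.1, 1.0), lambda = c(9e-5, 9e-5, 6e-4), theta = 2)
}

discordance_scenario_spec <- function() {
  list(z = list(dist = "bernoulli", prob = 0.5),
       x = list(dist = "truncnorm", mean = 0, sd = 1, lo = -4, hi = 4))
}

# random valid subject + parameter draw for oracle-equivalence sweeps
random_subject_param_pair <- function(seed) {
  set.seed(seed)
  p <- 2
  x <- c(stats::rbinom(1, 1, 0.5), round(stats::rnorm(1), 3))
  pattern <- sample(0:3, 1)  # 0:(0,0) 1:(0,1) 2:(1,0) 3:(1,1)
  d1 <- as.numeric(pattern >= 2); d2 <- as.numeric(pattern %% 2 == 1)
  y2 <- round(stats::runif(1, 50, 2500), 2)
  y1 <- if (d1 == 1) round(y2 * stats::runif(1, 0.2, 0.98), 2) else y2
  params <- idm_params(
    beta1 = stats::rnorm(p, 0, 0.5), beta2 = stats::rnorm(p, 0, 0.5),
    beta3 = stats::rnorm(p, 0, 0.5),
    kappa = stats::runif(3, 0.7, 1.6),
    lambda = exp(stats::runif(3, log(1e-5), log(1e-3))),
    theta = stats::runif(1, 0.05, 2),
    clock = sample(c("semi-markov", "markov"), 1))
  list(subject = list(y1 = y1, delta1 = d1, y2 = y2, delta2 = d2, x = x),
       params = params)
}
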