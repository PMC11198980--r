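# Cause-specific Cox comparator: the "naive" analysis that treats death as
# random censoring for the non-terminal event, fitted by Newton-Raphson on
# the log partial likelihood (Breslow or Efron tie handling), plus
# Schoenfeld-residual proportional-hazards diagnostics and the
# event-indicator correlation check.

#' Recode a semi-competing-risks cohort for the naive non-terminal analysis
#'
#' Death and dropout are both treated as censoring for the non-terminal
#' event: time = `y1`, event = `delta1`.
#'
#' @param cohort a `cohort_table`.
#' @return list with `time`, `event` and covariate matrix `X`.
#' @export
censor_at_death <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  list(time = cohort$data$y1, event = cohort$data$delta1,
       X = covariate_matrix(cohort))
}

# Risk-set and death-set sums at each unique event time, ordered
# increasingly; internal, also used by the Schoenfeld machinery.
cox_event_slices <- function(time, event, X) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  ev_times <- unique(time[event == 1])
  list(time = time, event = event, X = X, ev_times = ev_times)
}

cox_loglik_deriv <- function(beta, time, event, X, ties = "efron") {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  r <- exp(eta)
  ord <- order(-time)  # decreasing time so cumulative sums give risk sets
  to <- time[ord]; eo <- event[ord]; Xo <- X[ord, , drop = FALSE]; ro <- r[ord]
  S0 <- cumsum(ro)
  S1 <- apply(Xo * ro, 2, cumsum)
  # S2 as p x p per position is expensive; accumulate per event time instead
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  ev_times <- unique(to[eo == 1])
  for (t in ev_times) {
    at_risk <- max(which(to >= t))          # positions 1..at_risk are at risk
    idx_d <- which(to == t & eo == 1)
    d <- length(idx_d)
    Xd <- Xo[idx_d, , drop = FALSE]; rd <- ro[idx_d]
    s0R <- S0[at_risk]
    s1R <- S1[at_risk, ]
    riskpos <- which(to >= t)
    XR <- Xo[riskpos, , drop = FALSE]; rR <- ro[riskpos]
    s2R <- crossprod(XR * sqrt(rR))
    ll <- ll + sum(Xd %*% beta)
    U <- U + colSums(Xd)
    if (ties == "breslow" || d == 1) {
      ll <- ll - d * log(s0R)
      U <- U - d * s1R / s0R
      I <- I + d * (s2R / s0R - tcrossprod(s1R / s0R))
    } else {
      s0D <- sum(rd)
      s1D <- colSums(Xd * rd)
      s2D <- crossprod(Xd * sqrt(rd))
      for (j in 0:(d - 1)) {
        f <- j / d
        den <- s0R - f * s0D
        num1 <- s1R - f * s1D
        num2 <- s2R - f * s2D
        ll <- ll - log(den)
        U <- U - num1 / den
        I <- I + num2 / den - tcrossprod(num1 / den)
      }
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards fit by Newton-Raphson partial likelihood
#'
#' Maximises the log partial likelihood with Breslow or Efron tie handling,
#' starting from `beta = 0`, with step-halving whenever a Newton step would
#' decrease the log partial likelihood.  Standard errors come from the
#' inverse observed information.  A coefficient exceeding 50 in absolute
#' value (separation/divergence) is flagged as non-convergence.
#'
#' @param time follow-up times.
#' @param event event indicators (0/1); at least one event required.
#' @param X covariate matrix; every column must be non-constant.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param control list: `maxit` (25), `tol` (1e-9, on the log partial
#'   likelihood change).
#' @return object of class `cox_fit`: `beta`, `se`, `vcov`, `loglik`,
#'   `loglik_null`, `hr_table`, `ties`, `converged`, `iter`.
#' @export
cox_fit <- function(time, event, X, ties = c("efron", "breslow"),
                    control = list()) {
  ties <- match.arg(ties)
  ctl <- utils::modifyList(list(maxit = 25L, tol = 1e-9), control)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(time) == nrow(X), length(event) == nrow(X))
  if (sum(event) == 0)
    stop_scr("no events: the partial likelihood is undefined", class = "no_events_error")
  const <- apply(X, 2, function(col) stats::var(col) == 0)
  if (any(const))
    stop_scr("constant covariate(s): %s", paste(colnames(X)[const], collapse = ", "),
             class = "identifiability_error")

  p <- ncol(X)
  beta <- numeric(p)
  cur <- cox_loglik_deriv(beta, time, event, X, ties)
  ll_null <- cur$loglik
  converged <- FALSE; iter <- 0L
  for (iter in seq_len(ctl$maxit)) {
    step <- tryCatch(solve(cur$info, cur$score), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    repeat {
      cand <- beta + lam * step
      nxt <- cox_loglik_deriv(cand, time, event, X, ties)
      if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { nxt <- cur; cand <- beta; break }
    }
    delta_ll <- nxt$loglik - cur$loglik
    beta <- cand; cur <- nxt
    if (abs(delta_ll) < ctl$tol && max(abs(cur$score)) < 1e-5) {
      converged <- TRUE; break
    }
  }
  if (any(abs(beta) > 50)) converged <- FALSE
  V <- tryCatch(solve(cur$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- names(se) <- colnames(X)
  z <- beta / se
  hr_table <- data.frame(covariate = colnames(X), hr = exp(beta),
                         lo = exp(beta - 1.96 * se), hi = exp(beta + 1.96 * se),
                         p_value = 2 * stats::pnorm(-abs(z)),
                         stringsAsFactors = FALSE)
  rownames(hr_table) <- NULL
  structure(list(beta = beta, se = se, vcov = V, loglik = cur$loglik,
                 loglik_null = ll_null, hr_table = hr_table, ties = ties,
                 converged = converged, iter = iter),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties), loglik = %.4f, %s\n",
              x$ties, x$loglik,
              if (x$converged) sprintf("converged in %d iterations", x$iter)
              else "NOT converged"))
  print(format(x$hr_table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Grambsch-Therneau score test: Schoenfeld residuals at each event time
#' are regressed on a transform of time (Kaplan-Meier by default; identity
#' and rank offered).  Per-covariate chi-square statistics (1 df) use the
#' averaged-variance form; the global statistic (p df) tests all covariates
#' jointly.
#'
#' @param fit a converged [cox_fit()].
#' @param time,event,X the data the fit was computed from.
#' @param transform `"km"`, `"identity"` or `"rank"`.
#' @return object of class `ph_test`: data.frame `table` (covariate,
#'   chisq, df, p), `global` (chisq, df, p), and `n_satisfying` — the number
#'   of covariates with p > 0.05.
#' @export
schoenfeld_ph_test <- function(fit, time, event, X,
                               transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "cox_fit"))
  X <- as.matrix(X)
  if (sum(event) == 0)
    stop_scr("no events: Schoenfeld residuals are undefined", class = "no_events_error")
  p <- ncol(X)
  beta <- fit$beta
  eta <- drop(X %*% beta); r <- exp(eta)
  ord <- order(time); to <- time[ord]; eo <- event[ord]
  Xo <- X[ord, , drop = FALSE]; ro <- r[ord]
  ev_idx <- which(eo == 1)
  m <- length(ev_idx)

  resid <- matrix(0, m, p)      # one residual per death (ties kept separate)
  Vbar <- matrix(0, p, p)
  for (i in seq_len(m)) {
    ti <- to[ev_idx[i]]
    risk <- which(to >= ti)
    rr <- ro[risk]; XR <- Xo[risk, , drop = FALSE]
    s0 <- sum(rr)
    xbar <- colSums(XR * rr) / s0
    Vk <- crossprod(XR * sqrt(rr)) / s0 - tcrossprod(xbar)
    resid[i, ] <- Xo[ev_idx[i], ] - xbar
    Vbar <- Vbar + Vk
  }
  Vbar <- Vbar / m

  g <- switch(transform,
              identity = to[ev_idx],
              rank = rank(to[ev_idx], ties.method = "average"),
              km = {
                # left-continuous Kaplan-Meier of the censoring-inclusive
                # follow-up distribution, evaluated just before each death
                n <- length(to)
                surv <- numeric(n); s <- 1
                for (i in seq_len(n)) {
                  surv[i] <- s
                  if (eo[i] == 1) s <- s * (1 - 1 / (n - i + 1))
                }
                1 - surv[ev_idx]
              })
  gc <- g - mean(g)
  ssg <- sum(gc^2)
  U <- drop(crossprod(resid, gc))        # sum_k (g_k - gbar) s_k
  Vinv <- solve(Vbar)
  per_chisq <- (Vinv %*% U)^2 / (diag(Vinv) * ssg)
  per_p <- stats::pchisq(per_chisq, df = 1, lower.tail = FALSE)
  glob <- drop(t(U) %*% Vinv %*% U) / ssg
  glob_p <- stats::pchisq(glob, df = p, lower.tail = FALSE)

  tab <- data.frame(covariate = colnames(X) %||% paste0("x", 1:p),
                    chisq = drop(per_chisq), df = 1, p_value = drop(per_p),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 global = list(chisq = glob, df = p, p_value = glob_p),
                 transform = transform,
                 n_satisfying = sum(tab$p_value > 0.05)),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat(sprintf("Proportional-hazards test (Schoenfeld residuals, %s transform)\n",
              x$transform))
  print(format(x$table, digits = 4), row.names = FALSE)
  cat(sprintf("GLOBAL: chisq = %.3f, df = %d, p = %.4g\n",
              x$global$chisq, x$global$df, x$global$p_value))
  cat(sprintf("%d of %d covariates satisfy proportionality at 0.05\n",
              x$n_satisfying, nrow(x$table)))
  invisible(x)
}

#' Pearson correlation between the two event indicators
#'
#' Checks the dependence between occurrence of the non-terminal event and
#' death — positive correlation is the empirical signature motivating a
#' shared-frailty model.
#'
#' @param cohort a `cohort_table`; both indicators must be non-constant.
#' @return list with `estimate`, `p_value`, `n`.
#' @export
event_correlation <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  d1 <- cohort$data$delta1; d2 <- cohort$data$delta2
  if (stats::var(d1) == 0 || stats::var(d2) == 0)
    stop_scr("an event indicator is constant: correlation undefined",
             class = "constant_indicator_error")
  ct <- stats::cor.test(d1, d2, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(d1))
}

#' Side-by-side hazard-ratio comparison of the naive and joint models
#'
#' Pairs the naive cause-specific Cox HRs (death treated as random
#' censoring) with the frailty illness-death model's transition-1 HRs for
#' the same covariates, flags significance at 0.05 in each column, and marks
#' covariates whose significance status differs between the two models.
#'
#' @param naive a [cox_fit()] on the censor-at-death recoding.
#' @param joint an [fit_idm()] result.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame of class `hr_comparison` with columns `covariate`,
#'   `hr_naive`, `lo_naive`, `hi_naive`, `hr_joint`, `lo_joint`, `hi_joint`,
#'   `sig_naive`, `sig_joint`, `discordant`.
#' @export
hr_comparison_table <- function(naive, joint, alpha = 0.05) {
  stopifnot(inherits(naive, "cox_fit"), inherits(joint, "idm_fit"))
  a <- naive$hr_table
  b <- joint$hr_table[joint$hr_table$transition == 1, , drop = FALSE]
  if (!identical(a$covariate, b$covariate))
    stop_scr("covariate names/order differ between the two fits",
             class = "covariate_mismatch_error")
  out <- data.frame(
    covariate = a$covariate,
    hr_naive = a$hr, lo_naive = a$lo, hi_naive = a$hi,
    hr_joint = b$hr, lo_joint = b$lo, hi_joint = b$hi,
    sig_naive = a$p_value < alpha,
    sig_joint = b$p_value < alpha,
    stringsAsFactors = FALSE)
  out$discordant <- out$sig_naive != out$sig_joint
  class(out) <- c("hr_comparison", "data.frame")
  out
}

#' @export
print.hr_comparison <- function(x, ...) {
  cat("Hazard ratios for the non-terminal event:\n")
  cat("  [naive]  treating death as random censoring\n")
  cat("  [joint]  considering death as a semi-competing risk\n")
  df <- data.frame(
    covariate = x$covariate,
    naive = sprintf("%.3f (%.3f, %.3f)%s", x$hr_naive, x$lo_naive, x$hi_naive,
                    ifelse(x$sig_naive, " *", "")),
    joint = sprintf("%.3f (%.3f, %.3f)%s", x$hr_joint, x$lo_joint, x$hi_joint,
                    ifelse(x$sig_joint, " *", "")),
    discordant = ifelse(x$discordant, "<-", ""))
  print(df, row.names = FALSE)
  cat("* p < 0.05\n")
  invisible(x)
}
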