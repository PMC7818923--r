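# Standalone single-outcome samplers for the separate-model baselines.
# Deliberately independent of the joint sampler's code path: the separate
# fits serve as the comparison arm (and, with all latent correlations fixed
# at zero, as a factorisation check on the joint fit).

# Poisson regression with a lognormal random intercept per unit:
#   y_i ~ Poisson(exp(offset_i + x_i'beta + z_i)),  z_i ~ N(0, theta^2)
mcmc_pois_ranint <- function(y, X, offset, iter, warmup, beta_sd, theta_scale) {
  n <- length(y); p <- ncol(X)
  beta <- c(log(mean(y) + 0.1) - mean(offset), rep(0, p - 1)) +
    stats::rnorm(p, 0, 0.05)
  ltheta <- stats::rnorm(1, log(0.5), 0.2)
  z <- stats::rnorm(n, 0, 0.1)
  s_z <- 0.6; s_t <- 0.3; s_sc <- 0.3; s_sh <- rep(0.3, p)
  am <- am_init(p)
  lp <- offset + drop(X %*% beta)
  keep <- iter - warmup
  draws <- matrix(NA_real_, keep, p + 1)
  for (it in seq_len(iter)) {
    adapting <- it <= warmup
    for (rr in 1:3) {
    th <- exp(ltheta)
    # z
    zp <- z + s_z * stats::rnorm(n)
    la <- poisson_ll(y, lp + zp) - poisson_ll(y, lp + z) +
      stats::dnorm(zp, 0, th, log = TRUE) - stats::dnorm(z, 0, th, log = TRUE)
    acc <- log(stats::runif(n)) < la
    z[acc] <- zp[acc]
    if (adapting) s_z <- adapt_scale(s_z, mean(acc), it, 0.44)
    # beta block
    bp <- am_propose(am, beta)
    lpp <- offset + drop(X %*% bp)
    la <- sum(poisson_ll(y, lpp + z)) - sum(poisson_ll(y, lp + z)) +
      sum(stats::dnorm(bp, 0, beta_sd, log = TRUE)) -
      sum(stats::dnorm(beta, 0, beta_sd, log = TRUE))
    if (is.finite(la) && log(stats::runif(1)) < la) { beta <- bp; lp <- lpp; a1 <- 1 }
    else a1 <- 0
    am <- am_learn(am, beta, a1, it, adapting)
    # translation moves: shift a coefficient against the random intercepts
    # (likelihood-invariant)
    for (k in seq_len(p)) {
      delta <- s_sh[k] * stats::rnorm(1)
      zp <- z - delta * X[, k]
      la <- sum(stats::dnorm(zp, 0, th, log = TRUE)) -
        sum(stats::dnorm(z, 0, th, log = TRUE)) +
        stats::dnorm(beta[k] + delta, 0, beta_sd, log = TRUE) -
        stats::dnorm(beta[k], 0, beta_sd, log = TRUE)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        beta[k] <- beta[k] + delta; z <- zp; lp <- lp + delta * X[, k]; a1 <- 1
      } else a1 <- 0
      if (adapting) s_sh[k] <- adapt_scale(s_sh[k], a1, it, 0.44)
    }
    # scale move: rescale theta together with the random intercepts
    eps <- s_sc * stats::rnorm(1)
    zp <- z * exp(eps); ltp <- ltheta + eps
    la <- sum(poisson_ll(y, lp + zp) - poisson_ll(y, lp + z)) +
      sum(stats::dnorm(zp, 0, exp(ltp), log = TRUE) -
            stats::dnorm(z, 0, exp(ltheta), log = TRUE)) +
      log_half_cauchy(exp(ltp), theta_scale) -
      log_half_cauchy(exp(ltheta), theta_scale) + ltp - ltheta + n * eps
    if (is.finite(la) && log(stats::runif(1)) < la) {
      z <- zp; ltheta <- ltp; a1 <- 1
    } else a1 <- 0
    if (adapting) s_sc <- adapt_scale(s_sc, a1, it, 0.44)
    # theta
    ltp <- ltheta + s_t * stats::rnorm(1)
    la <- sum(stats::dnorm(z, 0, exp(ltp), log = TRUE)) -
      sum(stats::dnorm(z, 0, exp(ltheta), log = TRUE)) +
      log_half_cauchy(exp(ltp), theta_scale) - log_half_cauchy(exp(ltheta), theta_scale) +
      ltp - ltheta
    if (is.finite(la) && log(stats::runif(1)) < la) { ltheta <- ltp; a1 <- 1 } else a1 <- 0
    if (adapting) s_t <- adapt_scale(s_t, a1, it, 0.44)
    }
    if (it > warmup) draws[it - warmup, ] <- c(beta, exp(ltheta))
  }
  draws
}

# Proportional-odds cumulative-logit regression with a unit-level (patient)
# random intercept; grades in 1..4, three thresholds.
mcmc_cumlogit_ranint <- function(grades, X, unit, n_unit, iter, warmup,
                                 beta_sd, alpha_sd, theta_scale) {
  p <- ncol(X)
  cum <- cumsum(tabulate(grades, 4))[1:3] / length(grades)
  alpha <- stats::qlogis(pmin(pmax(cum, 0.01), 0.99)) + stats::rnorm(3, 0, 0.05)
  for (k in 2:3) alpha[k] <- max(alpha[k], alpha[k - 1] + 0.1)
  beta <- stats::rnorm(p, 0, 0.05)
  ltheta <- stats::rnorm(1, log(0.5), 0.2)
  z <- stats::rnorm(n_unit, 0, 0.1)
  s_z <- 0.6; s_t <- 0.3; s_sc <- 0.3; s_sh <- rep(0.3, p + 1)
  q <- p + 3
  am <- am_init(q)
  # unit-level covariate values for translation moves (cycle-constant only)
  ufirst <- match(seq_len(n_unit), unit)
  const_k <- which(apply(X, 2, function(v)
    all(tapply(v, unit, function(x) max(x) - min(x)) == 0)))
  xu <- X[ufirst, , drop = FALSE]
  lp <- drop(X %*% beta)
  keep <- iter - warmup
  draws <- matrix(NA_real_, keep, q + 1)
  for (it in seq_len(iter)) {
    adapting <- it <= warmup
    for (rr in 1:3) {
    th <- exp(ltheta)
    # z (vectorised over units via rowsum of per-observation differences)
    zp <- z + s_z * stats::rnorm(n_unit)
    dll <- ord_ll_emb(alpha, lp + zp[unit], grades) -
      ord_ll_emb(alpha, lp + z[unit], grades)
    la <- drop(rowsum(dll, unit)) +
      stats::dnorm(zp, 0, th, log = TRUE) - stats::dnorm(z, 0, th, log = TRUE)
    acc <- log(stats::runif(n_unit)) < la
    z[acc] <- zp[acc]
    if (adapting) s_z <- adapt_scale(s_z, mean(acc), it, 0.44)
    # (alpha, beta) block
    prop <- am_propose(am, c(alpha, beta))
    if (all(diff(prop[1:3]) > 0)) {
      lpp <- drop(X %*% prop[-(1:3)])
      la <- sum(ord_ll_emb(prop[1:3], lpp + z[unit], grades)) -
        sum(ord_ll_emb(alpha, lp + z[unit], grades)) +
        sum(stats::dnorm(prop[1:3], 0, alpha_sd, log = TRUE)) -
        sum(stats::dnorm(alpha, 0, alpha_sd, log = TRUE)) +
        sum(stats::dnorm(prop[-(1:3)], 0, beta_sd, log = TRUE)) -
        sum(stats::dnorm(beta, 0, beta_sd, log = TRUE))
      if (is.finite(la) && log(stats::runif(1)) < la) {
        alpha <- prop[1:3]; beta <- prop[-(1:3)]; lp <- lpp; a1 <- 1
      } else a1 <- 0
    } else a1 <- 0
    am <- am_learn(am, c(alpha, beta), a1, it, adapting)
    # translation moves: thresholds shift with the random intercepts, and
    # coefficients of unit-constant covariates shift against them
    delta <- s_sh[1] * stats::rnorm(1)
    la <- sum(stats::dnorm(z + delta, 0, th, log = TRUE)) -
      sum(stats::dnorm(z, 0, th, log = TRUE)) +
      sum(stats::dnorm(alpha + delta, 0, alpha_sd, log = TRUE)) -
      sum(stats::dnorm(alpha, 0, alpha_sd, log = TRUE))
    if (is.finite(la) && log(stats::runif(1)) < la) {
      alpha <- alpha + delta; z <- z + delta; a1 <- 1
    } else a1 <- 0
    if (adapting) s_sh[1] <- adapt_scale(s_sh[1], a1, it, 0.44)
    for (k in const_k) {
      delta <- s_sh[1 + k] * stats::rnorm(1)
      zp <- z - delta * xu[, k]
      la <- sum(stats::dnorm(zp, 0, th, log = TRUE)) -
        sum(stats::dnorm(z, 0, th, log = TRUE)) +
        stats::dnorm(beta[k] + delta, 0, beta_sd, log = TRUE) -
        stats::dnorm(beta[k], 0, beta_sd, log = TRUE)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        beta[k] <- beta[k] + delta; z <- zp; lp <- lp + delta * X[, k]; a1 <- 1
      } else a1 <- 0
      if (adapting) s_sh[1 + k] <- adapt_scale(s_sh[1 + k], a1, it, 0.44)
    }
    # scale move: rescale theta together with the random intercepts
    eps <- s_sc * stats::rnorm(1)
    zp <- z * exp(eps); ltp <- ltheta + eps
    la <- sum(ord_ll_emb(alpha, lp + zp[unit], grades) -
                ord_ll_emb(alpha, lp + z[unit], grades)) +
      sum(stats::dnorm(zp, 0, exp(ltp), log = TRUE) -
            stats::dnorm(z, 0, exp(ltheta), log = TRUE)) +
      log_half_cauchy(exp(ltp), theta_scale) -
      log_half_cauchy(exp(ltheta), theta_scale) + ltp - ltheta + n_unit * eps
    if (is.finite(la) && log(stats::runif(1)) < la) {
      z <- zp; ltheta <- ltp; a1 <- 1
    } else a1 <- 0
    if (adapting) s_sc <- adapt_scale(s_sc, a1, it, 0.44)
    # theta
    ltp <- ltheta + s_t * stats::rnorm(1)
    la <- sum(stats::dnorm(z, 0, exp(ltp), log = TRUE)) -
      sum(stats::dnorm(z, 0, exp(ltheta), log = TRUE)) +
      log_half_cauchy(exp(ltp), theta_scale) - log_half_cauchy(exp(ltheta), theta_scale) +
      ltp - ltheta
    if (is.finite(la) && log(stats::runif(1)) < la) { ltheta <- ltp; a1 <- 1 } else a1 <- 0
    if (adapting) s_t <- adapt_scale(s_t, a1, it, 0.44)
    }
    if (it > warmup) draws[it - warmup, ] <- c(alpha, beta, exp(ltheta))
  }
  draws
}

# Plain probit regression by exact Gibbs with truncated-normal data
# augmentation: w_i ~ N(x_i'beta, 1) truncated by the outcome's sign.
mcmc_probit <- function(y, X, iter, warmup, beta_sd) {
  n <- length(y); p <- ncol(X)
  beta <- c(stats::qnorm(mean(y)), rep(0, p - 1)) + stats::rnorm(p, 0, 0.05)
  Prec <- crossprod(X) + diag(1 / beta_sd^2, p)
  Uc <- chol(Prec)
  am <- am_init(p)
  probit_ll <- function(b) {
    q <- drop(X %*% b)
    sum(ifelse(y == 1, stats::pnorm(q, log.p = TRUE),
               stats::pnorm(q, lower.tail = FALSE, log.p = TRUE))) +
      sum(stats::dnorm(b, 0, beta_sd, log = TRUE))
  }
  keep <- iter - warmup
  draws <- matrix(NA_real_, keep, p)
  for (it in seq_len(iter)) {
    adapting <- it <= warmup
    # truncated-normal data augmentation with a conjugate coefficient draw
    lp <- drop(X %*% beta)
    plo <- stats::pnorm(-lp)
    u <- ifelse(y == 1, plo + stats::runif(n) * (1 - plo), stats::runif(n) * plo)
    u <- pmin(pmax(u, 1e-14), 1 - 1e-14)
    w <- lp + stats::qnorm(u)
    mu <- backsolve(Uc, backsolve(Uc, crossprod(X, w), transpose = TRUE))
    beta <- drop(mu + backsolve(Uc, stats::rnorm(p)))
    # collapsed Metropolis step against the exact probit likelihood (the
    # augmented chain alone mixes slowly for weakly identified coefficients)
    for (rr in 1:2) {
      prop <- am_propose(am, beta)
      la <- probit_ll(prop) - probit_ll(beta)
      a1 <- if (is.finite(la) && log(stats::runif(1)) < la) 1 else 0
      if (a1 == 1) beta <- prop
      am <- am_learn(am, beta, a1, it, adapting)
    }
    if (it > warmup) draws[it - warmup, ] <- beta
  }
  draws
}

run_separate_chain <- function(md, priors, iter, warmup) {
  dO <- mcmc_pois_ranint(md$y_O, md$X_O, rep(0, md$n), iter, warmup,
                         priors$beta_sd["O"], priors$theta_scale)
  dM <- mcmc_pois_ranint(md$y_M, md$X_M, md$off_M, iter, warmup,
                         priors$beta_sd["M"], priors$theta_scale)
  dE <- mcmc_cumlogit_ranint(md$grades_E, md$X_E, md$emb_group,
                             length(md$pat_emb), iter, warmup,
                             priors$beta_sd["E"], priors$alpha_sd,
                             priors$theta_scale)
  dF <- mcmc_cumlogit_ranint(md$grades_F, md$X_F, md$emb_group,
                             length(md$pat_emb), iter, warmup,
                             priors$beta_sd["F"], priors$alpha_sd,
                             priors$theta_scale)
  dD <- mcmc_probit(md$y_D, md$X_D, iter, warmup, priors$beta_sd["D"])
  dL <- mcmc_probit(md$y_L, md$X_L, iter, warmup, priors$beta_sd["L"])
  out <- cbind(dO[, seq_len(ncol(md$X_O))], dM[, seq_len(ncol(md$X_M))],
               dE[, seq_len(3 + ncol(md$X_E))], dF[, seq_len(3 + ncol(md$X_F))],
               dD, dL,
               dO[, ncol(md$X_O) + 1], dM[, ncol(md$X_M) + 1],
               dE[, 4 + ncol(md$X_E)], dF[, 4 + ncol(md$X_F)])
  colnames(out) <- make_param_names(md, eta_mode = "zero")
  out
}
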