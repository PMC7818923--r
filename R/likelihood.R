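# Likelihood building blocks for the six submodels, conditional on the
# latent vector, plus analytic/numeric marginalisation utilities.

dot_check <- function(x_row, beta) {
  if (is.matrix(x_row)) {
    if (ncol(x_row) != length(beta))
      stop("covariate row has ", ncol(x_row), " elements but beta has ",
           length(beta))
    return(drop(x_row %*% beta))
  }
  if (length(x_row) != length(beta))
    stop("covariate row has ", length(x_row), " elements but beta has ",
         length(beta))
  sum(x_row * beta)
}

#' Linear predictors of the count submodels
#'
#' `oocyte_log_rate()` returns the log Poisson rate of the oocyte yield,
#' `x %*% beta + z`, where `z` is the patient's latent overdispersion term.
#' `fert_log_rate()` returns the log rate of the fertilisation count,
#' `log(n_oocytes) + x %*% beta + z`: the offset encodes that each retrieved
#' oocyte is an opportunity for fertilisation (oocytes that were never mixed
#' are assumed incapable of successful fertilisation).
#'
#' @param x_row covariate row vector (or matrix of rows), first element the
#'   intercept.
#' @param beta coefficient vector aligned with `x_row`.
#' @param z latent value(s), default 0.
#' @param n_oocytes positive oocyte count(s); a patient with none is not in
#'   the fertilisation submodel.
#' @return log rate(s); the Poisson rate is `exp()` of the result.
#' @export
oocyte_log_rate <- function(x_row, beta, z = 0) {
  dot_check(x_row, beta) + z
}

#' @rdname oocyte_log_rate
#' @export
fert_log_rate <- function(n_oocytes, x_row, beta, z = 0) {
  if (any(n_oocytes < 1))
    stop("fertilisation submodel requires n_oocytes >= 1 (patient with no ",
         "oocytes mixed is not in this submodel)")
  log(n_oocytes) + dot_check(x_row, beta) + z
}

#' Grade probabilities of the cumulative-logit submodels
#'
#' Cumulative probabilities `gamma_k = plogis(alpha_k - x %*% beta - z)` for
#' `k = 1, 2, 3`; the negative signs make a positive covariate effect shift
#' probability mass towards higher grades.
#'
#' @param alpha strictly increasing length-3 threshold vector.
#' @param x_row covariate row vector, or a matrix with one row per embryo;
#'   may be `NULL` for a threshold-only model.
#' @param beta coefficients (ignored when `x_row` is `NULL`).
#' @param z patient latent value(s).
#' @return probability vector over grades 1..4 (or a matrix with one row per
#'   embryo); rows sum to 1.
#' @export
ordinal_category_probs <- function(alpha, x_row = NULL, beta = NULL, z = 0) {
  if (length(alpha) != 3L || any(diff(alpha) <= 0))
    stop("alpha must be 3 strictly increasing thresholds")
  lp <- if (is.null(x_row)) 0 else dot_check(x_row, beta)
  shift <- lp + z
  g1 <- stats::plogis(alpha[1] - shift)
  g2 <- stats::plogis(alpha[2] - shift)
  g3 <- stats::plogis(alpha[3] - shift)
  out <- cbind(g1, g2 - g1, g3 - g2, 1 - g3)
  colnames(out) <- paste0("grade", 1:4)
  if (length(shift) == 1L) out[1, ] else out
}

#' Success probability of the latent-probit submodels
#'
#' The binary outcome is 1 exactly when `x %*% beta + z >= 0` with
#' `z ~ N(0, 1)`.  With `z = "marginal"` the latent is integrated out,
#' giving the probit probability `pnorm(x %*% beta)`; with a numeric `z` the
#' conditional outcome is deterministic and the 0/1 indicator is returned.
#'
#' @inheritParams oocyte_log_rate
#' @param z `"marginal"` or numeric latent value(s).
#' @return probability (marginal) or 0/1 indicator (conditional).
#' @export
probit_success_prob <- function(x_row, beta, z = "marginal") {
  lp <- dot_check(x_row, beta)
  if (identical(z, "marginal")) return(stats::pnorm(lp))
  as.numeric(lp + z >= 0)
}

# P(X <= h, Y <= k) for standard bivariate normal with correlation r,
# by 1-d quadrature of phi(x) * Phi((k - r x) / sqrt(1 - r^2)).
pbvn_lower <- function(h, k, r) {
  if (abs(r) > 1 - 1e-12) {
    if (r > 0) return(stats::pnorm(min(h, k)))
    return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  }
  if (!is.finite(h) && h > 0) return(stats::pnorm(k))
  if (!is.finite(k) && k > 0) return(stats::pnorm(h))
  if (!is.finite(h) || !is.finite(k)) return(0)
  s <- sqrt(1 - r^2)
  val <- stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((k - r * x) / s),
                          -9, h, rel.tol = 1e-11, abs.tol = 1e-16)$value
  min(max(val, 0), 1)
}

# P(sign events) for the two probit outcomes given conditional mean m (2),
# covariance C (2x2), linear predictors lp (2) and observed 0/1 y (2, may
# contain NA to drop a component).
probit_pair_prob <- function(m, C, lp, y) {
  use <- !is.na(y)
  if (!any(use)) return(1)
  s <- ifelse(y == 1, 1, -1)
  if (sum(use) == 1L) {
    i <- which(use)
    a <- (-lp[i] - m[i]) / sqrt(C[i, i])
    return(stats::pnorm(s[i] * a, lower.tail = FALSE))
  }
  sd1 <- sqrt(C[1, 1]); sd2 <- sqrt(C[2, 2])
  a <- (-lp - m) / c(sd1, sd2)
  r <- C[1, 2] / (sd1 * sd2)
  # P(s1 U >= s1 a1, s2 V >= s2 a2) = P(U' >= c1, V' >= c2) with U' = s1 U
  pbvn_lower(-s[1] * a[1], -s[2] * a[2], s[1] * s[2] * r)
}

#' Joint log-likelihood conditional on the latent vectors
#'
#' Sums, over patients, the Poisson log-pmf of the oocyte count, the
#' offset-Poisson log-pmf of the fertilisation count (cycles with mixing
#' only), the cumulative-logit log-pmf of every gradable embryo's two
#' grades, and the probit contributions of DET and LBE (transferred cycles
#' only).  Stages a patient never reached contribute nothing, matching the
#' model's dropout convention.
#'
#' Two probit evaluation modes are supported.  `"indicator"` treats the
#' supplied `z_D`, `z_L` as the sampled latent residuals and scores the
#' deterministic sign rule (0 or `-Inf` per observation); `"conditional"`
#' ignores the `D`/`L` columns of `latents` and integrates those two latents
#' analytically given the other four, using their conditional bivariate
#' normal distribution.
#'
#' @param cohort an [ivf_cohort].
#' @param params an [ivf_parameters]; its `scaling` is applied to the design
#'   matrices.
#' @param latents numeric matrix with one row per cycle (aligned with
#'   `cohort$cycles`) and columns `O, M, E, F, D, L`.
#' @param specs submodel specs from [ivf_specs()].
#' @param probit `"indicator"` or `"conditional"`.
#' @return scalar log-likelihood.
#' @export
joint_log_likelihood <- function(cohort, params, latents, specs = ivf_specs(),
                                 probit = c("indicator", "conditional")) {
  probit <- match.arg(probit)
  cy <- cohort$cycles
  n <- nrow(cy)
  latents <- as.matrix(latents)
  if (nrow(latents) != n || ncol(latents) != 6L)
    stop("latents must be an n x 6 matrix aligned with the cycle table")
  colnames(latents) <- OUTCOMES
  sigma <- latent_covariance(params$theta, params$eta)
  sc <- params$scaling

  ll <- 0
  # oocyte count: all cycles
  X <- build_design(specs$O, cohort, sc)
  if (any(is.na(latents[, "O"]))) stop("latent z_O missing for a patient")
  ll <- ll + sum(stats::dpois(cy$n_oocytes,
                              exp(oocyte_log_rate(X, params$beta_O, latents[, "O"])),
                              log = TRUE))
  # fertilisation count: cycles with mixing
  mix <- which(cy$mixed == 1)
  if (length(mix)) {
    if (any(is.na(latents[mix, "M"]))) stop("latent z_M missing for a mixed cycle")
    X <- build_design(specs$M, cohort, sc)[mix, , drop = FALSE]
    lr <- fert_log_rate(cy$n_oocytes[mix], X, params$beta_M, latents[mix, "M"])
    ll <- ll + sum(stats::dpois(cy$n_embryos[mix], exp(lr), log = TRUE))
  }
  # embryo grades
  if (nrow(cohort$embryos)) {
    pat <- match(cohort$embryos$cycle_id, cy$cycle_id)
    for (o in c("E", "F")) {
      zz <- latents[pat, o]
      if (any(is.na(zz))) stop("latent z_", o, " missing for a cycle with embryos")
      X <- build_design(specs[[o]], cohort, sc)
      probs <- ordinal_category_probs(params[[paste0("alpha_", o)]], X,
                                      params[[paste0("beta_", o)]], zz)
      if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
      grade <- if (o == "E") cohort$embryos$evenness else cohort$embryos$fragmentation
      ll <- ll + sum(log(probs[cbind(seq_along(grade), grade)]))
    }
  }
  # DET and LBE: transferred cycles
  tr <- which(!is.na(cy$transferred) & cy$transferred == 1)
  if (length(tr)) {
    XD <- build_design(specs$D, cohort, sc)[tr, , drop = FALSE]
    XL <- build_design(specs$L, cohort, sc)[tr, , drop = FALSE]
    lpD <- drop(XD %*% params$beta_D)
    lpL <- drop(XL %*% params$beta_L)
    if (probit == "indicator") {
      if (any(is.na(latents[tr, c("D", "L")])))
        stop("latent z_D/z_L missing for a transferred cycle")
      okD <- (lpD + latents[tr, "D"] >= 0) == (cy$det[tr] == 1)
      okL <- (lpL + latents[tr, "L"] >= 0) == (cy$lbe[tr] == 1)
      ll <- ll + sum(ifelse(okD & okL, 0, -Inf))
    } else {
      for (i in seq_along(tr)) {
        j <- tr[i]
        cond <- conditional_latent(sigma, 1:4, latents[j, 1:4])
        ll <- ll + log(probit_pair_prob(cond$mean, cond$sigma,
                                        c(lpD[i], lpL[i]),
                                        c(cy$det[j], cy$lbe[j])))
      }
    }
  }
  ll
}

#' Latent-integrated likelihood of a single patient by quadrature
#'
#' Integrates the conditional likelihood of one patient's observed outcomes
#' over the latent vector, using tensor-product Gauss--Hermite quadrature
#' over the latent components of the supplied count/ordinal outcomes and
#' exact (bivariate) normal probabilities for the probit outcomes given
#' those components.  This is a numerical reference primitive: stage
#' consistency of the supplied outcomes is not enforced, so arbitrary
#' subsets (for example only the oocyte count and the live-birth indicator)
#' can be integrated.
#'
#' @param obs list with any of: `y_O` and `x_O`; `y_M`, `x_M` and `y_O`
#'   (offset); `y_E` (embryo grade vector) and `x_E` (matrix, one row per
#'   embryo); `y_F`, `x_F`; `y_D`, `x_D`; `y_L`, `x_L`.  Design rows must
#'   already be on the scale of the coefficients.
#' @param params an [ivf_parameters].
#' @param nodes number of Gauss--Hermite nodes per latent dimension.
#' @return log of the integrated likelihood.
#' @export
marginal_loglik_gh <- function(obs, params, nodes = 40) {
  sigma <- latent_covariance(params$theta, params$eta)
  active <- c(O = !is.null(obs$y_O), M = !is.null(obs$y_M),
              E = !is.null(obs$y_E), F = !is.null(obs$y_F))
  A <- which(active)
  d <- length(A)
  gh <- pracma::gaussHermite(nodes)

  if (d > 0) {
    grids <- rep(list(seq_len(nodes)), d)
    G <- as.matrix(expand.grid(grids))
    Z <- sqrt(2) * matrix(gh$x[G], ncol = d) %*% chol(sigma[A, A, drop = FALSE])
    logW <- rowSums(matrix(log(gh$w[G]), ncol = d)) - d / 2 * log(pi)
  } else {
    Z <- matrix(0, 1, 0)
    logW <- 0
  }
  colnames(Z) <- names(A)

  logf <- rep(0, nrow(Z))
  if (active["O"])
    logf <- logf + stats::dpois(obs$y_O,
                                exp(sum(obs$x_O * params$beta_O) + Z[, "O"]), log = TRUE)
  if (active["M"])
    logf <- logf + stats::dpois(obs$y_M,
                                exp(fert_log_rate(obs$y_O, obs$x_M, params$beta_M, Z[, "M"])),
                                log = TRUE)
  for (o in c("E", "F")) {
    if (!active[o]) next
    grades <- obs[[paste0("y_", o)]]
    Xe <- obs[[paste0("x_", o)]]
    if (!is.matrix(Xe)) Xe <- matrix(Xe, nrow = length(grades), byrow = TRUE,
                                     ncol = length(params[[paste0("beta_", o)]]))
    for (e in seq_along(grades)) {
      probs <- ordinal_category_probs(params[[paste0("alpha_", o)]],
                                      matrix(Xe[e, ], nrow(Z), ncol(Xe), byrow = TRUE),
                                      params[[paste0("beta_", o)]], Z[, o])
      if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
      logf <- logf + log(probs[, grades[e]])
    }
  }
  yD <- if (is.null(obs$y_D)) NA else obs$y_D
  yL <- if (is.null(obs$y_L)) NA else obs$y_L
  if (!is.na(yD) || !is.na(yL)) {
    lpD <- if (is.na(yD)) 0 else sum(obs$x_D * params$beta_D)
    lpL <- if (is.na(yL)) 0 else sum(obs$x_L * params$beta_L)
    if (d > 0) {
      cnd <- conditional_latent(sigma, A, rep(0, d))
      dl <- match(c(5, 6), cnd$idx)
      W <- solve(sigma[A, A, drop = FALSE], sigma[A, 5:6, drop = FALSE])
      M <- Z[, seq_len(d), drop = FALSE] %*% W     # conditional means per node
      C <- cnd$sigma[dl, dl]
      for (i in seq_len(nrow(Z)))
        logf[i] <- logf[i] + log(probit_pair_prob(M[i, ], C, c(lpD, lpL), c(yD, yL)))
    } else {
      logf <- logf + log(probit_pair_prob(c(0, 0), sigma[5:6, 5:6],
                                          c(lpD, lpL), c(yD, yL)))
    }
  }
  lse <- logW + logf
  m <- max(lse)
  m + log(sum(exp(lse - m)))
}
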