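# Adaptive Metropolis-within-Gibbs sampler for the joint model.
#
# Updates per iteration:
#   * the six latent columns, vectorised across patients: Metropolis steps
#     against the Poisson/ordinal likelihoods for z_O, z_M, z_E, z_F (exact
#     conditional-normal draws for patients without a likelihood term), and
#     exact truncated-normal draws for the probit latents z_D, z_L;
#   * random-walk Metropolis blocks for the count and ordinal coefficient
#     vectors (thresholds and slopes jointly, with the ordering constraint
#     enforced through the prior support);
#   * conjugate Gibbs draws for the probit coefficients via the (beta, w)
#     reparameterisation w = x'beta + z (data augmentation);
#   * scalar Metropolis steps for log latent SDs and atanh canonical partial
#     correlations of the LKJ-distributed correlation matrix.
# Proposal scales adapt during warmup (diminishing adaptation, frozen
# afterwards) towards acceptance rates of 0.44 (scalars) / 0.234 (blocks).

prepare_model_data <- function(cohort, specs, scaling) {
  cy <- cohort$cycles
  if (nrow(cy) == 0L) stop("cannot fit a model to an empty cohort")
  mix <- which(cy$mixed == 1)
  tr <- which(!is.na(cy$transferred) & cy$transferred == 1)
  emb_pat <- match(cohort$embryos$cycle_id, cy$cycle_id)
  pat_emb <- sort(unique(emb_pat))
  md <- list(
    n = nrow(cy),
    y_O = cy$n_oocytes,
    X_O = build_design(specs$O, cohort, scaling),
    mix = mix,
    y_M = cy$n_embryos[mix],
    X_M = build_design(specs$M, cohort, scaling)[mix, , drop = FALSE],
    off_M = log(pmax(cy$n_oocytes[mix], 1)),
    emb_pat = emb_pat,
    pat_emb = pat_emb,
    emb_group = match(emb_pat, pat_emb),
    grades_E = cohort$embryos$evenness,
    grades_F = cohort$embryos$fragmentation,
    X_E = build_design(specs$E, cohort, scaling),
    X_F = build_design(specs$F, cohort, scaling),
    tr = tr,
    y_D = cy$det[tr],
    y_L = cy$lbe[tr],
    X_D = build_design(specs$D, cohort, scaling)[tr, , drop = FALSE],
    X_L = build_design(specs$L, cohort, scaling)[tr, , drop = FALSE],
    scaling = scaling)
  if (length(tr) == 0L)
    stop("degenerate data: no transferred cycles, the DET and LBE submodels are empty")
  if (length(unique(md$y_D)) < 2L)
    stop("degenerate data: no variation in the DET outcome")
  if (length(unique(md$y_L)) < 2L)
    stop("degenerate data: no variation in the LBE outcome")
  if (length(mix) == 0L)
    stop("degenerate data: no cycle with oocytes mixed")
  if (length(emb_pat) == 0L)
    stop("degenerate data: no gradable embryos")
  md
}

# per-embryo cumulative-logit log-probabilities of the observed grades
ord_ll_emb <- function(alpha, shift, grades) {
  hi <- c(alpha, Inf)[grades]
  lo <- c(-Inf, alpha)[grades]
  log(stats::plogis(hi - shift) - stats::plogis(lo - shift))
}

poisson_ll <- function(y, lp) {
  stats::dpois(y, exp(pmin(lp, 50)), log = TRUE)
}

# diminishing Robbins-Monro adaptation of a log proposal scale
adapt_scale <- function(s, acc_rate, it, target) {
  s * exp(min(0.5, 3 / sqrt(it)) * (acc_rate - target))
}

# full-covariance adaptive-Metropolis block state (Haario-style, with a
# Robbins-Monro scale multiplier; adaptation diminishes and stops at warmup)
am_init <- function(p, s = 1) {
  list(s = s, mean = rep(0, p), M2 = diag(p) * 0, cnt = 0)
}

am_propose <- function(a, cur) {
  p <- length(cur)
  if (a$cnt > 2 * p + 20) {
    cov <- a$M2 / (a$cnt - 1) * (2.38^2 / p)
    diag(cov) <- diag(cov) + 1e-10
    U <- tryCatch(chol(cov), error = function(e) NULL)
    if (!is.null(U)) return(cur + a$s * drop(crossprod(U, stats::rnorm(p))))
  }
  cur + a$s * 0.02 * stats::rnorm(p)
}

am_learn <- function(a, x, acc, it, adapting, target = 0.234) {
  if (!adapting) return(a)
  a$s <- adapt_scale(a$s, acc, it, target)
  a$cnt <- a$cnt + 1
  d <- x - a$mean
  a$mean <- a$mean + d / a$cnt
  a$M2 <- a$M2 + tcrossprod(d, x - a$mean)
  a
}

make_param_names <- function(md, eta_mode) {
  nm <- c(paste0("beta_O.", colnames(md$X_O)),
          paste0("beta_M.", colnames(md$X_M)),
          paste0("alpha_E.", 1:3), paste0("beta_E.", colnames(md$X_E)),
          paste0("alpha_F.", 1:3), paste0("beta_F.", colnames(md$X_F)),
          paste0("beta_D.", colnames(md$X_D)),
          paste0("beta_L.", colnames(md$X_L)),
          paste0("theta.", c("O", "M", "E", "F")))
  if (eta_mode == "free") nm <- c(nm, paste0("eta.", 1:15))
  nm
}

run_joint_chain <- function(md, priors, iter, warmup, eta_mode = "free",
                            chain_id = 1) {
  n <- md$n
  mix <- md$mix; tr <- md$tr
  pE <- ncol(md$X_E); pF <- ncol(md$X_F)
  jit <- function(x, s = 0.05) x + stats::rnorm(length(x), 0, s)

  # ---- initial values (crude moment estimates, jittered per chain)
  beta_O <- jit(c(log(mean(md$y_O) + 0.1), rep(0, ncol(md$X_O) - 1)))
  beta_M <- jit(c(log((sum(md$y_M) + 0.5) / sum(exp(md$off_M))),
                  rep(0, ncol(md$X_M) - 1)))
  cum_init <- function(grades) {
    p <- cumsum(tabulate(grades, 4))[1:3] / length(grades)
    stats::qlogis(pmin(pmax(p, 0.01), 0.99))
  }
  aE <- cum_init(md$grades_E); aF <- cum_init(md$grades_F)
  fix_order <- function(a) { for (k in 2:3) a[k] <- max(a[k], a[k - 1] + 0.1); a }
  ab_E <- c(fix_order(jit(aE)), rep(0, pE))
  ab_F <- c(fix_order(jit(aF)), rep(0, pF))
  beta_D <- jit(c(stats::qnorm(mean(md$y_D)), rep(0, ncol(md$X_D) - 1)))
  beta_L <- jit(c(stats::qnorm(mean(md$y_L)), rep(0, ncol(md$X_L) - 1)))
  ltheta <- jit(rep(log(0.5), 4), 0.2)
  gamma <- rep(0, 15)
  Z <- matrix(stats::rnorm(n * 6, 0, 0.1), n, 6)

  # ---- proposal-scale state
  target_s <- 0.44; target_b <- 0.234
  sc_z <- rep(0.6, 4)
  sc_sig <- rep(0.3, 19)
  sc_scale <- rep(0.3, 4)
  sh <- list(O = rep(0.3, ncol(md$X_O)), M = rep(0.3, ncol(md$X_M)),
             aE = 0.3, aF = 0.3, E = rep(0.3, pE), F = rep(0.3, pF))
  blocks <- list(O = length(beta_O), M = length(beta_M),
                 E = length(ab_E), F = length(ab_F),
                 Dc = length(beta_D), Lc = length(beta_L))
  ad <- lapply(blocks, function(p) am_init(p))

  # per-patient covariate values for the embryo-model translation moves;
  # only covariates constant within a cycle admit them
  emb_first <- match(md$pat_emb, md$emb_pat)
  cycle_const <- function(X) {
    which(apply(X, 2, function(v)
      all(tapply(v, md$emb_group, function(x) max(x) - min(x)) == 0)))
  }
  constE <- cycle_const(md$X_E); constF <- cycle_const(md$X_F)
  xpat_E <- md$X_E[emb_first, , drop = FALSE]
  xpat_F <- md$X_F[emb_first, , drop = FALSE]

  # ---- covariance bookkeeping
  sigma <- NULL; W <- NULL; vv <- NULL; ll_sig <- NULL
  refresh_sigma <- function() {
    R <- if (eta_mode == "free") cor_from_pcor(tanh(gamma)) else diag(6)
    sds <- c(exp(ltheta), 1, 1)
    sig <- R * outer(sds, sds)
    Wl <- vector("list", 6); vl <- numeric(6)
    for (c0 in 1:6) {
      w <- solve(sig[-c0, -c0], sig[-c0, c0])
      Wl[[c0]] <- w
      vl[c0] <- sig[c0, c0] - sum(sig[c0, -c0] * w)
    }
    sigma <<- sig; W <<- Wl; vv <<- vl
  }
  sig_loglik <- function(sig, Zm = Z) {
    U <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(U)) return(-Inf)
    V <- backsolve(U, t(Zm), transpose = TRUE)
    -n * sum(log(diag(U))) - 0.5 * sum(V * V)
  }
  refresh_sigma()

  # ---- likelihood caches
  lp_O <- drop(md$X_O %*% beta_O)
  lp_M <- md$off_M + drop(md$X_M %*% beta_M)
  lp_Ee <- drop(md$X_E %*% ab_E[-(1:3)])
  lp_Fe <- drop(md$X_F %*% ab_F[-(1:3)])
  lp_D <- drop(md$X_D %*% beta_D)
  lp_L <- drop(md$X_L %*% beta_L)

  prior_block <- function(x, sd_alpha, sd_beta, n_alpha) {
    a <- x[seq_len(n_alpha)]
    if (any(diff(a) <= 0)) return(-Inf)
    sum(stats::dnorm(a, 0, sd_alpha, log = TRUE)) +
      sum(stats::dnorm(x[-seq_len(n_alpha)], 0, sd_beta, log = TRUE))
  }

  keep <- iter - warmup
  nm <- make_param_names(md, eta_mode)
  draws <- matrix(NA_real_, keep, length(nm), dimnames = list(NULL, nm))

  # inner repetitions per stored iteration (extra sweeps cut autocorrelation;
  # the covariance sweep is cheap 6x6 algebra, so it gets the most)
  reps_z <- 2L; reps_b <- 4L; reps_s <- 8L

  for (it in seq_len(iter)) {
    adapting <- it <= warmup

    ## ---- latent columns -------------------------------------------------
    for (rz in seq_len(reps_z)) {
    # z_O: Poisson likelihood for every cycle
    for (col in 1:2) {
      m <- drop(Z[, -col, drop = FALSE] %*% W[[col]])
      sdv <- sqrt(vv[col])
      if (col == 1) { rows <- seq_len(n); y <- md$y_O; lp <- lp_O }
      else { rows <- mix; y <- md$y_M; lp <- lp_M }
      z <- Z[, col]
      pri <- setdiff(seq_len(n), rows)
      if (length(pri)) z[pri] <- stats::rnorm(length(pri), m[pri], sdv)
      zc <- z[rows]
      zp <- zc + sc_z[col] * stats::rnorm(length(rows))
      la <- poisson_ll(y, lp + zp) - poisson_ll(y, lp + zc) +
        stats::dnorm(zp, m[rows], sdv, log = TRUE) -
        stats::dnorm(zc, m[rows], sdv, log = TRUE)
      acc <- log(stats::runif(length(rows))) < la
      zc[acc] <- zp[acc]
      z[rows] <- zc
      Z[, col] <- z
      if (adapting) sc_z[col] <- adapt_scale(sc_z[col], mean(acc), it, target_s)
    }
    # z_E, z_F: ordinal likelihood summed over the patient's embryos
    for (col in 3:4) {
      m <- drop(Z[, -col, drop = FALSE] %*% W[[col]])
      sdv <- sqrt(vv[col])
      rows <- md$pat_emb
      z <- Z[, col]
      pri <- setdiff(seq_len(n), rows)
      if (length(pri)) z[pri] <- stats::rnorm(length(pri), m[pri], sdv)
      alpha <- if (col == 3) ab_E[1:3] else ab_F[1:3]
      lpe <- if (col == 3) lp_Ee else lp_Fe
      grades <- if (col == 3) md$grades_E else md$grades_F
      zc <- z[rows]
      zp <- zc + sc_z[col] * stats::rnorm(length(rows))
      dll <- ord_ll_emb(alpha, lpe + zp[md$emb_group], grades) -
        ord_ll_emb(alpha, lpe + zc[md$emb_group], grades)
      la <- drop(rowsum(dll, md$emb_group)) +
        stats::dnorm(zp, m[rows], sdv, log = TRUE) -
        stats::dnorm(zc, m[rows], sdv, log = TRUE)
      acc <- log(stats::runif(length(rows))) < la
      zc[acc] <- zp[acc]
      z[rows] <- zc
      Z[, col] <- z
      if (adapting) sc_z[col] <- adapt_scale(sc_z[col], mean(acc), it, target_s)
    }
    # z_D, z_L: exact truncated-normal draws (sign rule) for transferred
    for (col in 5:6) {
      m <- drop(Z[, -col, drop = FALSE] %*% W[[col]])
      sdv <- sqrt(vv[col])
      z <- stats::rnorm(n, m, sdv)
      y <- if (col == 5) md$y_D else md$y_L
      lp <- if (col == 5) lp_D else lp_L
      plo <- stats::pnorm((-lp - m[tr]) / sdv)
      u <- ifelse(y == 1,
                  plo + stats::runif(length(tr)) * (1 - plo),
                  stats::runif(length(tr)) * plo)
      u <- pmin(pmax(u, 1e-14), 1 - 1e-14)
      z[tr] <- m[tr] + sdv * stats::qnorm(u)
      Z[, col] <- z
    }
    }

    ## ---- coefficient blocks ---------------------------------------------
    mh_block <- function(cur, key, logpost) {
      prop <- am_propose(ad[[key]], cur)
      la <- logpost(prop) - logpost(cur)
      acc <- is.finite(la) && log(stats::runif(1)) < la
      new <- if (acc) prop else cur
      ad[[key]] <<- am_learn(ad[[key]], new, as.numeric(acc), it, adapting,
                             target_b)
      new
    }
    for (rb in seq_len(reps_b)) {
    lp_beta_O <- function(b) {
      sum(poisson_ll(md$y_O, drop(md$X_O %*% b) + Z[, 1])) +
        sum(stats::dnorm(b, 0, priors$beta_sd["O"], log = TRUE))
    }
    beta_O <- mh_block(beta_O, "O", lp_beta_O)
    lp_O <- drop(md$X_O %*% beta_O)

    lp_beta_M <- function(b) {
      sum(poisson_ll(md$y_M, md$off_M + drop(md$X_M %*% b) + Z[mix, 2])) +
        sum(stats::dnorm(b, 0, priors$beta_sd["M"], log = TRUE))
    }
    beta_M <- mh_block(beta_M, "M", lp_beta_M)
    lp_M <- md$off_M + drop(md$X_M %*% beta_M)

    lp_ord <- function(ab, X, grades, col, sd_beta) {
      pr <- prior_block(ab, priors$alpha_sd, sd_beta, 3)
      if (!is.finite(pr)) return(-Inf)
      shift <- drop(X %*% ab[-(1:3)]) + Z[md$emb_pat, col]
      sum(ord_ll_emb(ab[1:3], shift, grades)) + pr
    }
    ab_E <- mh_block(ab_E, "E", function(x)
      lp_ord(x, md$X_E, md$grades_E, 3, priors$beta_sd["E"]))
    lp_Ee <- drop(md$X_E %*% ab_E[-(1:3)])
    ab_F <- mh_block(ab_F, "F", function(x)
      lp_ord(x, md$X_F, md$grades_F, 4, priors$beta_sd["F"]))
    lp_Fe <- drop(md$X_F %*% ab_F[-(1:3)])

    # probit coefficients: conjugate draw on the w = x'beta + z scale
    for (col in 5:6) {
      X <- if (col == 5) md$X_D else md$X_L
      bcur <- if (col == 5) beta_D else beta_L
      sdp <- priors$beta_sd[if (col == 5) "D" else "L"]
      m <- drop(Z[tr, -col, drop = FALSE] %*% W[[col]])
      v <- vv[col]
      w <- drop(X %*% bcur) + Z[tr, col]
      Prec <- crossprod(X) / v + diag(1 / sdp^2, ncol(X))
      Uc <- chol(Prec)
      mu <- backsolve(Uc, backsolve(Uc, crossprod(X, w - m) / v, transpose = TRUE))
      bnew <- drop(mu + backsolve(Uc, stats::rnorm(ncol(X))))
      if (col == 5) { beta_D <- bnew; lp_D <- drop(X %*% bnew) }
      else { beta_L <- bnew; lp_L <- drop(X %*% bnew) }
      Z[tr, col] <- w - drop(X %*% bnew)
    }
    }

    ## ---- collapsed probit coefficient updates: Metropolis against the
    ## z-marginalised likelihood given the other latents, then an exact
    ## redraw of the probit latent column (partially collapsed Gibbs; far
    ## better mixing for weakly identified coefficients than the conjugate
    ## step alone)
    for (col in 5:6) {
      X <- if (col == 5) md$X_D else md$X_L
      y <- if (col == 5) md$y_D else md$y_L
      key <- if (col == 5) "Dc" else "Lc"
      sdp <- priors$beta_sd[if (col == 5) "D" else "L"]
      m_all <- drop(Z[, -col, drop = FALSE] %*% W[[col]])
      sdv <- sqrt(vv[col])
      mll <- function(b) {
        q <- (drop(X %*% b) + m_all[tr]) / sdv
        sum(ifelse(y == 1, stats::pnorm(q, log.p = TRUE),
                   stats::pnorm(q, lower.tail = FALSE, log.p = TRUE))) +
          sum(stats::dnorm(b, 0, sdp, log = TRUE))
      }
      bnew <- mh_block(if (col == 5) beta_D else beta_L, key, mll)
      lp <- drop(X %*% bnew)
      z <- stats::rnorm(n, m_all, sdv)
      plo <- stats::pnorm((-lp - m_all[tr]) / sdv)
      u <- ifelse(y == 1, plo + stats::runif(length(tr)) * (1 - plo),
                  stats::runif(length(tr)) * plo)
      u <- pmin(pmax(u, 1e-14), 1 - 1e-14)
      z[tr] <- m_all[tr] + sdv * stats::qnorm(u)
      Z[, col] <- z
      if (col == 5) { beta_D <- bnew; lp_D <- lp }
      else { beta_L <- bnew; lp_L <- lp }
    }

    ## ---- translation moves: shift one coefficient and absorb the shift in
    ## its latent column (likelihood-invariant; breaks the ridge between
    ## weakly identified coefficients and the latents)
    ll_sig <- sig_loglik(sigma)
    shift_move <- function(col, delta, zdelta, rows, prior_diff) {
      Zp <- Z
      Zp[rows, col] <- Z[rows, col] + zdelta
      llp <- sig_loglik(sigma, Zp)
      la <- llp - ll_sig + prior_diff
      acc <- is.finite(la) && log(stats::runif(1)) < la
      if (acc) { Z <<- Zp; ll_sig <<- llp }
      acc
    }
    dn <- function(x, s) stats::dnorm(x, 0, s, log = TRUE)
    for (k in seq_along(beta_O)) {
      delta <- sh$O[k] * stats::rnorm(1)
      acc <- shift_move(1, delta, -delta * md$X_O[, k], seq_len(n),
                        dn(beta_O[k] + delta, priors$beta_sd["O"]) -
                          dn(beta_O[k], priors$beta_sd["O"]))
      if (acc) { beta_O[k] <- beta_O[k] + delta; lp_O <- lp_O + delta * md$X_O[, k] }
      if (adapting) sh$O[k] <- adapt_scale(sh$O[k], as.numeric(acc), it, target_s)
    }
    for (k in seq_along(beta_M)) {
      delta <- sh$M[k] * stats::rnorm(1)
      acc <- shift_move(2, delta, -delta * md$X_M[, k], mix,
                        dn(beta_M[k] + delta, priors$beta_sd["M"]) -
                          dn(beta_M[k], priors$beta_sd["M"]))
      if (acc) { beta_M[k] <- beta_M[k] + delta; lp_M <- lp_M + delta * md$X_M[, k] }
      if (adapting) sh$M[k] <- adapt_scale(sh$M[k], as.numeric(acc), it, target_s)
    }
    # thresholds shift with the latent column (grade probabilities depend on
    # alpha_k - x'beta - z); coefficients of cycle-constant covariates admit
    # the analogous move
    for (o in c("E", "F")) {
      col <- if (o == "E") 3 else 4
      akey <- paste0("a", o)
      delta <- sh[[akey]] * stats::rnorm(1)
      ab <- if (o == "E") ab_E else ab_F
      acc <- shift_move(col, delta, rep(delta, length(md$pat_emb)), md$pat_emb,
                        sum(dn(ab[1:3] + delta, priors$alpha_sd)) -
                          sum(dn(ab[1:3], priors$alpha_sd)))
      if (acc) {
        if (o == "E") ab_E[1:3] <- ab_E[1:3] + delta
        else ab_F[1:3] <- ab_F[1:3] + delta
      }
      if (adapting) sh[[akey]] <- adapt_scale(sh[[akey]], as.numeric(acc), it, target_s)
      xpat <- if (o == "E") xpat_E else xpat_F
      for (k in (if (o == "E") constE else constF)) {
        delta <- sh[[o]][k] * stats::rnorm(1)
        acc <- shift_move(col, delta, -delta * xpat[, k], md$pat_emb,
                          dn((if (o == "E") ab_E else ab_F)[3 + k] + delta,
                             priors$beta_sd[o]) -
                            dn((if (o == "E") ab_E else ab_F)[3 + k],
                               priors$beta_sd[o]))
        if (acc) {
          if (o == "E") {
            ab_E[3 + k] <- ab_E[3 + k] + delta
            lp_Ee <- lp_Ee + delta * md$X_E[, k]
          } else {
            ab_F[3 + k] <- ab_F[3 + k] + delta
            lp_Fe <- lp_Fe + delta * md$X_F[, k]
          }
        }
        if (adapting) sh[[o]][k] <- adapt_scale(sh[[o]][k], as.numeric(acc), it, target_s)
      }
    }

    ## ---- scale moves: rescale a latent SD together with its column
    ## (decouples theta from the latents' overall spread)
    lp_theta <- function(lt) sum(log_half_cauchy(exp(lt), priors$theta_scale)) + sum(lt)
    for (col in 1:4) {
      eps <- sc_scale[col] * stats::rnorm(1)
      cfac <- exp(eps)
      Zp <- Z
      Zp[, col] <- Z[, col] * cfac
      ltp <- ltheta; ltp[col] <- ltp[col] + eps
      R <- if (eta_mode == "free") cor_from_pcor(tanh(gamma)) else diag(6)
      sds <- c(exp(ltp), 1, 1)
      sigp <- R * outer(sds, sds)
      likdiff <- switch(col,
        sum(poisson_ll(md$y_O, lp_O + Zp[, 1]) - poisson_ll(md$y_O, lp_O + Z[, 1])),
        sum(poisson_ll(md$y_M, lp_M + Zp[mix, 2]) - poisson_ll(md$y_M, lp_M + Z[mix, 2])),
        sum(ord_ll_emb(ab_E[1:3], lp_Ee + Zp[md$emb_pat, 3], md$grades_E) -
              ord_ll_emb(ab_E[1:3], lp_Ee + Z[md$emb_pat, 3], md$grades_E)),
        sum(ord_ll_emb(ab_F[1:3], lp_Fe + Zp[md$emb_pat, 4], md$grades_F) -
              ord_ll_emb(ab_F[1:3], lp_Fe + Z[md$emb_pat, 4], md$grades_F)))
      la <- likdiff + sig_loglik(sigp, Zp) - sig_loglik(sigma, Z) +
        lp_theta(ltp) - lp_theta(ltheta) + n * eps
      acc <- is.finite(la) && log(stats::runif(1)) < la
      if (acc) {
        Z <- Zp; ltheta <- ltp; sigma <- sigp
        ll_sig <- sig_loglik(sigma, Z)
      }
      if (adapting) sc_scale[col] <- adapt_scale(sc_scale[col], as.numeric(acc),
                                                 it, target_s)
    }

    ## ---- latent SDs and correlations ------------------------------------
    for (rs in seq_len(reps_s)) {
    for (k in 1:4) {
      ltp <- ltheta; ltp[k] <- ltp[k] + sc_sig[k] * stats::rnorm(1)
      R <- if (eta_mode == "free") cor_from_pcor(tanh(gamma)) else diag(6)
      sds <- c(exp(ltp), 1, 1)
      sigp <- R * outer(sds, sds)
      la <- sig_loglik(sigp) - ll_sig + lp_theta(ltp) - lp_theta(ltheta)
      if (is.finite(la) && log(stats::runif(1)) < la) {
        ltheta <- ltp; sigma <- sigp; ll_sig <- sig_loglik(sigma)
        if (adapting) sc_sig[k] <- adapt_scale(sc_sig[k], 1, it, target_s)
      } else if (adapting) sc_sig[k] <- adapt_scale(sc_sig[k], 0, it, target_s)
    }
    if (eta_mode == "free") {
      for (k in 1:15) {
        gp <- gamma; gp[k] <- gp[k] + sc_sig[4 + k] * stats::rnorm(1)
        sds <- c(exp(ltheta), 1, 1)
        sigp <- cor_from_pcor(tanh(gp)) * outer(sds, sds)
        la <- sig_loglik(sigp) - ll_sig +
          log_lkj_gamma_prior(gp, priors$lkj_shape) -
          log_lkj_gamma_prior(gamma, priors$lkj_shape)
        if (is.finite(la) && log(stats::runif(1)) < la) {
          gamma <- gp; sigma <- sigp; ll_sig <- sig_loglik(sigma)
          if (adapting) sc_sig[4 + k] <- adapt_scale(sc_sig[4 + k], 1, it, target_s)
        } else if (adapting) sc_sig[4 + k] <- adapt_scale(sc_sig[4 + k], 0, it, target_s)
      }
    }
    }
    refresh_sigma()

    if (it > warmup) {
      eta_draw <- if (eta_mode == "free") {
        R <- cor_from_pcor(tanh(gamma)); R[ETA_PAIRS]
      } else NULL
      draws[it - warmup, ] <- c(beta_O, beta_M, ab_E[1:3], ab_E[-(1:3)],
                                ab_F[1:3], ab_F[-(1:3)], beta_D, beta_L,
                                exp(ltheta), eta_draw)
    }
  }
  draws
}
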