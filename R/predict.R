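# Sequential posterior-predictive simulation: pre-treatment (whole cycle)
# and dynamic (conditional on an observed stage prefix), with deterministic
# dropout propagation and explicit denominators.

STAGE_ORDER <- c("n_oocytes", "n_embryos", "grades", "det", "lbe")

# scaled covariate value for the linear predictor
.pred_scale <- function(x, name, scaling) {
  s <- scaling[[name]]
  if (is.null(s)) x else (x - s[["center"]]) / s[["scale"]]
}

# linear predictor of one submodel from a named list of covariate vectors
.pred_lp <- function(terms, beta, vals, scaling) {
  lp <- 0
  for (i in seq_along(terms)) {
    t0 <- terms[i]
    v <- if (t0 == "intercept") 1 else .pred_scale(vals[[t0]], t0, scaling)
    lp <- lp + beta[i] * v
  }
  lp
}

# split one pooled-draws row into parameter pieces (precomputed index map)
.param_index <- function(colnames) {
  list(beta_O = grep("^beta_O\\.", colnames),
       beta_M = grep("^beta_M\\.", colnames),
       beta_E = grep("^beta_E\\.", colnames),
       beta_F = grep("^beta_F\\.", colnames),
       beta_D = grep("^beta_D\\.", colnames),
       beta_L = grep("^beta_L\\.", colnames),
       alpha_E = grep("^alpha_E\\.", colnames),
       alpha_F = grep("^alpha_F\\.", colnames),
       theta = grep("^theta\\.", colnames),
       eta = grep("^eta\\.", colnames))
}

# grade-count simulation: multinomial(n, probs) by successive binomials,
# vectorised across patients; returns counts (npat x 4)
.grade_counts <- function(n, probs) {
  npat <- length(n)
  counts <- matrix(0L, npat, 4)
  rem <- n
  prem <- rep(1, npat)
  for (k in 1:3) {
    p <- ifelse(prem > 0, pmin(probs[, k] / prem, 1), 0)
    counts[, k] <- stats::rbinom(npat, rem, p)
    rem <- rem - counts[, k]
    prem <- prem - probs[, k]
  }
  counts[, 4] <- rem
  counts
}

.sample_grade <- function(probs) {
  cum <- probs %*% upper.tri(diag(4), diag = TRUE)
  1L + rowSums(stats::runif(nrow(probs)) > cum[, 1:3, drop = FALSE])
}

.check_newdata <- function(newdata) {
  req <- c("age", "partner_age", "attempt", "icsi")
  miss <- setdiff(req, names(newdata))
  if (length(miss))
    stop("newdata is missing covariate(s): ", paste(miss, collapse = ", "))
  bad <- intersect(names(newdata),
                   c("n_oocytes", "n_embryos", "fert_rate", "mean_evenness",
                     "mean_fragmentation", "det", "lbe"))
  if (length(bad))
    stop("newdata must contain pre-treatment covariates only; found: ",
         paste(bad, collapse = ", "), " (use predict_dynamic for observed outcomes)")
  newdata$attempt <- pool_attempts(newdata$attempt)
  newdata
}

# core forward simulator shared by the pre-treatment and dynamic paths
.sim_chain <- function(fit, newdata, observed, n_draws, latents, seed) {
  if (!is.null(seed)) set.seed(seed)
  npat <- nrow(newdata)
  P <- pooled_draws(fit)
  idx <- .param_index(colnames(P))
  rows <- sample.int(nrow(P), n_draws, replace = TRUE)
  sc <- fit$scaling
  specs <- fit$specs

  base <- list(age = newdata$age, partner_age = newdata$partner_age,
               attempt2 = as.numeric(newdata$attempt == "2"),
               attempt3 = as.numeric(newdata$attempt == "3"),
               attempt4_5 = as.numeric(newdata$attempt == "4-5"),
               icsi = as.numeric(newdata$icsi))

  out <- list()
  for (v in c("y_O", "y_M", "transferred", "det", "lbe", "evenness",
              "fragmentation", "mean_evenness", "mean_fragmentation"))
    out[[v]] <- matrix(NA_real_, n_draws, npat)

  obs <- observed %||% list()
  has_obs <- function(v) !is.null(obs[[v]])

  for (d in seq_len(n_draws)) {
    r <- P[rows[d], ]
    th <- r[idx$theta]
    eta <- if (length(idx$eta)) r[idx$eta] else rep(0, 15)
    Z <- if (latents == "included") {
      sigma <- latent_covariance(th, eta)
      rmvn(npat, sigma)
    } else matrix(0, npat, 6)
    vals <- base

    # stage O ------------------------------------------------------------
    if (has_obs("n_oocytes")) y_O <- rep_len(obs$n_oocytes, npat)
    else {
      lp <- .pred_lp(spec_terms(specs$O), r[idx$beta_O], vals, sc)
      y_O <- stats::rpois(npat, exp(pmin(lp + Z[, 1], 50)))
    }
    vals$n_oocytes <- y_O
    alive <- y_O >= 1

    # stage M ------------------------------------------------------------
    if (has_obs("n_embryos")) y_M <- rep_len(obs$n_embryos, npat)
    else {
      lp <- .pred_lp(spec_terms(specs$M), r[idx$beta_M], vals, sc)
      lam <- y_O * exp(pmin(lp + Z[, 2], 50))
      y_M <- ifelse(alive, rpois_trunc(pmax(lam, 1e-12), y_O), NA)
    }
    y_M[!alive] <- NA
    vals$n_embryos <- y_M
    vals$fert_rate <- ifelse(alive & !is.na(y_M), y_M / y_O, NA)
    emb <- !is.na(y_M) & y_M >= 1

    # embryo grades -------------------------------------------------------
    ev <- fr <- mev <- mfr <- rep(NA_real_, npat)
    if (has_obs("mean_evenness")) {
      mev <- rep_len(obs$mean_evenness, npat)
      mfr <- rep_len(obs$mean_fragmentation, npat)
    } else if (any(emb)) {
      for (o in c("E", "F")) {
        b <- r[idx[[paste0("beta_", o)]]]
        a <- r[idx[[paste0("alpha_", o)]]]
        lp <- .pred_lp(spec_terms(specs[[o]]), b, vals, sc)
        zcol <- if (o == "E") 3 else 4
        shift <- lp + Z[, zcol]
        g1 <- stats::plogis(a[1] - shift); g2 <- stats::plogis(a[2] - shift)
        g3 <- stats::plogis(a[3] - shift)
        probs <- cbind(g1, g2 - g1, g3 - g2, 1 - g3)
        grade1 <- .sample_grade(probs)
        cnt <- .grade_counts(ifelse(emb, y_M, 0L), probs)
        mg <- ifelse(emb, (cnt %*% (1:4)) / pmax(y_M, 1), NA)
        if (o == "E") { ev <- ifelse(emb, grade1, NA); mev <- drop(mg) }
        else { fr <- ifelse(emb, grade1, NA); mfr <- drop(mg) }
      }
    }
    mev[!emb] <- NA; mfr[!emb] <- NA
    vals$mean_evenness <- mev
    vals$mean_fragmentation <- mfr

    # transfer, DET, LBE --------------------------------------------------
    transferred <- ifelse(alive & !is.na(y_M), as.numeric(emb), NA)
    tr <- !is.na(transferred) & transferred == 1
    det <- lbe <- rep(NA_real_, npat)
    if (has_obs("det")) det[tr] <- rep_len(obs$det, npat)[tr]
    else if (any(tr)) {
      lp <- .pred_lp(spec_terms(specs$D), r[idx$beta_D], vals, sc)
      lp[!tr] <- 0
      det_all <- if (latents == "included") as.numeric(lp + Z[, 5] >= 0)
      else stats::rbinom(npat, 1, stats::pnorm(lp))
      det_all[!is.na(y_M) & y_M == 1] <- 0  # single embryo: no double transfer
      det[tr] <- det_all[tr]
    }
    vals$det <- ifelse(is.na(det), 0, det)  # value irrelevant off the transfer set
    if (has_obs("lbe")) lbe[tr] <- rep_len(obs$lbe, npat)[tr]
    else if (any(tr)) {
      lp <- .pred_lp(spec_terms(specs$L), r[idx$beta_L], vals, sc)
      lp[!tr] <- 0
      lbe_all <- if (latents == "included") as.numeric(lp + Z[, 6] >= 0)
      else stats::rbinom(npat, 1, stats::pnorm(lp))
      lbe[tr] <- lbe_all[tr]
    }

    out$y_O[d, ] <- y_O
    out$y_M[d, ] <- y_M
    out$transferred[d, ] <- transferred
    out$det[d, ] <- det
    out$lbe[d, ] <- lbe
    out$evenness[d, ] <- ev
    out$fragmentation[d, ] <- fr
    out$mean_evenness[d, ] <- mev
    out$mean_fragmentation[d, ] <- mfr
  }
  structure(out, class = "ivf_draws", latents = latents,
            setting = fit$setting, mode = fit$mode, n_draws = n_draws,
            patients = if (!is.null(newdata$cycle_id)) as.character(newdata$cycle_id)
                       else as.character(seq_len(npat)))
}

#' Pre-treatment sequential prediction
#'
#' Simulates whole treatment cycles for hypothetical new patients, one
#' simulated cycle per posterior draw, propagating failure deterministically:
#' a patient predicted to have no oocytes has no embryos, no grades, no
#' transfer and no live birth.  With `latents = "included"` a fresh latent
#' vector is drawn from its posterior MVN for every simulated cycle; with
#' `"zero"` (the marginal mode) the four free latents are set to 0 and the
#' probit outcomes are drawn with their marginal probabilities
#' `pnorm(x'beta)`.
#'
#' @param fit a pre-treatment `ivf_fit`.
#' @param newdata data frame with columns `age`, `partner_age`, `attempt`,
#'   `icsi` (one row per hypothetical patient).
#' @param n_draws number of posterior-predictive draws.
#' @param latents `"zero"` or `"included"`.
#' @param seed integer seed.
#' @return an `ivf_draws` object: matrices (draws x patients) `y_O`, `y_M`,
#'   `transferred`, `det`, `lbe`, per-hypothetical-embryo grades `evenness`
#'   and `fragmentation`, and per-patient mean grades; stages not reached
#'   are `NA`.
#' @export
predict_pretreatment <- function(fit, newdata, n_draws = 1000,
                                 latents = c("zero", "included"), seed = NULL) {
  latents <- match.arg(latents)
  stopifnot(inherits(fit, "ivf_fit"))
  if (fit$setting != "pretreatment")
    stop("fit is a ", fit$setting, " model; pre-treatment prediction needs a ",
         "pretreatment fit (its covariate set contains downstream outcomes)")
  newdata <- .check_newdata(as.data.frame(newdata))
  .sim_chain(fit, newdata, observed = NULL, n_draws = n_draws,
             latents = latents, seed = seed)
}

#' Dynamic sequential prediction
#'
#' Predicts the remaining stages of a cycle conditional on the observed
#' outcomes of a stage-consistent prefix, plugging the observed (rather than
#' predicted) values into the downstream linear predictors.  Latents for the
#' remaining stages are drawn from their unconditional MVN prior
#' (`latents = "included"`) or set to zero; no filtering update of the
#' latents given the observed outcomes is performed --- the dynamic models
#' condition through covariates only.
#'
#' @param fit a dynamic-setting `ivf_fit`.
#' @param newdata as in [predict_pretreatment()] (one row per patient).
#' @param observed named list giving the observed prefix, applying to all
#'   rows of `newdata` (recycled): `n_oocytes`; optionally `n_embryos`;
#'   optionally both `mean_evenness` and `mean_fragmentation`; optionally
#'   `det`; optionally `lbe` (a complete cycle, leaving nothing to predict).
#'   A later stage without all earlier ones is an error.
#' @inheritParams predict_pretreatment
#' @return an `ivf_draws` object; observed stages are reproduced with zero
#'   predictive variance.
#' @export
predict_dynamic <- function(fit, newdata, observed, n_draws = 1000,
                            latents = c("zero", "included"), seed = NULL) {
  latents <- match.arg(latents)
  stopifnot(inherits(fit, "ivf_fit"))
  if (fit$setting != "dynamic")
    stop("dynamic prediction requires a dynamic-setting fit")
  newdata <- .check_newdata(as.data.frame(newdata))
  observed <- as.list(observed)
  have <- c(n_oocytes = !is.null(observed$n_oocytes),
            n_embryos = !is.null(observed$n_embryos),
            grades = !is.null(observed$mean_evenness) ||
              !is.null(observed$mean_fragmentation),
            det = !is.null(observed$det),
            lbe = !is.null(observed$lbe))
  if (have["grades"] && (is.null(observed$mean_evenness) ||
                         is.null(observed$mean_fragmentation)))
    stop("mean_evenness and mean_fragmentation must be observed together")
  last <- max(c(0, which(have)))
  if (last > 0 && !all(have[seq_len(last)]))
    stop("observed outcomes must form a stage-consistent prefix (missing: ",
         paste(names(have)[seq_len(last)][!have[seq_len(last)]], collapse = ", "), ")")
  if (last == 0) stop("no observed outcomes supplied; use predict_pretreatment")
  .sim_chain(fit, newdata, observed = observed, n_draws = n_draws,
             latents = latents, seed = seed)
}

#' Posterior-predictive percentile summaries
#'
#' 2.5/50/97.5 percentiles of every outcome per patient.  Under the
#' "per cycle started" denominator, failure before a patient-level stage
#' counts as outcome 0 (no oocytes means no embryos, no transfer, no DET, no
#' live birth); under "per stage reached" only draws reaching the stage
#' contribute.  Embryo grades are always summarised conditional on at least
#' one embryo existing.
#'
#' @param draws an `ivf_draws` object.
#' @param denominator `"per_cycle_started"` or `"per_stage_reached"`.
#' @return data frame with columns `patient`, `outcome`, `p2.5`, `p50`,
#'   `p97.5`, `denominator`.
#' @export
predictive_intervals <- function(draws,
                                 denominator = c("per_cycle_started",
                                                 "per_stage_reached")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(draws, "ivf_draws"))
  if (attr(draws, "n_draws") == 0) stop("empty predictive draws")
  outcomes <- c("y_O", "y_M", "evenness", "fragmentation", "det", "lbe")
  grade_like <- c("evenness", "fragmentation")
  res <- list()
  for (o in outcomes) {
    m <- draws[[o]]
    if (denominator == "per_cycle_started" && !o %in% grade_like)
      m[is.na(m)] <- 0
    qs <- apply(m, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA, NA, NA))
      stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    })
    res[[o]] <- data.frame(patient = attr(draws, "patients"), outcome = o,
                           p2.5 = qs[1, ], p50 = qs[2, ], p97.5 = qs[3, ],
                           denominator = denominator)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Probability of a joint event across the predictive distribution
#'
#' Evaluates a predicate on every simulated cycle; stages that failed
#' evaluate as non-events (their fields are `NA` and a predicate returning
#' `NA` is counted as `FALSE`).  The point estimate is the overall fraction
#' of events; the 95% interval is formed from the percentiles, across
#' posterior draws, of the predicted cohort proportion (not a draw-level
#' binomial interval).
#'
#' @param draws an `ivf_draws`.
#' @param predicate function of a data frame (one simulated cycle per row;
#'   columns `y_O`, `y_M`, `evenness`, `fragmentation`, `transferred`,
#'   `det`, `lbe`, `mean_evenness`, `mean_fragmentation`) returning a
#'   logical vector, e.g. `function(d) d$y_O < 15 & d$lbe == 1`.
#' @return list with `estimate`, `lower`, `upper` (cohort-proportion
#'   percentile interval) and `per_draw` proportions.
#' @export
joint_event_probability <- function(draws, predicate) {
  stopifnot(inherits(draws, "ivf_draws"))
  nd <- attr(draws, "n_draws")
  per_draw <- numeric(nd)
  for (d in seq_len(nd)) {
    df <- data.frame(y_O = draws$y_O[d, ], y_M = draws$y_M[d, ],
                     evenness = draws$evenness[d, ],
                     fragmentation = draws$fragmentation[d, ],
                     mean_evenness = draws$mean_evenness[d, ],
                     mean_fragmentation = draws$mean_fragmentation[d, ],
                     transferred = draws$transferred[d, ],
                     det = draws$det[d, ], lbe = draws$lbe[d, ])
    ev <- predicate(df)
    ev[is.na(ev)] <- FALSE
    per_draw[d] <- mean(ev)
  }
  qs <- stats::quantile(per_draw, c(0.025, 0.975), names = FALSE)
  list(estimate = mean(per_draw), lower = qs[1], upper = qs[2],
       per_draw = per_draw)
}

#' @export
print.ivf_draws <- function(x, ...) {
  cat(sprintf("Posterior-predictive draws: %d draws x %d patients (%s latents, %s fit)\n",
              attr(x, "n_draws"), ncol(x$y_O), attr(x, "latents"), attr(x, "setting")))
  invisible(x)
}

#' @export
predict.ivf_fit <- function(object, newdata, observed = NULL, n_draws = 1000,
                            latents = c("zero", "included"), seed = NULL, ...) {
  latents <- match.arg(latents)
  if (is.null(observed))
    predict_pretreatment(object, newdata, n_draws = n_draws,
                         latents = latents, seed = seed)
  else predict_dynamic(object, newdata, observed, n_draws = n_draws,
                       latents = latents, seed = seed)
}
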