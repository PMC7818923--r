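# Fitting interface: one entry point returning a classed fit object with the
# usual methods.

#' Fit the joint or separate IVF outcome models
#'
#' Fits the six submodels --- Poisson oocyte count, offset-Poisson
#' fertilisation count, two proportional-odds cumulative-logit embryo-grade
#' models with patient random intercepts, and two probit models for DET and
#' LBE --- either jointly, linked through a 6-d multivariate-normal latent
#' vector whose correlation matrix carries an LKJ(1) prior, or separately
#' (independent single-outcome fits).  Sampling is by adaptive
#' Metropolis-within-Gibbs; see the package vignette for the update scheme.
#'
#' Patients leave the downstream submodels once treatment fails: latents of
#' unreached stages carry prior-only contributions.  Continuous covariates
#' (ages, and in the dynamic setting the upstream outcomes) are standardised
#' by the cohort mean and SD before fitting; [summarise_posterior()]
#' converts coefficients back to the original per-unit scale.
#'
#' @param cohort a validated [ivf_cohort].
#' @param setting `"pretreatment"` (baseline covariates only) or `"dynamic"`
#'   (upstream outcomes enter downstream submodels as covariates).
#' @param mode `"joint"` or `"separate"`.
#' @param chains number of MCMC chains (at least 2, for the convergence
#'   diagnostic).
#' @param iter iterations per chain, including warmup.
#' @param warmup adaptation iterations discarded from each chain; defaults
#'   to half of `iter`.
#' @param eta `"free"` to estimate the 15 latent correlations under the LKJ
#'   prior, or `"zero"` to fix them all at 0 (the joint model then
#'   factorises into the separate models).  Ignored for `mode = "separate"`.
#' @param specs submodel covariate sets; defaults to [ivf_specs()] for the
#'   chosen setting.
#' @param priors an [build_priors()] object.
#' @param seed integer seed.
#' @param rhat_threshold convergence is flagged when any split R-hat exceeds
#'   this value (default 1.05).
#' @return an object of class `ivf_fit` with components `chains` (list of
#'   draw matrices, one per chain, post-warmup), `rhat`, `converged`,
#'   `scaling`, `specs` and run metadata.
#' @export
fit_ivf <- function(cohort, setting = c("pretreatment", "dynamic"),
                    mode = c("joint", "separate"), chains = 3, iter = 2000,
                    warmup = floor(iter / 2), eta = c("free", "zero"),
                    specs = NULL, priors = build_priors(), seed = NULL,
                    rhat_threshold = 1.05) {
  setting <- match.arg(setting)
  mode <- match.arg(mode)
  eta <- match.arg(eta)
  stopifnot(inherits(cohort, "ivf_cohort"))
  if (chains < 2) stop("at least 2 chains are required for the convergence diagnostic")
  if (warmup < 1 || warmup >= iter) stop("warmup must be in [1, iter)")
  if (is.null(specs)) specs <- ivf_specs(setting)
  scaling <- compute_scaling(cohort, specs)
  md <- prepare_model_data(cohort, specs, scaling)
  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)
  draw_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    draw_list[[ch]] <- if (mode == "joint")
      run_joint_chain(md, priors, iter, warmup, eta_mode = eta, chain_id = ch)
    else run_separate_chain(md, priors, iter, warmup)
  }
  rh <- rhat(draw_list)
  fit <- structure(list(
    mode = mode, setting = setting, eta = if (mode == "joint") eta else "separate",
    chains = draw_list, iter = iter, warmup = warmup, n_chains = chains,
    specs = specs, priors = priors, scaling = scaling, seed = seed,
    rhat = rh, rhat_threshold = rhat_threshold,
    converged = all(is.na(rh) | rh <= rhat_threshold),
    data_summary = c(n_cycles = md$n, n_mixed = length(md$mix),
                     n_embryos = length(md$emb_pat), n_transfers = length(md$tr))),
    class = "ivf_fit")
  if (!fit$converged)
    warning(sprintf("convergence flag: %d parameter(s) with split R-hat > %.2f (max %.3f)",
                    sum(rh > rhat_threshold, na.rm = TRUE), rhat_threshold,
                    max(rh, na.rm = TRUE)))
  fit
}

#' @rdname fit_ivf
#' @param ... passed on to [fit_ivf()].
#' @export
fit_joint <- function(cohort, ...) fit_ivf(cohort, mode = "joint", ...)

#' @rdname fit_ivf
#' @export
fit_separate <- function(cohort, ...) fit_ivf(cohort, mode = "separate", ...)

# pooled post-warmup draws across chains
pooled_draws <- function(fit) do.call(rbind, fit$chains)

#' Split-chain potential scale reduction factor
#'
#' Split R-hat: each chain is halved, and the ratio of pooled-to-within
#' variance is computed across the resulting half-chains.  Values near 1
#' indicate the chains agree; a constant quantity yields `NaN` with a
#' warning.
#'
#' @param x an `ivf_fit`, a list of per-chain draw matrices (iterations x
#'   parameters), or a list of per-chain numeric vectors.
#' @return named vector of R-hat values (or a scalar for vector input).
#' @export
rhat <- function(x) {
  if (inherits(x, "ivf_fit")) return(x$rhat)
  if (!is.list(x) || length(x) < 2) stop("need at least 2 chains")
  if (is.matrix(x[[1]])) {
    out <- vapply(seq_len(ncol(x[[1]])),
                  function(j) rhat_one(lapply(x, function(m) m[, j])),
                  numeric(1))
    names(out) <- colnames(x[[1]])
    return(out)
  }
  rhat_one(x)
}

rhat_one <- function(chains) {
  n2 <- floor(min(lengths(chains)) / 2)
  halves <- unlist(lapply(chains, function(v)
    list(v[seq_len(n2)], v[n2 + seq_len(n2)])), recursive = FALSE)
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  Wv <- mean(vars)
  if (!is.finite(Wv) || Wv == 0) {
    warning("split R-hat undefined for a zero-variance quantity")
    return(NaN)
  }
  B <- n2 * stats::var(means)
  sqrt(((n2 - 1) / n2 * Wv + B / n2) / Wv)
}

#' Posterior coefficient table
#'
#' Posterior medians and central 95% credible intervals per parameter, with
#' split R-hat.  With `original_scale = TRUE` (default), coefficients of
#' standardised covariates are divided by the covariate SD so they are
#' reported per original unit (for example per year of age), the convention
#' of the reference analysis.
#'
#' @param fit an `ivf_fit`.
#' @param original_scale report standardised-covariate coefficients per
#'   original unit?
#' @return data frame with columns `parameter`, `median`, `lower95`,
#'   `upper95`, `rhat`.
#' @export
summarise_posterior <- function(fit, original_scale = TRUE) {
  draws <- pooled_draws(fit)
  if (original_scale) {
    for (j in colnames(draws)) {
      cov <- sub("^(beta|alpha|theta|eta)_?[A-Z]?\\.", "", j)
      if (startsWith(j, "beta_") && cov %in% names(fit$scaling))
        draws[, j] <- draws[, j] / fit$scaling[[cov]][["scale"]]
    }
  }
  qs <- t(apply(draws, 2, stats::quantile, c(0.5, 0.025, 0.975), names = FALSE))
  data.frame(parameter = colnames(draws), median = qs[, 1],
             lower95 = qs[, 2], upper95 = qs[, 3],
             rhat = fit$rhat[colnames(draws)], row.names = NULL)
}

#' @export
print.ivf_fit <- function(x, ...) {
  cat(sprintf("IVF %s model (%s setting)\n", x$mode, x$setting))
  if (x$mode == "joint")
    cat(sprintf("  latent correlations: %s\n", x$eta))
  cat(sprintf("  %d chains x %d iterations (%d warmup); %d cycles, %d embryos, %d transfers\n",
              x$n_chains, x$iter, x$warmup, x$data_summary["n_cycles"],
              x$data_summary["n_embryos"], x$data_summary["n_transfers"]))
  cat(sprintf("  max split R-hat %.3f (%s)\n", max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.ivf_fit <- function(object, original_scale = TRUE, ...) {
  out <- summarise_posterior(object, original_scale = original_scale)
  class(out) <- c("summary.ivf_fit", class(out))
  attr(out, "header") <- sprintf("IVF %s model, %s setting (coefficients %s)",
                                 object$mode, object$setting,
                                 if (original_scale) "on the original covariate scale"
                                 else "standardised")
  out
}

#' @export
print.summary.ivf_fit <- function(x, ...) {
  cat(attr(x, "header"), "\n")
  print.data.frame(cbind(x["parameter"],
                         round(x[c("median", "lower95", "upper95", "rhat")], 3)),
                   row.names = FALSE)
  invisible(x)
}

#' @export
coef.ivf_fit <- function(object, ...) {
  apply(pooled_draws(object), 2, stats::median)
}

# Posterior medians arranged as an ivf_parameters object (standardised
# scale); eta medians are projected to the nearest valid correlation matrix
# simply by validity check -- medians of valid draws are used as-is.
#' Posterior-median parameter set
#'
#' @param fit an `ivf_fit`.
#' @return an [ivf_parameters] on the fit's standardised covariate scale.
#' @export
median_parameters <- function(fit) {
  med <- coef(fit)
  pick <- function(prefix) {
    v <- med[startsWith(names(med), prefix)]
    stats::setNames(v, sub(prefix, "", names(v), fixed = TRUE))
  }
  eta <- if (fit$mode == "joint" && fit$eta == "free") unname(pick("eta.")) else rep(0, 15)
  ivf_parameters(beta_O = pick("beta_O."), beta_M = pick("beta_M."),
                 beta_E = pick("beta_E."), beta_F = pick("beta_F."),
                 beta_D = pick("beta_D."), beta_L = pick("beta_L."),
                 alpha_E = unname(pick("alpha_E.")),
                 alpha_F = unname(pick("alpha_F.")),
                 theta = unname(pick("theta.")), eta = eta,
                 scaling = fit$scaling)
}

#' Compare posterior precision of a dynamic joint fit with its separate
#' counterpart
#'
#' The joint dynamic model's coefficients for upstream-outcome covariates
#' are known to be markedly less precise than the separate fits'.  This
#' check warns when the posterior SD of any outcome-covariate coefficient in
#' `joint` exceeds `factor` times its counterpart in `separate`.
#'
#' @param joint,separate `ivf_fit` objects on the same data and specs.
#' @param factor warning threshold (default 5).
#' @return invisibly, a data frame of the compared SDs.
#' @export
check_precision <- function(joint, separate, factor = 5) {
  dj <- pooled_draws(joint); ds <- pooled_draws(separate)
  dyn <- grep("\\.(n_oocytes|fert_rate|mean_evenness|mean_fragmentation|det)$",
              colnames(dj), value = TRUE)
  dyn <- intersect(dyn, colnames(ds))
  if (!length(dyn)) return(invisible(NULL))
  tab <- data.frame(parameter = dyn,
                    sd_joint = apply(dj[, dyn, drop = FALSE], 2, stats::sd),
                    sd_separate = apply(ds[, dyn, drop = FALSE], 2, stats::sd))
  tab$ratio <- tab$sd_joint / tab$sd_separate
  worst <- tab[tab$ratio > factor, , drop = FALSE]
  if (nrow(worst))
    warning(sprintf("precision: %d outcome-covariate coefficient(s) over %gx less precise than the separate fit (worst: %s, %.1fx)",
                    nrow(worst), factor, worst$parameter[which.max(worst$ratio)],
                    max(worst$ratio)))
  invisible(tab)
}

#' Write / read a fitted model as JSON
#'
#' Serialises the posterior draws and metadata so predictions and
#' evaluations can be run in a separate process (the command-line pipeline
#' uses this format).
#'
#' @param fit an `ivf_fit`.
#' @param path file path.
#' @return `read_fit()` returns the `ivf_fit`; `write_fit()` its input,
#'   invisibly.
#' @export
write_fit <- function(fit, path) {
  obj <- unclass(fit)
  obj$priors <- unclass(obj$priors)
  obj$chains <- lapply(obj$chains, function(m)
    list(colnames = colnames(m), data = unname(m)))
  obj$specs <- lapply(unclass(obj$specs),
                      function(s) list(outcome = s$outcome, covariates = s$covariates))
  obj$setting_attr <- attr(fit$specs, "setting")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(fit)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chains <- lapply(seq_len(nrow_safe(obj$chains)), function(i) NULL)
  ch <- obj$chains
  if (is.data.frame(ch)) {
    chains <- lapply(seq_len(nrow(ch)), function(i) {
      m <- ch$data[[i]]
      colnames(m) <- ch$colnames[[i]]
      m
    })
  } else {
    chains <- lapply(ch, function(x) {
      m <- x$data
      colnames(m) <- x$colnames
      m
    })
  }
  specs <- lapply(obj$specs, function(s)
    submodel_spec(s$outcome, unlist(s$covariates)))
  names(specs) <- vapply(specs, function(s) s$outcome, character(1))
  attr(specs, "setting") <- obj$setting_attr
  scaling <- lapply(obj$scaling, function(s)
    stats::setNames(as.numeric(unlist(s)), c("center", "scale")))
  rh <- unlist(obj$rhat)
  structure(list(mode = obj$mode, setting = obj$setting, eta = obj$eta,
                 chains = chains, iter = obj$iter, warmup = obj$warmup,
                 n_chains = obj$n_chains, specs = specs,
                 priors = do.call(build_priors, list()), scaling = scaling,
                 seed = obj$seed, rhat = rh,
                 rhat_threshold = obj$rhat_threshold,
                 converged = obj$converged,
                 data_summary = unlist(obj$data_summary)),
            class = "ivf_fit")
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
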