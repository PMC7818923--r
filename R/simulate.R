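# Synthetic two-level IVF cohorts drawn from the full generative chain:
# covariates -> latent vector -> oocyte count -> fertilisation count ->
# embryo grades -> transfer -> DET -> live birth, with deterministic dropout
# propagation.

#' Default covariate-generating distributions
#'
#' Matched to the baseline characteristics of a large routine clinical IVF
#' cohort: age median 33 (IQR 30--36, range 21--43), partner age median 35
#' (IQR 32--39, range 19--72), attempt numbers 72/22/5/1% across categories
#' 1, 2, 3 and pooled 4--5.  Ages are drawn from truncated normals and
#' rounded to whole years.  The fertilisation method (ICSI) is decided
#' prospectively per cycle; no rate is reported for the reference cohort, so
#' the default is 0.5.
#'
#' @return a named list understood by [simulate_cohort()].
#' @export
default_covariate_model <- function() {
  list(age = list(mean = 33, sd = 4.5, min = 21, max = 43),
       partner_age = list(mean = 35.5, sd = 5.5, min = 19, max = 72),
       attempt_probs = c("1" = 0.72, "2" = 0.22, "3" = 0.05, "4-5" = 0.01),
       icsi_prob = 0.5)
}

rtruncnorm_round <- function(n, spec) {
  lo <- stats::pnorm(spec$min - 0.5, spec$mean, spec$sd)
  hi <- stats::pnorm(spec$max + 0.5, spec$mean, spec$sd)
  x <- stats::qnorm(stats::runif(n, lo, hi), spec$mean, spec$sd)
  pmin(pmax(round(x), spec$min), spec$max)
}

# Poisson truncated at ymax by inverse-CDF (embryos cannot exceed oocytes).
rpois_trunc <- function(lambda, ymax) {
  u <- stats::runif(length(lambda)) * stats::ppois(ymax, lambda)
  stats::qpois(pmin(u, stats::ppois(ymax, lambda)), lambda)
}

#' Simulate a synthetic IVF cohort
#'
#' Per cycle: draw baseline covariates; draw the 6-d latent vector from
#' `MVN(0, latent_covariance(theta, eta))`; draw the oocyte count from
#' `Poisson(exp(x b_O + z_O))`; if zero, all downstream fields are
#' undefined.  Otherwise draw the fertilisation count from the offset
#' Poisson, truncated at the oocyte count (the fitted likelihood is
#' untruncated; truncation keeps the data valid and is negligible at
#' realistic rates); if zero, downstream fields are undefined except
#' `transferred = 0`.  Each fertilised embryo receives evenness and
#' fragmentation grades from the cumulative-logit probabilities.  Transfer
#' follows `transferred <=> n_embryos >= 1`, optionally thinned.  For
#' transferred cycles DET and LBE follow the probit sign rules
#' `x b + z >= 0`; DET is forced to 0 when only one embryo exists.
#'
#' @param n_cycles number of cycles.
#' @param params generating [ivf_parameters]; coefficients are applied on
#'   the scale recorded in `params$scaling`.
#' @param covariate_model see [default_covariate_model()].
#' @param specs submodel covariate sets; defaults to the pre-treatment sets.
#' @param mixing_prob probability that a cycle with oocytes proceeds to
#'   mixing (default 1; about 0.966 reproduces the funnel gap seen in
#'   routine data, a transition the model itself does not describe).
#' @param transfer_prob probability that a cycle with embryos proceeds to
#'   transfer (default 1; about 0.90 reproduces the observed gap).
#' @param seed integer; fixed seed gives a bit-reproducible cohort.
#' @return a validated [ivf_cohort].
#' @export
simulate_cohort <- function(n_cycles, params = default_parameters(),
                            covariate_model = default_covariate_model(),
                            specs = ivf_specs("pretreatment"),
                            mixing_prob = 1, transfer_prob = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_cycles >= 0)
  empty <- ivf_cohort(
    cycles = data.frame(cycle_id = character(0), age = numeric(0),
                        partner_age = numeric(0), attempt = character(0),
                        n_oocytes = integer(0), mixed = integer(0),
                        n_embryos = integer(0), transferred = integer(0),
                        det = integer(0), lbe = integer(0)),
    embryos = data.frame(cycle_id = character(0), evenness = integer(0),
                         fragmentation = integer(0), icsi = integer(0)),
    validate = FALSE)
  if (n_cycles == 0L) return(empty)

  cm <- covariate_model
  n <- as.integer(n_cycles)
  cy <- data.frame(
    cycle_id = sprintf("C%06d", seq_len(n)),
    age = rtruncnorm_round(n, cm$age),
    partner_age = rtruncnorm_round(n, cm$partner_age),
    attempt = sample(names(cm$attempt_probs), n, replace = TRUE,
                     prob = cm$attempt_probs),
    n_oocytes = NA_integer_, mixed = NA_integer_, n_embryos = NA_integer_,
    transferred = NA_integer_, det = NA_integer_, lbe = NA_integer_,
    stringsAsFactors = FALSE)
  icsi_cycle <- stats::rbinom(n, 1, cm$icsi_prob)

  Z <- rmvn(n, latent_covariance(params$theta, params$eta))
  colnames(Z) <- OUTCOMES

  # work cohort for design construction (downstream fields filled as we go)
  co <- ivf_cohort(cy, empty$embryos, validate = FALSE)
  X_O <- build_design(specs$O, co, params$scaling)
  cy$n_oocytes <- stats::rpois(n, exp(drop(X_O %*% params$beta_O) + Z[, "O"]))

  cy$mixed <- as.integer(cy$n_oocytes >= 1 &
                           stats::runif(n) < mixing_prob)
  mix <- which(cy$mixed == 1)
  co$cycles <- cy
  if (length(mix)) {
    X_M <- build_design(specs$M, co, params$scaling)[mix, , drop = FALSE]
    lam <- cy$n_oocytes[mix] * exp(drop(X_M %*% params$beta_M) + Z[mix, "M"])
    cy$n_embryos[mix] <- rpois_trunc(lam, cy$n_oocytes[mix])
  }

  # embryo grades: one row per fertilised embryo
  has_emb <- which(cy$mixed == 1 & cy$n_embryos >= 1)
  embryos <- empty$embryos
  if (length(has_emb)) {
    pat <- rep(has_emb, cy$n_embryos[has_emb])
    embryos <- data.frame(cycle_id = cy$cycle_id[pat],
                          evenness = NA_integer_, fragmentation = NA_integer_,
                          icsi = icsi_cycle[pat], stringsAsFactors = FALSE)
    co$cycles <- cy
    co$embryos <- embryos
    for (o in c("E", "F")) {
      Xe <- build_design(specs[[o]], co, params$scaling)
      probs <- ordinal_category_probs(params[[paste0("alpha_", o)]], Xe,
                                      params[[paste0("beta_", o)]], Z[pat, o])
      if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
      cum <- probs %*% upper.tri(diag(4), diag = TRUE)
      grade <- 1L + rowSums(stats::runif(nrow(probs)) > cum[, 1:3, drop = FALSE])
      embryos[[if (o == "E") "evenness" else "fragmentation"]] <- as.integer(grade)
      co$embryos <- embryos
    }
  }

  cy$transferred[mix] <- 0L
  tr <- has_emb[stats::runif(length(has_emb)) < transfer_prob]
  cy$transferred[tr] <- 1L
  if (length(tr)) {
    co$cycles <- cy
    X_D <- build_design(specs$D, co, params$scaling)[tr, , drop = FALSE]
    X_L <- build_design(specs$L, co, params$scaling)[tr, , drop = FALSE]
    det <- as.integer(drop(X_D %*% params$beta_D) + Z[tr, "D"] >= 0)
    det[cy$n_embryos[tr] == 1L] <- 0L  # a single embryo cannot be a double transfer
    cy$det[tr] <- det
    cy$lbe[tr] <- as.integer(drop(X_L %*% params$beta_L) + Z[tr, "L"] >= 0)
  }
  ivf_cohort(cy, embryos, scaling = params$scaling)
}

#' Read a generator configuration from YAML
#'
#' Recognised fields: `n_cycles`, `seed`, `mixing_prob`, `transfer_prob`,
#' `params` (path to a parameter JSON, see [write_parameters()]), and
#' `covariate_model` overrides.
#'
#' @param path YAML file path.
#' @return a list of arguments for [simulate_cohort()].
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(n_cycles = cfg$n_cycles %||% 100,
              seed = cfg$seed,
              mixing_prob = cfg$mixing_prob %||% 1,
              transfer_prob = cfg$transfer_prob %||% 1)
  out$params <- if (!is.null(cfg$params)) read_parameters(cfg$params)
                else default_parameters()
  cm <- default_covariate_model()
  for (nm in names(cfg$covariate_model %||% list())) {
    ov <- cfg$covariate_model[[nm]]
    cm[[nm]] <- if (is.list(cm[[nm]]) && is.list(ov))
      utils::modifyList(cm[[nm]], ov) else unlist(ov)
  }
  out$covariate_model <- cm
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
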