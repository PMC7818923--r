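# Submodel covariate specifications and design-matrix construction.
#
# Pre-treatment specs use only baseline covariates; dynamic specs add the
# observed outcomes of upstream stages (oocyte count, fertilisation rate,
# mean embryo grades, DET) as covariates of downstream submodels.  The stage
# ordering O < M < {E, F} < D < L restricts which outcomes may appear where;
# evenness and fragmentation are coincident and may not predict each other.

BASE_COVARIATES <- c("age", "partner_age", "attempt", "icsi")
DYNAMIC_COVARIATES <- c("n_oocytes", "fert_rate", "mean_evenness",
                        "mean_fragmentation", "det")
ALLOWED_DYNAMIC <- list(
  O = character(0),
  M = "n_oocytes",
  E = c("n_oocytes", "fert_rate"),
  F = c("n_oocytes", "fert_rate"),
  D = c("n_oocytes", "fert_rate", "mean_evenness", "mean_fragmentation"),
  L = c("n_oocytes", "fert_rate", "mean_evenness", "mean_fragmentation", "det"))

#' Define a submodel's covariate set
#'
#' @param outcome one of `"O"`, `"M"`, `"E"`, `"F"`, `"D"`, `"L"`.
#' @param covariates character vector of covariate names; `"attempt"` expands
#'   to dummy columns for the 2nd, 3rd and pooled 4th--5th attempts.  Upstream
#'   outcomes (`"n_oocytes"`, `"fert_rate"`, `"mean_evenness"`,
#'   `"mean_fragmentation"`, `"det"`) are admitted only for temporally
#'   downstream submodels.
#' @return a `submodel_spec` object.  The outcome implies the family:
#'   Poisson (O), offset-Poisson (M), cumulative logit (E, F) or latent
#'   probit (D, L); the count and probit submodels carry an intercept, the
#'   ordinal ones absorb it into their thresholds.
#' @export
submodel_spec <- function(outcome, covariates = character(0)) {
  outcome <- match.arg(outcome, OUTCOMES)
  covariates <- as.character(covariates)
  known <- c(BASE_COVARIATES, DYNAMIC_COVARIATES)
  bad <- setdiff(covariates, known)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  dyn <- intersect(covariates, DYNAMIC_COVARIATES)
  not_upstream <- setdiff(dyn, ALLOWED_DYNAMIC[[outcome]])
  if (length(not_upstream))
    stop(sprintf("covariate(s) %s are not temporally upstream of outcome %s",
                 paste(not_upstream, collapse = ", "), outcome))
  if ("icsi" %in% covariates && !outcome %in% c("E", "F"))
    stop("icsi is an embryo-level covariate, admitted only in the E and F submodels")
  structure(list(outcome = outcome, covariates = covariates,
                 intercept = outcome %in% c("O", "M", "D", "L"),
                 family = switch(outcome, O = "poisson", M = "offset-poisson",
                                 E = , F = "cumulative-logit",
                                 D = , L = "latent-probit")),
            class = "submodel_spec")
}

#' Standard covariate sets for the two prediction settings
#'
#' Pre-treatment: age and partner age in every submodel; attempt number in
#' the oocyte and DET submodels; the fertilisation-method indicator (ICSI) in
#' the two embryo-grade submodels.  Dynamic: additionally the observed
#' number of oocytes and fertilisation rate in all downstream submodels, the
#' mean embryo grades in the DET and LBE submodels, and DET in the LBE
#' submodel.
#'
#' @param setting `"pretreatment"` or `"dynamic"`.
#' @return named list of [submodel_spec()] objects (`O`, `M`, `E`, `F`, `D`, `L`).
#' @export
ivf_specs <- function(setting = c("pretreatment", "dynamic")) {
  setting <- match.arg(setting)
  base <- list(
    O = c("age", "partner_age", "attempt"),
    M = c("age", "partner_age"),
    E = c("age", "partner_age", "icsi"),
    F = c("age", "partner_age", "icsi"),
    D = c("age", "partner_age", "attempt"),
    L = c("age", "partner_age"))
  if (setting == "dynamic") {
    base$E <- c(base$E, "n_oocytes", "fert_rate")
    base$F <- c(base$F, "n_oocytes", "fert_rate")
    base$D <- c(base$D, "n_oocytes", "fert_rate", "mean_evenness",
                "mean_fragmentation")
    base$L <- c(base$L, "n_oocytes", "fert_rate", "mean_evenness",
                "mean_fragmentation", "det")
  }
  specs <- lapply(OUTCOMES, function(o) submodel_spec(o, base[[o]]))
  names(specs) <- OUTCOMES
  structure(specs, setting = setting)
}

# Expanded column names of a spec's design matrix (coefficient names).
spec_terms <- function(spec) {
  out <- character(0)
  if (spec$intercept) out <- "intercept"
  for (v in spec$covariates)
    out <- c(out, if (v == "attempt") c("attempt2", "attempt3", "attempt4_5") else v)
  out
}

# Cycle-level values of every covariate, unscaled.  Dynamic outcome
# covariates are NA for cycles that never produced them.
raw_covariate_table <- function(cohort) {
  cy <- cohort$cycles
  em <- cohort$embryos
  fert_rate <- ifelse(cy$mixed == 1 & cy$n_oocytes > 0,
                      cy$n_embryos / cy$n_oocytes, NA_real_)
  mean_grade <- function(col) {
    f <- factor(em$cycle_id, levels = cy$cycle_id)
    as.numeric(tapply(as.numeric(em[[col]]), f, mean))
  }
  data.frame(cycle_id = cy$cycle_id, age = cy$age, partner_age = cy$partner_age,
             attempt2 = as.numeric(cy$attempt == "2"),
             attempt3 = as.numeric(cy$attempt == "3"),
             attempt4_5 = as.numeric(cy$attempt == "4-5"),
             n_oocytes = as.numeric(cy$n_oocytes),
             fert_rate = fert_rate,
             mean_evenness = mean_grade("evenness"),
             mean_fragmentation = mean_grade("fragmentation"),
             det = as.numeric(cy$det),
             stringsAsFactors = FALSE)
}

SCALED_COVARIATES <- c("age", "partner_age", "n_oocytes", "fert_rate",
                       "mean_evenness", "mean_fragmentation")

# Per-covariate center/scale from the training cohort.  Continuous baseline
# and dynamic-outcome covariates are standardised by the mean and SD of the
# cycles for which they are defined; indicator covariates are left as 0/1.
compute_scaling <- function(cohort, specs) {
  raw <- raw_covariate_table(cohort)
  used <- unique(unlist(lapply(specs, spec_terms)))
  out <- list()
  for (v in intersect(SCALED_COVARIATES, used)) {
    x <- raw[[v]]
    x <- x[!is.na(x)]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    out[[v]] <- c(center = mean(x), scale = s)
  }
  out
}

scale_covariate <- function(x, name, scaling) {
  s <- scaling[[name]]
  if (is.null(s)) x else (x - s[["center"]]) / s[["scale"]]
}

#' Build a submodel design matrix
#'
#' @param spec a [submodel_spec()].
#' @param cohort an [ivf_cohort].
#' @param scaling named list of `c(center, scale)` pairs; covariates with an
#'   entry enter as `(x - center) / scale`.
#' @param rows `"cycle"` for patient-level submodels (one row per cycle) or
#'   `"embryo"` for the grade submodels (one row per gradable embryo, cycle
#'   covariates expanded to the embryo level).
#' @return numeric matrix with one named column per coefficient.
#' @keywords internal
build_design <- function(spec, cohort, scaling = NULL,
                         rows = if (spec$outcome %in% c("E", "F")) "embryo" else "cycle") {
  raw <- raw_covariate_table(cohort)
  if (rows == "embryo") {
    idx <- match(cohort$embryos$cycle_id, raw$cycle_id)
    raw <- raw[idx, , drop = FALSE]
    raw$icsi <- as.numeric(cohort$embryos$icsi)
  }
  terms <- spec_terms(spec)
  X <- matrix(NA_real_, nrow(raw), length(terms),
              dimnames = list(NULL, terms))
  for (v in terms) {
    X[, v] <- if (v == "intercept") 1
    else if (v %in% SCALED_COVARIATES) scale_covariate(raw[[v]], v, scaling)
    else raw[[v]]
  }
  X
}
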