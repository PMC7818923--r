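# Shared fixtures, built in code.

# Three-cycle cohort exercising every stage pattern: a full cycle with
# transfer, a cycle that failed at stimulation, and a cycle with oocytes but
# no embryos.
toy_cohort <- function() {
  cycles <- data.frame(
    cycle_id = c("C1", "C2", "C3"),
    age = c(33, 38, 29),
    partner_age = c(36, 40, 31),
    attempt = c("1", "2", "1"),
    n_oocytes = c(5L, 0L, 7L),
    mixed = c(1L, 0L, 1L),
    n_embryos = c(2L, NA, 0L),
    transferred = c(1L, NA, 0L),
    det = c(1L, NA, NA),
    lbe = c(0L, NA, NA),
    stringsAsFactors = FALSE)
  embryos <- data.frame(
    cycle_id = c("C1", "C1"),
    evenness = c(3L, 4L),
    fragmentation = c(2L, 3L),
    icsi = c(0L, 0L),
    stringsAsFactors = FALSE)
  ivf_cohort(cycles, embryos)
}

# Parameters aligned with a spec's design-matrix terms, all-zero by default,
# with named overrides, e.g. toy_params(beta_O = c(intercept = 2.09)).
toy_params <- function(setting = "pretreatment", theta = c(0.5, 0.3, 0.8, 0.9),
                       eta = rep(0, 15), alpha_E = c(-1, 0, 1),
                       alpha_F = c(-1, 0, 1), scaling = NULL, ...) {
  specs <- ivf_specs(setting)
  ov <- list(...)
  beta <- lapply(c(O = "O", M = "M", E = "E", F = "F", D = "D", L = "L"),
                 function(o) {
                   terms <- ivfjm:::spec_terms(specs[[o]])
                   b <- stats::setNames(rep(0, length(terms)), terms)
                   give <- ov[[paste0("beta_", o)]]
                   b[names(give)] <- give
                   b
                 })
  if (is.null(scaling))
    scaling <- list(age = c(center = 33, scale = 1),
                    partner_age = c(center = 36, scale = 1))
  ivf_parameters(beta_O = beta$O, beta_M = beta$M, beta_E = beta$E,
                 beta_F = beta$F, beta_D = beta$D, beta_L = beta$L,
                 alpha_E = alpha_E, alpha_F = alpha_F, theta = theta,
                 eta = eta, scaling = scaling)
}

# Fabricate an ivf_fit whose posterior is a point mass at `params`
# (standardised scale = the params' own scale), for prediction tests with
# exactly known parameters.
fake_fit <- function(params, setting = "pretreatment", n_rows = 4) {
  specs <- ivf_specs(setting)
  nm <- c()
  vals <- c()
  for (o in ivfjm:::OUTCOMES) {
    if (o %in% c("E", "F")) {
      nm <- c(nm, paste0("alpha_", o, ".", 1:3))
      vals <- c(vals, params[[paste0("alpha_", o)]])
    }
    b <- params[[paste0("beta_", o)]]
    nm <- c(nm, paste0("beta_", o, ".", ivfjm:::spec_terms(specs[[o]])))
    vals <- c(vals, b)
  }
  nm <- c(nm, paste0("theta.", c("O", "M", "E", "F")), paste0("eta.", 1:15))
  vals <- c(vals, params$theta, params$eta)
  chain <- matrix(rep(vals, each = n_rows), n_rows, length(vals),
                  dimnames = list(NULL, nm))
  structure(list(mode = "joint", setting = setting, eta = "free",
                 chains = list(chain, chain), iter = 2 * n_rows,
                 warmup = n_rows, n_chains = 2, specs = specs,
                 priors = build_priors(), scaling = params$scaling,
                 seed = 1, rhat = stats::setNames(rep(1, length(nm)), nm),
                 rhat_threshold = 1.05, converged = TRUE,
                 data_summary = c(n_cycles = 0, n_mixed = 0, n_embryos = 0,
                                  n_transfers = 0)),
            class = "ivf_fit")
}

new_patients <- function(n, age = 33, partner_age = 36, attempt = "1",
                         icsi = 0) {
  data.frame(age = rep_len(age, n), partner_age = rep_len(partner_age, n),
             attempt = rep_len(attempt, n), icsi = rep_len(icsi, n),
             stringsAsFactors = FALSE)
}
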