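# Prior specification.

#' Priors for the joint and separate model fits
#'
#' Weak normal(0, 1000^2) priors on the count and ordinal regression
#' coefficients and thresholds; weakly informative normal(0, 2^2) priors on
#' the probit (DET, LBE) coefficients, whose latent responses have variance
#' fixed at 1; half-Cauchy(0, 2.5) priors on the free latent standard
#' deviations; and an LKJ prior with shape 1 --- uniform over all valid
#' correlation matrices --- on the 6x6 latent correlation matrix.
#'
#' @param beta_sd_count,beta_sd_probit,alpha_sd,theta_scale,lkj_shape
#'   overrides of the defaults above.
#' @return an `ivf_priors` list.
#' @export
build_priors <- function(beta_sd_count = 1000, beta_sd_probit = 2,
                         alpha_sd = 1000, theta_scale = 2.5, lkj_shape = 1) {
  structure(list(
    beta_sd = c(O = beta_sd_count, M = beta_sd_count, E = beta_sd_count,
                F = beta_sd_count, D = beta_sd_probit, L = beta_sd_probit),
    alpha_sd = alpha_sd, theta_scale = theta_scale, lkj_shape = lkj_shape),
    class = "ivf_priors")
}

# log density of the half-Cauchy(0, scale) evaluated at sd > 0
log_half_cauchy <- function(x, scale) {
  log(2) + stats::dcauchy(x, 0, scale, log = TRUE)
}

# LKJ(shape) density of a correlation matrix expressed through the canonical
# partial correlations of a C-vine: the partial correlation at tree level i
# (of d - 1 levels) has an independent scaled Beta(b_i, b_i) distribution on
# (-1, 1) with b_i = shape + (d - 1 - i) / 2.  We sample on the atanh scale;
# including the tanh Jacobian the level-i log density is b_i * log(1 - p^2).
lkj_level_shapes <- function(d = 6, shape = 1) {
  i <- seq_len(d - 1)
  shape + (d - 1 - i) / 2
}

log_lkj_gamma_prior <- function(gamma, shape = 1) {
  b <- lkj_level_shapes(6, shape)[ETA_PAIRS[, 1]]
  p2 <- tanh(gamma)^2
  sum(b * log1p(-p2))
}

# Correlation matrix from canonical partial correlations (vine construction:
# rows of the lower-triangular factor have unit norm).
cor_from_pcor <- function(pc) {
  d <- 6
  zm <- matrix(0, d, d)
  zm[ETA_PAIRS] <- pc
  L <- matrix(0, d, d)
  L[1, 1] <- 1
  for (j in 2:d) {
    rem <- 1
    for (i in seq_len(j - 1)) {
      L[j, i] <- zm[i, j] * rem
      rem <- rem * sqrt(1 - zm[i, j]^2)
    }
    L[j, j] <- rem
  }
  tcrossprod(L)
}
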