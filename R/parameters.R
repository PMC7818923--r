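# Model parameters for the six linked submodels.  Outcome order throughout
# the package is O (oocyte count), M (fertilisation count), E (evenness),
# F (fragmentation), D (double embryo transfer), L (live birth event).

OUTCOMES <- c("O", "M", "E", "F", "D", "L")

# Row-wise upper triangle of the 6x6 latent correlation matrix in outcome
# order, i.e. eta_1 = (O,M), eta_2 = (O,E), ..., eta_15 = (D,L).
ETA_PAIRS <- {
  p <- which(upper.tri(diag(6)), arr.ind = TRUE)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  p
}

#' Construct a full parameter set for the joint model
#'
#' @param beta_O,beta_M,beta_D,beta_L named regression coefficient vectors
#'   (first element the intercept) for the oocyte, fertilisation, double
#'   embryo transfer and live-birth submodels.
#' @param beta_E,beta_F named coefficient vectors (no intercept) for the two
#'   cumulative-logit embryo-grade submodels.
#' @param alpha_E,alpha_F strictly increasing length-3 threshold vectors:
#'   the log-odds of an embryo having grade `k` or lower at covariate zero.
#' @param theta positive standard deviations of the latent variables of the
#'   four non-probit submodels, in order (O, M, E, F).  The probit latents
#'   for DET and LBE have their variances fixed at 1.
#' @param eta length-15 vector of latent correlations: the row-wise upper
#'   triangle of the 6x6 correlation matrix in outcome order O, M, E, F, D,
#'   L (so `eta[1]` is the O--M correlation and `eta[15]` the D--L one).
#' @param scaling named list of `c(center, scale)` per continuous covariate,
#'   defining the scale on which the coefficients apply: each covariate
#'   enters its linear predictor as `(x - center) / scale`.
#' @return an object of class `ivf_parameters`.
#' @seealso [default_parameters()], [latent_covariance()]
#' @export
ivf_parameters <- function(beta_O, beta_M, beta_E, beta_F, beta_D, beta_L,
                           alpha_E, alpha_F, theta, eta = rep(0, 15),
                           scaling = NULL) {
  check_alpha <- function(a, nm) {
    if (length(a) != 3L) stop(nm, " must have length 3")
    if (any(diff(a) <= 0)) stop(nm, " thresholds must be strictly increasing")
    as.numeric(a)
  }
  alpha_E <- check_alpha(alpha_E, "alpha_E")
  alpha_F <- check_alpha(alpha_F, "alpha_F")
  theta <- as.numeric(theta)
  if (length(theta) != 4L || any(theta <= 0))
    stop("theta must be 4 positive standard deviations (O, M, E, F)")
  eta <- as.numeric(eta)
  if (length(eta) != 15L || any(abs(eta) >= 1))
    stop("eta must be 15 correlations in (-1, 1)")
  obj <- structure(list(beta_O = beta_O, beta_M = beta_M, beta_E = beta_E,
                        beta_F = beta_F, beta_D = beta_D, beta_L = beta_L,
                        alpha_E = alpha_E, alpha_F = alpha_F,
                        theta = theta, eta = eta, scaling = scaling),
                   class = "ivf_parameters")
  latent_covariance(theta, eta)  # errors if not positive definite
  obj
}

#' Assemble the latent covariance matrix
#'
#' Builds the 6x6 covariance of the multivariate-normal latent vector
#' `(z_O, z_M, z_E, z_F, z_D, z_L)`: diagonal
#' `(theta_O^2, theta_M^2, theta_E^2, theta_F^2, 1, 1)` with off-diagonal
#' entries `eta_m` scaled by the relevant standard deviations (unit SD for
#' the two probit components).
#'
#' @inheritParams ivf_parameters
#' @return a symmetric positive-definite 6x6 matrix with dimnames
#'   `O, M, E, F, D, L`.  The 15 correlations are not free of joint
#'   constraints: a combination that is not positive definite is an error.
#' @export
latent_covariance <- function(theta, eta = rep(0, 15)) {
  stopifnot(length(theta) == 4L, all(theta > 0), length(eta) == 15L)
  R <- diag(6)
  R[ETA_PAIRS] <- eta
  R[ETA_PAIRS[, 2:1]] <- eta
  sds <- c(theta, 1, 1)
  sigma <- R * outer(sds, sds)
  dimnames(sigma) <- list(OUTCOMES, OUTCOMES)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("latent covariance is not positive definite for the given eta")
  sigma
}

# Extract (theta, eta) back out of a covariance matrix.
covariance_to_theta_eta <- function(sigma) {
  sds <- sqrt(diag(sigma))
  R <- sigma / outer(sds, sds)
  list(theta = sds[1:4], eta = R[ETA_PAIRS])
}

#' Conditional distribution of unobserved latent components
#'
#' Standard multivariate-normal conditioning: given values for a subset of
#' the zero-mean latent vector, returns the mean and covariance of the
#' remaining components.  Used when integrating out the latents of stages a
#' patient never reached and when evaluating probit likelihood contributions
#' given the other latents.
#'
#' @param sigma positive-definite covariance matrix.
#' @param observed_idx indices (or names) of the conditioned components;
#'   must be a strict, non-empty subset.
#' @param observed_vals their values.
#' @return `list(mean, sigma, idx)` for the remaining components.
#' @export
conditional_latent <- function(sigma, observed_idx, observed_vals) {
  d <- nrow(sigma)
  if (is.character(observed_idx)) observed_idx <- match(observed_idx, colnames(sigma))
  observed_idx <- as.integer(observed_idx)
  if (length(observed_idx) == 0L || length(observed_idx) >= d)
    stop("observed_idx must be a non-empty strict subset of the components")
  stopifnot(length(observed_vals) == length(observed_idx))
  rest <- setdiff(seq_len(d), observed_idx)
  S22 <- sigma[observed_idx, observed_idx, drop = FALSE]
  S12 <- sigma[rest, observed_idx, drop = FALSE]
  W <- tryCatch(solve(S22, t(S12)), error = function(e)
    stop("singular conditioning block"))
  mu <- drop(crossprod(W, observed_vals))
  S <- sigma[rest, rest, drop = FALSE] - S12 %*% W
  S <- (S + t(S)) / 2
  list(mean = mu, sigma = S, idx = rest)
}

# Draw n samples from MVN(0, sigma); rows are draws.
rmvn <- function(n, sigma) {
  d <- nrow(sigma)
  matrix(stats::rnorm(n * d), n, d) %*% chol(sigma)
}

#' Default generating parameters for the synthetic cohort
#'
#' Point values for the pre-treatment joint fit to a large routine clinical
#' IVF cohort: oocyte-count intercept 2.10 with age effect -0.04/year,
#' fertilisation intercept -0.95, evenness thresholds (-4.35, -1.38, 1.33),
#' fragmentation thresholds (-5.11, -2.44, -0.33), DET intercept 0.13 and
#' LBE intercept -0.49, among others.  Age and partner-age coefficients are
#' per year of age, centred at 33 and 36 years respectively
#' (`scaling` records this).
#'
#' The latent standard deviations and correlations are NOT estimates from
#' that cohort (which are not publicly available): they are package defaults
#' chosen to give realistic overdispersion --- `theta = (0.5, 0.3, 0.8,
#' 0.9)` and all correlations zero except a DET--LBE correlation of 0.2.
#'
#' @return an [ivf_parameters] object.
#' @export
default_parameters <- function() {
  ivf_parameters(
    beta_O = c(intercept = 2.10, age = -0.04, partner_age = 0.01,
               attempt2 = 0.06, attempt3 = 0.14, attempt4_5 = 0.04),
    beta_M = c(intercept = -0.95, age = 0.02, partner_age = 0.00),
    beta_E = c(age = 0.00, partner_age = 0.01, icsi = -0.27),
    beta_F = c(age = -0.03, partner_age = 0.01, icsi = -0.33),
    beta_D = c(intercept = 0.13, age = 0.02, partner_age = -0.01,
               attempt2 = 0.23, attempt3 = 0.44, attempt4_5 = 0.60),
    beta_L = c(intercept = -0.49, age = -0.02, partner_age = -0.01),
    alpha_E = c(-4.35, -1.38, 1.33),
    alpha_F = c(-5.11, -2.44, -0.33),
    theta = c(0.5, 0.3, 0.8, 0.9),
    eta = c(rep(0, 14), 0.2),
    scaling = list(age = c(center = 33, scale = 1),
                   partner_age = c(center = 36, scale = 1)))
}

#' @export
print.ivf_parameters <- function(x, ...) {
  cat("Joint IVF model parameters\n")
  for (o in OUTCOMES) {
    b <- x[[paste0("beta_", o)]]
    cat(sprintf("  beta_%s: %s\n", o,
                paste(sprintf("%s=%.3g", names(b), b), collapse = ", ")))
  }
  cat(sprintf("  alpha_E: %s\n", paste(sprintf("%.3g", x$alpha_E), collapse = ", ")))
  cat(sprintf("  alpha_F: %s\n", paste(sprintf("%.3g", x$alpha_F), collapse = ", ")))
  cat(sprintf("  theta (O,M,E,F): %s\n", paste(x$theta, collapse = ", ")))
  cat(sprintf("  eta: %d correlations, %d nonzero\n", length(x$eta),
              sum(x$eta != 0)))
  invisible(x)
}

#' Write / read model parameters as JSON
#'
#' Flat JSON with named coefficient vectors; lossless round trip.
#'
#' @param params an [ivf_parameters] object.
#' @param path file path.
#' @return `read_parameters()` returns an [ivf_parameters] object;
#'   `write_parameters()` its input, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ivf_parameters"))
  obj <- unclass(params)
  for (f in paste0("beta_", OUTCOMES))
    obj[[f]] <- as.list(obj[[f]])  # objects, so coefficient names survive
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(params)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaling <- raw$scaling
  if (!is.null(scaling))
    scaling <- lapply(scaling, function(s) {
      s <- unlist(s)
      stats::setNames(as.numeric(s), c("center", "scale"))
    })
  ivf_parameters(beta_O = unlist(raw$beta_O), beta_M = unlist(raw$beta_M),
                 beta_E = unlist(raw$beta_E), beta_F = unlist(raw$beta_F),
                 beta_D = unlist(raw$beta_D), beta_L = unlist(raw$beta_L),
                 alpha_E = unlist(raw$alpha_E), alpha_F = unlist(raw$alpha_F),
                 theta = unlist(raw$theta), eta = unlist(raw$eta),
                 scaling = scaling)
}
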