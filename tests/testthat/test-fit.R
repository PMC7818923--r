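test_that("priors follow the published specification", {
  pr <- build_priors()
  expect_equal(unname(pr$beta_sd["L"]), 2)   # weakly informative probit prior
  expect_equal(unname(pr$beta_sd["D"]), 2)
  expect_equal(unname(pr$beta_sd["O"]), 1000)
  expect_equal(pr$theta_scale, 2.5)          # half-Cauchy scale on latent SDs
  expect_equal(pr$lkj_shape, 1)
  # LKJ(1): constant density over valid correlation matrices, so the prior
  # ratio between any two parameter points is exactly the Jacobian term
  g1 <- rnorm(15, 0, 0.3); g2 <- rnorm(15, 0, 0.3)
  b <- ivfjm:::lkj_level_shapes(6, 1)[ivfjm:::ETA_PAIRS[, 1]]
  expect_equal(ivfjm:::log_lkj_gamma_prior(g1, 1) - ivfjm:::log_lkj_gamma_prior(g2, 1),
               sum(b * log1p(-tanh(g1)^2)) - sum(b * log1p(-tanh(g2)^2)))
})

test_that("split R-hat matches the published formula and flags divergence", {
  set.seed(12)
  chains <- list(rnorm(1000), rnorm(1000))
  r <- rhat(chains)
  expect_gt(r, 0.99); expect_lt(r, 1.01)

  # independent implementation of the split formula
  split_manual <- function(chains) {
    n2 <- length(chains[[1]]) %/% 2
    halves <- unlist(lapply(chains, function(v)
      list(v[1:n2], v[(n2 + 1):(2 * n2)])), recursive = FALSE)
    mu <- sapply(halves, mean); vv <- sapply(halves, var)
    W <- mean(vv); B <- n2 * var(mu)
    sqrt(((n2 - 1) / n2 * W + B / n2) / W)
  }
  expect_equal(r, split_manual(chains), tolerance = 1e-12)

  expect_gt(rhat(list(rnorm(500, 0), rnorm(500, 10))), 1.1)
  expect_warning(rc <- rhat(list(rep(1, 100), rep(1, 100))), "zero-variance")
  expect_true(is.nan(rc))
  expect_error(rhat(list(rnorm(100))), "2 chains")
})

test_that("posterior summaries report medians, central intervals and unit conversion", {
  fit <- fake_fit(toy_params())
  draws <- rnorm(600, 0.5, 0.2)
  fit$chains <- list(matrix(draws[1:300], ncol = 1,
                            dimnames = list(NULL, "beta_O.age")),
                     matrix(draws[301:600], ncol = 1,
                            dimnames = list(NULL, "beta_O.age")))
  fit$rhat <- c(beta_O.age = 1.0)
  fit$scaling <- list(age = c(center = 33, scale = 5))
  s <- summarise_posterior(fit, original_scale = FALSE)
  expect_equal(s$median, median(draws))
  expect_equal(s$lower95, unname(quantile(draws, 0.025)))
  expect_equal(s$upper95, unname(quantile(draws, 0.975)))
  # standardised coefficient -0.20 with SD 5 reports as -0.04 per year
  fit$chains <- lapply(fit$chains, function(m) { m[] <- -0.20; m })
  s <- summarise_posterior(fit, original_scale = TRUE)
  expect_equal(s$median, -0.04)
})

test_that("degenerate cohorts are refused with explicit errors", {
  expect_error(fit_ivf(simulate_cohort(0)), "empty cohort")
  co <- simulate_cohort(80, seed = 8)
  cy <- co$cycles
  cy$lbe[!is.na(cy$lbe)] <- 0L    # constant outcome
  expect_error(fit_ivf(ivf_cohort(cy, co$embryos)), "no variation in the LBE")
})

test_that("the separate probit fit recovers an intercept-only success probability", {
  set.seed(41)
  n <- 2500
  y <- rbinom(n, 1, 0.32)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  d <- ivfjm:::mcmc_probit(y, X, iter = 1500, warmup = 500, beta_sd = 2)
  p_hat <- pnorm(median(d))
  se <- sqrt(0.32 * 0.68 / n)
  expect_lt(abs(p_hat - mean(y)), 3 * se)
  # maximum-likelihood cross-check
  ml <- glm(y ~ 1, family = binomial("probit"))
  expect_lt(abs(median(d) - unname(coef(ml))), 0.05)
})

test_that("the separate Poisson sampler recovers generating coefficients", {
  set.seed(42)
  n <- 1200
  x <- rnorm(n)
  y <- rpois(n, exp(1.5 + 0.3 * x))
  X <- cbind(intercept = 1, x = x)
  d <- ivfjm:::mcmc_pois_ranint(y, X, rep(0, n), iter = 1500, warmup = 500,
                                beta_sd = 1000, theta_scale = 2.5)
  ml <- glm(y ~ x, family = poisson)
  expect_lt(abs(median(d[, 1]) - unname(coef(ml)[1])), 0.06)
  expect_lt(abs(median(d[, 2]) - unname(coef(ml)[2])), 0.06)
})

test_that("the separate ordinal sampler recovers clustered generating values", {
  set.seed(43)
  n_unit <- 300; per <- 5
  unit <- rep(seq_len(n_unit), each = per)
  x <- rnorm(n_unit)[unit]          # unit-constant covariate
  alpha <- c(-1.5, 0, 1.2); beta <- 0.6; theta <- 0.8
  z <- rnorm(n_unit, 0, theta)[unit]
  g <- plogis(outer(alpha, x * beta + z, `-`))
  grades <- 1L + colSums(outer(rep(1, 3), runif(n_unit * per)) > g)
  d <- ivfjm:::mcmc_cumlogit_ranint(grades, cbind(x = x), unit, n_unit,
                                    iter = 1500, warmup = 500,
                                    beta_sd = 1000, alpha_sd = 1000,
                                    theta_scale = 2.5)
  med <- apply(d, 2, median)
  expect_lt(max(abs(med[1:3] - alpha)), 0.3)
  expect_lt(abs(med[4] - beta), 0.25)
  expect_lt(abs(med[5] - theta), 0.25)
})

test_that("the separate grade fit ignores the transfer outcomes entirely", {
  co <- simulate_cohort(80, seed = 13)
  cy <- co$cycles
  tr <- which(!is.na(cy$det))
  cy$det[tr] <- rev(cy$det[tr])   # permute DET among transferred cycles
  cy$det[tr][cy$n_embryos[tr] == 1] <- 0L
  co2 <- ivf_cohort(cy, co$embryos, validate = FALSE)
  f1 <- suppressWarnings(fit_ivf(co, mode = "separate", chains = 2, iter = 300,
                                 seed = 5))
  f2 <- suppressWarnings(fit_ivf(co2, mode = "separate", chains = 2, iter = 300,
                                 seed = 5))
  eF <- grep("^(alpha_E|beta_E|alpha_F|beta_F|theta\\.E|theta\\.F)",
             colnames(f1$chains[[1]]), value = TRUE)
  expect_identical(f1$chains[[1]][, eF], f2$chains[[1]][, eF])
})

test_that("dynamic-setting fits run with upstream outcomes as covariates", {
  co <- simulate_cohort(150, seed = 61)
  fj <- suppressWarnings(fit_ivf(co, setting = "dynamic", mode = "joint",
                                 eta = "zero", chains = 2, iter = 400,
                                 seed = 7))
  fs <- suppressWarnings(fit_ivf(co, setting = "dynamic", mode = "separate",
                                 chains = 2, iter = 400, seed = 8))
  expect_true("beta_L.fert_rate" %in% colnames(fj$chains[[1]]))
  expect_true("beta_D.mean_fragmentation" %in% colnames(fs$chains[[1]]))
  # the precision comparison runs and returns the outcome-covariate table
  tab <- suppressWarnings(check_precision(fj, fs))
  expect_true(all(c("sd_joint", "sd_separate") %in% names(tab)))
  expect_gt(nrow(tab), 5)
})
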