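test_that("failure at stimulation propagates deterministically", {
  params <- toy_params(beta_O = c(intercept = -30))  # rate ~ 0
  fit <- fake_fit(params)
  d <- predict_pretreatment(fit, new_patients(20), n_draws = 200, seed = 1)
  expect_true(all(d$y_O == 0))
  expect_true(all(is.na(d$y_M)))
  expect_true(all(is.na(d$lbe)))
  pi <- predictive_intervals(d, "per_cycle_started")
  expect_equal(pi$p97.5[pi$outcome == "lbe"], rep(0, 20))
  jp <- joint_event_probability(d, function(x) x$lbe == 1)
  expect_equal(jp$estimate, 0)
  expect_equal(jp$lower, jp$upper)
})

test_that("the funnel invariant holds in every draw, in every mode", {
  fit <- fake_fit(default_parameters())
  for (lat in c("zero", "included")) {
    d <- predict_pretreatment(fit, new_patients(40, age = c(25, 42)),
                              n_draws = 400, latents = lat, seed = 2)
    lbe1 <- !is.na(d$lbe) & d$lbe == 1
    expect_true(all(d$transferred[lbe1] == 1))
    tr1 <- !is.na(d$transferred) & d$transferred == 1
    expect_true(all(d$y_M[tr1] >= 1))
    expect_true(all(d$y_O[!is.na(d$y_M)] >= 1))
    # failed stages are never imputed
    expect_true(all(is.na(d$det[is.na(d$transferred) | d$transferred == 0])))
  }
})

test_that("denominator conservation holds exactly on draw counts", {
  fit <- fake_fit(default_parameters())
  d <- predict_pretreatment(fit, new_patients(1), n_draws = 2000, seed = 3)
  n <- attr(d, "n_draws")
  reach <- sum(!is.na(d$lbe))
  events <- sum(d$lbe == 1, na.rm = TRUE)
  p_started <- events / n
  expect_equal(p_started, (reach / n) * (events / reach))
})

test_that("with vanishing latent SDs the chain matches closed-form products", {
  params <- toy_params(beta_O = c(intercept = 2.0),
                       beta_M = c(intercept = -1.0),
                       beta_L = c(intercept = -0.45),
                       theta = rep(1e-9, 4))
  fit <- fake_fit(params)
  nd <- 40000
  d <- predict_pretreatment(fit, new_patients(1), n_draws = nd, seed = 4)
  lamO <- exp(2.0)
  # P(transfer) = sum_k P(y_O = k) P(truncated-Poisson fertilisation >= 1)
  k <- 1:200
  p_k <- dpois(k, lamO)
  lamM <- k * exp(-1.0)
  p_fert <- 1 - dpois(0, lamM) / ppois(k, lamM)  # truncated at y_O
  p_reach <- sum(p_k * p_fert)
  p_lbe <- pnorm(-0.45) * p_reach
  obs <- sum(d$lbe == 1, na.rm = TRUE) / nd
  se <- sqrt(p_lbe * (1 - p_lbe) / nd)
  expect_lt(abs(obs - p_lbe), 3.5 * se)
  obs_reach <- mean(!is.na(d$lbe))
  expect_lt(abs(obs_reach - p_reach), 3.5 * sqrt(p_reach * (1 - p_reach) / nd))
})

test_that("including the latents strictly inflates predictive dispersion", {
  params <- toy_params(beta_O = c(intercept = 2.0), theta = c(0.6, 0.3, 0.8, 0.9))
  fit <- fake_fit(params)
  d0 <- predict_pretreatment(fit, new_patients(1), n_draws = 30000,
                             latents = "zero", seed = 5)
  d1 <- predict_pretreatment(fit, new_patients(1), n_draws = 30000,
                             latents = "included", seed = 6)
  v0 <- var(d0$y_O[, 1]); v1 <- var(d1$y_O[, 1])
  # law of total variance: lambda + lambda^2 (e^{s2} - 1) e^{s2} terms
  lam <- exp(2.0 + 0.36 / 2)
  v_theory0 <- exp(2.0)
  v_theory1 <- lam + lam^2 * (exp(0.36) - 1)
  expect_lt(abs(v0 - v_theory0) / v_theory0, 0.1)
  expect_lt(abs(v1 - v_theory1) / v_theory1, 0.1)
  expect_gt(v1, v0)
})

test_that("predictive intervals follow the exact Poisson quantiles", {
  params <- toy_params(beta_O = c(intercept = 2.09), theta = rep(1e-9, 4))
  fit <- fake_fit(params)
  d <- predict_pretreatment(fit, new_patients(1), n_draws = 10000, seed = 7)
  pi <- predictive_intervals(d)
  row <- pi[pi$outcome == "y_O", ]
  lam <- exp(2.09)
  expect_lte(abs(row$p50 - qpois(0.5, lam)), 1)
  expect_lte(abs(row$p2.5 - qpois(0.025, lam)), 1)
  expect_lte(abs(row$p97.5 - qpois(0.975, lam)), 1)
})

test_that("degenerate draws give degenerate intervals; denominators act downstream only", {
  fit <- fake_fit(default_parameters())
  d <- predict_pretreatment(fit, new_patients(3), n_draws = 300, seed = 8)
  # identical draws: collapse all to one simulated cycle
  for (f in names(d)) d[[f]] <- d[[f]][rep(1, 300), , drop = FALSE]
  attr(d, "n_draws") <- 300
  pi <- predictive_intervals(d)
  expect_true(all(pi$p2.5 == pi$p97.5, na.rm = TRUE))

  # certain birth once transfer is reached, frequent failure before it:
  # the denominators must disagree on LBE but never on the oocyte stage
  p2 <- toy_params(beta_O = c(intercept = 0.1),
                   beta_M = c(intercept = -0.5),
                   beta_L = c(intercept = 30), theta = rep(1e-9, 4))
  fit2 <- fake_fit(p2)
  d2 <- predict_pretreatment(fit2, new_patients(5), n_draws = 500, seed = 9)
  a <- predictive_intervals(d2, "per_cycle_started")
  b <- predictive_intervals(d2, "per_stage_reached")
  expect_identical(a[a$outcome == "y_O", 3:5], b[b$outcome == "y_O", 3:5])
  expect_equal(b$p2.5[b$outcome == "lbe"], rep(1, 5))
  expect_equal(a$p2.5[a$outcome == "lbe"], rep(0, 5))
})

test_that("joint-event probabilities respect bounds and exact CDF checks", {
  params <- toy_params(beta_O = c(intercept = 2.09), theta = rep(1e-9, 4))
  fit <- fake_fit(params)
  d <- predict_pretreatment(fit, new_patients(4), n_draws = 8000, seed = 10)
  jp <- joint_event_probability(d, function(x) x$y_O < 15)
  p_exact <- ppois(14, exp(2.09))
  expect_lt(abs(jp$estimate - p_exact), 3.5 * sqrt(p_exact * (1 - p_exact) / (8000 * 4)))

  fit2 <- fake_fit(default_parameters())
  d2 <- predict_pretreatment(fit2, new_patients(30), n_draws = 600, seed = 11)
  pj <- joint_event_probability(d2, function(x) x$y_O < 15 & x$lbe == 1)
  pa <- joint_event_probability(d2, function(x) x$y_O < 15)
  pb <- joint_event_probability(d2, function(x) x$lbe == 1)
  expect_lte(pj$estimate, min(pa$estimate, pb$estimate))  # Frechet bound
  expect_lte(pj$lower, pj$upper)
})

test_that("pre-treatment prediction refuses downstream covariates and dynamic fits", {
  fit <- fake_fit(default_parameters())
  nd <- new_patients(2); nd$n_oocytes <- c(5, 8)
  expect_error(predict_pretreatment(fit, nd), "pre-treatment covariates only")
  dyn_fit <- fake_fit(default_parameters(), setting = "pretreatment")
  dyn_fit$setting <- "dynamic"
  expect_error(predict_pretreatment(dyn_fit, new_patients(1)), "pretreatment fit")
})

test_that("dynamic prediction conditions on the observed prefix", {
  specs <- ivf_specs("dynamic")
  params <- toy_params("dynamic",
                       beta_O = c(intercept = 2.0),
                       beta_M = c(intercept = -1.0),
                       beta_L = c(intercept = -0.4, fert_rate = 1.5),
                       scaling = list(age = c(center = 33, scale = 1),
                                      partner_age = c(center = 36, scale = 1),
                                      n_oocytes = c(center = 9, scale = 5),
                                      fert_rate = c(center = 0.4, scale = 0.2),
                                      mean_evenness = c(center = 3, scale = 0.7),
                                      mean_fragmentation = c(center = 3, scale = 0.7)))
  fit <- fake_fit(params, setting = "dynamic")

  # observed zero oocytes: everything downstream deterministically fails
  d0 <- predict_dynamic(fit, new_patients(2), list(n_oocytes = 0),
                        n_draws = 50, seed = 12)
  expect_true(all(is.na(d0$y_M)))
  expect_true(all(is.na(d0$lbe)))

  # prefix gap is an error
  expect_error(predict_dynamic(fit, new_patients(1),
                               list(n_embryos = 3), n_draws = 10),
               "prefix")
  expect_error(predict_dynamic(fit, new_patients(1),
                               list(n_oocytes = 9, det = 1), n_draws = 10),
               "prefix")

  # LBE probability is monotone in the observed fertilisation rate, in the
  # direction of the (positive) coefficient
  dlo <- predict_dynamic(fit, new_patients(1),
                         list(n_oocytes = 10, n_embryos = 2,
                              mean_evenness = 3, mean_fragmentation = 3, det = 1),
                         n_draws = 4000, seed = 13)
  dhi <- predict_dynamic(fit, new_patients(1),
                         list(n_oocytes = 10, n_embryos = 9,
                              mean_evenness = 3, mean_fragmentation = 3, det = 1),
                         n_draws = 4000, seed = 14)
  expect_gt(mean(dhi$lbe[, 1] == 1, na.rm = TRUE),
            mean(dlo$lbe[, 1] == 1, na.rm = TRUE))

  # a complete observed cycle reproduces itself with zero predictive variance
  dfull <- predict_dynamic(fit, new_patients(1),
                           list(n_oocytes = 10, n_embryos = 4,
                                mean_evenness = 3.2, mean_fragmentation = 2.8,
                                det = 1, lbe = 1), n_draws = 100, seed = 15)
  expect_true(all(dfull$y_O == 10))
  expect_true(all(dfull$y_M == 4))
  expect_true(all(dfull$det == 1))
  expect_true(all(dfull$lbe == 1))
  expect_equal(var(dfull$lbe[, 1]), 0)
})
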