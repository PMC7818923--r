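test_that("RMSE: identity, hand arithmetic and missing-pair handling", {
  expect_equal(rmse(c(3, 5, 8), c(3, 5, 8)), 0)
  expect_equal(rmse(c(1, 1), c(1, 3)), sqrt(2))
  expect_equal(rmse(c(1, NA, 2), c(1, 5, NA)), 0)  # only the defined pair
  expect_error(rmse(c(NA, NA), c(1, 2)), "no defined")
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("RMSE approaches the generative residual scale with growing n", {
  set.seed(21)
  lam <- 8
  y <- rpois(5e4, lam)
  pred <- rep(qpois(0.5, lam), length(y))
  r <- rmse(pred, y)
  # oracle: E[(Y - 8)^2] = Var + bias^2 = 8 exactly at the median point 8
  expect_equal(r, sqrt(lam), tolerance = 0.02)
})

test_that("Brier score: perfect, constant and closed-form cases", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 7), c(1, 0, 0, 1, 1, 0, 1)), 0.25)
  set.seed(22)
  y <- rbinom(4000, 1, 0.3)
  p <- 0.6
  pi_hat <- mean(y)
  expect_equal(brier(rep(p, 4000), y),
               p^2 * (1 - pi_hat) + (1 - p)^2 * pi_hat, tolerance = 1e-12)
  expect_error(brier(numeric(0), numeric(0)), "empty")
  expect_error(brier(c(1.4), c(1)), "\\[0, 1\\]")
})

test_that("AUC: separation, concordant pairs, midranks and the DeLong interval", {
  a <- auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(a$auc, 1)
  a <- auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(a$auc, 1)
  expect_error(auc(c(0.2, 0.3), c(1, 1)), "both outcome classes")

  # independent Mann-Whitney midrank oracle
  mw_auc <- function(p, y) {
    r <- rank(p)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  set.seed(23)
  for (i in 1:5) {
    p <- round(runif(60), 1)  # ties on purpose
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(p, y)$auc, mw_auc(p, y), tolerance = 1e-12)
  }

  a <- auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
  expect_lte(a$lower, a$auc); expect_gte(a$upper, a$auc)
})

test_that("uninformative scores give AUC near one half (permutation null)", {
  set.seed(24)
  n <- 3000
  y <- rbinom(n, 1, 0.4)
  p <- runif(n)
  null_sd <- sqrt((n + 1) / (12 * sum(y == 1) * sum(y == 0)))
  expect_lt(abs(auc(p, y)$auc - 0.5), 3.5 * null_sd)
})

test_that("metric evaluation is invariant to cycle order", {
  co <- simulate_cohort(150, seed = 25)
  fit <- fake_fit(default_parameters())
  nd <- co$cycles[c("cycle_id", "age", "partner_age", "attempt")]
  nd$icsi <- 0
  d <- predict_pretreatment(fit, nd, n_draws = 400, seed = 26)
  m1 <- evaluate_predictions(d, co)

  perm <- sample(nrow(co$cycles))
  co2 <- ivf_cohort(co$cycles[perm, ], co$embryos, validate = FALSE)
  d2 <- d
  for (f in c("y_O", "y_M", "transferred", "det", "lbe", "evenness",
              "fragmentation", "mean_evenness", "mean_fragmentation"))
    d2[[f]] <- d[[f]][, perm, drop = FALSE]
  attr(d2, "patients") <- attr(d, "patients")[perm]
  m2 <- evaluate_predictions(d2, co2)
  for (k in c("rmse_oocytes", "rmse_embryos", "rmse_evenness",
              "rmse_fragmentation", "brier_det", "brier_lbe"))
    expect_equal(m1[[k]], m2[[k]], info = k)
  expect_equal(m1$auc_lbe$auc, m2$auc_lbe$auc)
  expect_identical(m1$denominator_binary, "per_transfer")
})

test_that("calibration data join predictions with observations", {
  co <- simulate_cohort(100, seed = 27)
  fit <- fake_fit(default_parameters())
  nd <- co$cycles[c("cycle_id", "age", "partner_age", "attempt")]
  nd$icsi <- 0
  d <- predict_pretreatment(fit, nd, n_draws = 300, seed = 28)
  cal <- calibration_data(d, co)
  expect_setequal(unique(cal$outcome),
                  c("y_O", "y_M", "evenness", "fragmentation", "det", "lbe"))
  yo <- cal[cal$outcome == "y_O", ]
  expect_equal(yo$observed, co$cycles$n_oocytes)
  expect_true(all(cal$in_sample))

  # observations equal to the medians sit exactly on the centre line
  cal2 <- cal[cal$outcome == "y_O", ]
  cal2$observed <- cal2$p50
  expect_equal(cal2$observed - cal2$p50, rep(0, nrow(cal2)))

  # disjoint cycle sets cannot be joined
  attr(d, "patients") <- paste0("X", seq_len(ncol(d$y_O)))
  expect_error(calibration_data(d, co), "no cycles in common")
})

test_that("the calibration plot renders to a file device", {
  co <- simulate_cohort(60, seed = 29)
  fit <- fake_fit(default_parameters())
  nd <- co$cycles[c("cycle_id", "age", "partner_age", "attempt")]
  nd$icsi <- 0
  d <- predict_pretreatment(fit, nd, n_draws = 200, seed = 30)
  cal <- calibration_data(d, co)
  f <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_silent(plot_calibration(cal))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
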