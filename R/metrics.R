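# Performance metrics and calibration machinery.

#' Root mean squared error
#'
#' @param predicted point predictions (for the count and grade outcomes the
#'   posterior-predictive median by convention, switchable to the mean at the
#'   evaluation level); ordinal grades are treated as equally spaced
#'   integers 1--4.
#' @param observed outcomes aligned with `predicted`; pairs with a missing
#'   value (stage not reached) are dropped.
#' @return non-negative scalar.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  ok <- !is.na(predicted) & !is.na(observed)
  if (!any(ok)) stop("no defined prediction/observation pairs")
  sqrt(mean((predicted[ok] - observed[ok])^2))
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes.
#'
#' @param predicted_prob probabilities in `[0, 1]`.
#' @param observed 0/1 outcomes.
#' @return value in `[0, 1]`.
#' @export
brier <- function(predicted_prob, observed) {
  if (!length(predicted_prob)) stop("empty input")
  if (length(predicted_prob) != length(observed))
    stop("predicted and observed must have equal length")
  if (any(predicted_prob < 0 | predicted_prob > 1, na.rm = TRUE))
    stop("probabilities must be in [0, 1]")
  ok <- !is.na(predicted_prob) & !is.na(observed)
  if (!any(ok)) stop("no defined prediction/observation pairs")
  mean((predicted_prob[ok] - observed[ok])^2)
}

#' Area under the ROC curve with a DeLong 95% confidence interval
#'
#' Rank-based (Mann--Whitney) AUC with midrank tie handling; the interval is
#' computed by the DeLong method.
#'
#' @inheritParams brier
#' @return list with `auc`, `lower`, `upper`.
#' @export
auc <- function(predicted_prob, observed) {
  ok <- !is.na(predicted_prob) & !is.na(observed)
  predicted_prob <- predicted_prob[ok]; observed <- observed[ok]
  if (length(unique(observed)) < 2L)
    stop("AUC requires both outcome classes to be present")
  r <- pROC::roc(observed, predicted_prob, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), lower = as.numeric(ci[1]),
       upper = as.numeric(ci[3]))
}

# per-cycle point predictions and event probabilities from predictive draws
.point_predictions <- function(draws, point = c("median", "mean")) {
  point <- match.arg(point)
  fun <- if (point == "median") function(v) stats::median(v, na.rm = TRUE)
  else function(v) mean(v, na.rm = TRUE)
  safe <- function(m) apply(m, 2, function(v) if (all(is.na(v))) NA_real_ else fun(v))
  prob_given_transfer <- function(m) {
    apply(rbind(m, draws$transferred), 2, function(v) {
      n <- length(v) / 2
      x <- v[seq_len(n)]; tr <- v[n + seq_len(n)]
      x <- x[!is.na(tr) & tr == 1]
      if (!length(x)) NA_real_ else mean(x, na.rm = TRUE)
    })
  }
  list(y_O = safe(draws$y_O),
       y_M = safe(draws$y_M),
       evenness = safe(draws$evenness),
       fragmentation = safe(draws$fragmentation),
       p_det = prob_given_transfer(draws$det),
       p_lbe = prob_given_transfer(draws$lbe))
}

#' Evaluate sequential predictions against an observed cohort
#'
#' RMSE for the oocyte count, fertilisation count and the two embryo grade
#' scales (grades compared per embryo against the predicted median grade of
#' its cycle), and Brier score plus AUC (with DeLong 95% CI) for DET and
#' LBE.  Following the submodels' fitting population, the binary metrics are
#' computed only over cycles that reached the transfer stage, with predicted
#' probabilities conditional on reaching it; the report records that
#' denominator.
#'
#' @param draws an `ivf_draws` for exactly the cohort's cycles (same order).
#' @param cohort the observed [ivf_cohort].
#' @param point point predictor for RMSE: posterior-predictive `"median"`
#'   (default) or `"mean"`.
#' @param in_sample set to `TRUE` when the predictions were produced by a
#'   model fitted on this same cohort; recorded in the report (in-sample
#'   agreement does not constitute validation).
#' @return an `ivf_metrics` list.
#' @export
evaluate_predictions <- function(draws, cohort, point = "median",
                                 in_sample = TRUE) {
  stopifnot(inherits(draws, "ivf_draws"), inherits(cohort, "ivf_cohort"))
  cy <- cohort$cycles
  if (ncol(draws$y_O) != nrow(cy))
    stop("draws and cohort have different numbers of cycles")
  pp <- .point_predictions(draws, point)

  mix <- cy$mixed == 1
  out <- list(
    rmse_oocytes = rmse(pp$y_O, cy$n_oocytes),
    rmse_embryos = rmse(pp$y_M[mix], cy$n_embryos[mix]))

  epat <- match(cohort$embryos$cycle_id, cy$cycle_id)
  out$rmse_evenness <- rmse(pp$evenness[epat], cohort$embryos$evenness)
  out$rmse_fragmentation <- rmse(pp$fragmentation[epat], cohort$embryos$fragmentation)

  tr <- !is.na(cy$transferred) & cy$transferred == 1
  out$brier_det <- brier(pp$p_det[tr], cy$det[tr])
  out$brier_lbe <- brier(pp$p_lbe[tr], cy$lbe[tr])
  out$auc_det <- auc(pp$p_det[tr], cy$det[tr])
  out$auc_lbe <- auc(pp$p_lbe[tr], cy$lbe[tr])

  structure(c(out, list(
    n = nrow(cy), n_transfers = sum(tr), point = point,
    denominator_binary = "per_transfer", in_sample = in_sample,
    mode = attr(draws, "mode"), setting = attr(draws, "setting"))),
    class = "ivf_metrics")
}

#' @export
print.ivf_metrics <- function(x, ...) {
  cat(sprintf("Performance metrics (%s %s model; n = %d, %d transfers; %s)\n",
              x$setting, x$mode, x$n, x$n_transfers,
              if (isTRUE(x$in_sample)) "IN-SAMPLE, not a validation" else "external data"))
  cat(sprintf("  Number of oocytes (RMSE)      %.2f\n", x$rmse_oocytes))
  cat(sprintf("  Fertilisation count (RMSE)    %.2f\n", x$rmse_embryos))
  cat(sprintf("  Embryo evenness (RMSE)        %.2f\n", x$rmse_evenness))
  cat(sprintf("  Embryo fragmentation (RMSE)   %.2f\n", x$rmse_fragmentation))
  cat(sprintf("  DET (Brier)                   %.2f\n", x$brier_det))
  cat(sprintf("  DET (AUC, 95%% CI)             %.2f, %.2f to %.2f\n",
              x$auc_det$auc, x$auc_det$lower, x$auc_det$upper))
  cat(sprintf("  LBE (Brier)                   %.2f\n", x$brier_lbe))
  cat(sprintf("  LBE (AUC, 95%% CI)             %.2f, %.2f to %.2f\n",
              x$auc_lbe$auc, x$auc_lbe$lower, x$auc_lbe$upper))
  cat(sprintf("  [binary metrics %s]\n", x$denominator_binary))
  invisible(x)
}

#' Calibration-plot data
#'
#' Per cycle, the 2.5/50/97.5 posterior-predictive percentiles of each
#' outcome joined with the observed stage response, in the layout needed for
#' interval-versus-observed calibration plots.
#'
#' @param draws an `ivf_draws` for the cohort's cycles.
#' @param cohort the observed [ivf_cohort].
#' @param denominator passed to [predictive_intervals()].
#' @param in_sample flag recorded on the output; in-sample curves do not
#'   constitute validation.
#' @return data frame `patient, outcome, p2.5, p50, p97.5, observed,
#'   in_sample`.
#' @export
calibration_data <- function(draws, cohort,
                             denominator = "per_cycle_started",
                             in_sample = TRUE) {
  stopifnot(inherits(draws, "ivf_draws"), inherits(cohort, "ivf_cohort"))
  pi_tab <- predictive_intervals(draws, denominator)
  cy <- cohort$cycles
  ids <- attr(draws, "patients")
  if (!any(ids %in% cy$cycle_id))
    stop("no cycles in common between predictions and observations")
  obs_of <- function(outcome) {
    j <- match(ids, cy$cycle_id)
    switch(outcome,
           y_O = cy$n_oocytes[j],
           y_M = if (denominator == "per_cycle_started")
             ifelse(cy$mixed[j] == 1, cy$n_embryos[j], 0) else cy$n_embryos[j],
           evenness = {
             mg <- raw_covariate_table(cohort)$mean_evenness
             mg[j]
           },
           fragmentation = {
             mg <- raw_covariate_table(cohort)$mean_fragmentation
             mg[j]
           },
           det = if (denominator == "per_cycle_started")
             ifelse(is.na(cy$det[j]), 0, cy$det[j]) else cy$det[j],
           lbe = if (denominator == "per_cycle_started")
             ifelse(is.na(cy$lbe[j]), 0, cy$lbe[j]) else cy$lbe[j])
  }
  pi_tab$observed <- NA_real_
  for (o in unique(pi_tab$outcome))
    pi_tab$observed[pi_tab$outcome == o] <- obs_of(o)
  pi_tab$in_sample <- in_sample
  pi_tab
}

#' Minimal calibration plot
#'
#' Observed responses over the predictive median and 95% interval, one panel
#' per outcome, cycles sorted by predictive median.
#'
#' @param caldata output of [calibration_data()].
#' @param outcomes which outcomes to draw.
#' @return invisibly `caldata`.
#' @export
plot_calibration <- function(caldata, outcomes = c("y_O", "y_M")) {
  old <- graphics::par(mfrow = c(1, length(outcomes)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (o in outcomes) {
    d <- caldata[caldata$outcome == o & !is.na(caldata$observed), ]
    d <- d[order(d$p50, d$observed), ]
    n <- nrow(d)
    graphics::plot(seq_len(n), d$observed, pch = 16, cex = 0.4,
                   col = "grey40", xlab = "cycle (sorted by predictive median)",
                   ylab = o, main = o,
                   ylim = range(c(d$observed, d$p2.5, d$p97.5), na.rm = TRUE))
    graphics::polygon(c(seq_len(n), rev(seq_len(n))), c(d$p2.5, rev(d$p97.5)),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    graphics::lines(seq_len(n), d$p50, col = "steelblue", lwd = 2)
  }
  invisible(caldata)
}
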