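## Top-level modelling interface: one fitting function running the whole
## pipeline and returning a classed object with the usual methods.

#' Fit the persistent-AKI-stage-3 risk model on a cohort
#'
#' Runs the full pipeline: unit standardization, plausibility filtering,
#' hourly resampling, baseline creatinine, hourly KDIGO staging, endpoint
#' adjudication with the exclusion cascade, per-hour sample labeling,
#' rolling-window feature construction, a patient-grouped class-stratified
#' 70/30 stay split, gradient-boosted-tree training, per-stay MAX-metric
#' scoring of the validation stays, and calibration of the operating
#' threshold to the target sensitivity on the validation (calibration)
#' cohort. The calibrated cutoff is part of the fitted object and is never
#' recalibrated when the model is applied to new cohorts.
#'
#' @param events long-format event table (`stay_id`, `time`, `variable`,
#'   `value`, `unit`).
#' @param statics per-stay static table.
#' @param specs variable specification table, see [variable_specs()].
#' @param fspec feature specification, see [feature_spec()].
#' @param config model configuration, see [model_config()].
#' @param n_boot bootstrap resamples for ROC/PR intervals.
#' @return An object of class `paki3`: the fitted booster, the calibrated
#'   `cutoff`, cohort `labels` and `exclusions`, the `split`, validation
#'   `evaluation` (per-stay), and `metrics` (auROC/auPR with intervals,
#'   confusion rates, standardized PPV at 10% prevalence, lead times,
#'   fairness audit).
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_stays = 150, seed = 42))
#' fit <- paki3(cohort$events, cohort$statics,
#'              config = model_config(nrounds = 50))
#' print(fit)
#' }
paki3 <- function(events, statics, specs = variable_specs(),
                  fspec = feature_spec(), config = model_config(),
                  n_boot = 1000) {
  events <- standardize_units(events, specs)
  filt <- plausibility_filter(events, specs)
  events <- filt$events
  hm <- resample_hourly(events, statics, specs)
  adj <- adjudicate_cohort(hm, events, statics, use_rise = config$use_rise)
  samples <- label_samples(adj$stages, adj$labels, window = config$label_window)
  feats <- build_features(hm, events, statics, samples, fspec)
  split <- split_cohort(adj$labels, statics,
                        train_fraction = config$train_fraction,
                        seed = config$seed)
  in_train <- feats$index$stay_id %in% split$train
  ftrain <- structure(list(x = feats$x[in_train, , drop = FALSE],
                           index = feats$index[in_train, , drop = FALSE],
                           spec = fspec), class = "paki3_features")
  fval <- structure(list(x = feats$x[!in_train, , drop = FALSE],
                         index = feats$index[!in_train, , drop = FALSE],
                         spec = fspec), class = "paki3_features")
  model <- train_risk_model(ftrain, config)
  risk_val <- predict_risk(model, fval)
  val_labels <- adj$labels[adj$labels$stay_id %in% split$validation, , drop = FALSE]
  ## per-stay maxima for calibration
  ev0 <- max_metric(risk_val, val_labels, cutoff = Inf)
  cutoff <- calibrate_threshold(ev0$max_score, ev0$truth,
                                target = config$target_sensitivity)
  evaluation <- max_metric(risk_val, val_labels, cutoff)
  metrics <- evaluate_stays(evaluation, statics, n_boot = n_boot,
                            seed = config$seed)
  structure(list(model = model, cutoff = cutoff, specs = specs,
                 fspec = fspec, config = config,
                 baselines = adj$baselines, labels = adj$labels,
                 exclusions = adj$exclusions, split = split,
                 risk = risk_val, evaluation = evaluation,
                 metrics = metrics, rejected = filt$rejected),
            class = "paki3")
}

#' Summarize a per-stay evaluation into the headline metrics
#'
#' @param evaluation a `stay_evaluation`, see [max_metric()].
#' @param statics static table (for the fairness audit; optional).
#' @param prevalence reference prevalence for standardized PPV
#'   (default 0.10).
#' @param n_boot,seed bootstrap settings for [roc_pr()].
#' @return list `auroc`, `aupr` (+ intervals), `rates` (confusion rates),
#'   `ppv_std` (PPV at `prevalence`), `lead_time_median`, `lead_times`,
#'   `fairness` (AOD table, when `statics` given).
#' @export
evaluate_stays <- function(evaluation, statics = NULL, prevalence = 0.10,
                           n_boot = 1000, seed = 1) {
  rp <- roc_pr(evaluation, n_boot = n_boot, seed = seed)
  rates <- confusion_rates(evaluation)
  ppv_std <- standardized_ppv(rates$sensitivity, rates$specificity, prevalence)
  lt <- evaluation$lead_time[!is.na(evaluation$lead_time)]
  out <- list(auroc = rp$auroc, auroc_ci = rp$auroc_ci,
              aupr = rp$aupr, aupr_ci = rp$aupr_ci, roc = rp$roc,
              rates = rates, ppv_std = ppv_std, ppv_std_prevalence = prevalence,
              lead_time_median = if (length(lt)) median(lt) else NA_real_,
              lead_times = lt)
  if (!is.null(statics)) out$fairness <- fairness_audit(evaluation, statics)
  out
}

#' @export
print.paki3 <- function(x, ...) {
  m <- x$metrics
  cat("Persistent AKI stage 3 risk model (gradient boosted trees)\n")
  cat(sprintf("  included stays: %d (train %d / validation %d); excluded: %d\n",
              nrow(x$labels), length(x$split$train),
              length(x$split$validation), nrow(x$exclusions)))
  tab <- table(factor(x$labels$class, levels = PAKI3_CLASSES))
  cat("  endpoint classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  calibrated cutoff: %.4f (target sensitivity %.0f%%)\n",
              x$cutoff, 100 * x$config$target_sensitivity))
  ci <- function(v) if (is.null(v)) "" else sprintf(" [%.3f, %.3f]", v[1], v[2])
  cat(sprintf("  validation auROC: %.3f%s, auPR: %.3f%s\n",
              m$auroc, ci(m$auroc_ci), m$aupr, ci(m$aupr_ci)))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, PPV %.3f, NPV %.3f\n",
              m$rates$sensitivity, m$rates$specificity,
              m$rates$ppv, m$rates$npv))
  cat(sprintf("  PPV at %.0f%% prevalence: %.3f; median lead time: %s h\n",
              100 * m$ppv_std_prevalence, m$ppv_std,
              format(m$lead_time_median)))
  invisible(x)
}

#' @export
summary.paki3 <- function(object, ...) {
  structure(list(metrics = object$metrics, cutoff = object$cutoff,
                 exclusions = table(object$exclusions$rule),
                 classes = table(object$labels$class),
                 importance = head(object$model$importance, 20)),
            class = "summary.paki3")
}

#' @export
print.summary.paki3 <- function(x, ...) {
  cat("Exclusions:\n"); print(x$exclusions)
  cat("\nEndpoint classes (included stays):\n"); print(x$classes)
  cat(sprintf("\nCalibrated cutoff: %.4f\n", x$cutoff))
  r <- x$metrics$rates
  cat(sprintf("auROC %.3f  auPR %.3f  sens %.3f  spec %.3f  F1 %.3f\n",
              x$metrics$auroc, x$metrics$aupr, r$sensitivity, r$specificity,
              r$f1))
  if (!is.null(x$metrics$fairness) && nrow(x$metrics$fairness)) {
    cat("\nFairness audit (Average Odds Difference; |AOD| <= 0.1 fair):\n")
    print(x$metrics$fairness, row.names = FALSE)
  }
  cat("\nTop feature importances (gain):\n")
  print(head(x$importance, 10), row.names = FALSE)
  invisible(x)
}

#' Feature importances of a fitted model
#' @param object a `paki3` fit.
#' @param ... unused.
#' @return data.frame of xgboost gain importances (features with non-null
#'   importance only).
#' @export
coef.paki3 <- function(object, ...) object$model$importance

#' Apply a fitted model to a new cohort
#'
#' Runs the data pipeline on the new cohort and scores it at the fitted,
#' frozen cutoff (no recalibration on unseen populations).
#'
#' @param object a `paki3` fit.
#' @param events,statics the new cohort.
#' @param n_boot bootstrap resamples for the metric intervals.
#' @param ... unused.
#' @return list `risk` (per-sample scores), `labels`, `exclusions`,
#'   `evaluation` (per-stay), `metrics`.
#' @export
predict.paki3 <- function(object, events, statics, n_boot = 1000, ...) {
  events <- standardize_units(events, object$specs)
  events <- plausibility_filter(events, object$specs)$events
  hm <- resample_hourly(events, statics, object$specs)
  adj <- adjudicate_cohort(hm, events, statics,
                           use_rise = object$config$use_rise)
  samples <- label_samples(adj$stages, adj$labels,
                           window = object$config$label_window)
  feats <- build_features(hm, events, statics, samples, object$fspec)
  risk <- predict_risk(object$model, feats)
  evaluation <- max_metric(risk, adj$labels, object$cutoff)
  metrics <- evaluate_stays(evaluation, statics, n_boot = n_boot,
                            seed = object$config$seed)
  list(risk = risk, labels = adj$labels, exclusions = adj$exclusions,
       evaluation = evaluation, metrics = metrics)
}

#' Plot ROC and precision-recall curves of a fitted model
#'
#' @param x a `paki3` fit.
#' @param ... unused.
#' @export
plot.paki3 <- function(x, ...) {
  ev <- x$evaluation
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  p <- x$metrics$roc
  plot(p$fpr, p$tpr, type = "l", xlab = "1 - specificity",
       ylab = "sensitivity",
       main = sprintf("ROC (auROC %.3f)", x$metrics$auroc))
  abline(0, 1, lty = 2)
  s <- ev$max_score; y <- ev$truth
  o <- order(s, decreasing = TRUE)
  tp <- cumsum(y[o]); fp <- cumsum(!y[o])
  rec <- tp / sum(y); prec <- tp / (tp + fp)
  plot(rec, prec, type = "s", xlab = "recall (sensitivity)",
       ylab = "precision (PPV)", ylim = c(0, 1),
       main = sprintf("PR (auPR %.3f)", x$metrics$aupr))
  abline(h = mean(y), lty = 2)
  invisible(x)
}

#' Simulate a cohort from a fitted model's study design
#'
#' Draws new synthetic cohorts with the generator; a convenience wrapper so
#' `simulate()` works on fits the way it does for classical models.
#'
#' @param object a `paki3` fit.
#' @param nsim number of cohorts.
#' @param seed base seed (incremented per cohort).
#' @param config generator configuration, see [sim_config()].
#' @param ... unused.
#' @return A list of `generated_cohort` objects (length `nsim`).
#' @export
simulate.paki3 <- function(object, nsim = 1, seed = 1,
                           config = sim_config(), ...) {
  lapply(seq_len(nsim), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i - 1)
    simulate_cohort(cfg)
  })
}
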