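## Gradient-boosted-tree risk scorer: stay-level split, training with L1
## regularization and class re-weighting, prediction, and calibration of
## the operating threshold to a target per-stay sensitivity.

#' Model configuration
#'
#' Defaults: 500 trees of depth 6, learning rate 0.05, strong L1 penalty
#' (`alpha = 5`), positive-class weight set to the negative/positive sample
#' ratio, histogram tree construction on a single thread (deterministic
#' given the seed).
#'
#' @param nrounds,max_depth,eta,alpha,lambda boosting hyperparameters.
#' @param scale_pos_weight positive-class weight; `NULL` means neg/pos of
#'   the training samples.
#' @param train_fraction stay-level training fraction of the 70/30 split.
#' @param target_sensitivity per-stay sensitivity the cutoff is calibrated
#'   to.
#' @param label_window hours before Tp labeled positive, see
#'   [label_samples()].
#' @param use_rise see [stage_scr()].
#' @param nthread xgboost threads.
#' @param seed integer seed driving the split and the learner.
#' @return A list of class `model_config`.
#' @export
model_config <- function(nrounds = 500, max_depth = 6, eta = 0.05,
                         alpha = 5, lambda = 1, scale_pos_weight = NULL,
                         train_fraction = 0.7, target_sensitivity = 0.8,
                         label_window = 48, use_rise = TRUE,
                         nthread = 1, seed = 1) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must lie in (0, 1)")
  }
  structure(list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                 alpha = alpha, lambda = lambda,
                 scale_pos_weight = scale_pos_weight,
                 train_fraction = train_fraction,
                 target_sensitivity = target_sensitivity,
                 label_window = label_window, use_rise = use_rise,
                 nthread = nthread, seed = seed),
            class = "model_config")
}

#' Stay-level, patient-grouped, class-stratified split
#'
#' All stays of a patient land in the same partition; patients are
#' stratified by their most severe endpoint class. Classes with fewer than
#' two patients are merged into the persistent stratum with a warning.
#'
#' @param labels data.frame `stay_id`, `class` for included stays.
#' @param statics per-stay static table (for `patient_id`).
#' @param train_fraction fraction of stays in the training partition.
#' @param seed RNG seed.
#' @return A list `train`, `validation` of stay ids.
#' @export
split_cohort <- function(labels, statics, train_fraction = 0.7, seed = 1) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must lie in (0, 1)")
  }
  pid <- setNames(statics$patient_id, statics$stay_id)[labels$stay_id]
  sev <- factor(labels$class, levels = PAKI3_CLASSES)
  ## patient stratum: most severe class among the patient's stays
  pat <- tapply(as.integer(sev), pid, max)
  strata <- PAKI3_CLASSES[pat]
  small <- names(which(table(strata) < 2))
  small <- setdiff(small, "transient")
  if (length(small)) {
    warning(sprintf("class(es) with < 2 patients merged for stratification: %s",
                    paste(small, collapse = ", ")))
    strata[strata %in% small] <- "persistent"
  }
  train_pat <- character()
  with_seed(seed, {
    for (s in unique(strata)) {
      p <- names(pat)[strata == s]
      n_tr <- round(train_fraction * length(p))
      n_tr <- max(min(n_tr, length(p)), if (length(p) > 1) 1L else 0L)
      train_pat <- c(train_pat, sample(p, n_tr))
    }
  })
  list(train = labels$stay_id[pid %in% train_pat],
       validation = labels$stay_id[!pid %in% train_pat])
}

#' Train the gradient-boosted risk scorer
#'
#' @param features a `paki3_features` object whose `index` carries a
#'   `label` column; rows are the training samples.
#' @param config a [model_config()].
#' @return A list of class `paki3_model`: `booster` (xgboost handle),
#'   `feature_names`, `spec_hash`, `importance` (data.frame, xgboost gain),
#'   `config`.
#' @export
train_risk_model <- function(features, config = model_config()) {
  y <- features$index$label
  if (length(unique(y)) < 2) stopf("training set must contain both classes")
  spw <- config$scale_pos_weight %||% (sum(y == 0) / sum(y == 1))
  dtrain <- xgboost::xgb.DMatrix(features$x, label = y)
  params <- list(objective = "binary:logistic",
                 eval_metric = "logloss",
                 tree_method = "hist",
                 max_depth = config$max_depth, eta = config$eta,
                 alpha = config$alpha, lambda = config$lambda,
                 scale_pos_weight = spw, nthread = config$nthread,
                 seed = config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$nrounds, verbose = 0)
  imp <- tryCatch(
    as.data.frame(xgboost::xgb.importance(model = booster)),
    error = function(e) data.frame(Feature = character(), Gain = numeric())
  )
  structure(list(booster = booster,
                 feature_names = colnames(features$x),
                 spec_hash = spec_hash(features$spec),
                 importance = imp, config = config),
            class = "paki3_model")
}

spec_hash <- function(spec) {
  ## dependency-free stable digest of the feature layout
  s <- paste(deparse(unclass(spec)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% .Machine$integer.max)
}

#' Score samples with a trained model
#'
#' @param model a `paki3_model`.
#' @param features a `paki3_features` built with the same [feature_spec()]
#'   as the training data (enforced via the spec hash).
#' @return data.frame `stay_id`, `hour`, `score` in `[0, 1]`.
#' @export
predict_risk <- function(model, features) {
  if (!identical(model$spec_hash, spec_hash(features$spec))) {
    stopf("feature specification does not match the one the model was trained with")
  }
  sc <- predict(model$booster, xgboost::xgb.DMatrix(features$x))
  data.frame(stay_id = features$index$stay_id, hour = features$index$hour,
             score = as.numeric(sc), stringsAsFactors = FALSE)
}

#' Calibrate the operating threshold to a target per-stay sensitivity
#'
#' Per-stay maxima are compared against candidate cutoffs just below each
#' observed maximum (a stay alarms when its maximum strictly exceeds the
#' cutoff); the largest candidate whose per-stay sensitivity reaches the
#' target is returned. Once fixed, the cutoff is never recalibrated on new
#' cohorts.
#'
#' @param max_scores per-stay maximum risk scores.
#' @param truth logical/0-1 vector, TRUE for persistent stays.
#' @param target target sensitivity (default 0.80).
#' @return The calibrated cutoff.
#' @export
calibrate_threshold <- function(max_scores, truth, target = 0.8) {
  truth <- as.logical(truth)
  pos <- max_scores[truth]
  if (!length(pos)) stopf("no persistent stays to calibrate on")
  if (all(pos <= 0)) stopf("sensitivity target unreachable: all persistent maxima are zero")
  eps <- 1e-9
  cand <- sort(unique(c(max_scores - eps, max(max_scores))), decreasing = TRUE)
  for (c0 in cand) {
    if (mean(pos > c0) >= target) return(c0)
  }
  min(cand)
}
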