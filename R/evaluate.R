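## Per-stay MAX-metric evaluation, ROC/PR summaries with stay-level
## bootstrap intervals, prevalence-standardized predictive values, lead
## time, and the Average Odds Difference fairness audit.

#' Per-stay MAX-metric classification
#'
#' Each stay is summarized by the maximum risk score over its admissible
#' sample hours (persistent stays are scored only up to `Tp + 12`, which
#' the sampling contract already enforces; transient stays over their whole
#' stay). A stay is predicted persistent iff its maximum strictly exceeds
#' the cutoff. For correctly predicted persistent stays the lead time is
#' `Tp` minus the first above-cutoff hour (negative when the first alarm
#' falls in `(Tp, Tp + 12]`).
#'
#' @param risk data.frame `stay_id`, `hour`, `score`, see [predict_risk()].
#' @param labels data.frame `stay_id`, `class`, `Tp`.
#' @param cutoff operating threshold.
#' @return data.frame of class `stay_evaluation`: `stay_id`, `truth`
#'   (logical), `class`, `max_score`, `predicted`, `lead_time`.
#' @export
max_metric <- function(risk, labels, cutoff) {
  idx <- split(seq_len(nrow(risk)), risk$stay_id)
  miss <- setdiff(labels$stay_id[labels$class != "transient"], names(idx))
  if (length(miss)) {
    stopf("persistent stay(s) with no admissible risk samples: %s",
          paste(miss, collapse = ", "))
  }
  labels <- labels[labels$stay_id %in% names(idx), , drop = FALSE]
  out <- data.frame(
    stay_id = labels$stay_id,
    truth = labels$class != "transient",
    class = labels$class,
    max_score = NA_real_, predicted = NA, lead_time = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(out))) {
    i <- idx[[out$stay_id[k]]]
    sc <- risk$score[i]
    out$max_score[k] <- max(sc)
    out$predicted[k] <- out$max_score[k] > cutoff
    if (out$truth[k] && out$predicted[k]) {
      first <- min(risk$hour[i][sc > cutoff])
      out$lead_time[k] <- labels$Tp[k] - first
    }
  }
  class(out) <- c("stay_evaluation", "data.frame")
  out
}

## ROC curve points over all cutoffs of the per-stay maxima.
roc_points <- function(scores, truth) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  P <- sum(truth); N <- sum(!truth)
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(diff(s) != 0, TRUE)   # one point per distinct threshold
  data.frame(tpr = c(0, tp[keep] / P), fpr = c(0, fp[keep] / N))
}

auroc_trapezoid <- function(scores, truth) {
  p <- roc_points(scores, truth)
  sum(diff(p$fpr) * (head(p$tpr, -1) + tail(p$tpr, -1)) / 2)
}

## Area under the precision-recall step curve (no interpolation between
## points): sum over recall increments of the precision at that threshold.
aupr_step <- function(scores, truth) {
  o <- order(scores, decreasing = TRUE)
  y <- truth[o]; s <- scores[o]
  P <- sum(truth)
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(diff(s) != 0, TRUE)
  rec <- tp[keep] / P
  prec <- tp[keep] / (tp[keep] + fp[keep])
  sum(diff(c(0, rec)) * prec)
}

#' ROC and PR summaries of per-stay maxima
#'
#' auROC by the trapezoidal rule over the ROC curve (equal to the pairwise
#' ranking probability with ties counted 1/2); auPR by the
#' precision-recall step curve, the standard choice for imbalanced
#' endpoints. Intervals are percentile bootstrap over stays.
#'
#' @param evals a `stay_evaluation` (or any data.frame with `max_score`,
#'   `truth`).
#' @param n_boot bootstrap resamples (0 disables intervals).
#' @param probs interval percentiles.
#' @param seed RNG seed for the bootstrap.
#' @return list `auroc`, `aupr`, `auroc_ci`, `aupr_ci`, `roc` (curve
#'   points).
#' @export
roc_pr <- function(evals, n_boot = 1000, probs = c(0.025, 0.975), seed = 1) {
  s <- evals$max_score; y <- as.logical(evals$truth)
  if (length(unique(y)) < 2) stopf("both classes are required for ROC/PR analysis")
  out <- list(auroc = auroc_trapezoid(s, y), aupr = aupr_step(s, y),
              roc = roc_points(s, y))
  if (n_boot > 0) {
    n <- length(s)
    bo <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[i])) < 2) return(c(NA_real_, NA_real_))
        c(auroc_trapezoid(s[i], y[i]), aupr_step(s[i], y[i]))
      }, numeric(2))
    })
    out$auroc_ci <- unname(quantile(bo[1, ], probs, na.rm = TRUE))
    out$aupr_ci <- unname(quantile(bo[2, ], probs, na.rm = TRUE))
  }
  out
}

#' Prevalence-standardized positive predictive value
#'
#' `PPV = sens * p / (sens * p + (1 - spec) * (1 - p))` — the precision the
#' classifier would attain in a population with persistent-AKI prevalence
#' `p`, given its sensitivity and specificity.
#'
#' @param sensitivity,specificity operating characteristics in `[0, 1]`.
#' @param prevalence assumed prevalence in `[0, 1]`.
#' @return PPV in `[0, 1]`; NA (with a warning) when the denominator is 0.
#' @export
standardized_ppv <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1)
  den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  if (den == 0) {
    warning("standardized PPV undefined: no predicted positives at this operating point")
    return(NA_real_)
  }
  sensitivity * prevalence / den
}

#' Prevalence-standardized negative predictive value
#'
#' `NPV = spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)`.
#'
#' @inheritParams standardized_ppv
#' @return NPV in `[0, 1]`; NA when undefined.
#' @export
standardized_npv <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1)
  den <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (den == 0) {
    warning("standardized NPV undefined: no predicted negatives at this operating point")
    return(NA_real_)
  }
  specificity * (1 - prevalence) / den
}

#' Confusion-matrix rates at a fixed cutoff
#'
#' Rates are computed from the per-stay 2x2 counts; F1 is the harmonic
#' mean of PPV and sensitivity recomputed from counts, never from rounded
#' rates.
#'
#' @param evals a `stay_evaluation`.
#' @return list `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `f1`, `prevalence`.
#' @export
confusion_rates <- function(evals) {
  y <- as.logical(evals$truth); p <- as.logical(evals$predicted)
  if (!length(y)) stopf("empty evaluation set")
  tp <- sum(y & p); fp <- sum(!y & p); fn <- sum(y & !p); tn <- sum(!y & !p)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       f1 = f1, prevalence = mean(y))
}

#' Average Odds Difference of a monitored subgroup
#'
#' `AOD = ((FPR_mon - FPR_ref) + (TPR_mon - TPR_ref)) / 2`, the
#' single-number summary of equalized odds; the reference group is the
#' remainder of the cohort. Values within `[-0.1, 0.1]` are conventionally
#' considered fair. When either group lacks a positive or a negative stay
#' the estimate is flagged unreliable.
#'
#' @param evals a `stay_evaluation`.
#' @param monitored logical vector marking the monitored subgroup (same
#'   order as `evals`).
#' @return list `aod`, `tpr_monitored`, `tpr_reference`, `fpr_monitored`,
#'   `fpr_reference`, `fair` (|AOD| <= 0.1), `reliable`.
#' @export
average_odds_difference <- function(evals, monitored) {
  stopifnot(length(monitored) == nrow(evals))
  y <- as.logical(evals$truth); p <- as.logical(evals$predicted)
  g <- as.logical(monitored)
  rates <- function(i) {
    c(tpr = sum(y[i] & p[i]) / sum(y[i]),
      fpr = sum(!y[i] & p[i]) / sum(!y[i]))
  }
  rm_ <- rates(g); rr <- rates(!g)
  reliable <- sum(y[g]) >= 1 && sum(!y[g]) >= 1 &&
    sum(y[!g]) >= 1 && sum(!y[!g]) >= 1
  aod <- ((rm_["fpr"] - rr["fpr"]) + (rm_["tpr"] - rr["tpr"])) / 2
  list(aod = unname(aod),
       tpr_monitored = unname(rm_["tpr"]), tpr_reference = unname(rr["tpr"]),
       fpr_monitored = unname(rm_["fpr"]), fpr_reference = unname(rr["fpr"]),
       fair = isTRUE(abs(aod) <= 0.1 + 1e-12), reliable = reliable)
}

#' Fairness audit across subgroup columns
#'
#' Computes the Average Odds Difference for every level of each grouping
#' column of the static table (each level monitored against the rest of
#' the cohort).
#'
#' @param evals a `stay_evaluation`.
#' @param statics per-stay static table.
#' @param keys grouping columns present in `statics`.
#' @return data.frame `key`, `level`, `n`, `aod`, `fair`, `reliable`.
#' @export
fairness_audit <- function(evals, statics,
                           keys = intersect(c("sex", "age_band", "admission_reason",
                                              "unit_type", "ckd", "ethnicity"),
                                            names(statics))) {
  st <- statics[match(evals$stay_id, statics$stay_id), , drop = FALSE]
  if (!"age_band" %in% names(st) && "age" %in% names(st)) {
    st$age_band <- cut(st$age, c(18, 39, 64, Inf), include.lowest = TRUE,
                       labels = c("18-39", "40-64", "65+"))
    keys <- union(keys, "age_band")
  }
  out <- list()
  for (k in keys) {
    for (lv in unique(as.character(st[[k]]))) {
      if (is.na(lv)) next
      mon <- !is.na(st[[k]]) & as.character(st[[k]]) == lv
      if (!any(mon) || all(mon)) next
      a <- average_odds_difference(evals, mon)
      out[[length(out) + 1L]] <- data.frame(
        key = k, level = lv, n = sum(mon), aod = a$aod,
        fair = a$fair, reliable = a$reliable, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res %||% data.frame(key = character(), level = character(), n = integer(),
                      aod = numeric(), fair = logical(), reliable = logical())
}
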