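## Per-timestamp feature vectors: trailing-window statistics of the carried
## hourly series and of the consecutive-difference series of raw
## measurements, plus staleness and missingness channels.
##
## Differences are taken between consecutive raw measurements (not between
## carried hourly values, which would fabricate zero differences while a
## value is merely being carried forward); each difference is indexed by the
## hour bin of its later measurement.

#' Feature specification
#'
#' @param variables canonical variable names (default all 13).
#' @param windows trailing-window lengths in hours.
#' @param stats statistics per window, subset of
#'   `c("mean", "min", "max", "std", "last")`.
#' @param staleness_vars variables contributing an hours-since-last-
#'   measurement feature (default all).
#' @param missing_flag_vars variables contributing a missingness indicator
#'   (default all except creatinine and urine output, whose absence is
#'   already encoded by staleness).
#' @return A list of class `feature_spec`. The default yields
#'   `13 * 2 * 4 * 5 + 13 + 11 = 544` features.
#' @export
feature_spec <- function(variables = CANONICAL_VARS,
                         windows = c(6L, 12L, 24L, 48L),
                         stats = c("mean", "min", "max", "std", "last"),
                         staleness_vars = variables,
                         missing_flag_vars = setdiff(variables, c("creatinine", "urine_output"))) {
  bad <- setdiff(variables, CANONICAL_VARS)
  if (length(bad)) stopf("unknown variable(s): %s", paste(bad, collapse = ", "))
  if (any(windows < 1) || any(windows > PAD_HOURS)) {
    stopf("windows must lie in [1, %d] hours", PAD_HOURS)
  }
  bad <- setdiff(stats, c("mean", "min", "max", "std", "last"))
  if (length(bad)) stopf("unknown statistic(s): %s", paste(bad, collapse = ", "))
  structure(list(variables = variables, windows = as.integer(windows),
                 stats = stats, staleness_vars = staleness_vars,
                 missing_flag_vars = missing_flag_vars),
            class = "feature_spec")
}

#' Deterministic feature names for a specification
#'
#' Window statistics are named `<variable>_<W>h_<stat>` for the carried
#' series and `<variable>_diff_<W>h_<stat>` for the difference series
#' (e.g. `creatinine_diff_48h_mean`), followed by `<variable>_tsl`
#' staleness features and `<variable>_missing` flags.
#'
#' @param spec a [feature_spec()].
#' @return Character vector of feature names in stable column order.
#' @export
feature_names <- function(spec = feature_spec()) {
  nm <- character()
  for (v in spec$variables) {
    for (src in c("raw", "diff")) {
      base <- if (src == "raw") v else paste0(v, "_diff")
      for (w in spec$windows) {
        nm <- c(nm, paste0(base, "_", w, "h_", spec$stats))
      }
    }
  }
  c(nm,
    if (length(spec$staleness_vars)) paste0(spec$staleness_vars, "_tsl"),
    if (length(spec$missing_flag_vars)) paste0(spec$missing_flag_vars, "_missing"))
}

## Hour-binned difference series per stay for one variable. `times` are
## elapsed hours of raw measurements, `values` in canonical units.
## Returns a vector over the stay grid, NA where no measurement closed a
## difference that hour (collisions within an hour keep the last).
diff_series <- function(times, values, n_hours) {
  out <- rep(NA_real_, n_hours)
  if (length(times) >= 2) {
    o <- order(times)
    times <- times[o]; values <- values[o]
    d <- diff(values)
    b <- floor(times[-1])
    ok <- b >= 0 & b < n_hours
    out[b[ok] + 1L] <- d[ok]   # later entry wins on collision
  }
  out
}

#' Build the feature matrix at sample hours
#'
#' For each `(stay, hour)` sample, computes every windowed statistic over
#' the carried values and over the measurement-difference series within
#' `(t - W, t]`, the staleness channels, and the missingness flags. Windows
#' holding no observation yield missing features; the downstream tree
#' learner routes missing values natively, so no imputation is applied.
#'
#' @param matrix an `hourly_matrix` (cohort).
#' @param events standardized, filtered event table (for difference
#'   series).
#' @param statics per-stay static table.
#' @param samples data.frame `stay_id`, `hour` (and optionally `label`),
#'   see [label_samples()].
#' @param spec a [feature_spec()].
#' @return A list of class `paki3_features`: `x` (numeric matrix, one row
#'   per sample, columns [feature_names()]), `index` (the `samples` rows in
#'   matching order), `spec`.
#' @export
build_features <- function(matrix, events, statics, samples, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"))
  ids <- unique(matrix$stay_id)
  o <- order(match(matrix$stay_id, ids), matrix$hour)
  if (is.unsorted(o)) matrix <- matrix[o, ]
  m_idx <- split(seq_len(nrow(matrix)), factor(matrix$stay_id, levels = ids))
  n_hours <- setNames(lengths(m_idx), ids)

  samples <- samples[samples$stay_id %in% ids, , drop = FALSE]
  samples <- samples[order(match(samples$stay_id, ids), samples$hour), , drop = FALSE]
  rownames(samples) <- NULL
  ## row of `matrix` (grid order) holding each sample hour
  row_offset <- setNames(cumsum(c(0L, unname(n_hours)))[seq_along(ids)], ids)
  samp_row <- row_offset[samples$stay_id] + samples$hour + 1L

  ev <- data.table::as.data.table(events)
  adm <- setNames(statics$admission_time, statics$stay_id)

  nm <- feature_names(spec)
  x <- array(NA_real_, dim = c(nrow(samples), length(nm)),
             dimnames = list(NULL, nm))
  col <- 1L
  for (v in spec$variables) {
    carried <- pad_concat(lapply(m_idx, function(i) matrix[[v]][i]))
    if (v == "urine_output") {
      ## the hourly flow series is the measurement series for urine output
      dvecs <- lapply(m_idx, function(i) {
        f <- matrix$urine_output[i]
        diff_series(which(!is.na(f)) - 1L, f[!is.na(f)], length(f))
      })
    } else {
      sev <- ev[variable == v]
      sev_idx <- split(seq_len(nrow(sev)), factor(sev$stay_id, levels = ids))
      dvecs <- lapply(seq_along(ids), function(k) {
        i <- sev_idx[[k]]
        diff_series(hours_between(sev$time[i], adm[[ids[k]]]),
                    sev$value[i], n_hours[[k]])
      })
    }
    diffs <- pad_concat(dvecs)
    for (src in c("raw", "diff")) {
      padded <- if (src == "raw") carried else diffs
      for (w in spec$windows) {
        for (st in spec$stats) {
          per_grid_row <- roll_stat(padded$x, w, st)[padded$pos]
          x[, col] <- per_grid_row[samp_row]
          col <- col + 1L
        }
      }
    }
  }
  for (v in spec$staleness_vars) {
    x[, col] <- matrix[[paste0(v, "_tsl")]][samp_row]
    col <- col + 1L
  }
  for (v in spec$missing_flag_vars) {
    x[, col] <- as.numeric(matrix[[paste0(v, "_miss")]][samp_row])
    col <- col + 1L
  }
  structure(list(x = x, index = samples, spec = spec), class = "paki3_features")
}
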