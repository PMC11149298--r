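## Hourly KDIGO staging from serum creatinine, urine output and RRT.
##
## Creatinine bands (relative to the baseline bSCr):
##   stage 3: sCr >= 3 x bSCr, or sCr >= 4.0 mg/dL with an acute qualifier
##            (>= 0.3 mg/dL rise within 48 h, or ratio >= 1.5) so that stable
##            chronic elevation is not staged;
##   stage 2: sCr >= 2 x bSCr;
##   stage 1: sCr >= 1.5 x bSCr, or a >= 0.3 mg/dL rise over the trailing
##            48 h minimum (switchable via `use_rise`).
## Urine-output bands (trailing means of hourly flow, ml/kg/h):
##   stage 3: mean over (t-24, t] < 0.3, or anuria (zero flow) over the whole
##            of (t-12, t];
##   stage 2: mean over (t-12, t] < 0.5;
##   stage 1: mean over (t-6, t]  < 0.5.
## Oliguria bands need >= 80% window coverage (mean over observed hours);
## the anuria band needs 100% coverage. Any hour under active RRT is stage 3.

#' Baseline serum creatinine per stay
#'
#' Computes the nadir-modified baseline: for stays with RRT, the minimum
#' creatinine between admission and the first RRT initiation; for stays
#' without RRT, the minimum creatinine pooled over all of the same
#' patient's stays that never involved RRT.
#'
#' @param events standardized event table (creatinine rows and `rrt`
#'   markers are used).
#' @param statics per-stay static table with `patient_id`.
#' @return A data.frame `stay_id`, `bscr`, `provenance`
#'   (`"pre-RRT nadir"` or `"cross-stay nadir"`); `bscr` is NA for stays
#'   with no qualifying creatinine (later excluded).
#' @export
baseline_scr <- function(events, statics) {
  scr <- events[events$variable == "creatinine", , drop = FALSE]
  rrt_h <- rrt_start_hours(events, statics)
  has_rrt <- !is.na(rrt_h)
  bscr <- rep(NA_real_, nrow(statics))
  prov <- rep(NA_character_, nrow(statics))
  ## per-stay nadirs
  stay_min <- rep(NA_real_, nrow(statics))
  pre_rrt_min <- rep(NA_real_, nrow(statics))
  for (k in seq_len(nrow(statics))) {
    i <- which(scr$stay_id == statics$stay_id[k])
    if (!length(i)) next
    tau <- hours_between(scr$time[i], statics$admission_time[k])
    stay_min[k] <- min(scr$value[i])
    if (has_rrt[k]) {
      j <- tau < rrt_h[k]
      if (any(j)) pre_rrt_min[k] <- min(scr$value[i][j])
    }
  }
  for (k in seq_len(nrow(statics))) {
    if (has_rrt[k]) {
      bscr[k] <- pre_rrt_min[k]
      prov[k] <- "pre-RRT nadir"
    } else {
      sib <- which(statics$patient_id == statics$patient_id[k] & !has_rrt)
      pool <- stay_min[sib]
      if (any(!is.na(pool))) bscr[k] <- min(pool, na.rm = TRUE)
      prov[k] <- "cross-stay nadir"
    }
  }
  data.frame(stay_id = statics$stay_id, bscr = bscr, provenance = prov,
             stringsAsFactors = FALSE)
}

#' Hourly creatinine-based KDIGO stage
#'
#' @param scr carried hourly creatinine series (mg/dL, NA where stale).
#' @param bscr baseline creatinine (> 0).
#' @param use_rise apply the 0.3 mg/dL-in-48-h rise criterion (stage 1 band
#'   and the acute qualifier of the 4.0 mg/dL stage-3 band).
#' @return Integer vector of stages 0-3, NA where creatinine is not
#'   evaluable.
#' @export
stage_scr <- function(scr, bscr, use_rise = TRUE) {
  if (!isTRUE(bscr > 0)) stopf("baseline creatinine must be positive")
  ratio <- scr / bscr
  if (use_rise) {
    min48 <- roll_min(scr, 48L)
    rise <- !is.na(scr) & !is.na(min48) & (scr - min48 >= 0.3)
  } else {
    rise <- rep(FALSE, length(scr))
  }
  acute <- rise | (!is.na(ratio) & ratio >= 1.5)
  st <- ifelse(is.na(scr), NA_integer_, 0L)
  st[!is.na(ratio) & (ratio >= 1.5 | rise)] <- 1L
  st[!is.na(ratio) & ratio >= 2] <- 2L
  st[(!is.na(ratio) & ratio >= 3) | (!is.na(scr) & scr >= 4 & acute)] <- 3L
  st
}

#' Hourly urine-output-based KDIGO stage
#'
#' @param flow hourly urine flow in ml/kg/h (NA where uncovered).
#' @return A data.frame with `stage` (0-3, NA where no band is evaluable)
#'   and `anuric` (stage 3 reached via the zero-output band).
#' @export
stage_uo <- function(flow) {
  n <- length(flow)
  t <- seq_len(n) - 1L
  m6 <- roll_mean(flow, 6L);   c6 <- roll_n(flow, 6L)
  m12 <- roll_mean(flow, 12L); c12 <- roll_n(flow, 12L)
  m24 <- roll_mean(flow, 24L); c24 <- roll_n(flow, 24L)
  max12 <- roll_max(flow, 12L)
  ok6  <- t >= 5L  & c6 >= 5
  ok12 <- t >= 11L & c12 >= 10
  ok24 <- t >= 23L & c24 >= 20
  okan <- t >= 11L & c12 >= 12
  anuric <- okan & !is.na(max12) & max12 <= 0
  st <- rep(NA_integer_, n)
  evaluable <- ok6 | ok12 | ok24 | okan
  st[evaluable] <- 0L
  st[ok6 & m6 < 0.5] <- 1L
  st[ok12 & m12 < 0.5] <- 2L
  st[(ok24 & m24 < 0.3) | anuric] <- 3L
  data.frame(stage = st, anuric = anuric)
}

#' Hourly KDIGO stage for one stay
#'
#' Combines the creatinine and urine-output stages (hourly maximum) and
#' forces stage 3 at any hour with active renal replacement therapy (from
#' initiation to the end of the stay grid).
#'
#' @param matrix_stay rows of an `hourly_matrix` for one stay, ordered by
#'   hour.
#' @param bscr baseline creatinine for the stay.
#' @param rrt_start hour of first RRT initiation (NA for none).
#' @param use_rise see [stage_scr()].
#' @return A data.frame (`stay_id`, `hour`, `stage`, `criterion`,
#'   `evaluable`, `scr_stage`, `uo_stage`, `uo_anuric`). `criterion` is one
#'   of `none`, `scr`, `uo`, `scr+uo`, `rrt`; `evaluable` is FALSE where
#'   neither criterion could be assessed (stage reported as 0).
#' @export
stage_hourly <- function(matrix_stay, bscr, rrt_start = NA, use_rise = TRUE) {
  n <- nrow(matrix_stay)
  scr_st <- if (is.na(bscr)) rep(NA_integer_, n) else
    stage_scr(matrix_stay$creatinine, bscr, use_rise = use_rise)
  uo <- stage_uo(matrix_stay$urine_output)
  s <- pmax(scr_st, uo$stage, na.rm = TRUE)
  evaluable <- !is.na(s)
  stg <- ifelse(evaluable, s, 0L)
  crit <- rep("none", n)
  scr_hit <- !is.na(scr_st) & scr_st == stg & stg > 0
  uo_hit <- !is.na(uo$stage) & uo$stage == stg & stg > 0
  crit[scr_hit & !uo_hit] <- "scr"
  crit[uo_hit & !scr_hit] <- "uo"
  crit[scr_hit & uo_hit] <- "scr+uo"
  if (!is.na(rrt_start)) {
    on <- which(seq_len(n) - 1L >= floor(rrt_start))
    stg[on] <- 3L
    crit[on] <- "rrt"
    evaluable[on] <- TRUE
  }
  data.frame(
    stay_id = matrix_stay$stay_id, hour = matrix_stay$hour,
    stage = as.integer(stg), criterion = crit, evaluable = evaluable,
    scr_stage = as.integer(scr_st), uo_stage = uo$stage,
    uo_anuric = uo$anuric, stringsAsFactors = FALSE
  )
}

#' Hourly KDIGO stages for a whole cohort
#'
#' @param matrix an `hourly_matrix`, see [resample_hourly()].
#' @param baselines output of [baseline_scr()].
#' @param rrt named vector of first-RRT hours, see [rrt_start_hours()].
#' @param use_rise see [stage_scr()].
#' @return Row-bound [stage_hourly()] output for all stays, class
#'   `stage_series`.
#' @export
stage_cohort <- function(matrix, baselines, rrt, use_rise = TRUE) {
  idx <- split(seq_len(nrow(matrix)), matrix$stay_id)
  ids <- names(idx)
  out <- vector("list", length(ids))
  b <- setNames(baselines$bscr, baselines$stay_id)
  for (k in seq_along(ids)) {
    ms <- matrix[idx[[k]], ]
    out[[k]] <- stage_hourly(ms, b[[ids[k]]],
                             rrt_start = unname(rrt[ids[k]]),
                             use_rise = use_rise)
  }
  res <- as.data.frame(data.table::rbindlist(out))
  class(res) <- c("stage_series", "data.frame")
  res
}
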