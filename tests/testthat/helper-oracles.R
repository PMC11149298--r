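## Independent brute-force oracles used by the tests. These deliberately
## re-derive every quantity from raw inputs with naive per-hour scans and
## exhaustive enumeration, sharing no code path with the package internals.

## hours since admission for event rows of one stay
.ev_hours <- function(events, static) {
  as.numeric(difftime(events$time, static$admission_time, units = "hours"))
}

## Brute-force per-hour staging for one stay, straight from raw events.
oracle_stage_stay <- function(events, static, bscr, rrt_h, use_rise = TRUE) {
  end <- min(static$discharge_time, static$death_time, na.rm = TRUE)
  n <- ceiling(as.numeric(difftime(end, static$admission_time, units = "hours")))
  scr <- events[events$variable == "creatinine", , drop = FALSE]
  scr_t <- floor(.ev_hours(scr, static)); scr_v <- scr$value
  uo <- events[events$variable == "urine_output", , drop = FALSE]
  uo_tau <- .ev_hours(uo, static)
  o <- order(uo_tau); uo_tau <- uo_tau[o]; uo_v <- uo$value[o]
  w <- static$weight
  ## own interval attribution for urine flow
  flow <- rep(NA_real_, n)
  prev <- 0
  for (i in seq_along(uo_tau)) {
    g <- uo_tau[i] - prev
    if (g > 0) {
      credited <- min(g, 6)
      bins <- seq.int(floor(uo_tau[i] - credited) + 1, floor(uo_tau[i]))
      bins <- bins[bins >= 0 & bins < n]
      for (bb in bins) flow[bb + 1] <- uo_v[i] / (credited * w)
    }
    prev <- uo_tau[i]
  }
  carr <- rep(NA_real_, n)
  for (t in 0:(n - 1)) {
    j <- which(scr_t <= t & t - scr_t < 24)
    if (length(j)) {
      j <- j[scr_t[j] == max(scr_t[j])]      # freshest bin, last-loaded wins
      carr[t + 1] <- scr_v[j[length(j)]]
    }
  }
  stage <- integer(n); crit <- character(n); evaluable <- logical(n)
  for (t in 0:(n - 1)) {
    s <- carr[t + 1]
    scr_st <- NA_integer_
    if (!is.na(s) && !is.na(bscr)) {
      win <- carr[seq.int(max(1, t - 48 + 2), t + 1)]   # hours (t-48, t]
      m48 <- if (all(is.na(win))) NA else min(win, na.rm = TRUE)
      rise <- use_rise && !is.na(m48) && s - m48 >= 0.3
      r <- s / bscr
      scr_st <- 0L
      if (r >= 1.5 || rise) scr_st <- 1L
      if (r >= 2) scr_st <- 2L
      if (r >= 3 || (s >= 4 && (rise || r >= 1.5))) scr_st <- 3L
    }
    band <- function(wd) {
      v <- flow[seq.int(max(1, t - wd + 2), t + 1)]
      list(full = t >= wd - 1, m = mean(v, na.rm = TRUE), k = sum(!is.na(v)),
           allz = t >= wd - 1 && sum(!is.na(v)) == wd && all(v[!is.na(v)] <= 0))
    }
    b6 <- band(6); b12 <- band(12); b24 <- band(24)
    uo_st <- NA_integer_
    if ((b6$full && b6$k >= 5) || (b12$full && b12$k >= 10) ||
        (b24$full && b24$k >= 20) || (b12$full && b12$k == 12)) {
      uo_st <- 0L
      if (b6$full && b6$k >= 5 && b6$m < 0.5) uo_st <- 1L
      if (b12$full && b12$k >= 10 && b12$m < 0.5) uo_st <- 2L
      if ((b24$full && b24$k >= 20 && b24$m < 0.3) || b12$allz) uo_st <- 3L
    }
    st <- max(scr_st, uo_st, -1L, na.rm = TRUE)
    ev_ok <- !(is.na(scr_st) && is.na(uo_st))
    if (st < 0) st <- 0L
    cr <- "none"
    if (st > 0) {
      hit_s <- !is.na(scr_st) && scr_st == st
      hit_u <- !is.na(uo_st) && uo_st == st
      cr <- if (hit_s && hit_u) "scr+uo" else if (hit_s) "scr" else "uo"
    }
    if (!is.na(rrt_h) && t >= floor(rrt_h)) {
      st <- 3L; cr <- "rrt"; ev_ok <- TRUE
    }
    stage[t + 1] <- if (ev_ok) st else 0L
    crit[t + 1] <- if (ev_ok) cr else "none"
    evaluable[t + 1] <- ev_ok
  }
  data.frame(hour = 0:(n - 1), stage = stage, criterion = crit,
             evaluable = evaluable)
}

## Run-length-encoding severe-event oracle (no RRT, no terminators).
oracle_runs <- function(stage_vec) {
  r <- rle(stage_vec == 3L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values] - 1L, end = ends[r$values])
}

## Pairwise ranking probability (ties count 1/2).
oracle_auroc <- function(scores, truth) {
  pos <- scores[as.logical(truth)]; neg <- scores[!as.logical(truth)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## Exhaustive threshold scan: evaluate per-stay sensitivity at every
## candidate cutoff and keep the largest admissible one.
oracle_cutoff <- function(max_scores, truth, target) {
  pos <- max_scores[as.logical(truth)]
  cand <- sort(unique(c(max_scores - 1e-9, max(max_scores))))
  ok <- vapply(cand, function(c0) mean(pos > c0) >= target, logical(1))
  max(cand[ok])
}

## Direct-recount AOD oracle.
oracle_aod <- function(truth, pred, mon) {
  tpr <- function(i) sum(truth[i] & pred[i]) / sum(truth[i])
  fpr <- function(i) sum(!truth[i] & pred[i]) / sum(!truth[i])
  ((fpr(mon) - fpr(!mon)) + (tpr(mon) - tpr(!mon))) / 2
}

## Naive windowed statistics over hour-binned series for the feature
## oracle: values at hours in (t - W, t] of `series` (NA = no entry).
oracle_window_stat <- function(series, t, w, stat) {
  v <- series[seq.int(max(1, t - w + 2), t + 1)]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  switch(stat,
    mean = mean(v), min = min(v), max = max(v),
    std = if (length(v) < 2) NA_real_ else sd(v),
    last = v[length(v)])
}

## ---- small fixture builders ------------------------------------------------

fx_time <- function(h) as.POSIXct("2024-01-01 00:00:00", tz = "UTC") + h * 3600

fx_static <- function(stay_id = "a", patient_id = stay_id, L = 96, age = 60,
                      height = 170, weight = 80, sex = "F", death_h = NA) {
  data.frame(stay_id = stay_id, patient_id = patient_id, age = age, sex = sex,
             height = height, weight = weight,
             admission_time = fx_time(0), discharge_time = fx_time(L),
             death_time = if (is.na(death_h)) as.POSIXct(NA) else fx_time(death_h),
             admission_reason = "medical", ckd = FALSE,
             renal_transplant = FALSE, unit_type = "MICU",
             ethnicity = "other", stringsAsFactors = FALSE)
}

fx_events <- function(stay_id, hours, variable, values,
                      unit = c(creatinine = "mg/dL", urine_output = "mL",
                               heart_rate = "bpm", rrt = "")[variable]) {
  data.frame(stay_id = stay_id, time = fx_time(hours), variable = variable,
             value = values, unit = unname(unit), stringsAsFactors = FALSE)
}

## random event table for one stay (creatinine + urine output + heart rate)
fx_random_stay <- function(sid, L = 120, with_rrt = FALSE) {
  scr_t <- sort(sample(0:(L - 1), min(L - 2, sample(6:14, 1))))
  scr_v <- round(runif(length(scr_t), 0.4, 6), 2)
  uo_t <- sort(sample(1:(L - 1), min(L - 2, sample(20:45, 1))))
  uo_v <- round(runif(length(uo_t), 0, 400))
  hr_t <- sort(sample(0:(L - 1), min(L - 2, sample(10:40, 1))))
  hr_v <- round(runif(length(hr_t), 40, 140))
  ev <- rbind(
    fx_events(sid, scr_t, "creatinine", scr_v),
    fx_events(sid, uo_t, "urine_output", uo_v),
    fx_events(sid, hr_t, "heart_rate", hr_v),
    if (with_rrt) fx_events(sid, sample(10:(L - 10), 1), "rrt", 1)
  )
  ev
}
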