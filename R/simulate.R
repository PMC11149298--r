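## Synthetic ICU cohort generator.
##
## Every generated stay carries a severe (stage-3) creatinine excursion:
## baseline phase, a ramp through stages 1-2, an onset measurement crossing
## 3x baseline at the intended hour, a plateau held strictly above the
## stage-3 band, and - for transient and T72 stays - a measured recovery.
## The intended class is realized by the run-length structure alone:
##   transient  plateau of 14-40 h ending in recovery;
##   T72        plateau of >= 80 h ending in recovery;
##   D48        plateau held until death exactly 48 h after onset;
##   RRT24      RRT initiated 25 h after onset (stage 3 forced thereafter).
## Value clamps are chosen so that the staging rules read the planted run
## back exactly whatever the realized within-stay nadir: baseline draws lie
## in [0.95, 1.12] x b, ramp values below 2.75 x b, plateau values above
## 3.45 x b (>= 3 x the largest possible nadir).
##
## Class-correlated signal is controlled by `signal_strength` and vanishes
## at 0, where pre-onset trajectories are exchangeable between classes:
## persistent stays get a pre-onset urine-output decline, ancillary-variable
## drift starting 48 h before onset, and a higher plateau. Urine output is
## emitted as irregular volume records (1-4 h apart) whose volumes
## accumulate across dropped recordings, so the volume-to-flow conversion is
## genuinely exercised.

ANC_VARS <- setdiff(CANONICAL_VARS, c("creatinine", "urine_output"))

## per-variable mean, noise SD, and drift direction (units of SD) for
## persistent stays approaching onset
ANC_PARAMS <- data.frame(
  name = ANC_VARS,
  mean = c(33, 11, 24, 25, 104, 130, 85, 220, 4.1, 138, 10),
  sd   = c(4, 1.5, 3, 8, 4, 30, 12, 60, 0.4, 4, 3),
  drift = c(-0.6, -0.6, -1.0, 1.2, 0.3, 0.5, 0.7, -0.7, 0.8, -0.4, 0.6),
  stringsAsFactors = FALSE
)

#' Simulation configuration
#'
#' @param n_stays number of ICU stays.
#' @param class_mix named proportions over
#'   `c("transient", "T72", "D48", "RRT24")`, non-negative, summing to 1.
#' @param stay_length_range stay duration range in hours (minimum >= 24).
#' @param baseline_scr_range per-patient baseline creatinine range, mg/dL.
#' @param missingness probability that any scheduled measurement is not
#'   recorded (scalar, or named per variable). The first creatinine and
#'   urine-output records and the run-defining anchor measurements are
#'   always kept.
#' @param lab_schedule named mean inter-measurement gaps in hours for
#'   ancillary variables (default 12 h for labs, 1 h for heart rate).
#' @param signal_strength scalar >= 0 scaling how strongly pre-onset
#'   trajectories diverge between persistent and transient stays; 0 makes
#'   the classes exchangeable before `Tp + 12`.
#' @param oliguria_episode_prob probability of a benign oliguric episode
#'   (flow ~0.4-0.48 ml/kg/h for 12-18 h), identical across classes.
#' @param paired_patient_prob fraction of transient stays paired into
#'   two-stay patients (exercises the cross-stay baseline nadir rule).
#' @param seed integer seed; identical configurations generate identical
#'   cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_stays = 200,
                       class_mix = c(transient = 0.90, T72 = 0.08,
                                     D48 = 0.01, RRT24 = 0.01),
                       stay_length_range = c(160, 280),
                       baseline_scr_range = c(0.5, 1.3),
                       missingness = 0.1,
                       lab_schedule = NULL,
                       signal_strength = 1,
                       oliguria_episode_prob = 0.3,
                       paired_patient_prob = 0.05,
                       seed = 1) {
  if (!isTRUE(n_stays > 0)) stopf("n_stays must be positive")
  if (is.null(names(class_mix)) || !setequal(names(class_mix), PAKI3_CLASSES)) {
    class_mix <- setNames(as.numeric(class_mix), PAKI3_CLASSES[seq_along(class_mix)])
  }
  class_mix <- class_mix[PAKI3_CLASSES]
  class_mix[is.na(class_mix)] <- 0
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9) {
    stopf("class_mix components must be >= 0 and sum to 1")
  }
  if (stay_length_range[1] < 24) stopf("stay_length_range minimum must be >= 24 h")
  if (signal_strength < 0) stopf("signal_strength must be >= 0")
  mv <- setNames(rep(0.1, length(CANONICAL_VARS)), CANONICAL_VARS)
  if (length(missingness) == 1 && is.null(names(missingness))) {
    mv[] <- missingness
  } else {
    mv[names(missingness)] <- missingness
  }
  ls_ <- setNames(rep(12, length(ANC_VARS)), ANC_VARS)
  ls_["heart_rate"] <- 1
  if (!is.null(lab_schedule)) ls_[names(lab_schedule)] <- lab_schedule
  structure(list(n_stays = as.integer(n_stays), class_mix = class_mix,
                 stay_length_range = stay_length_range,
                 baseline_scr_range = baseline_scr_range,
                 missingness = mv, lab_schedule = ls_,
                 signal_strength = signal_strength,
                 oliguria_episode_prob = oliguria_episode_prob,
                 paired_patient_prob = paired_patient_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' High-missingness preset
#'
#' The default configuration with per-draw missingness raised to 0.4,
#' stressing robustness of the pipeline to sparse registries.
#'
#' @param ... passed to [sim_config()].
#' @export
sim_config_sparse <- function(...) sim_config(missingness = 0.4, ...)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

ramp01 <- function(x) clamp(x, 0, 1)

## Integer draw guarded against degenerate/reversed bounds.
rint <- function(lo, hi) if (hi <= lo) as.integer(lo) else sample(lo:hi, 1)

## One stay's event rows + metadata. All hours are integers.
simulate_stay <- function(sid, pid, cls, cfg, b) {
  L <- round(runif(1, cfg$stay_length_range[1], cfg$stay_length_range[2]))
  sig <- cfg$signal_strength
  ramp_dur <- rint(18, 30)
  lo <- ramp_dur + 14
  onset <- switch(cls,
    transient = rint(lo, min(100, L - 76)),
    T72       = rint(lo, min(100, L - 106)),
    D48       = rint(lo, min(100, L - 49)),
    RRT24     = rint(lo, min(100, L - 65)))
  run_len <- switch(cls,
    transient = rint(14, 40),
    T72       = rint(80, min(96, L - onset - 26)),
    D48       = 48L,
    RRT24     = NA_integer_)
  death_h <- if (cls == "D48") onset + 48 else NA_real_
  rrt_h <- if (cls == "RRT24") onset + 25 else NA_real_
  if (cls == "RRT24") L <- onset + 25 + rint(24, 40)
  grid_end <- if (!is.na(death_h)) death_h else L
  persistent <- cls != "transient"

  ## ---- creatinine schedule ----
  hold_end <- switch(cls, transient = onset + run_len, T72 = onset + run_len,
                     D48 = onset + 48, RRT24 = onset + 24)
  sched <- 0
  while (tail(sched, 1) < grid_end - 4) {
    gap <- if (tail(sched, 1) >= onset - ramp_dur && tail(sched, 1) < hold_end)
      rint(4, 6) else rint(4, 8)
    sched <- c(sched, tail(sched, 1) + gap)
  }
  sched <- sched[sched < grid_end]
  anchors <- c(onset, if (cls %in% c("transient", "T72")) onset + run_len)
  sched <- sort(unique(c(sched, anchors)))
  keep <- runif(length(sched)) >= cfg$missingness[["creatinine"]]
  keep[sched %in% anchors] <- TRUE
  keep[1] <- TRUE                      # admission labs are always drawn
  sched <- sched[keep]
  rec_vals <- c(2.4, 1.9, 1.5, 1.25, 1.1)
  scr_val <- vapply(sched, function(t) {
    if (t < onset - ramp_dur) {                       # baseline phase
      clamp(b * rnorm(1, 1.02, 0.04), 0.95 * b, 1.12 * b)
    } else if (t < onset) {                           # ramp
      f <- (t - (onset - ramp_dur)) / ramp_dur
      clamp(b * (1.1 + f * 1.5) + rnorm(1, 0, 0.08 * b), 1.0 * b, 2.75 * b)
    } else if (t < hold_end + 1 && (is.na(run_len) || t < onset + run_len)) {
      lvl <- 3.55 + 0.3 * sig * persistent            # plateau
      clamp(b * lvl + rnorm(1, 0, 0.08 * b), 3.45 * b, 8 * b)
    } else if (cls %in% c("transient", "T72")) {      # measured recovery
      k <- floor((t - (onset + run_len)) / 6) + 1
      v <- if (k <= length(rec_vals)) rec_vals[k] else NA
      if (is.na(v)) clamp(b * rnorm(1, 1.02, 0.04), 0.95 * b, 1.12 * b)
      else clamp(b * (v + rnorm(1, 0, 0.04)), 0.95 * b, 2.6 * b)
    } else {                                          # post-RRT decline
      clamp(b * (3.0 - 0.05 * (t - hold_end)), 0.95 * b, 8 * b)
    }
  }, numeric(1))

  ## ---- urine output: hourly latent flow -> irregular volume records ----
  base_flow <- runif(1, 0.8, 1.4)
  tt <- seq_len(grid_end) - 1L
  flow <- base_flow + rnorm(grid_end, 0, 0.1)
  if (persistent) {
    dec <- 0.3 * min(sig, 2) * ramp01((tt - (onset - 36)) / 36)
    flow <- flow * (1 - dec)
  }
  if (runif(1) < cfg$oliguria_episode_prob && grid_end > 40) {
    e0 <- rint(8, grid_end - 25)
    dur <- rint(12, 18)
    ep <- tt >= e0 & tt < e0 + dur
    flow[ep] <- runif(sum(ep), 0.40, 0.48)
  }
  flow <- clamp(flow, 0.38, 4)
  uo_t <- 0
  while (tail(uo_t, 1) < grid_end - 1) {
    uo_t <- c(uo_t, tail(uo_t, 1) + rint(1, 4))
  }
  uo_t <- uo_t[-1]
  uo_t <- uo_t[uo_t < grid_end]
  keep <- runif(length(uo_t)) >= cfg$missingness[["urine_output"]]
  if (length(keep)) keep[1] <- TRUE
  uo_t <- uo_t[keep]
  w <- round(rnorm(1, 80, 14))
  w <- clamp(w, 45, 140)
  ## urine accumulates across dropped recordings: each kept record carries
  ## the volume produced since the previous kept record
  cum_vol <- cumsum(flow) * w
  uo_vol <- cum_vol[uo_t] - c(0, cum_vol[head(uo_t, -1)])[seq_along(uo_t)]

  ## ---- ancillary variables ----
  anc <- list()
  for (j in seq_len(nrow(ANC_PARAMS))) {
    v <- ANC_PARAMS$name[j]
    gap_mean <- cfg$lab_schedule[[v]]
    t <- cumsum(pmax(1, round(runif(ceiling(grid_end / max(gap_mean * 0.5, 1)) + 2,
                                    gap_mean * 0.5, gap_mean * 1.5))))
    t <- c(1, t[t < grid_end])
    keep <- runif(length(t)) >= cfg$missingness[[v]]
    t <- t[keep]
    if (!length(t)) next
    drift <- if (persistent) {
      ANC_PARAMS$drift[j] * ANC_PARAMS$sd[j] * sig * ramp01((t - (onset - 48)) / 48)
    } else 0
    val <- ANC_PARAMS$mean[j] + drift + rnorm(length(t), 0, ANC_PARAMS$sd[j])
    anc[[v]] <- data.frame(hour = t, variable = v, value = val)
  }

  ev <- rbind(
    data.frame(hour = sched, variable = "creatinine", value = scr_val),
    data.frame(hour = uo_t, variable = "urine_output", value = uo_vol),
    if (!is.na(rrt_h)) data.frame(hour = rrt_h, variable = "rrt", value = 1),
    do.call(rbind, anc)
  )
  list(events = ev, L = L, onset = onset, death_h = death_h, weight = w,
       cls = cls, stay_id = sid, patient_id = pid)
}

#' Generate a synthetic ICU cohort
#'
#' @param config a [sim_config()].
#' @return A list of class `generated_cohort`: `events` (long event
#'   table), `statics` (per-stay static table), `truth` (intended
#'   `stay_id`, `class`, `Tp`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_stays
    cls <- sample(PAKI3_CLASSES, n, replace = TRUE, prob = config$class_mix)
    sid <- sprintf("s%04d", seq_len(n))
    pid <- sprintf("p%04d", seq_len(n))
    ## pair a fraction of transient stays into two-stay patients
    tr <- which(cls == "transient")
    n_pairs <- floor(min(config$paired_patient_prob * n, length(tr) / 2))
    if (n_pairs > 0) {
      picked <- sample(tr, 2 * n_pairs)
      for (q in seq_len(n_pairs)) {
        pid[picked[2 * q]] <- pid[picked[2 * q - 1]]
      }
    }
    b_pat <- setNames(runif(n, config$baseline_scr_range[1],
                            config$baseline_scr_range[2]), pid)
    epoch <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
    stays <- vector("list", n)
    for (k in seq_len(n)) {
      stays[[k]] <- simulate_stay(sid[k], pid[k], cls[k], config, b_pat[[pid[k]]])
    }
    ## admissions: sequential per patient, far apart across stays
    adm <- epoch + (seq_len(n) - 1) * 400 * 3600
    seen <- new.env()
    for (k in seq_len(n)) {
      p <- stays[[k]]$patient_id
      prior <- mget(p, envir = seen, ifnotfound = list(NULL))[[1]]
      if (!is.null(prior)) adm[k] <- prior + 48 * 3600   # after sibling stay
      assign(p, adm[k] + stays[[k]]$L * 3600, envir = seen)
    }
    ev_list <- vector("list", n)
    units_map <- setNames(variable_specs()$canonical_unit, CANONICAL_VARS)
    for (k in seq_len(n)) {
      s <- stays[[k]]
      u <- unname(units_map[s$events$variable])
      u[s$events$variable == "rrt"] <- ""
      ev_list[[k]] <- data.frame(
        stay_id = s$stay_id,
        time = adm[k] + s$events$hour * 3600,
        variable = s$events$variable, value = s$events$value,
        unit = u, stringsAsFactors = FALSE)
    }
    events <- as.data.frame(data.table::rbindlist(ev_list))
    statics <- data.frame(
      stay_id = sid, patient_id = pid,
      age = round(runif(n, 25, 85)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      height = round(runif(n, 155, 195)),
      weight = vapply(stays, function(s) s$weight, numeric(1)),
      admission_time = adm,
      discharge_time = adm + vapply(stays, function(s) s$L, numeric(1)) * 3600,
      death_time = adm + vapply(stays, function(s) s$death_h, numeric(1)) * 3600,
      admission_reason = sample(c("medical", "surgical", "sepsis", "trauma"),
                                n, replace = TRUE, prob = c(.5, .3, .15, .05)),
      ckd = runif(n) < 0.15,
      renal_transplant = FALSE,
      unit_type = sample(c("MICU", "SICU", "CCU"), n, replace = TRUE),
      ethnicity = sample(c("white", "black", "asian", "other"),
                         n, replace = TRUE, prob = c(.6, .2, .1, .1)),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      stay_id = sid, class = cls,
      Tp = ifelse(cls == "transient", NA_real_,
                  vapply(stays, function(s) s$onset, numeric(1))),
      stringsAsFactors = FALSE)
    structure(list(events = events, statics = statics, truth = truth,
                   config = config), class = "generated_cohort")
  })
}

#' Hand-parameterized single-stay fixtures
#'
#' Deterministic one-stay cohorts that trigger exactly one endpoint class
#' or exclusion rule; used as worked examples and test fixtures.
#'
#' @param template one of `transient`, `T72`, `D48`, `RRT24`,
#'   `excluded_demographic`, `excluded_imminence_death`,
#'   `excluded_imminence_rrt`, `excluded_oliguria_start`.
#' @return A `generated_cohort` with a single stay.
#' @export
worked_stay <- function(template = c("transient", "T72", "D48", "RRT24",
                                     "excluded_demographic",
                                     "excluded_imminence_death",
                                     "excluded_imminence_rrt",
                                     "excluded_oliguria_start")) {
  template <- match.arg(template)
  adm <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  w <- 80
  scr <- function(h, r) data.frame(hour = h, variable = "creatinine", value = r)
  uo_flow <- function(h, flow, gap = 2) {
    data.frame(hour = h, variable = "urine_output", value = flow * gap * w)
  }
  base_uo <- function(to, from = 2) uo_flow(seq(from, to, by = 2), 1.2)
  mk <- function(ev, L, death_h = NA, age = 60, Tp = NA, cls = NA) {
    ev <- ev[ev$hour < L | ev$variable == "rrt", ]
    events <- data.frame(stay_id = "w001", time = adm + ev$hour * 3600,
                         variable = ev$variable, value = ev$value,
                         unit = c(creatinine = "mg/dL", urine_output = "mL",
                                  rrt = "")[ev$variable],
                         stringsAsFactors = FALSE)
    statics <- data.frame(
      stay_id = "w001", patient_id = "wp01", age = age, sex = "F",
      height = 170, weight = w, admission_time = adm,
      discharge_time = adm + L * 3600,
      death_time = if (is.na(death_h)) as.POSIXct(NA) else adm + death_h * 3600,
      admission_reason = "medical", ckd = FALSE, renal_transplant = FALSE,
      unit_type = "MICU", ethnicity = "other", stringsAsFactors = FALSE)
    truth <- data.frame(stay_id = "w001", class = cls, Tp = Tp,
                        stringsAsFactors = FALSE)
    structure(list(events = events, statics = statics, truth = truth),
              class = "generated_cohort")
  }
  ramp <- scr(c(0, 6, 12, 18), c(1.0, 1.0, 1.6, 2.2))
  switch(template,
    transient = mk(rbind(ramp,
      scr(c(24, 30, 36, 42, 48), c(3.6, 3.7, 3.6, 3.7, 3.65)),
      scr(c(54, 60, 66, 72, 84), c(2.4, 1.6, 1.2, 1.0, 1.0)),
      base_uo(94)), L = 96, Tp = NA, cls = "transient"),
    T72 = mk(rbind(ramp,
      scr(seq(24, 102, by = 6), rep(c(3.6, 3.7), len = 14)),
      scr(c(104, 110, 116, 128), c(2.4, 1.6, 1.1, 1.0)),
      base_uo(138)), L = 140, Tp = 24, cls = "T72"),
    D48 = mk(rbind(ramp,
      scr(seq(24, 68, by = 6), rep(3.6, 8)),
      base_uo(70)), L = 120, death_h = 72, Tp = 24, cls = "D48"),
    RRT24 = mk(rbind(ramp,
      scr(seq(24, 48, by = 6), rep(3.6, 5)),
      data.frame(hour = 49, variable = "rrt", value = 1),
      scr(c(54, 66, 78), c(3.0, 2.2, 1.6)),
      base_uo(88)), L = 90, Tp = 24, cls = "RRT24"),
    excluded_demographic = mk(rbind(ramp,
      scr(c(24, 30, 36), c(3.6, 2.0, 1.2)),
      base_uo(70)), L = 72, age = 16),
    excluded_imminence_death = mk(rbind(ramp,
      scr(c(24, 30, 36, 42, 48), rep(3.6, 5)),
      base_uo(52)), L = 120, death_h = 54),
    excluded_imminence_rrt = mk(rbind(ramp,
      scr(c(24, 30), c(3.6, 3.7)),
      data.frame(hour = 34, variable = "rrt", value = 1),
      base_uo(58)), L = 60),
    excluded_oliguria_start = mk(rbind(
      scr(c(0, 12, 24, 30, 36, 48), c(1.0, 1.0, 2.2, 2.1, 1.2, 1.0)),
      uo_flow(1:10, 0.4, gap = 1),
      base_uo(70, from = 12)), L = 72)
  )
}
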