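## Severe-event detection, persistence endpoint, exclusion cascade and
## per-hour training labels.
##
## A severe AKI event is a maximal run of consecutive hours at stage 3.
## A run is truncated at the first RRT initiation: stage-3 hours forced by
## the RRT criterion alone never count towards event duration (the endpoint
## explicitly discounts stage 3 "solely attributed to RRT"), so the
## classifiable event is the organic stage-3 period preceding RRT.
##
## Endpoint classes, applied to each event in chronological order with
## precedence T72 > D48 > RRT24 (the 72-h rule is the primary endpoint):
##   T72   event lasted >= 72 h;
##   D48   event lasted >= 48 h and was terminated by death;
##   RRT24 event was terminated by RRT initiation after > 24 h.
## The first event meeting any rule fixes the class and Tp (its first hour);
## later episodes are not analyzed. Stays with no persistent event are
## transient unless an event was cut short by death, RRT or end of data, in
## which case the stay is excluded (imminence / ambiguity).

#' Detect severe (stage-3) AKI events
#'
#' @param stages [stage_hourly()] output for one stay.
#' @param rrt_start hour of first RRT initiation (NA for none).
#' @param died TRUE if the stay grid ends with death.
#' @return A data.frame of maximal stage-3 runs: `stay_id`, `start`, `end`
#'   (half-open hours), `length`, `terminated_by` in
#'   `{recovery, death, discharge, rrt}`. Runs lying entirely within the
#'   RRT period are not emitted (not classifiable).
#' @export
severe_events <- function(stages, rrt_start = NA, died = FALSE) {
  s3 <- stages$stage == 3L
  n <- length(s3)
  if (!n || !any(s3)) {
    return(data.frame(stay_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      terminated_by = character(), stringsAsFactors = FALSE))
  }
  d <- diff(c(FALSE, s3, FALSE))
  starts <- which(d == 1L) - 1L   # hours are 0-based
  ends <- which(d == -1L) - 1L
  rrt_h <- if (is.na(rrt_start)) Inf else floor(rrt_start)
  out <- list()
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- ends[i]
    if (a >= rrt_h) next                       # RRT-supported only
    term <- if (b >= rrt_h) "rrt" else NULL
    if (b > rrt_h) b <- rrt_h
    if (is.null(term)) {
      if (b >= n) {
        term <- if (died) "death" else "discharge"
      } else if (stages$evaluable[b + 1L]) {
        term <- "recovery"
      } else {
        ## staging gap: if any later hour is evaluable the event resolved,
        ## otherwise the data ran out under the gap
        nxt <- any(stages$evaluable[seq.int(b + 1L, n)])
        term <- if (nxt) "recovery" else if (died) "death" else "discharge"
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      stay_id = stages$stay_id[1], start = a, end = b, length = b - a,
      terminated_by = term, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(stay_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      terminated_by = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Classify persistence of one stay
#'
#' @param events severe events of the stay, see [severe_events()].
#' @param has_rrt TRUE if the stay received RRT at any point.
#' @return A list: `class` (`transient`, `T72`, `D48`, `RRT24`,
#'   or NA when excluded), `Tp` (first hour of the persistent event, NA for
#'   transient), `exclusion` (NULL, or `list(category, rule)` for stays
#'   whose outcome is not adjudicable).
#' @export
classify_persistence <- function(events, has_rrt = FALSE) {
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$length >= 72) {
        return(list(class = "T72", Tp = e$start, exclusion = NULL))
      }
      if (e$terminated_by == "death" && e$length >= 48) {
        return(list(class = "D48", Tp = e$start, exclusion = NULL))
      }
      if (e$terminated_by == "rrt" && e$length > 24) {
        return(list(class = "RRT24", Tp = e$start, exclusion = NULL))
      }
    }
    for (i in seq_len(nrow(events))) {
      term <- events$terminated_by[i]
      if (term == "death") {
        return(list(class = NA_character_, Tp = NA_real_, exclusion = list(
          category = "imminence", rule = "Death after less than 48 h of AKI stage 3")))
      }
      if (term == "rrt") {
        return(list(class = NA_character_, Tp = NA_real_, exclusion = list(
          category = "imminence", rule = "RRT after less than 24 h of AKI stage 3")))
      }
      if (term == "discharge") {
        return(list(class = NA_character_, Tp = NA_real_, exclusion = list(
          category = "ambiguity", rule = "No measurement till 72nd hour")))
      }
    }
  }
  if (has_rrt) {
    ## RRT given without a preceding organic stage-3 period
    return(list(class = NA_character_, Tp = NA_real_, exclusion = list(
      category = "imminence", rule = "RRT after less than 24 h of AKI stage 3")))
  }
  list(class = "transient", Tp = NA_real_, exclusion = NULL)
}

first_uo_band_check <- function(stages) {
  ## "Oliguria (no Anuria) at start of data": oliguric at the earliest hour
  ## where the 6-h band is evaluable AND that window reaches back to the
  ## start of the data (hour 5), so the oliguria onset is unobservable.
  i <- which(stages$hour == 5L)
  if (!length(i)) return(FALSE)
  isTRUE(stages$uo_stage[i] >= 1L) && !isTRUE(stages$uo_anuric[i])
}

#' Apply the inclusion/exclusion cascade
#'
#' Evaluates, in order, demographic, staging, imminence and ambiguity
#' exclusions; each excluded stay receives exactly one (first-matching)
#' rule. Demographic rules: age under 18, height outside 130-200 cm, renal
#' transplant at admission, missing sex/height/weight. Staging rules: under
#' 24 h of data, no concomitant creatinine and urine-output measurement in
#' the first 12 h, oliguria (without anuria) at the start of data, no hour
#' at AKI stage 2 or higher. Imminence and ambiguity rules come from
#' [classify_persistence()].
#'
#' @param statics per-stay static table.
#' @param stages cohort `stage_series`, see [stage_cohort()].
#' @param events standardized event table (for the concomitance check).
#' @param classifications named list of [classify_persistence()] results
#'   per stay.
#' @return A list: `included` (stay ids), `labels` (data.frame `stay_id`,
#'   `class`, `Tp` for included stays), `exclusions` (data.frame `stay_id`,
#'   `category`, `rule`).
#' @export
apply_exclusions <- function(statics, stages, events, classifications) {
  exc <- list()
  included <- character()
  labels <- list()
  st_idx <- split(seq_len(nrow(stages)), stages$stay_id)
  scr_ev <- events[events$variable == "creatinine", , drop = FALSE]
  uo_ev <- events[events$variable == "urine_output", , drop = FALSE]
  for (k in seq_len(nrow(statics))) {
    sid <- statics$stay_id[k]
    adm <- statics$admission_time[k]
    rule <- NULL; category <- NULL
    if (is.na(statics$sex[k]) || is.na(statics$height[k]) || is.na(statics$weight[k])) {
      category <- "demographic"; rule <- "Missing sex, height, or weight"
    } else if (!is.na(statics$age[k]) && statics$age[k] < 18) {
      category <- "demographic"; rule <- "Age < 18 years"
    } else if (statics$height[k] < 130 || statics$height[k] > 200) {
      category <- "demographic"; rule <- "Height < 130 cm and > 200 cm"
    } else if (isTRUE(statics$renal_transplant[k])) {
      category <- "demographic"; rule <- "Renal Transplant at admission"
    }
    ss <- stages[st_idx[[sid]], ]
    if (is.null(rule)) {
      h_scr <- hours_between(scr_ev$time[scr_ev$stay_id == sid], adm)
      h_uo <- hours_between(uo_ev$time[uo_ev$stay_id == sid], adm)
      if (nrow(ss) < 24L) {
        category <- "staging"; rule <- "Less than 24 h of data"
      } else if (!any(h_scr >= 0 & h_scr < 12) || !any(h_uo >= 0 & h_uo < 12)) {
        category <- "staging"; rule <- "No concomitant sCr and UO in first 12 h"
      } else if (first_uo_band_check(ss)) {
        category <- "staging"; rule <- "Oliguria (no Anuria) at start of data"
      } else if (!any(ss$stage >= 2L)) {
        category <- "staging"; rule <- "No hour at AKI stage 2 or 3"
      }
    }
    cl <- classifications[[sid]]
    if (is.null(rule) && !is.null(cl$exclusion)) {
      category <- cl$exclusion$category; rule <- cl$exclusion$rule
    }
    if (is.null(rule)) {
      included <- c(included, sid)
      labels[[length(labels) + 1L]] <- data.frame(
        stay_id = sid, class = cl$class, Tp = cl$Tp, stringsAsFactors = FALSE)
    } else {
      exc[[length(exc) + 1L]] <- data.frame(
        stay_id = sid, category = category, rule = rule, stringsAsFactors = FALSE)
    }
  }
  list(
    included = included,
    labels = if (length(labels)) do.call(rbind, labels) else
      data.frame(stay_id = character(), class = character(), Tp = numeric()),
    exclusions = if (length(exc)) do.call(rbind, exc) else
      data.frame(stay_id = character(), category = character(), rule = character())
  )
}

#' Per-hour training labels
#'
#' Emits one sample per hour at AKI stage 2 or 3. For persistent stays,
#' hours in `[Tp - window, Tp + 12]` are positive, hours before `Tp - window`
#' are dropped from training, and no sample exists after `Tp + 12`. For
#' transient stays every stage >= 2 hour is a negative sample.
#'
#' @param stages cohort `stage_series` (included stays).
#' @param labels data.frame `stay_id`, `class`, `Tp`.
#' @param window hours before Tp treated as positive (default 48).
#' @return data.frame `stay_id`, `hour`, `label` (0/1).
#' @export
label_samples <- function(stages, labels, window = 48) {
  if (!isTRUE(window > 0)) stopf("labeling window must be positive")
  st_idx <- split(seq_len(nrow(stages)), stages$stay_id)
  out <- vector("list", nrow(labels))
  for (k in seq_len(nrow(labels))) {
    sid <- labels$stay_id[k]
    ss <- stages[st_idx[[sid]], ]
    h <- ss$hour[ss$stage >= 2L]
    if (labels$class[k] == "transient") {
      lab <- rep(0L, length(h))
    } else {
      tp <- labels$Tp[k]
      h <- h[h >= tp - window & h <= tp + 12]
      lab <- rep(1L, length(h))
    }
    if (length(h)) {
      out[[k]] <- data.frame(stay_id = sid, hour = h, label = lab,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(stay_id = character(), hour = integer(),
                                      label = integer())
  rownames(res) <- NULL
  res
}

#' Run staging and labeling for a whole cohort
#'
#' Convenience wrapper chaining [baseline_scr()], [stage_cohort()],
#' [severe_events()], [classify_persistence()] and [apply_exclusions()].
#'
#' @param matrix an `hourly_matrix`.
#' @param events standardized event table.
#' @param statics per-stay static table.
#' @param use_rise see [stage_scr()].
#' @return A list: `stages`, `baselines`, `events_severe` (per-stay list),
#'   `labels`, `exclusions`, `included`, `rrt` (first-RRT hours).
#' @export
adjudicate_cohort <- function(matrix, events, statics, use_rise = TRUE) {
  baselines <- baseline_scr(events, statics)
  rrt <- rrt_start_hours(events, statics)
  stages <- stage_cohort(matrix, baselines, rrt, use_rise = use_rise)
  n_hours <- stay_grid_hours(statics)
  died <- if (is.null(statics$death_time)) rep(FALSE, nrow(statics)) else
    !is.na(statics$death_time) & statics$death_time <= statics$discharge_time
  st_idx <- split(seq_len(nrow(stages)), stages$stay_id)
  sev <- list(); cls <- list()
  for (k in seq_len(nrow(statics))) {
    sid <- statics$stay_id[k]
    ss <- stages[st_idx[[sid]], ]
    ev <- severe_events(ss, rrt_start = unname(rrt[sid]), died = died[k])
    sev[[sid]] <- ev
    cls[[sid]] <- classify_persistence(ev, has_rrt = !is.na(rrt[sid]))
    ## stays whose baseline could not be computed are not stageable
    if (is.na(baselines$bscr[baselines$stay_id == sid])) {
      cls[[sid]] <- list(class = NA_character_, Tp = NA_real_, exclusion = list(
        category = "staging", rule = "No qualifying baseline creatinine"))
    }
  }
  adj <- apply_exclusions(statics, stages, events, cls)
  c(list(stages = stages, baselines = baselines, events_severe = sev,
         rrt = rrt), adj)
}
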