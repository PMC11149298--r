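## Uniform hourly resampling of irregular event streams.
##
## Hour bins are half-open [t, t+1), anchored at ICU admission; a measurement
## at elapsed time tau belongs to bin floor(tau). A value is carried forward
## to hour t while the bin of its measurement lies within (t - max_gap, t].

#' Convert urine-output volumes to an hourly flow series
#'
#' Each recorded volume `V` at elapsed hour `tau`, with previous record at
#' `tau'` (admission for the first record), is spread uniformly over the hour
#' bins in `(tau', tau]`, giving a flow of `V / ((tau - tau') * weight)`
#' ml/kg/h. When the gap exceeds `max_gap` the volume is spread over the
#' trailing `max_gap` hours only and the intervening hours stay missing.
#'
#' @param times numeric vector of record times, hours since admission,
#'   increasing.
#' @param volumes recorded volumes in mL (same length as `times`).
#' @param weight patient weight in kg (> 0).
#' @param max_gap longest credited collection interval in hours.
#' @param n_hours number of hour bins in the stay grid.
#' @return A list with `flow` (ml/kg/h per hour, NA where uncovered) and
#'   `tsl` (hours since the last record, NA before the first).
#' @export
uo_to_flow <- function(times, volumes, weight, max_gap = 6, n_hours) {
  if (!isTRUE(weight > 0)) stopf("weight must be positive, got %s", format(weight))
  flow <- rep(NA_real_, n_hours)
  o <- order(times)
  times <- times[o]; volumes <- volumes[o]
  prev <- 0
  for (i in seq_along(times)) {
    tau <- times[i]
    gap <- tau - prev
    if (gap > 0 && tau >= 0) {
      credited <- min(gap, max_gap)
      rate <- volumes[i] / (credited * weight)
      first_bin <- floor(tau - credited) + 1
      bins <- seq.int(max(0, first_bin), min(floor(tau), n_hours - 1))
      if (length(bins) && bins[1] <= bins[length(bins)]) flow[bins + 1] <- rate
    }
    prev <- tau
  }
  tsl <- rep(NA_real_, n_hours)
  if (length(times)) {
    bin <- floor(times)
    last <- findInterval(seq_len(n_hours) - 1L, bin)
    has <- last > 0
    tsl[has] <- (seq_len(n_hours) - 1L)[has] - bin[last[has]]
  }
  list(flow = flow, tsl = tsl)
}

## Carried values, staleness and missingness for one variable in one stay.
carry_forward <- function(times, values, max_gap, n_hours) {
  val <- rep(NA_real_, n_hours)
  tsl <- rep(NA_real_, n_hours)
  if (length(times)) {
    bin <- floor(times)
    o <- order(bin)               # within-bin order preserved; later wins
    bin <- bin[o]; values <- values[o]
    keep <- !duplicated(bin, fromLast = TRUE)
    bin <- bin[keep]; values <- values[keep]
    t <- seq_len(n_hours) - 1L
    last <- findInterval(t, bin)
    has <- last > 0
    age <- rep(NA_real_, n_hours)
    age[has] <- t[has] - bin[last[has]]
    tsl <- age
    ok <- has & age < max_gap
    val[ok] <- values[last[ok]]
  }
  list(val = val, tsl = tsl)
}

stay_grid_hours <- function(statics) {
  end <- statics$discharge_time
  if ("death_time" %in% names(statics)) {
    dt <- statics$death_time
    end <- as.POSIXct(ifelse(!is.na(dt) & dt < end, dt, end),
                      origin = "1970-01-01", tz = "UTC")
  }
  n <- ceiling(hours_between(end, statics$admission_time))
  pmax(as.integer(n), 0L)
}

#' Resample irregular events to a uniform hourly grid
#'
#' Builds, per stay, an hour-indexed grid spanning admission to the earlier
#' of discharge and death. For every canonical variable the grid carries the
#' last measurement within its validity window (`max_gap`), the hours since
#' the last raw measurement (staleness), and a missingness flag. Urine
#' output is converted from recorded volumes to an hourly flow in ml/kg/h
#' via [uo_to_flow()].
#'
#' Duplicate `(stay, time, variable)` rows keep the last-loaded value.
#'
#' @param events standardized, plausibility-filtered event table.
#' @param statics per-stay static table (`stay_id`, `weight`,
#'   `admission_time`, `discharge_time`, optional `death_time`, ...).
#' @param specs variable specification table.
#' @return A `data.table` of class `hourly_matrix` keyed by
#'   `(stay_id, hour)` with, per variable `v`, columns `v` (carried value;
#'   flow for urine output), `v_tsl` and `v_miss`.
#' @export
resample_hourly <- function(events, statics, specs = variable_specs()) {
  check_event_table(events)
  events <- events[!duplicated(events[c("stay_id", "time", "variable")],
                               fromLast = TRUE), , drop = FALSE]
  n_hours <- stay_grid_hours(statics)
  ev <- data.table::as.data.table(events)
  out <- vector("list", nrow(statics))
  for (k in seq_len(nrow(statics))) {
    sid <- statics$stay_id[k]
    nh <- n_hours[k]
    if (nh < 1L) nh <- 0L
    g <- data.table::data.table(stay_id = sid, hour = seq_len(nh) - 1L)
    se <- ev[stay_id == sid]
    adm <- statics$admission_time[k]
    tau <- hours_between(se$time, adm)
    inside <- tau >= 0 & tau <= hours_between(statics$discharge_time[k], adm)
    se <- se[inside]; tau <- tau[inside]
    for (v in CANONICAL_VARS) {
      i <- which(se$variable == v)
      if (v == "urine_output") {
        uf <- uo_to_flow(tau[i], se$value[i], statics$weight[k],
                         max_gap = spec_row(specs, v)$max_gap, n_hours = nh)
        g[[v]] <- uf$flow
        g[[paste0(v, "_tsl")]] <- uf$tsl
        g[[paste0(v, "_miss")]] <- is.na(uf$flow)
      } else {
        cf <- carry_forward(tau[i], se$value[i],
                            spec_row(specs, v)$max_gap, nh)
        g[[v]] <- cf$val
        g[[paste0(v, "_tsl")]] <- cf$tsl
        g[[paste0(v, "_miss")]] <- is.na(cf$val)
      }
    }
    out[[k]] <- g
  }
  m <- data.table::rbindlist(out)
  data.table::setattr(m, "class", c("hourly_matrix", class(m)))
  data.table::setattr(m, "specs", specs)
  m
}

#' First renal replacement therapy initiation per stay, in grid hours
#'
#' @param events event table containing `rrt` marker rows.
#' @param statics per-stay static table.
#' @return Named numeric vector, hours since admission of the first RRT
#'   initiation (NA for stays without RRT).
#' @export
rrt_start_hours <- function(events, statics) {
  out <- setNames(rep(NA_real_, nrow(statics)), statics$stay_id)
  r <- events[events$variable == "rrt", , drop = FALSE]
  if (nrow(r)) {
    for (k in seq_len(nrow(statics))) {
      i <- which(r$stay_id == statics$stay_id[k])
      if (length(i)) {
        out[k] <- min(hours_between(r$time[i], statics$admission_time[k]))
      }
    }
  }
  out
}
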