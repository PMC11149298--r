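## Canonical variable vocabulary, units, plausibility limits and validity
## durations (Max_gap) for the thirteen model variables.

#' Default variable specifications
#'
#' Returns the specification table that drives unit standardization,
#' plausibility filtering and hourly resampling: one row per canonical
#' variable with its canonical unit, plausibility limits (in canonical
#' units) and validity duration `max_gap` in hours, i.e. how long a
#' measurement may be carried forward on the hourly grid.
#'
#' The shipped limits are broad physiologic ranges and the shipped
#' `max_gap` values (24 h for laboratory values, 8 h for heart rate, 6 h
#' for urine output) are package defaults chosen to be clinically
#' conservative; both are meant to be overridden per deployment, e.g. via
#' [read_variable_specs()].
#'
#' @return A data.frame with columns `name`, `canonical_unit`, `low`,
#'   `high`, `max_gap`, and an attribute `conversions`: a named list
#'   mapping, per variable, source unit name to the multiplicative factor
#'   into the canonical unit.
#' @export
#' @examples
#' variable_specs()
variable_specs <- function() {
  sp <- data.frame(
    name = CANONICAL_VARS,
    canonical_unit = c("mg/dL", "mL", "%", "g/dL", "mmol/L", "mg/dL",
                       "mmol/L", "mg/dL", "bpm", "10^3/uL", "mmol/L",
                       "mmol/L", "10^3/uL"),
    low  = c(0.1,    0,   5,   2,   5,   1,  60,  10,  10,   1, 1,  90, 0.1),
    high = c(20,  5000,  75,  25,  60, 300, 150, 2000, 300, 2000, 12, 200, 500),
    max_gap = c(24, 6, 24, 24, 24, 24, 24, 24, 8, 24, 24, 24, 24),
    stringsAsFactors = FALSE
  )
  attr(sp, "conversions") <- list(
    creatinine   = c("mg/dL" = 1, "umol/L" = 1 / 88.4),
    urine_output = c("mL" = 1, "L" = 1000),
    hematocrit   = c("%" = 1, "fraction" = 100),
    hemoglobin   = c("g/dL" = 1, "g/L" = 0.1, "mmol/L" = 1.611),
    bicarbonate  = c("mmol/L" = 1, "mEq/L" = 1),
    bun          = c("mg/dL" = 1, "mmol/L" = 2.801),
    chloride     = c("mmol/L" = 1, "mEq/L" = 1),
    glucose      = c("mg/dL" = 1, "mmol/L" = 18.016),
    heart_rate   = c("bpm" = 1),
    platelets    = c("10^3/uL" = 1, "10^9/L" = 1),
    potassium    = c("mmol/L" = 1, "mEq/L" = 1),
    sodium       = c("mmol/L" = 1, "mEq/L" = 1),
    wbc          = c("10^3/uL" = 1, "10^9/L" = 1)
  )
  class(sp) <- c("variable_specs", "data.frame")
  sp
}

#' Read variable specifications from a YAML file
#'
#' The file holds one entry per variable with fields `canonical_unit`,
#' `low`, `high`, `max_gap` and an optional `conversions` map
#' (unit -> factor). Entries not present fall back to [variable_specs()].
#'
#' @param path path to a YAML file.
#' @return A `variable_specs` data.frame, as [variable_specs()].
#' @export
read_variable_specs <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stopf("reading YAML variable specs requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  sp <- variable_specs()
  conv <- attr(sp, "conversions")
  for (nm in names(raw)) {
    if (!nm %in% sp$name) stopf("unknown variable '%s' in %s", nm, path)
    e <- raw[[nm]]
    i <- match(nm, sp$name)
    for (f in c("canonical_unit", "low", "high", "max_gap")) {
      if (!is.null(e[[f]])) sp[[f]][i] <- e[[f]]
    }
    if (!is.null(e$conversions)) conv[[nm]] <- unlist(e$conversions)
  }
  attr(sp, "conversions") <- conv
  sp
}

spec_row <- function(specs, var) {
  i <- match(var, specs$name)
  if (is.na(i)) stopf("variable '%s' is not in the specification table", var)
  specs[i, ]
}

check_event_table <- function(events) {
  need <- c("stay_id", "time", "variable", "value", "unit")
  miss <- setdiff(need, names(events))
  if (length(miss)) stopf("event table lacks column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(events$variable), c(CANONICAL_VARS, EVENT_MARKERS))
  if (length(bad)) stopf("unknown variable(s) in event table: %s", paste(bad, collapse = ", "))
  invisible(events)
}

#' Standardize measurement units
#'
#' Converts every event row to its variable's canonical unit using the
#' per-variable conversion maps attached to `specs`. Rows whose unit is not
#' in the map are dropped and reported in the `rejected` attribute rather
#' than silently discarded.
#'
#' @param events long-format event table (`stay_id`, `time`, `variable`,
#'   `value`, `unit`).
#' @param specs variable specification table, see [variable_specs()].
#' @return The event table with all values in canonical units; attribute
#'   `rejected` holds rows with unconvertible units (with a `reason` column).
#' @export
standardize_units <- function(events, specs = variable_specs()) {
  check_event_table(events)
  conv <- attr(specs, "conversions")
  factor <- rep(NA_real_, nrow(events))
  canon <- rep(NA_character_, nrow(events))
  is_marker <- events$variable %in% EVENT_MARKERS
  factor[is_marker] <- 1
  canon[is_marker] <- ""
  for (v in intersect(unique(events$variable), CANONICAL_VARS)) {
    i <- which(events$variable == v)
    map <- conv[[v]]
    factor[i] <- unname(map[events$unit[i]])
    canon[i] <- spec_row(specs, v)$canonical_unit
  }
  bad <- is.na(factor)
  rejected <- events[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "unknown unit"
  out <- events[!bad, , drop = FALSE]
  out$value <- out$value * factor[!bad]
  out$unit <- canon[!bad]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Filter implausible values
#'
#' Retains rows whose value lies within the variable's plausibility limits
#' (`low <= value <= high`, canonical units). Out-of-limits rows are never
#' silently dropped: they are returned in the `rejected` element with the
#' limit they violated.
#'
#' @param events standardized event table.
#' @param specs variable specification table.
#' @return A list with elements `events` (retained rows) and `rejected`
#'   (excluded rows, with a `reason` column).
#' @export
plausibility_filter <- function(events, specs = variable_specs()) {
  check_event_table(events)
  keep <- rep(TRUE, nrow(events))
  reason <- rep(NA_character_, nrow(events))
  for (v in intersect(unique(events$variable), CANONICAL_VARS)) {
    r <- spec_row(specs, v)
    i <- which(events$variable == v)
    bad <- is.na(events$value[i]) | events$value[i] < r$low | events$value[i] > r$high
    keep[i[bad]] <- FALSE
    reason[i[bad]] <- sprintf("outside [%g, %g] %s", r$low, r$high, r$canonical_unit)
  }
  rejected <- events[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  list(events = events[keep, , drop = FALSE], rejected = rejected)
}
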