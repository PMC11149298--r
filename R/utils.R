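## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Hours elapsed between two time points
#' @noRd
hours_between <- function(t, origin) {
  as.numeric(difftime(t, origin, units = "hours"))
}

## Run a block with a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## ---- rolling-window engine -------------------------------------------------
##
## All trailing-window statistics in the package run over hour-binned series.
## Stays are concatenated into one long vector separated by PAD_HOURS missing
## values, so a single vectorized pass serves the whole cohort without any
## window leaking across stay boundaries (PAD_HOURS >= the largest window).

## Concatenate per-stay vectors with NA padding. Returns the padded vector and
## the integer positions of the original entries.
pad_concat <- function(vecs) {
  ns <- lengths(vecs)
  total <- sum(ns) + PAD_HOURS * length(vecs)
  x <- rep(NA_real_, total)
  pos <- integer(sum(ns))
  at <- 0L
  filled <- 0L
  for (i in seq_along(vecs)) {
    at <- at + PAD_HOURS
    n <- ns[i]
    if (n > 0L) {
      x[(at + 1L):(at + n)] <- vecs[[i]]
      pos[(filled + 1L):(filled + n)] <- (at + 1L):(at + n)
      filled <- filled + n
    }
    at <- at + n
  }
  list(x = x, pos = pos)
}

## Trailing-window max of the PREVIOUS w entries ending at t (window (t-w, t]),
## skipping NA; NA where the window holds no observed value.  Built by
## shift/pmax doubling so cost is O(log w) vector passes.
roll_max <- function(x, w) {
  out <- x
  done <- 1L
  while (done < w) {
    step <- min(done, w - done)
    out <- pmax(out, data.table::shift(out, step), na.rm = TRUE)
    done <- done + step
  }
  out
}

roll_min <- function(x, w) -roll_max(-x, w)

## Trailing-window count of non-missing entries.
roll_n <- function(x, w) {
  n <- data.table::frollsum(as.numeric(!is.na(x)), w, na.rm = TRUE)
  n[is.na(n)] <- cumsum(!is.na(x))[is.na(n)]  # partial leading windows
  n
}

roll_mean <- function(x, w) {
  m <- data.table::frollmean(x, w, na.rm = TRUE)
  ## leading positions (< w entries seen) and all-NA windows
  m[is.nan(m)] <- NA_real_
  lead <- seq_len(min(w - 1L, length(x)))
  cs <- cumsum(ifelse(is.na(x[lead]), 0, x[lead]))
  cn <- cumsum(!is.na(x[lead]))
  m[lead] <- ifelse(cn > 0, cs / cn, NA_real_)
  m
}

roll_sum <- function(x, w) {
  s <- data.table::frollsum(x, w, na.rm = TRUE)
  lead <- seq_len(min(w - 1L, length(x)))
  s[lead] <- cumsum(ifelse(is.na(x[lead]), 0, x[lead]))
  s[roll_n(x, w) == 0] <- NA_real_
  s
}

## Trailing-window sample standard deviation (denominator n-1; NA for n < 2).
roll_sd <- function(x, w) {
  n <- roll_n(x, w)
  s1 <- roll_sum(x, w)
  s2 <- roll_sum(x * x, w)
  v <- (s2 - s1 * s1 / n) / (n - 1)
  out <- sqrt(pmax(v, 0))
  out[!is.finite(out) | n < 2] <- NA_real_
  out
}

## Last observed value within the trailing window (t-w, t].
roll_last <- function(x, w) {
  obs <- !is.na(x)
  pos <- cummax(ifelse(obs, seq_along(x), 0L))
  idx <- seq_along(x)
  ok <- pos > 0L & pos > idx - w
  out <- rep(NA_real_, length(x))
  out[ok] <- x[pos[ok]]
  out
}

roll_stat <- function(x, w, stat) {
  switch(stat,
    mean = roll_mean(x, w),
    min  = roll_min(x, w),
    max  = roll_max(x, w),
    std  = roll_sd(x, w),
    last = roll_last(x, w),
    stopf("unknown rolling statistic '%s'", stat)
  )
}
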