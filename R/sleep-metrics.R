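#' Call sleep bouts from a minute-binned count vector
#'
#' A sleep bout is a maximal run of consecutive zero-count minutes of length
#' at least `min_bout` (the canonical five-minute inactivity rule for
#' Drosophila beam-crossing data).  Runs are disjoint and returned in order.
#'
#' @param counts Non-negative integer vector of per-minute beam crossings.
#' @param min_bout Minimum run length, in minutes, to qualify as sleep.
#' @return data.frame with one row per bout: `start` (1-based minute index)
#'   and `length` (minutes).  Empty input gives a zero-row frame.
#' @export
#' @examples
#' call_sleep_bouts(c(3, 0, 0, 0, 0, 0, 2))   # one 5-min bout at minute 2
call_sleep_bouts <- function(counts, min_bout = 5L) {
  if (length(counts) == 0L)
    return(data.frame(start = integer(0), length = integer(0)))
  if (any(counts < 0)) stop("counts must be non-negative")
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Flag a fly as dead from terminal inactivity
#'
#' Deterministic stand-in for end-of-experiment visual inspection: a fly is
#' called dead iff the final `window` minutes of its record contain no beam
#' crossings.  Records shorter than `window` are flagged if entirely silent.
#'
#' @param counts Minute-count vector.
#' @param window Terminal window, minutes (default one full day).
#' @return Logical flag.
#' @export
detect_dead <- function(counts, window = 1440L) {
  n <- length(counts)
  if (n == 0L) return(TRUE)
  all(tail(counts, min(window, n)) == 0)
}

## Minute-level sleep indicator restricted to qualifying bouts.
sleep_indicator <- function(counts, min_bout = 5L) {
  asleep <- logical(length(counts))
  b <- call_sleep_bouts(counts, min_bout)
  if (nrow(b) > 0L)
    for (i in seq_len(nrow(b)))
      asleep[b$start[i]:(b$start[i] + b$length[i] - 1L)] <- TRUE
  asleep
}

#' Summarize one fly's record into the seven sleep traits
#'
#' The record must start at lights-on and span whole 24-h days; minutes
#' 1..720 of each day are the light phase, 721..1440 the dark phase.  Sleep
#' bouts are called on the full record (five-minute rule applied once);
#' bouts spanning a phase transition are split at the boundary and each
#' segment counts as one bout in its phase, without re-applying the
#' five-minute rule.  Per-phase sleep and bout counts are totals divided by
#' the number of days; average bout length is total phase sleep divided by
#' total phase bouts, so `phase sleep = bout_n x avg_bout_len` holds
#' exactly.  Waking activity is total counts over the whole record divided
#' by total non-sleeping minutes (NA if the fly never wakes).
#'
#' @param counts Minute-count vector, length a multiple of 1440.
#' @param min_bout Minimum sleep-bout length, minutes.
#' @param dead_window Terminal-inactivity window passed to [detect_dead()].
#' @return One-row data.frame: `night_sleep`, `day_sleep`, `night_bout_n`,
#'   `day_bout_n`, `night_avg_bout_len`, `day_avg_bout_len`,
#'   `waking_activity`, `n_days_used`, `dead`.
#' @export
summarize_fly <- function(counts, min_bout = 5L, dead_window = 1440L) {
  n <- length(counts)
  if (n == 0L || n %% .DAY_MIN != 0L)
    stop("record length must be a positive multiple of 1440 minutes")
  days <- n %/% .DAY_MIN
  asleep <- sleep_indicator(counts, min_bout)
  minute_in_day <- ((seq_len(n) - 1L) %% .DAY_MIN) + 1L
  is_day <- minute_in_day <= .PHASE_MIN
  ## phase windows index: each (day, phase) pair is one window; bout
  ## segments are maximal sleep runs within a window
  window_id <- (seq_len(n) - 1L) %/% .PHASE_MIN
  seg_start <- asleep & (c(TRUE, diff(window_id) != 0L) |
                           !c(FALSE, asleep[-n]))
  day_sleep_tot <- sum(asleep & is_day)
  night_sleep_tot <- sum(asleep & !is_day)
  day_bouts_tot <- sum(seg_start & is_day)
  night_bouts_tot <- sum(seg_start & !is_day)
  awake_min <- n - sum(asleep)
  data.frame(
    night_sleep = night_sleep_tot / days,
    day_sleep = day_sleep_tot / days,
    night_bout_n = night_bouts_tot / days,
    day_bout_n = day_bouts_tot / days,
    night_avg_bout_len = if (night_bouts_tot > 0)
      night_sleep_tot / night_bouts_tot else 0,
    day_avg_bout_len = if (day_bouts_tot > 0)
      day_sleep_tot / day_bouts_tot else 0,
    waking_activity = if (awake_min > 0) sum(counts) / awake_min else NA_real_,
    n_days_used = days,
    dead = detect_dead(counts, dead_window))
}

#' Summarize every fly in an activity set
#'
#' @param act A `sleepqg_activity` object ([simulate_activity()] /
#'   [read_dam_dir()]).
#' @param min_bout,dead_window As in [summarize_fly()].
#' @return data.frame: per-fly metadata columns followed by the
#'   [summarize_fly()] traits.
#' @export
summarize_activity <- function(act, min_bout = 5L, dead_window = 1440L) {
  stopifnot(inherits(act, "sleepqg_activity"))
  res <- do.call(rbind, lapply(seq_len(ncol(act$counts)), function(j)
    summarize_fly(act$counts[, j], min_bout, dead_window)))
  cbind(act$meta[, intersect(c("fly_id", "line", "sex", "block", "rep"),
                             names(act$meta)), drop = FALSE], res)
}

#' Build the long per-fly phenotype table from sleep summaries
#'
#' Dead flies are removed entirely; flies with undefined waking activity
#' contribute no waking-activity row.  Output is the unit of observation
#' for variance partitioning: one row per fly x trait.
#'
#' @param summaries Output of [summarize_activity()].
#' @return data.frame: `fly_id`, `line`, `sex`, `block`, `rep`, `trait`,
#'   `value`.  The number of dead flies removed is recorded in attribute
#'   `n_dead`.
#' @export
phenotype_table <- function(summaries) {
  alive <- summaries[!summaries$dead, , drop = FALSE]
  keys <- intersect(c("fly_id", "line", "sex", "block", "rep"),
                    names(alive))
  out <- do.call(rbind, lapply(SLEEP_TRAITS, function(tr) {
    d <- alive[, keys, drop = FALSE]
    d$trait <- tr
    d$value <- alive[[tr]]
    d[!is.na(d$value), , drop = FALSE]
  }))
  rownames(out) <- NULL
  attr(out, "n_dead") <- sum(summaries$dead)
  out
}

#' Coefficient of environmental variation of one replicate cell
#'
#' `CV_E = (sd / mean) x 100` over the flies of one line x sex x replicate,
#' with the sample (n-1) standard deviation as the within-replicate
#' environmental sigma_E.  Undefined (NA) for fewer than two values or a
#' non-positive mean.
#'
#' @param values Numeric trait values of one line x sex x replicate cell.
#' @return CV_E in percent, or NA when undefined.
#' @export
#' @examples
#' compute_cve(c(90, 100, 110))  # sd 10, mean 100 -> 10
compute_cve <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  100 * sd(values) / m
}

#' Per-cell CV_E table from a per-fly phenotype table
#'
#' Aggregates [compute_cve()] over every line x sex x replicate x trait
#' cell.  Cells where CV_E is undefined are dropped; their keys and the
#' reason are kept in attribute `dropped`.
#'
#' @param phenos Long phenotype table ([phenotype_table()] or
#'   `simulate_phenotypes()$phenos`).
#' @return data.frame: `line`, `sex`, `block`, `rep`, `trait`, `value`
#'   (CV_E, percent).
#' @export
cve_table <- function(phenos) {
  dt <- data.table::as.data.table(phenos)
  agg <- dt[, list(value = compute_cve(value), n = .N),
            by = c("line", "sex", "block", "rep", "trait")]
  agg <- as.data.frame(agg)
  bad <- is.na(agg$value)
  dropped <- agg[bad, c("line", "sex", "rep", "trait", "n"), drop = FALSE]
  if (nrow(dropped) > 0)
    dropped$reason <- ifelse(dropped$n < 2, "fewer than 2 flies",
                             "non-positive mean")
  out <- agg[!bad, c("line", "sex", "block", "rep", "trait", "value"),
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
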