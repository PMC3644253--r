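#' Simulate minute-binned activity streams from a sleep/wake Markov chain
#'
#' Each fly is a two-state (sleep/wake) Markov chain run at one-minute
#' resolution over `n_days` 24-h days starting at lights-on, with
#' phase-specific transition probabilities (`cfg$markov_rates`): minutes
#' 1..720 of each day are the light phase, minutes 721..1440 the dark phase.
#' Wake minutes carry `1 + Poisson(activity_lambda)` beam crossings; sleep
#' minutes carry 0.  A `dead_fraction` of flies dies at a uniform time at
#' least 24 h before the end of the record, producing an all-zero suffix
#' that [detect_dead()] must flag.
#'
#' @param cfg A [sim_config()].
#' @param flies Optional data.frame of flies to simulate (`line`, `sex`,
#'   `block`, `rep`, optionally `fly_id`); defaults to the full design grid
#'   of the config.
#' @param rates Optional per-fly transition-rate overrides: a data.frame
#'   with one row per fly and columns `night_p_sleep`, `night_p_wake`,
#'   `day_p_sleep`, `day_p_wake` (recycled from `cfg$markov_rates` when
#'   absent).  Probabilities are per minute: `p_sleep` = P(wake to sleep),
#'   `p_wake` = P(sleep to wake).
#' @return An object of class `sleepqg_activity`: list with `counts`
#'   (integer matrix, minutes x flies), `meta` (per-fly data.frame with
#'   channel assignment), `lights_on` (clock time, "08:00") and `n_days`.
#' @export
simulate_activity <- function(cfg, flies = NULL, rates = NULL) {
  validate_sim_config(cfg)
  set.seed(sub_seed(cfg, "activity"))
  if (is.null(flies)) {
    lb <- line_block_map(cfg)
    flies <- expand.grid(fly = seq_len(cfg$flies_per_sex_per_rep),
                         sex = c("M", "F"),
                         rep = seq_len(cfg$n_reps_per_block),
                         line = lb$line,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    flies$block <- lb$block[match(flies$line, lb$line)]
    flies$fly_id <- sprintf("%s_%s_r%d_f%d", flies$line, flies$sex,
                            flies$rep, flies$fly)
  }
  if (is.null(flies$fly_id))
    flies$fly_id <- sprintf("fly_%04d", seq_len(nrow(flies)))
  nf <- nrow(flies)
  total <- cfg$n_days * .DAY_MIN

  mr <- cfg$markov_rates
  p_sleep <- cbind(day = rep(mr$day[["p_sleep"]], nf),
                   night = rep(mr$night[["p_sleep"]], nf))
  p_wake <- cbind(day = rep(mr$day[["p_wake"]], nf),
                  night = rep(mr$night[["p_wake"]], nf))
  if (!is.null(rates)) {
    stopifnot(nrow(rates) == nf)
    for (nm in c("day_p_sleep", "night_p_sleep"))
      if (nm %in% names(rates))
        p_sleep[, sub("_p_sleep", "", nm)] <- rates[[nm]]
    for (nm in c("day_p_wake", "night_p_wake"))
      if (nm %in% names(rates))
        p_wake[, sub("_p_wake", "", nm)] <- rates[[nm]]
  }

  ## initial state from the day-phase stationary distribution (the record
  ## starts at lights-on); guard the all-absorbing corner cases
  denom <- p_sleep[, "day"] + p_wake[, "day"]
  pi_sleep <- ifelse(denom > 0, p_sleep[, "day"] / denom, 0)
  asleep <- runif(nf) < pi_sleep

  minute_in_day <- ((seq_len(total) - 1L) %% .DAY_MIN) + 1L
  phase <- ifelse(minute_in_day <= .PHASE_MIN, "day", "night")
  sleep_mat <- matrix(FALSE, total, nf)
  for (t in seq_len(total)) {
    ph <- phase[t]
    u <- runif(nf)
    asleep <- ifelse(asleep, u >= p_wake[, ph], u < p_sleep[, ph])
    sleep_mat[t, ] <- asleep
  }
  counts <- matrix(0L, total, nf)
  wake_idx <- which(!sleep_mat)
  counts[wake_idx] <- 1L + rpois(length(wake_idx), cfg$activity_lambda)

  if (cfg$dead_fraction > 0) {
    dead <- runif(nf) < cfg$dead_fraction
    if (any(dead)) {
      death_min <- sample(.DAY_MIN:(total - .DAY_MIN), sum(dead),
                          replace = TRUE)
      for (k in seq_along(which(dead)))
        counts[death_min[k]:total, which(dead)[k]] <- 0L
    }
  }

  meta <- flies
  meta$monitor <- sprintf("M%03d", ((seq_len(nf) - 1L) %/% 32L) + 1L)
  meta$channel <- ((seq_len(nf) - 1L) %% 32L) + 1L
  colnames(counts) <- meta$fly_id
  structure(list(counts = counts, meta = meta, lights_on = "08:00",
                 n_days = cfg$n_days),
            class = "sleepqg_activity")
}

#' @export
print.sleepqg_activity <- function(x, ...) {
  cat("sleepqg activity streams:", ncol(x$counts), "flies x",
      nrow(x$counts), "minutes (", x$n_days, "days )\n")
  invisible(x)
}

#' Write activity streams as DAM-dialect monitor files
#'
#' One tab-separated file per simulated monitor (up to 32 channels), in the
#' TriKinetics dialect: reading index, date, time, a status column, then one
#' count column per channel.  A `channel_map.tsv` sidecar records which fly
#' occupies each monitor/channel.
#'
#' @param act A `sleepqg_activity` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_dam_dir <- function(act, dir) {
  stopifnot(inherits(act, "sleepqg_activity"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  total <- nrow(act$counts)
  start <- as.POSIXct(paste("2026-01-05", act$lights_on), tz = "UTC")
  stamp <- start + (seq_len(total) - 1L) * 60
  date_col <- format(stamp, "%d %b %y")
  time_col <- format(stamp, "%H:%M:%S")
  files <- character(0)
  for (mon in unique(act$meta$monitor)) {
    sel <- act$meta$monitor == mon
    block <- act$counts[, sel, drop = FALSE]
    df <- data.frame(idx = seq_len(total), date = date_col, time = time_col,
                     status = 1L, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(block))
    f <- file.path(dir, paste0(mon, ".txt"))
    data.table::fwrite(df, f, sep = "\t", col.names = FALSE)
    files <- c(files, f)
  }
  map <- act$meta[, c("fly_id", "monitor", "channel",
                      intersect(c("line", "sex", "block", "rep"),
                                names(act$meta)))]
  data.table::fwrite(map, file.path(dir, "channel_map.tsv"), sep = "\t")
  writeLines(c(paste0("lights_on\t", act$lights_on),
               paste0("n_days\t", act$n_days)),
             file.path(dir, "recording_info.tsv"))
  invisible(c(files, file.path(dir, "channel_map.tsv")))
}

#' Read a directory of DAM-dialect monitor files
#'
#' Inverse of [write_dam_dir()].  Count columns start after `n_meta_cols`
#' leading columns (reading index, date, time, status by default).
#'
#' @param dir Directory containing `M*.txt` monitor files plus
#'   `channel_map.tsv` and `recording_info.tsv`.
#' @param n_meta_cols Number of leading non-count columns in monitor files.
#' @return A `sleepqg_activity` object.
#' @export
read_dam_dir <- function(dir, n_meta_cols = 4L) {
  map <- as.data.frame(data.table::fread(file.path(dir, "channel_map.tsv")))
  info <- read.delim(file.path(dir, "recording_info.tsv"), header = FALSE,
                     row.names = 1)
  lights_on <- as.character(info["lights_on", 1])
  n_days <- as.integer(info["n_days", 1])
  counts <- NULL
  ids <- character(0)
  for (mon in unique(map$monitor)) {
    raw <- as.data.frame(data.table::fread(file.path(dir,
                                                     paste0(mon, ".txt")),
                                           header = FALSE))
    cm <- map[map$monitor == mon, ]
    cols <- as.matrix(raw[, n_meta_cols + cm$channel, drop = FALSE])
    storage.mode(cols) <- "integer"
    counts <- cbind(counts, cols)
    ids <- c(ids, cm$fly_id)
  }
  colnames(counts) <- ids
  ## restore the channel-map fly ordering
  counts <- counts[, map$fly_id, drop = FALSE]
  structure(list(counts = counts, meta = map, lights_on = lights_on,
                 n_days = n_days),
            class = "sleepqg_activity")
}
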