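#' Replace spike artifacts in activity counts
#'
#' Implements the pooled six-sigma outlier rule: the mean and SD are
#' computed from the pooled non-zero per-minute counts across all flies
#' of the experiment, minutes with counts at least mean + `threshold_sd`
#' standard deviations above that pooled mean are treated as monitor
#' artifacts, and each is replaced by the average of the activity counts
#' in the minute preceding and the minute following the affected bin.
#' Replacements are kept as real numbers (no re-rounding). Edge minutes
#' use the single existing neighbor; consecutive artifact minutes use the
#' nearest non-artifact neighbor on each side.
#'
#' @param data Activity tibble with columns `fly_id` (or `channel`),
#'   `minute` and `count`.
#' @param threshold_sd Number of SDs above the pooled non-zero mean
#'   (default 6).
#' @return List with `data` (counts replaced, `count` numeric) and
#'   `log` (tibble: `fly_id`, `minute`, `original`, `replacement`) plus
#'   `threshold` (the count cutoff used).
#' @export
filter_artifacts <- function(data, threshold_sd = 6) {
  if (!"fly_id" %in% names(data) && "channel" %in% names(data))
    data$fly_id <- sprintf("fly_%02d", data$channel)
  stopifnot(all(c("fly_id", "minute", "count") %in% names(data)))
  nz <- data$count[data$count > 0]
  if (length(nz) < 3) abort("need at least 3 minutes of non-zero data")
  cutoff <- mean(nz) + threshold_sd * sd(nz)
  data <- arrange(data, .data$fly_id, .data$minute)
  logs <- list()
  out <- data
  out$count <- as.numeric(out$count)
  for (f in unique(data$fly_id)) {
    idx <- which(out$fly_id == f)
    x <- out$count[idx]
    is_out <- x >= cutoff
    if (!any(is_out)) next
    pos <- which(is_out)
    repl <- numeric(length(pos))
    ok <- which(!is_out)
    for (i in seq_along(pos)) {
      left <- ok[ok < pos[i]]
      right <- ok[ok > pos[i]]
      lv <- if (length(left)) x[max(left)] else NULL
      rv <- if (length(right)) x[min(right)] else NULL
      repl[i] <- mean(c(lv, rv))
    }
    logs[[f]] <- tibble(fly_id = f, minute = out$minute[idx][pos],
                        original = x[pos], replacement = repl)
    out$count[idx[pos]] <- repl
  }
  list(data = out,
       log = if (length(logs)) bind_rows(logs) else
         tibble(fly_id = character(0), minute = integer(0),
                original = numeric(0), replacement = numeric(0)),
       threshold = cutoff)
}

#' Score sleep from a minute-binned count vector
#'
#' Applies the 5-minute inactivity definition of fly sleep: every maximal
#' run of zero counts lasting at least `min_bout` minutes is sleep in its
#' entirety; shorter zero-runs are wake. A pure function of the
#' zero/non-zero pattern.
#'
#' @param counts Numeric vector of per-minute counts.
#' @param min_bout Minimum zero-run length scored as sleep (default 5).
#' @return List with `sleep` (logical vector, same length) and `bouts`
#'   (tibble: `start`, `length`).
#' @examples
#' score_sleep(c(1, rep(0, 10), 1, rep(0, 5), 1))$bouts
#' @export
score_sleep <- function(counts, min_bout = 5) {
  z <- counts == 0
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout
  sleep <- logical(length(counts))
  for (i in which(keep)) sleep[starts[i]:ends[i]] <- TRUE
  list(sleep = sleep,
       bouts = tibble(start = starts[keep], length = r$lengths[keep]))
}

#' Per-fly, per-day sleep and activity summaries
#'
#' Scores sleep over the analysis window (the first `days` full days) and
#' summarises each fly-day: total/day/night sleep minutes, bout count and
#' mean bout length (bouts attributed to their start day), total activity
#' counts and waking activity (counts per waking minute; missing for an
#' all-sleep day). Day is the 12 h from lights-on; under DD the lights-on
#' hour of prior entrainment is carried forward as subjective day. Flies
#' with zero counts over the final 24 h of the window are presumed dead
#' and excluded (listed in the `excluded_flies` attribute).
#'
#' @param data Activity tibble (`fly_id`, `minute`, `count`), minute 1 =
#'   midnight of day 1.
#' @param schedule List with `mode` ("LD"/"DD") and `lights_on` hour.
#' @param days Number of full days to analyse (default: all full days).
#' @param min_bout Sleep definition (default 5 minutes).
#' @param exclude_dead Drop presumed-dead flies (default TRUE).
#' @return Tibble with one row per fly-day plus the columns above;
#'   attributes `excluded_flies` and `window_days`.
#' @export
summarize_sleep <- function(data, schedule = list(mode = "LD", lights_on = 0),
                            days = NULL, min_bout = 5,
                            exclude_dead = TRUE) {
  stopifnot(all(c("fly_id", "minute", "count") %in% names(data)))
  n_min_all <- max(data$minute)
  full_days <- n_min_all %/% 1440L
  if (is.null(days)) days <- full_days
  if (days < 1 || full_days < days) abort("window contains no such full days")
  n_min <- days * 1440L
  data <- data[data$minute <= n_min, , drop = FALSE] |>
    arrange(.data$fly_id, .data$minute)
  hour <- ((seq_len(n_min) - 1) %/% 60) %% 24
  is_day_min <- ((hour - schedule$lights_on) %% 24) < 12

  excluded <- character(0)
  out <- list()
  for (f in unique(data$fly_id)) {
    x <- data$count[data$fly_id == f]
    if (exclude_dead && sum(x[(n_min - 1439L):n_min]) == 0) {
      excluded <- c(excluded, f)
      next
    }
    sc <- score_sleep(x, min_bout)
    day_of <- (seq_len(n_min) - 1L) %/% 1440L + 1L
    bout_day <- (sc$bouts$start - 1L) %/% 1440L + 1L
    for (d in seq_len(days)) {
      in_d <- day_of == d
      sl <- sc$sleep[in_d]
      waking_min <- sum(!sl)
      tot_act <- sum(x[in_d])
      bd <- bout_day == d
      out[[length(out) + 1]] <- tibble(
        fly_id = f, day = d,
        total_sleep = sum(sl),
        day_sleep = sum(sl & is_day_min[in_d]),
        night_sleep = sum(sl & !is_day_min[in_d]),
        bout_count = sum(bd),
        mean_bout_length = if (any(bd)) mean(sc$bouts$length[bd])
          else NA_real_,
        total_activity = tot_act,
        waking_activity = if (waking_min > 0) tot_act / waking_min
          else NA_real_)
    }
  }
  res <- bind_rows(out)
  attr(res, "excluded_flies") <- excluded
  attr(res, "window_days") <- days
  attr(res, "schedule") <- schedule
  res
}

#' FFT rhythm power of an activity record
#'
#' Mean-subtracts the minute-binned series, computes the discrete-Fourier
#' periodogram, and reports the power at the frequency bin nearest a 24-h
#' period together with the peak in the 18-30 h circadian band. Power is
#' normalized to the total power over all positive-frequency bins, so
#' values are fractions of variance in \[0, 1\]. A record is called
#' rhythmic when the 24-h normalized power reaches `threshold`.
#'
#' @param counts Minute-binned count vector covering at least 3 full days.
#' @param threshold Rhythmicity threshold on normalized 24-h power
#'   (default 0.01).
#' @param band Period band searched for the peak, hours (default 18-30).
#' @return One-row tibble: `peak_period`, `peak_power`, `power_24`,
#'   `rhythmic`, `n_minutes`.
#' @export
fft_rhythm_power <- function(counts, threshold = 0.01, band = c(18, 30)) {
  n <- length(counts)
  if (n < 3 * 1440) abort("need at least 3 days of minute data")
  if (all(counts == 0))
    return(tibble(peak_period = NA_real_, peak_power = 0, power_24 = 0,
                  rhythmic = FALSE, n_minutes = n))
  x <- counts - mean(counts)
  spec <- Mod(fft(x))^2
  k <- seq_len(floor(n / 2))          # positive frequencies
  pw <- spec[k + 1]
  total <- sum(pw)
  period_h <- n / (k * 60)
  in_band <- period_h >= band[1] & period_h <= band[2]
  norm <- pw / total
  k24 <- which.min(abs(period_h - 24))
  peak <- which(in_band)[which.max(norm[in_band])]
  tibble(peak_period = period_h[peak],
         peak_power = norm[peak],
         power_24 = norm[k24],
         rhythmic = norm[k24] >= threshold,
         n_minutes = n)
}
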