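#' Configuration for synthetic activity-monitor data
#'
#' Minute-binned beam-crossing counts for a 32-channel monitor:
#' per minute a fly is active with a time-of-day-modulated probability
#' (Bernoulli) and, if active, registers 1 + Poisson(counts_rate - 1)
#' crossings, so active minutes are never zero and the mean count per
#' active minute equals `counts_rate`. Night inactivity produces the
#' zero-runs that downstream sleep scoring consumes; the default night
#' activity probability is `1 / sleep_bout_mean_min`, giving geometric
#' zero-runs with that mean. Rare spike artifacts (isolated minutes with
#' counts far above the activity scale) are injected at known positions.
#'
#' @param n_flies Number of flies (channels used), at most 32 per monitor.
#' @param days Number of full days (>= 1).
#' @param schedule List with `mode` ("LD" or "DD") and `lights_on` hour;
#'   under DD the lights-on hour marks subjective day carried forward from
#'   entrainment.
#' @param mean_active_prob_day,mean_active_prob_night Activity
#'   probabilities per minute; night defaults to `1/sleep_bout_mean_min`.
#' @param counts_rate Mean counts per active minute (>= 1).
#' @param sleep_bout_mean_min Target mean nighttime zero-run length.
#' @param artifact_rate Expected spikes per fly-day.
#' @param artifact_magnitude Spike size as a multiple of `counts_rate`
#'   (> 1).
#' @param seed Integer seed.
#' @return List of class `activity_sim_config`.
#' @export
activity_sim_config <- function(n_flies = 32, days = 5,
                                schedule = list(mode = "LD", lights_on = 0),
                                mean_active_prob_day = 0.5,
                                mean_active_prob_night = NULL,
                                counts_rate = 2,
                                sleep_bout_mean_min = 20,
                                artifact_rate = 0.5,
                                artifact_magnitude = 30,
                                seed = 1L) {
  if (is.null(mean_active_prob_night))
    mean_active_prob_night <- 1 / sleep_bout_mean_min
  if (days < 1) abort("days must be >= 1")
  if (n_flies < 1 || n_flies > 32) abort("n_flies must be in 1..32")
  probs <- c(mean_active_prob_day, mean_active_prob_night)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (counts_rate < 1) abort("counts_rate must be >= 1")
  if (artifact_magnitude <= 1) abort("artifact_magnitude must be > 1")
  stopifnot(schedule$mode %in% c("LD", "DD"))
  structure(list(n_flies = n_flies, days = days, schedule = schedule,
                 mean_active_prob_day = mean_active_prob_day,
                 mean_active_prob_night = mean_active_prob_night,
                 counts_rate = counts_rate,
                 sleep_bout_mean_min = sleep_bout_mean_min,
                 artifact_rate = artifact_rate,
                 artifact_magnitude = artifact_magnitude,
                 seed = as.integer(seed)),
            class = "activity_sim_config")
}

#' Simulate minute-binned fly activity with known artifact positions
#'
#' @param config An [activity_sim_config()].
#' @return List of class `activity_sim` with `data` (tibble: `fly_id`,
#'   `channel`, `minute` (1-based from midnight of day 1), `count`),
#'   `truth` (tibble of injected artifact minutes per fly) and `config`.
#' @export
simulate_activity <- function(config) {
  stopifnot(inherits(config, "activity_sim_config"))
  n_min <- config$days * 1440L
  minute <- seq_len(n_min)
  hour <- ((minute - 1) %/% 60) %% 24
  # day = 12 h from lights-on (subjective day under DD)
  is_day <- ((hour - config$schedule$lights_on) %% 24) < 12
  p <- ifelse(is_day, config$mean_active_prob_day,
              config$mean_active_prob_night)
  with_local_seed(config$seed, {
    rows <- vector("list", config$n_flies)
    art <- vector("list", config$n_flies)
    for (f in seq_len(config$n_flies)) {
      active <- rbinom(n_min, 1, p)
      counts <- active * (1 + rpois(n_min, config$counts_rate - 1))
      n_art <- rpois(1, config$artifact_rate * config$days)
      pos <- integer(0)
      if (n_art > 0) {
        cand <- sample(2:(n_min - 1), min(n_art, n_min - 2))
        # keep spikes isolated so adjacent-minute replacement is well posed
        keep <- !logical(length(cand))
        for (i in seq_along(cand)) {
          if (any(abs(cand[i] - cand[seq_len(i - 1)][keep[seq_len(i - 1)]])
                  <= 1)) keep[i] <- FALSE
        }
        pos <- sort(cand[keep])
        counts[pos] <- as.integer(ceiling(config$artifact_magnitude *
                                            config$counts_rate))
      }
      fid <- sprintf("fly_%02d", f)
      rows[[f]] <- tibble(fly_id = fid, channel = f, minute = minute,
                          count = as.integer(counts))
      art[[f]] <- if (length(pos)) tibble(fly_id = fid, minute = pos)
        else tibble(fly_id = character(0), minute = integer(0))
    }
    structure(list(data = bind_rows(rows), truth = bind_rows(art),
                   config = config),
              class = "activity_sim")
  })
}
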