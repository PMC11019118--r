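#' Run the omics analysis pipeline end to end
#'
#' Simulate (or load) a time course, export the unit-variance-scaled
#' matrix for heatmap display, run the JTK rhythm screen per group,
#' summarise the overlap of significant sets, and judge an OPLS
#' time-of-day model per group. All outputs are written with fixed
#' numeric formatting and listed, with md5 checksums, in
#' `manifest.csv`; a run is byte-identical given the same config and
#' seed.
#'
#' @param config List with elements `omics` (an [omics_sim_config()]) or
#'   `input`/`meta` (paths to the TSV dialect), `q_threshold` (default
#'   0.2), `alpha` (default 0.05), `max_ortho` (default 3).
#' @param out_dir Output directory (created if needed).
#' @return List of class `report_bundle`: `screens`, `overlap`,
#'   `opls`, `manifest`, `files`.
#' @export
run_omics_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  q_thr <- config$q_threshold %||% 0.2
  alpha <- config$alpha %||% 0.05
  max_ortho <- config$max_ortho %||% 3

  if (!is.null(config$omics)) {
    sim <- simulate_omics(config$omics)
    data <- sim$data
    truth <- sim$truth
  } else if (!is.null(config$input)) {
    data <- read_timecourse(config$input, config$meta)
    truth <- NULL
  } else abort("omics pipeline: no input source in config")

  files <- character(0)
  tc <- file.path(out_dir, "timecourse.tsv")
  write_timecourse(data, tc)
  files <- c(files, tc, sub("\\.tsv$", "_meta.tsv", tc))

  scaled <- zscale_features(data)
  sm <- file.path(out_dir, "scaled_matrix.tsv")
  write_timecourse(scaled, sm)
  files <- c(files, sm, sub("\\.tsv$", "_meta.tsv", sm))

  groups <- unique(data$group)
  screens <- list(); verdicts <- list()
  for (g in groups) {
    sc <- jtk_screen(data, group = g, q_threshold = q_thr)
    screens[[g]] <- sc
    f <- file.path(out_dir, paste0("screen_", g, ".tsv"))
    write_screen_tsv(sc, f); files <- c(files, f)
    verdicts[[g]] <- opls_significance(data, group = g, alpha = alpha,
                                       max_ortho = max_ortho)
    vf <- file.path(out_dir, paste0("opls_", g, ".json"))
    v <- verdicts[[g]]
    write_json_stable(list(
      group = g, significant = v$significant, n_ortho = v$n_ortho,
      R2Y = v$model$R2Y, Q2cum = v$Q2cum,
      cv_anova = as.list(v$anova),
      scores = list(LV1 = round(v$model$t, 9),
                    LVo1 = if (v$n_ortho > 0)
                      round(v$model$T_o[, 1], 9) else NULL)), vf)
    files <- c(files, vf)
  }

  overlap <- NULL
  if (length(groups) == 2) {
    overlap <- overlap_summary(screens[[1]], screens[[2]])
    of <- file.path(out_dir, "overlap.json")
    write_json_stable(list(groups = groups,
                           only_a = overlap$only_a,
                           shared = overlap$shared,
                           only_b = overlap$only_b,
                           counts = as.list(overlap$counts)), of)
    files <- c(files, of)
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- purrr::map_dfr(groups, function(g) {
      tr <- truth[truth$group == g, ]
      sig <- screens[[g]]$feature_id[screens[[g]]$significant]
      rh <- tr$feature_id[tr$rhythmic]
      tibble(group = g,
             sensitivity = if (length(rh)) mean(rh %in% sig) else NA_real_,
             fdr = if (length(sig)) mean(!sig %in% rh) else 0,
             n_called = length(sig))
    })
    rf <- file.path(out_dir, "screen_recovery.csv")
    readr::write_csv(mutate(recovery, across(c("sensitivity", "fdr"),
                                             fmt_num)),
                     rf, progress = FALSE)
    files <- c(files, rf)
  }

  manifest <- write_manifest(files, out_dir, extra = list(
    stage = "omics", q_threshold = q_thr, alpha = alpha,
    max_ortho = max_ortho,
    seed = if (!is.null(config$omics)) config$omics$seed else NA,
    version = as.character(utils::packageVersion("chronoscreen"))))

  structure(list(screens = screens, overlap = overlap, opls = verdicts,
                 recovery = recovery, manifest = manifest,
                 files = c(files, file.path(out_dir, "manifest.csv"))),
            class = "report_bundle")
}

#' Run the behavioral analysis pipeline end to end
#'
#' Simulate (or read) per-genotype activity monitor data, filter spike
#' artifacts with the pooled six-sigma rule, score sleep by the 5-minute
#' definition, summarise per fly, compute FFT rhythm power, and compare
#' the experimental genotype against both controls on total sleep.
#' Outputs and checksums mirror [run_omics_pipeline()].
#'
#' @param config List with `sim` (named list of [activity_sim_config()]
#'   per genotype) or `dam_files` (named vector of DAM2 paths per
#'   genotype); `schedule` (list `mode`, `lights_on`); `days`;
#'   `controls` (two labels); `experimental` (label).
#' @param out_dir Output directory.
#' @return List of class `report_bundle`: `sleep`, `rhythm`,
#'   `comparison`, `artifact_log`, `manifest`, `files`.
#' @export
run_behavior_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- config$schedule %||% list(mode = "LD", lights_on = 0)
  days <- config$days %||% 5

  if (!is.null(config$sim)) {
    raw <- purrr::imap_dfr(config$sim, function(cf, g) {
      simulate_activity(cf)$data |>
        mutate(genotype = g, fly_id = paste0(g, "_", .data$fly_id))
    })
  } else if (!is.null(config$dam_files)) {
    raw <- purrr::imap_dfr(config$dam_files, function(p, g) {
      read_dam(p) |>
        filter(.data$status_ok) |>
        mutate(genotype = g,
               fly_id = sprintf("%s_fly_%02d", g, .data$channel)) |>
        select("fly_id", "channel", "minute", "count", "genotype")
    })
  } else abort("behavior pipeline: no input source in config")

  flt <- filter_artifacts(raw)
  genos <- distinct(raw, .data$fly_id, .data$genotype)

  sleep <- summarize_sleep(flt$data, schedule = schedule, days = days) |>
    left_join(genos, by = "fly_id")
  per_fly <- sleep |>
    group_by(.data$fly_id, .data$genotype) |>
    summarise(total_sleep = mean(.data$total_sleep),
              total_activity = mean(.data$total_activity),
              waking_activity = mean(.data$waking_activity, na.rm = TRUE),
              .groups = "drop")

  rhythm <- flt$data |>
    group_by(.data$fly_id) |>
    dplyr::group_modify(~ fft_rhythm_power(.x$count)) |>
    ungroup() |>
    left_join(genos, by = "fly_id")

  comparison <- NULL
  if (!is.null(config$controls)) {
    comparison <- compare_groups(per_fly, value = "total_sleep",
                                 group = "genotype",
                                 design = "multi_group",
                                 controls = config$controls,
                                 experimental = config$experimental)
  }

  files <- character(0)
  sf <- file.path(out_dir, "sleep_summary.csv")
  readr::write_csv(mutate(sleep, across(c("mean_bout_length",
                                          "waking_activity"), fmt_num)),
                   sf, progress = FALSE)
  pf <- file.path(out_dir, "per_fly_summary.csv")
  readr::write_csv(mutate(per_fly, across(c("total_sleep",
                                            "total_activity",
                                            "waking_activity"), fmt_num)),
                   pf, progress = FALSE)
  af <- file.path(out_dir, "artifact_log.csv")
  readr::write_csv(mutate(flt$log, across(c("original", "replacement"),
                                          fmt_num)), af, progress = FALSE)
  rf <- file.path(out_dir, "rhythm_power.csv")
  readr::write_csv(mutate(rhythm, across(c("peak_period", "peak_power",
                                           "power_24"), fmt_num)),
                   rf, progress = FALSE)
  files <- c(files, sf, pf, af, rf)
  if (!is.null(comparison)) {
    cf <- file.path(out_dir, "comparison.json")
    write_json_stable(list(
      test_used = comparison$test_used,
      pairwise = comparison$pairwise,
      both_controls_significant = comparison$both_controls_significant),
      cf)
    files <- c(files, cf)
  }

  manifest <- write_manifest(files, out_dir, extra = list(
    stage = "behavior", days = days, schedule = schedule,
    controls = config$controls,
    artifact_threshold = flt$threshold,
    version = as.character(utils::packageVersion("chronoscreen"))))

  structure(list(sleep = sleep, per_fly = per_fly, rhythm = rhythm,
                 comparison = comparison, artifact_log = flt$log,
                 manifest = manifest,
                 files = c(files, file.path(out_dir, "manifest.csv"))),
            class = "report_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
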