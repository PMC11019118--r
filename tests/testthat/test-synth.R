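test_that("default omics simulation matches the study design shape", {
  sim <- simulate_omics(omics_sim_config(seed = 1))
  expect_s3_class(sim, "omics_sim")
  expect_equal(length(unique(sim$data$feature_id)), 159)
  expect_equal(nrow(sim$data), 159 * 6 * (5 + 4))
  expect_setequal(unique(sim$data$group), c("young", "old"))
  expect_setequal(unique(sim$data$zt), c(0, 4, 8, 12, 16, 20))
  expect_true(all(sim$data$value > 0))
  # 17 rhythmic per group, 4 shared
  ty <- sim$truth[sim$truth$group == "young" & sim$truth$rhythmic, ]
  to <- sim$truth[sim$truth$group == "old" & sim$truth$rhythmic, ]
  expect_equal(nrow(ty), 17)
  expect_equal(nrow(to), 17)
  expect_equal(length(intersect(ty$feature_id, to$feature_id)), 4)
})

test_that("all four generators are deterministic given their seed", {
  oc <- tiny_omics(seed = 5, n_features = 8)
  expect_identical(simulate_omics(oc)$data, simulate_omics(oc)$data)
  ac <- activity_sim_config(n_flies = 3, days = 1, seed = 5)
  expect_identical(simulate_activity(ac)$data, simulate_activity(ac)$data)
  ic <- imaging_sim_config(n_brains = 2, seed = 5)
  expect_identical(simulate_roi_table(ic)$data, simulate_roi_table(ic)$data)
  s1 <- simulate_rogfp_stack(ic, seed = 7)
  s2 <- simulate_rogfp_stack(ic, seed = 7)
  expect_identical(s1$ch405, s2$ch405)
  expect_identical(s1$mask, s2$mask)
  # and they do not disturb the caller's RNG stream
  set.seed(77); before <- rnorm(3)
  set.seed(77); invisible(simulate_omics(oc)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("in the noiseless limit values follow the cosine model exactly", {
  cfg <- tiny_omics(seed = 2, n_features = 6, n_rhythmic = 2,
                    amplitude = 0.5, cv = 1e-12)
  sim <- simulate_omics(cfg)
  tr <- sim$truth
  d <- left_join(sim$data, tr, by = c("feature_id", "group"))
  expected <- d$baseline *
    (1 + d$amplitude_rel *
       cos(2 * pi * (d$zt - ifelse(is.na(d$phase_hours), 0,
                                   d$phase_hours)) / 24))
  expect_equal(d$value, expected, tolerance = 1e-9)
  # flat features sit exactly at baseline
  flat <- d[!d$rhythmic, ]
  expect_equal(flat$value, flat$baseline, tolerance = 1e-9)
})

test_that("the old group is noisier and flatter than the young group", {
  cfg <- omics_sim_config(n_features = 30, seed = 10,
    reps_per_group = c(young = 5, old = 5),
    rhythmic_sets = list(young = sprintf("met_%03d", 1:10),
                         old = sprintf("met_%03d", 1:10)),
    amplitude_rel = c(young = 0.5, old = 0.25),
    noise_cv = c(young = 0.1, old = 0.3))
  sim <- simulate_omics(cfg)
  cvs <- sim$data |>
    dplyr::group_by(.data$group, .data$feature_id, .data$zt) |>
    dplyr::summarise(cv = sd(.data$value) / mean(.data$value),
                     .groups = "drop") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cv = mean(.data$cv))
  expect_gt(cvs$cv[cvs$group == "old"], cvs$cv[cvs$group == "young"])
})

test_that("activity generator honors schedule and artifact contract", {
  cfg <- activity_sim_config(n_flies = 4, days = 2,
                             mean_active_prob_night = 0, seed = 3,
                             artifact_rate = 0)
  sim <- simulate_activity(cfg)
  expect_equal(nrow(sim$data), 4 * 2 * 1440)
  hour <- ((sim$data$minute - 1) %/% 60) %% 24
  expect_true(all(sim$data$count[hour >= 12] == 0))   # silent night
  expect_equal(nrow(sim$truth), 0)
  # artifacts reach the documented ceiling and are isolated
  cfg2 <- activity_sim_config(n_flies = 6, days = 3, artifact_rate = 2,
                              seed = 4)
  sim2 <- simulate_activity(cfg2)
  expect_gt(nrow(sim2$truth), 0)
  spike <- ceiling(cfg2$artifact_magnitude * cfg2$counts_rate)
  marked <- dplyr::left_join(sim2$truth,
                             sim2$data, by = c("fly_id", "minute"))
  expect_true(all(marked$count == spike))
  iso <- sim2$truth |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::summarise(ok = all(diff(sort(.data$minute)) > 1) ||
                       dplyr::n() < 2)
  expect_true(all(iso$ok))
  # spikes clear the pooled six-sigma rule by construction
  nz <- sim2$data$count[sim2$data$count > 0]
  expect_true(spike > mean(nz) + 6 * sd(nz))
})

test_that("ROI generator recovers the configured per-brain ratio", {
  cfg <- imaging_sim_config(n_brains = 12, noise_cv = 1e-12, seed = 6)
  sim <- simulate_roi_table(cfg)
  d <- sim$data
  # noiseless: the per-cell ratio equals the configured condition ratio
  cell_ratio <- (d$gfp / d$bg_gfp) / (d$rfp / d$bg_rfp)
  expect_equal(cell_ratio,
               dplyr::left_join(d, sim$truth, by = "brain_id")$true_ratio,
               tolerance = 1e-9)
  # with realistic noise, the mean of brain means stays within 5%
  cfgn <- imaging_sim_config(n_brains = 12, noise_cv = 0.1, seed = 6)
  simn <- simulate_roi_table(cfgn)
  bm <- simn$data |>
    dplyr::mutate(r = (.data$gfp / .data$bg_gfp) /
                    (.data$rfp / .data$bg_rfp)) |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::summarise(r = mean(.data$r)) |>
    dplyr::left_join(simn$truth, by = "brain_id")
  rel <- bm |>
    dplyr::group_by(.data$true_ratio) |>
    dplyr::summarise(err = abs(mean(.data$r) - .data$true_ratio[1]) /
                       .data$true_ratio[1])
  expect_true(all(rel$err < 0.05))
})

test_that("redox stack generator produces a valid masked 8-bit stack", {
  cfg <- imaging_sim_config(stack_shape = c(3L, 48L, 48L), seed = 8)
  st <- simulate_rogfp_stack(cfg, genotype = "control", zt = 2, seed = 11)
  expect_equal(dim(st$ch405), c(3, 48, 48))
  expect_true(all(st$ch405 >= 0 & st$ch405 <= 255))
  expect_true(all(st$ch488 == as.integer(st$ch488)))
  # every slice meets the target foreground fraction (disks overshoot it)
  frac <- apply(st$mask, 1, mean)
  expect_true(all(frac >= cfg$mito_fraction))
  expect_true(all(frac < 4 * cfg$mito_fraction))
  # within-mask intensity ratio approximates the configured redox ratio
  r <- mean(st$ch405[st$mask]) / mean(st$ch488[st$mask])
  expect_equal(r, st$true_ratio, tolerance = 0.05)
  expect_error(imaging_sim_config(stack_shape = c(0L, 4L, 4L)), "positive")
  expect_error(simulate_rogfp_stack(cfg, genotype = "control", zt = 99),
               "condition")
})
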