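make_dam_lines <- function(count_rows) {
  # count_rows: list of 32-length integer vectors, one per minute
  vapply(seq_along(count_rows), function(i) {
    tod <- sprintf("%02d:%02d:00", ((i - 1) %/% 60) %% 24, (i - 1) %% 60)
    paste(c(i, "1 Jan 24", tod, 1, rep(0, 6), count_rows[[i]]),
          collapse = "\t")
  }, "")
}

test_that("read_dam parses a hand-built three-minute file", {
  rows <- list(c(0L, rep(0L, 31)), c(5L, rep(0L, 31)), c(2L, 7L, rep(0L, 30)))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(make_dam_lines(rows), path)
  d <- read_dam(path)
  expect_equal(nrow(d), 3 * 32)
  ch1 <- d$count[d$channel == 1]
  expect_equal(ch1, c(0L, 5L, 2L))
  expect_equal(d$count[d$channel == 2], c(0L, 0L, 7L))
  expect_true(all(d$status_ok))
  expect_equal(attr(d, "minute_gaps"), integer(0))
})

test_that("read_dam rejects malformed lines and flags bad status", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("1\t1 Jan 24\t00:00:00\t1\t0\t0", path)
  expect_error(read_dam(path), "42")
  rows <- list(rep(0L, 32), rep(0L, 32))
  lines <- make_dam_lines(rows)
  lines[2] <- sub("00:01:00\t1", "00:01:00\t51", lines[2], fixed = TRUE)
  writeLines(lines, path)
  d <- read_dam(path)
  expect_equal(sum(!d$status_ok), 32)            # one bad reading x 32 ch
  # non-integer count
  lines2 <- make_dam_lines(rows)
  lines2[1] <- sub("\t0$", "\txx", lines2[1])
  writeLines(lines2, path)
  expect_error(read_dam(path), "non-integer")
})

test_that("write_dam followed by read_dam round-trips counts", {
  set.seed(55)
  d <- tidyr::expand_grid(channel = 1:4, minute = 1:120)
  d$count <- rpois(nrow(d), 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_dam(d, path)
  back <- read_dam(path)
  merged <- dplyr::left_join(d, back, by = c("channel", "minute"),
                             suffix = c("", "_r"))
  expect_equal(merged$count_r, merged$count)
  # unused channels are all zero
  expect_true(all(back$count[back$channel > 4] == 0))
})

test_that("the six-sigma filter replaces a known spike by its neighbors", {
  # fly with quiet baseline and one huge spike: neighbors 2 and 3 -> 2.5
  base <- rep(c(2L, 3L), 50)
  x <- base; x[50] <- 500L; x[51] <- 3L
  d <- tibble::tibble(fly_id = "f1", minute = seq_along(x), count = x)
  out <- filter_artifacts(d, threshold_sd = 6)
  expect_equal(nrow(out$log), 1)
  expect_equal(out$log$minute, 50)
  expect_equal(out$log$original, 500)
  expect_equal(out$log$replacement, mean(c(x[49], x[51])))
  expect_equal(out$data$count[50], 2.5)
  # everything else untouched
  expect_equal(out$data$count[-50], as.numeric(x[-50]))
})

test_that("edge and consecutive artifacts use the nearest valid neighbors", {
  # long quiet baseline so the pooled SD stays small relative to the spikes
  base <- rep(2L, 1000)
  x <- base
  x[1] <- 400L                       # leading edge: single right neighbor
  x[20] <- 400L; x[21] <- 400L       # consecutive pair
  d <- tibble::tibble(fly_id = "f1", minute = seq_along(x), count = x)
  out <- filter_artifacts(d)
  expect_equal(out$data$count[1], 2)
  expect_equal(out$data$count[20], 2)            # mean(x[19], x[22])
  expect_equal(out$data$count[21], 2)
  expect_equal(nrow(out$log), 3)
})

test_that("the filter is a no-op on clean data and logs nothing", {
  set.seed(60)
  d <- tibble::tibble(fly_id = rep(c("a", "b"), each = 200),
                      minute = rep(1:200, 2),
                      count = rpois(400, 2))
  out <- filter_artifacts(d)
  expect_equal(nrow(out$log), 0)
  expect_equal(out$data$count, as.numeric(d$count))
})

test_that("sleep scoring applies the 5-minute rule exactly", {
  # 10-zero run and 5-zero run are sleep; 4-zero run is wake
  counts <- c(1, rep(0, 10), 1, rep(0, 5), 1, rep(0, 4), 1)
  sc <- score_sleep(counts)
  expect_equal(sum(sc$sleep), 15)
  expect_equal(sc$bouts$start, c(2L, 13L))
  expect_equal(sc$bouts$length, c(10L, 5L))
  expect_false(any(sc$sleep[19:22]))
  # count magnitude is irrelevant: only the zero pattern matters
  sc2 <- score_sleep(counts * 37)
  expect_identical(sc2$sleep, sc$sleep)
})

test_that("sleep summaries partition a hand-built fly-day correctly", {
  # day 1 of an LD schedule (lights on 0): asleep all night (720 min),
  # awake all day except one 10-min nap
  day_counts <- rep(1L, 720); day_counts[100:109] <- 0L
  x <- c(day_counts, rep(0L, 720))
  # a second day of activity so the fly is not presumed dead
  x <- c(x, rep(1L, 1440))
  d <- tibble::tibble(fly_id = "f1", minute = seq_along(x), count = x)
  s <- summarize_sleep(d, days = 2)
  d1 <- s[s$day == 1, ]
  expect_equal(d1$total_sleep, 730)
  expect_equal(d1$day_sleep, 10)
  expect_equal(d1$night_sleep, 720)
  expect_equal(d1$bout_count, 2)
  expect_equal(d1$mean_bout_length, mean(c(10, 720)))
  expect_equal(d1$total_activity, 710)
  expect_equal(d1$waking_activity, 710 / 710)
})

test_that("dead flies are excluded and all-sleep days give NA waking activity", {
  dead <- tibble::tibble(fly_id = "dead", minute = 1:2880,
                         count = c(rep(1L, 1440), rep(0L, 1440)))
  alive <- tibble::tibble(fly_id = "alive", minute = 1:2880,
                          count = rep(c(1L, 1L, 0L, 1L), 720))
  s <- summarize_sleep(dplyr::bind_rows(dead, alive), days = 2)
  expect_equal(attr(s, "excluded_flies"), "dead")
  expect_setequal(unique(s$fly_id), "alive")
  # keep the dead fly: its all-sleep day 2 has NA waking activity
  s2 <- summarize_sleep(dplyr::bind_rows(dead, alive), days = 2,
                        exclude_dead = FALSE)
  d2 <- s2[s2$fly_id == "dead" & s2$day == 2, ]
  expect_equal(d2$total_sleep, 1440)
  expect_true(is.na(d2$waking_activity))
})

test_that("sleep + wake minutes are conserved on random traces", {
  set.seed(61)
  for (i in 1:20) {
    x <- rbinom(1440, 1, 0.3) * rpois(1440, 2)
    sc <- score_sleep(x)
    expect_equal(sum(sc$sleep) + sum(!sc$sleep), 1440)
    expect_equal(sum(sc$bouts$length), sum(sc$sleep))
    # sleep minutes are all zero-count minutes
    expect_true(all(x[sc$sleep] == 0))
  }
})

test_that("FFT rhythm power detects a 24-h rhythm and rejects noise", {
  n <- 4 * 1440
  t_min <- seq_len(n)
  rhythmic <- 1 + cos(2 * pi * t_min / 1440)
  r <- fft_rhythm_power(rhythmic)
  expect_equal(r$peak_period, 24, tolerance = 0.5)
  expect_gt(r$power_24, 0.9)
  expect_true(r$rhythmic)
  # a 12-h rhythm leaves nothing in the 18-30 h band
  ultradian <- 1 + cos(2 * pi * t_min / 720)
  u <- fft_rhythm_power(ultradian)
  expect_lt(u$peak_power, 1e-6)
  expect_false(u$rhythmic)
  # all-zero record: power 0, non-rhythmic
  z <- fft_rhythm_power(rep(0, n))
  expect_equal(z$power_24, 0)
  expect_false(z$rhythmic)
  expect_error(fft_rhythm_power(rep(1, 100)), "3 days")
})
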