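#' Read a Trikinetics DAM2 monitor file
#'
#' Parses the tab-separated DAM2 dialect: per line, fields 1-3 are the
#' reading index, date and time, field 4 the monitor status (1 = OK),
#' fields 5-10 reserved metadata, and fields 11-42 the counts of the 32
#' channels. Rows with a non-OK status are kept but flagged and should be
#' excluded from analysis; gaps in the minute sequence are reported via
#' the `minute_gaps` attribute.
#'
#' @param path Path to a DAM2 text file.
#' @return Long tibble with columns `monitor`, `reading`, `date`, `time`,
#'   `status`, `status_ok`, `minute` (1-based row order), `channel`,
#'   `count`; attribute `minute_gaps` lists readings following a gap.
#' @export
read_dam <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 42L)
  if (length(bad) > 0)
    abort(paste0("line ", bad[1], " of ", basename(path), " has ",
                 lengths(parts)[bad[1]], " fields (expected 42)"))
  m <- do.call(rbind, parts)
  counts <- m[, 11:42, drop = FALSE]
  suppressWarnings(cnum <- as.integer(counts))
  if (any(is.na(cnum)))
    abort(paste("non-integer activity count in", basename(path)))
  n <- nrow(m)
  tod <- strsplit(m[, 3], ":", fixed = TRUE)
  min_of_day <- vapply(tod, function(h)
    as.integer(h[1]) * 60L + as.integer(h[2]), 0L)
  gaps <- which(diff(min_of_day) %% 1440L != 1L) + 1L
  out <- tibble(
    monitor = sub("\\.txt$", "", basename(path)),
    reading = rep(as.integer(m[, 1]), 32),
    date = rep(m[, 2], 32),
    time = rep(m[, 3], 32),
    status = rep(as.integer(m[, 4]), 32),
    minute = rep(seq_len(n), 32),
    channel = rep(1:32, each = n),
    count = cnum) |>
    mutate(status_ok = .data$status == 1L) |>
    arrange(.data$channel, .data$minute)
  attr(out, "minute_gaps") <- gaps
  out
}

#' Write minute-binned activity as a DAM2 monitor file
#'
#' Emits the 42-field tab-separated dialect read by [read_dam()]. Flies
#' are mapped to channels 1-32; unused channels are written as zeros.
#'
#' @param data Tibble with columns `channel`, `minute`, `count`.
#' @param path Output path.
#' @param start_date Date string stamped on the first midnight reading.
#' @return `path`, invisibly.
#' @export
write_dam <- function(data, path, start_date = "1 Jan 24") {
  stopifnot(all(c("channel", "minute", "count") %in% names(data)))
  n <- max(data$minute)
  counts <- matrix(0L, n, 32)
  counts[cbind(data$minute, data$channel)] <- as.integer(data$count)
  tod <- sprintf("%02d:%02d:00", ((seq_len(n) - 1) %/% 60) %% 24,
                 (seq_len(n) - 1) %% 60)
  meta <- matrix(0L, n, 6)
  lines <- paste(seq_len(n), start_date, tod, 1L,
                 apply(meta, 1, paste, collapse = "\t"),
                 apply(counts, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
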