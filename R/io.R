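#' Write a time course as the wide TSV dialect
#'
#' First column `feature_id`; one column per sample named
#' `group_ZT<hh>_rep<k>`; a companion metadata TSV with columns
#' `sample_id`, `group`, `zt`, `replicate`. Values are written with fixed
#' 9-significant-digit formatting so files are byte-stable across
#' platforms.
#'
#' @param data Long time-course tibble.
#' @param path Output TSV path for the matrix.
#' @param meta_path Output TSV path for the metadata (default: `path`
#'   with `_meta` suffix).
#' @return Invisibly, c(path, meta_path).
#' @export
write_timecourse <- function(data, path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- sub("(\\.tsv)?$", "_meta.tsv", path)
  wide <- data |>
    select("feature_id", "sample_id", "value") |>
    mutate(value = fmt_num(.data$value)) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  meta <- distinct(data, .data$sample_id, .data$group, .data$zt,
                   .data$replicate)
  readr::write_tsv(meta, meta_path, progress = FALSE)
  invisible(c(path, meta_path))
}

#' Read the wide time-course TSV dialect back into long form
#'
#' @param path Matrix TSV written by [write_timecourse()].
#' @param meta_path Companion metadata TSV.
#' @return Long time-course tibble.
#' @export
read_timecourse <- function(path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- sub("(\\.tsv)?$", "_meta.tsv", path)
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          progress = FALSE)
  wide |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "value") |>
    left_join(meta, by = "sample_id") |>
    select("feature_id", "sample_id", "group", "zt", "replicate", "value")
}

# screen results TSV with stable numeric formatting
write_screen_tsv <- function(screen, path) {
  out <- as_tibble(screen) |>
    mutate(across(c("tau", "p_lag_min", "p_value", "q_value",
                    "amplitude_est"), fmt_num))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# fixed-precision JSON writer (stable across platforms)
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 9,
                       pretty = TRUE)
  invisible(path)
}

# manifest: every emitted file with its md5 checksum
write_manifest <- function(files, out_dir, extra = list()) {
  sums <- tools::md5sum(files)
  man <- tibble(file = basename(files), md5 = unname(sums))
  path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(man, path, progress = FALSE)
  if (length(extra) > 0)
    write_json_stable(extra, file.path(out_dir, "run_config.json"))
  man
}
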