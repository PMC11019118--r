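#' Per-cell calcium-reporter signal
#'
#' The background-corrected ratiometric signal of one cell:
#' (GFP / slice background GFP) / (RFP / slice background RFP), in
#' arbitrary units. Vectorized over records.
#'
#' @param gfp,bg_gfp GFP signal and its slice background (> 0).
#' @param rfp,bg_rfp RFP signal (> 0) and its slice background (> 0).
#' @return Numeric vector of per-cell ratios.
#' @examples
#' calexa_cell_signal(gfp = 200, bg_gfp = 100, rfp = 400, bg_rfp = 100)
#' @export
calexa_cell_signal <- function(gfp, bg_gfp, rfp, bg_rfp) {
  if (any(bg_gfp <= 0) || any(bg_rfp <= 0))
    abort("invalid record: background intensities must be > 0")
  if (any(rfp <= 0)) abort("invalid record: RFP must be > 0")
  (gfp / bg_gfp) / (rfp / bg_rfp)
}

#' Per-brain calcium-reporter summary
#'
#' Averages per-cell ratios within each brain and cell class. The large
#' and small ventral-lateral neuron classes are never pooled: each
#' (brain, class) combination yields its own row.
#'
#' @param data ROI tibble with columns `brain_id`, `cell_class`, `gfp`,
#'   `rfp`, `bg_gfp`, `bg_rfp` (extra metadata columns such as `genotype`
#'   and `zt` are carried through).
#' @param cell_class Optional single class to restrict to (`"l-LNv"` or
#'   `"s-LNv"`); an error is raised if no cells of that class exist.
#' @return Tibble: `brain_id`, `cell_class`, `mean_ratio`, `n_cells`,
#'   plus carried metadata.
#' @export
calexa_brain_summary <- function(data, cell_class = NULL) {
  stopifnot(all(c("brain_id", "cell_class", "gfp", "rfp", "bg_gfp",
                  "bg_rfp") %in% names(data)))
  if (!is.null(cell_class)) {
    data <- data[data$cell_class %in% cell_class, , drop = FALSE]
    if (nrow(data) == 0)
      abort(paste("no cells of class", cell_class))
  }
  carry <- intersect(c("genotype", "zt"), names(data))
  data$.ratio <- calexa_cell_signal(data$gfp, data$bg_gfp,
                                    data$rfp, data$bg_rfp)
  data |>
    group_by(across(dplyr::all_of(c("brain_id", "cell_class", carry)))) |>
    summarise(mean_ratio = mean(.data$.ratio), n_cells = dplyr::n(),
              .groups = "drop")
}

#' Threshold a redox-sensor stack to the mitochondrial foreground
#'
#' Per-slice automatic intensity threshold (Otsu, computed on the 488 nm
#' channel via [EBImage::otsu()]) combined with an upper-intensity cap
#' that excludes saturating trachea-like structures. The chosen per-slice
#' thresholds are attached as the `thresholds` attribute.
#'
#' @param stack List with `ch405` and `ch488` (z, y, x) 8-bit arrays (a
#'   `rogfp_sim` object works directly).
#' @param upper_cap Intensities at or above this value are excluded
#'   (default 250).
#' @return Logical (z, y, x) mask array; error if the mask is empty.
#' @export
rogfp_mask <- function(stack, upper_cap = 250) {
  ch <- stack$ch488
  stopifnot(!is.null(ch), length(dim(ch)) == 3)
  dims <- dim(ch)
  mask <- array(FALSE, dims)
  thr <- numeric(dims[1])
  for (z in seq_len(dims[1])) {
    sl <- ch[z, , ] / 255
    if (length(unique(as.vector(sl))) == 1L) {
      thr[z] <- NA_real_
      next
    }
    t8 <- EBImage::otsu(sl, range = c(0, 1), levels = 256) * 255
    thr[z] <- t8
    mask[z, , ] <- ch[z, , ] > t8 & ch[z, , ] < upper_cap
  }
  if (!any(mask))
    abort("empty mask after thresholding (uniform or background-only stack)")
  attr(mask, "thresholds") <- thr
  mask
}

#' Raw 405/488 redox ratio of a masked brain
#'
#' @param stack List with `ch405` and `ch488` arrays.
#' @param mask Logical array from [rogfp_mask()] (or ground truth).
#' @param brain_id,run_id Identifiers carried into the result.
#' @return One-row tibble: `brain_id`, `run_id`, `mask_px`, `ratio`
#'   (mean 405 within mask / mean 488 within mask).
#' @export
rogfp_brain_ratio <- function(stack, mask, brain_id = "brain",
                              run_id = "run1") {
  stopifnot(any(mask))
  m488 <- mean(stack$ch488[mask])
  if (m488 == 0) abort("zero mean 488 signal within mask")
  tibble(brain_id = brain_id, run_id = run_id,
         mask_px = sum(mask),
         ratio = mean(stack$ch405[mask]) / m488)
}

#' Normalize redox ratios to each run's control brains
#'
#' Divides every brain's raw 405/488 ratio by the mean raw ratio of the
#' control brains of the same imaging run (controls pooled across
#' timepoints within the run; runs never mixed). The per-run normalized
#' control mean is exactly 1.
#'
#' @param results Tibble with columns `brain_id`, `run_id`, `ratio`.
#' @param control_ids Character vector of control brain ids.
#' @return `results` with added columns `is_control` and
#'   `normalized_ratio`; errors if any run lacks controls.
#' @export
normalize_rogfp_run <- function(results, control_ids) {
  stopifnot(all(c("brain_id", "run_id", "ratio") %in% names(results)))
  results$is_control <- results$brain_id %in% control_ids
  ctrl <- results |>
    filter(.data$is_control) |>
    group_by(.data$run_id) |>
    summarise(ctrl_mean = mean(.data$ratio), .groups = "drop")
  missing_runs <- setdiff(unique(results$run_id), ctrl$run_id)
  if (length(missing_runs) > 0)
    abort(paste("run(s) without control brains:",
                paste(missing_runs, collapse = ", ")))
  results |>
    left_join(ctrl, by = "run_id") |>
    mutate(normalized_ratio = .data$ratio / .data$ctrl_mean) |>
    select(-"ctrl_mean")
}
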