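#' Configuration for synthetic imaging fixtures
#'
#' Covers both imaging assays: per-cell GFP/RFP ROI tables for the
#' calcium-reporter quantification and two-channel (405/488 nm) 8-bit
#' stacks for the mitochondrial redox sensor. `true_ratio` carries the
#' configured expected signal per (genotype, ZT); defaults emulate a
#' nighttime increase (ZT14, ZT20) in the overexpression genotype against
#' a flat control.
#'
#' @param n_brains Brains per (genotype, ZT) condition.
#' @param cells_per_brain Named counts for the `l-LNv` and `s-LNv` classes.
#' @param true_ratio Tibble with columns `genotype`, `zt`, `ratio`:
#'   expected calcium-reporter signal per condition.
#' @param rogfp_ratio Tibble with the same columns: expected 405/488
#'   redox ratio per condition (kept below 1 so the bright 488 channel
#'   stays within 8-bit range).
#' @param background_level Mean background intensity (8-bit scale).
#' @param noise_cv Multiplicative lognormal CV on intensities.
#' @param stack_shape Integer (z, y, x) dimensions of each stack.
#' @param mito_fraction Target foreground (mitochondria) pixel fraction
#'   per slice, in (0, 1).
#' @param fg_488 Mean foreground 488-channel intensity (8-bit).
#' @param seed Integer seed.
#' @return List of class `imaging_sim_config`.
#' @export
imaging_sim_config <- function(n_brains = 8,
                               cells_per_brain = c("l-LNv" = 4, "s-LNv" = 4),
                               true_ratio = NULL,
                               rogfp_ratio = NULL,
                               background_level = 50,
                               noise_cv = 0.1,
                               stack_shape = c(4L, 64L, 64L),
                               mito_fraction = 0.10,
                               fg_488 = 180,
                               seed = 1L) {
  if (is.null(true_ratio)) {
    true_ratio <- tidyr::expand_grid(genotype = c("control", "G6PD-OE"),
                                     zt = c(2, 8, 14, 20)) |>
      mutate(ratio = ifelse(.data$genotype == "G6PD-OE" & .data$zt >= 14,
                            1.5, 1.0))
  }
  if (is.null(rogfp_ratio)) {
    rogfp_ratio <- tidyr::expand_grid(genotype = c("control", "G6PD-OE"),
                                      zt = c(2, 8, 14, 20)) |>
      mutate(ratio = ifelse(.data$genotype == "G6PD-OE" & .data$zt >= 14,
                            0.7, 0.5))
  }
  if (any(stack_shape < 1)) abort("stack_shape dimensions must be positive")
  if (mito_fraction <= 0 || mito_fraction >= 1)
    abort("mito_fraction must lie in (0, 1)")
  if (background_level < 0 || background_level > 255 || fg_488 > 255)
    abort("intensities must fit the 8-bit range")
  structure(list(n_brains = n_brains, cells_per_brain = cells_per_brain,
                 true_ratio = true_ratio, rogfp_ratio = rogfp_ratio,
                 background_level = background_level, noise_cv = noise_cv,
                 stack_shape = as.integer(stack_shape),
                 mito_fraction = mito_fraction, fg_488 = fg_488,
                 seed = as.integer(seed)),
            class = "imaging_sim_config")
}

#' Simulate per-cell ROI intensity records with known brain-level ratios
#'
#' For each brain and cell: GFP = background * signal * kappa and
#' RFP = background * kappa', with independent mean-1 lognormal noise
#' factors, so the recovered per-cell ratio (GFP/bgG)/(RFP/bgR) equals
#' signal * kappa/kappa'. Ground-truth per-brain ratios are returned.
#'
#' @param config An [imaging_sim_config()].
#' @return List of class `roi_sim` with `data` (tibble: `brain_id`,
#'   `cell_class`, `slice`, `gfp`, `rfp`, `bg_gfp`, `bg_rfp`, `genotype`,
#'   `zt`), `truth` (per-brain true ratio) and `config`.
#' @export
simulate_roi_table <- function(config) {
  stopifnot(inherits(config, "imaging_sim_config"))
  sigma <- sqrt(log(1 + config$noise_cv^2))
  ln <- function(n) exp(rnorm(n, -sigma^2 / 2, sigma))
  with_local_seed(config$seed, {
    conds <- config$true_ratio
    rows <- list(); truth <- list()
    for (ci in seq_len(nrow(conds))) {
      for (b in seq_len(config$n_brains)) {
        bid <- sprintf("%s_ZT%02d_brain%02d", conds$genotype[ci],
                       as.integer(conds$zt[ci]), b)
        for (cl in names(config$cells_per_brain)) {
          nc <- config$cells_per_brain[[cl]]
          if (nc == 0) next
          slice <- sample(1:10, nc, replace = TRUE)
          bg_g <- config$background_level * ln(nc)
          bg_r <- config$background_level * ln(nc)
          gfp <- bg_g * conds$ratio[ci] * ln(nc)
          rfp <- bg_r * ln(nc)
          rows[[length(rows) + 1]] <- tibble(
            brain_id = bid, cell_class = cl, slice = slice,
            gfp = gfp, rfp = rfp, bg_gfp = bg_g, bg_rfp = bg_r,
            genotype = conds$genotype[ci], zt = conds$zt[ci])
        }
        truth[[length(truth) + 1]] <- tibble(
          brain_id = bid, genotype = conds$genotype[ci],
          zt = conds$zt[ci], true_ratio = conds$ratio[ci])
      }
    }
    structure(list(data = bind_rows(rows), truth = bind_rows(truth),
                   config = config),
              class = "roi_sim")
  })
}

#' Simulate a two-channel 8-bit redox-sensor stack with known mask
#'
#' Places disk-shaped "mitochondria" on each slice until the configured
#' foreground fraction is reached. Foreground 488 intensity is bright
#' (`fg_488`) with multiplicative noise and the 405 channel is
#' `true_ratio` times the noiseless 488 level (independent noise), so the
#' within-mask mean 405/488 ratio recovers `true_ratio`. Background is dim
#' in both channels. Intensities are clipped and rounded to 0..255.
#'
#' @param config An [imaging_sim_config()].
#' @param genotype,zt Condition selecting `true_ratio` from the config
#'   (defaults to the first configured condition).
#' @param seed Overrides the config seed (so multiple brains per condition
#'   can be generated).
#' @return List of class `rogfp_sim`: `ch405` and `ch488` (z, y, x integer
#'   arrays), `mask` (logical ground-truth foreground), `true_ratio`,
#'   `genotype`, `zt`.
#' @export
simulate_rogfp_stack <- function(config, genotype = NULL, zt = NULL,
                                 seed = NULL) {
  stopifnot(inherits(config, "imaging_sim_config"))
  conds <- config$rogfp_ratio
  if (is.null(genotype)) genotype <- conds$genotype[1]
  if (is.null(zt)) zt <- conds$zt[conds$genotype == genotype][1]
  ratio <- conds$ratio[conds$genotype == genotype & conds$zt == zt]
  if (length(ratio) != 1) abort("no configured true_ratio for this condition")
  dims <- config$stack_shape
  sigma <- sqrt(log(1 + config$noise_cv^2))
  with_local_seed(if (is.null(seed)) config$seed else seed, {
    mask <- array(FALSE, dims)
    for (z in seq_len(dims[1])) {
      sl <- matrix(FALSE, dims[2], dims[3])
      target <- config$mito_fraction * dims[2] * dims[3]
      yy <- row(sl); xx <- col(sl)
      while (sum(sl) < target) {
        cy <- runif(1, 1, dims[2]); cx <- runif(1, 1, dims[3])
        r <- runif(1, 2, 5)
        sl <- sl | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
      }
      mask[z, , ] <- sl
    }
    n <- prod(dims)
    ln <- function(k) exp(rnorm(k, -sigma^2 / 2, sigma))
    base488 <- config$fg_488
    ch488 <- array(config$background_level * ln(n), dims)
    ch405 <- array(config$background_level * ln(n), dims)
    nf <- sum(mask)
    ch488[mask] <- base488 * ln(nf)
    ch405[mask] <- ratio * base488 * ln(nf)
    clip8 <- function(a) array(as.integer(pmin(255, pmax(0, round(a)))),
                               dims)
    structure(list(ch405 = clip8(ch405), ch488 = clip8(ch488),
                   mask = mask, true_ratio = ratio,
                   genotype = genotype, zt = zt),
              class = "rogfp_sim")
  })
}
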