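#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: q_(i) = min_{j >= i} m p_(j)/j,
#' capped at 1 and mapped back to input order (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' JTK rhythm screen of an omics time course
#'
#' Screens every feature of a time-course table for 24-h rhythmicity.
#' For each feature the JTK S statistic and its exact permutation p-value
#' are evaluated at every candidate peak lag on the sampling grid and the
#' minimum p across lags is taken with its best lag (`p_lag_min`). The
#' reported per-feature `p_value` is that minimum Bonferroni-corrected for
#' the scanned lag grid (`p = min(1, n_lags * p_lag_min)`): because lags
#' half a period apart give sign-flipped S, the one-sided scan over the
#' full grid is equivalent to half as many two-sided tests, and the
#' factor-n_lags bound keeps the per-feature null near-uniform (slightly
#' conservative) instead of catastrophically anti-conservative under the
#' step-up FDR procedure. Benjamini-Hochberg q-values are computed across
#' all features of the group, and the significant set is thresholded
#' strictly at `q < q_threshold`.
#'
#' Features whose values contain ties fall back to a seeded Monte-Carlo
#' permutation p-value; all-constant features get p = 1 by convention. The
#' `method` column records which null was used.
#'
#' @param data Time-course tibble with columns `feature_id`, `zt`, `value`
#'   and (optionally) `group`.
#' @param group Group label to screen (required when `data` has a `group`
#'   column with more than one level).
#' @param q_threshold Strict BH q cutoff (0.2 for metabolites, 0.05 for
#'   lipids in the default analysis).
#' @param period_hours Rhythm period (fixed 24 h for a 6-timepoint design;
#'   shorter periods are unidentifiable at that resolution).
#' @param lags Candidate peak lags in hours; defaults to the sampling grid.
#' @param n_perm,seed Monte-Carlo fallback settings for tied features.
#' @return A tibble (class `chrono_screen`) with one row per feature:
#'   `feature_id`, `period_hours`, `lag_hours`, `S`, `tau`, `p_lag_min`
#'   (uncorrected best-lag p), `p_value` (lag-corrected, used for BH),
#'   `q_value`, `amplitude_est` (half the range of the per-ZT mean
#'   profile), `method`, `significant`. Attributes `group` and
#'   `q_threshold` record the screen settings.
#' @export
jtk_screen <- function(data, group = NULL, q_threshold = 0.2,
                       period_hours = 24, lags = NULL,
                       n_perm = 1e5, seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c("feature_id", "zt", "value") %in% names(data)))
  if ("group" %in% names(data)) {
    groups <- unique(data$group)
    if (is.null(group)) {
      if (length(groups) > 1)
        abort("data contains multiple groups; supply `group`")
      group <- groups
    } else {
      if (!group %in% groups) abort(paste0("group '", group, "' not in data"))
      data <- data[data$group == group, , drop = FALSE]
    }
  }
  zts <- sort(unique(data$zt))
  if (length(zts) < 2) abort("need at least 2 distinct ZTs")
  if (is.null(lags)) lags <- zts

  features <- unique(data$feature_id)
  data <- dplyr::arrange(data, match(.data$feature_id, features), .data$zt)
  n_per <- table(factor(data$feature_id, levels = features))
  if (length(unique(n_per)) != 1)
    abort("all features must have the same sample set")
  n <- unname(n_per[1])
  zt_vec <- data$zt[seq_len(n)]
  X <- matrix(data$value, nrow = length(features), ncol = n, byrow = TRUE)

  refs <- lapply(lags, function(l) jtk_reference(zt_vec, period_hours, l))
  # one exact null per reference tie pattern (identical across grid lags)
  null_cache <- list()
  null_for <- function(r) {
    key <- paste(sort(table(r)), collapse = ",")
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <<- jtk_null_distribution(sort(table(r)))
    null_cache[[key]]
  }

  res <- purrr::map_dfr(seq_along(features), function(f) {
    x <- X[f, ]
    if (length(unique(x)) == 1L) {
      return(tibble(feature_id = features[f], period_hours = period_hours,
                    lag_hours = lags[1], S = 0, tau = 0, p_lag_min = 1,
                    p_value = 1, method = "degenerate"))
    }
    tied <- anyDuplicated(x) > 0
    ps <- numeric(length(lags)); ss <- numeric(length(lags))
    taus <- numeric(length(lags))
    for (l in seq_along(lags)) {
      st <- kendall_s(x, refs[[l]])
      ss[l] <- st$S; taus[l] <- st$tau
      ps[l] <- if (tied) {
        jtk_mc_pvalue(x, refs[[l]], n_perm = n_perm,
                      seed = seed + 1000L * f + l)
      } else {
        jtk_exact_pvalue(st$S, NULL, null_dist = null_for(refs[[l]]))
      }
    }
    best <- which.min(ps)
    tibble(feature_id = features[f], period_hours = period_hours,
           lag_hours = lags[best], S = ss[best], tau = taus[best],
           p_lag_min = ps[best],
           p_value = min(1, length(lags) * ps[best]),
           method = if (tied) "montecarlo" else "exact")
  })

  prof <- tapply(data$value,
                 list(factor(data$feature_id, levels = features), data$zt),
                 mean)
  res$amplitude_est <- as.numeric(apply(prof, 1, function(m)
    (max(m) - min(m)) / 2))
  res$q_value <- benjamini_hochberg(res$p_value)
  res$significant <- res$q_value < q_threshold
  res <- res[, c("feature_id", "period_hours", "lag_hours", "S", "tau",
                 "p_lag_min", "p_value", "q_value", "amplitude_est",
                 "method", "significant")]
  structure(res, class = c("chrono_screen", class(res)),
            group = group, q_threshold = q_threshold)
}

#' Overlap of significant feature sets between two rhythm screens
#'
#' Partitions the significant features of two screens over the same
#' feature universe into exclusive and shared sets (the Venn-diagram
#' summary of a young-vs-old comparison).
#'
#' @param screen_a,screen_b `chrono_screen` tibbles from [jtk_screen()].
#' @return List of class `chrono_overlap` with elements `only_a`, `shared`,
#'   `only_b` (character vectors) and `counts` (named integer vector).
#' @export
overlap_summary <- function(screen_a, screen_b) {
  ua <- sort(screen_a$feature_id); ub <- sort(screen_b$feature_id)
  if (!identical(ua, ub)) abort("screens cover different feature universes")
  a <- screen_a$feature_id[screen_a$significant]
  b <- screen_b$feature_id[screen_b$significant]
  out <- list(only_a = setdiff(a, b), shared = intersect(a, b),
              only_b = setdiff(b, a))
  out$counts <- c(only_a = length(out$only_a), shared = length(out$shared),
                  only_b = length(out$only_b))
  structure(out, class = "chrono_overlap",
            groups = c(attr(screen_a, "group"), attr(screen_b, "group")))
}

#' @export
print.chrono_overlap <- function(x, ...) {
  g <- attr(x, "groups")
  cat("Rhythm screen overlap (", g[1], " vs ", g[2], ")\n", sep = "")
  cat("  only ", g[1], ": ", x$counts["only_a"],
      "  shared: ", x$counts["shared"],
      "  only ", g[2], ": ", x$counts["only_b"], "\n", sep = "")
  invisible(x)
}

#' Per-feature unit-variance scaling for heatmap display
#'
#' Centers each feature at zero and scales it to unit variance
#' (population-SD convention: divide by sqrt(mean squared deviation)).
#' Zero-variance features map to all zeros and are flagged.
#'
#' @param data Time-course tibble with `feature_id` and `value` columns.
#' @return The tibble with `value` replaced by its scaled version;
#'   attribute `zero_variance_features` lists flagged feature ids.
#' @export
zscale_features <- function(data) {
  stopifnot(all(c("feature_id", "value") %in% names(data)))
  flagged <- character(0)
  out <- data |>
    group_by(.data$feature_id) |>
    mutate(.sd = sd_pop(.data$value),
           value = ifelse(.data$.sd == 0, 0,
                          (.data$value - mean(.data$value)) / .data$.sd)) |>
    ungroup()
  flagged <- unique(out$feature_id[out$.sd == 0])
  out$.sd <- NULL
  attr(out, "zero_variance_features") <- flagged
  out
}
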