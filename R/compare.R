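#' Normality-gated group comparisons with the two-control rule
#'
#' The statistical harness used throughout the behavioral and imaging
#' analyses. Each group is first gated by a Shapiro-Wilk normality test at
#' alpha 0.05: if every group passes, parametric tests are used (two
#' groups: t-test, optionally Welch; more: one-way ANOVA with Tukey's
#' post-hoc); if any group fails -- or has zero variance -- nonparametric
#' tests are used (Mann-Whitney, or Kruskal-Wallis with Dunn's multiple
#' comparisons). The `timepoints` design compares all pairs of timepoint
#' groups with a Bonferroni correction. When a pair of control genotypes
#' is supplied, a phenotype is called only if the experimental group
#' differs from *both* controls (adjusted p < 0.05 against each).
#'
#' @param data Data frame with a value column and a group column.
#' @param value,group Column names (strings) holding the measurements and
#'   group labels.
#' @param design `"two_group"`, `"multi_group"` or `"timepoints"`.
#' @param controls Optional character vector of the two control group
#'   labels (e.g. GAL4 and UAS controls).
#' @param experimental Experimental group label; defaults to the single
#'   non-control group.
#' @param welch Use Welch's t-test on the parametric two-group path.
#' @return List of class `group_comparison`: `gate` (per-group
#'   Shapiro-Wilk results), `test_used`, `omnibus` (tibble or NULL),
#'   `pairwise` (tibble: `group1`, `group2`, `statistic`, `p_value`,
#'   `p_adj`), `both_controls_significant` (logical or NA when no
#'   controls were supplied).
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           design = c("two_group", "multi_group",
                                      "timepoints"),
                           controls = NULL, experimental = NULL,
                           welch = FALSE) {
  design <- match.arg(design)
  v <- data[[value]]; g <- as.character(data[[group]])
  stopifnot(!is.null(v), !is.null(g))
  groups <- unique(g)
  if (length(groups) < 2) abort("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 3)) abort("need at least 3 values per group")

  gate <- purrr::map_dfr(groups, function(gr) {
    x <- v[g == gr]
    if (sd(x) == 0) {
      return(tibble(group = gr, W = NA_real_, p_value = NA_real_,
                    normal = FALSE, zero_variance = TRUE))
    }
    sw <- shapiro.test(x)
    tibble(group = gr, W = unname(sw$statistic),
           p_value = sw$p.value, normal = sw$p.value >= 0.05,
           zero_variance = FALSE)
  })
  if (any(gate$zero_variance))
    warn("zero-variance group: falling back to nonparametric tests")
  parametric <- all(gate$normal)

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pair_test <- function(g1, g2, adjust_n = 1) {
    x <- v[g == g1]; y <- v[g == g2]
    if (parametric) {
      tt <- t.test(x, y, var.equal = !welch)
      tibble(group1 = g1, group2 = g2, statistic = unname(tt$statistic),
             p_value = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(x, y))
      tibble(group1 = g1, group2 = g2, statistic = unname(wt$statistic),
             p_value = wt$p.value)
    }
  }

  omnibus <- NULL
  if (design == "two_group" && length(groups) == 2) {
    pw <- pair_test(groups[1], groups[2])
    pw$p_adj <- pw$p_value
    test_used <- if (parametric)
      ifelse(welch, "welch_t", "t_test") else "mann_whitney"
  } else if (design == "timepoints") {
    pw <- bind_rows(lapply(pairs, function(pr) pair_test(pr[1], pr[2])))
    pw$p_adj <- pmin(1, pw$p_value * nrow(pw))   # Bonferroni
    test_used <- paste0(if (parametric) "pairwise_t" else
      "pairwise_mann_whitney", "_bonferroni")
  } else {
    if (parametric) {
      fit <- aov(v ~ factor(g))
      sm <- summary(fit)[[1]]
      omnibus <- tibble(test = "anova", statistic = sm$`F value`[1],
                        p_value = sm$`Pr(>F)`[1])
      tk <- TukeyHSD(fit)[[1]]
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      pw <- tibble(group1 = vapply(nm, `[`, "", 1),
                   group2 = vapply(nm, `[`, "", 2),
                   statistic = tk[, "diff"], p_value = tk[, "p adj"],
                   p_adj = tk[, "p adj"])
      test_used <- "anova_tukey"
    } else {
      kw <- kruskal.test(v, factor(g))
      omnibus <- tibble(test = "kruskal_wallis",
                        statistic = unname(kw$statistic),
                        p_value = kw$p.value)
      pw <- dunn_test(v, g)
      test_used <- "kruskal_dunn"
    }
  }

  both <- NA
  if (!is.null(controls)) {
    if (length(controls) != 2 || !all(controls %in% groups))
      abort("controls must name two groups present in the data")
    if (is.null(experimental)) {
      experimental <- setdiff(groups, controls)
      if (length(experimental) != 1)
        abort("supply `experimental` when more than one candidate exists")
    }
    padj_vs <- function(ctrl) {
      hit <- (pw$group1 == experimental & pw$group2 == ctrl) |
        (pw$group2 == experimental & pw$group1 == ctrl)
      pw$p_adj[hit][1]
    }
    both <- padj_vs(controls[1]) < 0.05 && padj_vs(controls[2]) < 0.05
  }

  structure(list(gate = gate, test_used = test_used, omnibus = omnibus,
                 pairwise = pw, both_controls_significant = both,
                 controls = controls, experimental = experimental,
                 design = design),
            class = "group_comparison")
}

# Dunn's post-hoc test on the pooled Kruskal-Wallis ranking, with tie
# correction and Bonferroni adjustment across all pairs
dunn_test <- function(v, g) {
  N <- length(v)
  rk <- rank(v)
  tie_tab <- table(rk)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mr <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  groups <- names(mr)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    z <- (mr[[pr[1]]] - mr[[pr[2]]]) / se
    tibble(group1 = pr[1], group2 = pr[2], statistic = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  out$p_adj <- pmin(1, out$p_value * nrow(out))
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$design, "), test: ", x$test_used, "\n",
      sep = "")
  print(x$pairwise)
  if (!is.na(x$both_controls_significant))
    cat("different from both controls:",
        x$both_controls_significant, "\n")
  invisible(x)
}
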