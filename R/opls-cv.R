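#' Cross-validate an OPLS model
#'
#' 7-fold cross-validation with deterministic venetian-blind fold
#' assignment (every 7th sample in the supplied row order, which
#' [opls_preprocess()] fixes as group/ZT/replicate order). Unit-variance
#' scaling and centering are re-estimated inside each training fold --
#' never on the full matrix -- so no information leaks from held-out
#' samples. For every component count a = 0..n_ortho the predictive
#' residual sum of squares is
#' PRESS_a = sum (y_i - yhat_(-fold(i)))^2, the reference
#' SS = sum (y_i - ybar_train(-fold(i)))^2, Q2_a = 1 - PRESS_a/SS, and
#' Q2cum = 1 - prod_a (PRESS_a/SS).
#'
#' @param X Unscaled sample x feature matrix (scaling happens per fold).
#' @param y Numeric response.
#' @param n_ortho Maximum orthogonal component count evaluated.
#' @param folds Number of folds (default 7).
#' @param assignment `"venetian"` (deterministic) or `"random"`.
#' @param seed Seed for random fold assignment.
#' @return Object of class `opls_cv`: `components` tibble (`n_ortho`,
#'   `PRESS`, `SS`, `Q2`), `Q2cum`, `press_final`, `ss_total` (corrected
#'   total SS of y), `folds`, `fold_id`, `n`.
#' @export
opls_cross_validate <- function(X, y, n_ortho = 0, folds = 7,
                                assignment = c("venetian", "random"),
                                seed = 1L) {
  assignment <- match.arg(assignment)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < folds) abort("need at least as many samples as folds")
  fold_id <- ((seq_len(n) - 1L) %% folds) + 1L
  if (assignment == "random")
    fold_id <- with_local_seed(seed, sample(fold_id))
  if (min(table(fold_id)) < 2) abort("every fold needs at least 2 samples")

  comps <- 0:n_ortho
  press <- numeric(length(comps))
  ss <- 0
  pred <- matrix(NA_real_, n, length(comps))
  base <- numeric(n)
  for (k in seq_len(folds)) {
    test <- fold_id == k; train <- !test
    sc <- suppressWarnings(scale_uv(X[train, , drop = FALSE]))
    Xtr <- sc$X
    Xte <- sweep(sweep(X[test, colnames(Xtr), drop = FALSE], 2, sc$center),
                 2, sc$scale, "/")
    for (j in seq_along(comps)) {
      fit <- fit_opls(Xtr, y[train], n_ortho = comps[j])
      pred[test, j] <- predict(fit, Xte)
    }
    base[test] <- mean(y[train])
  }
  ss <- sum((y - base)^2)
  press <- colSums((y - pred)^2)
  q2 <- 1 - press / ss
  structure(list(
    components = tibble(n_ortho = comps, PRESS = press, SS = ss, Q2 = q2),
    Q2cum = 1 - prod(press / ss),
    press_final = press[length(press)],
    ss_total = sum((y - mean(y))^2),
    folds = folds, fold_id = fold_id, n = n),
    class = "opls_cv")
}

#' CV-ANOVA significance test for a cross-validated OPLS model
#'
#' F-test comparing the cross-validated predictive residuals of the final
#' model against the total corrected variation of y:
#' F = ((SS_y - PRESS)/d1) / (PRESS/d2). Degrees-of-freedom convention
#' (pinned here; conventions differ across software): d1 = number of
#' model components (1 predictive + n_ortho), d2 = n - 1 - d1. A model
#' whose PRESS reaches or exceeds SS_y gets F = 0, p = 1 (no model).
#'
#' @param cv An `opls_cv` object.
#' @param y Optional response vector; defaults to using the total
#'   corrected SS recorded in `cv`.
#' @return One-row tibble: `F_stat`, `df1`, `df2`, `p_value`.
#' @export
cv_anova <- function(cv, y = NULL) {
  stopifnot(inherits(cv, "opls_cv"))
  ss_y <- if (is.null(y)) cv$ss_total else sum((y - mean(y))^2)
  press <- cv$press_final
  d1 <- max(cv$components$n_ortho) + 1
  d2 <- cv$n - 1 - d1
  if (d2 < 1) abort("not enough samples for the CV-ANOVA dof convention")
  if (press >= ss_y) {
    return(tibble(F_stat = 0, df1 = d1, df2 = d2, p_value = 1))
  }
  f <- ((ss_y - press) / d1) / (press / d2)
  tibble(F_stat = f, df1 = d1, df2 = d2,
         p_value = pf(f, d1, d2, lower.tail = FALSE))
}

#' Fit, cross-validate and judge an OPLS time-of-day model
#'
#' The full model-significance workflow for one age group: preprocess,
#' grow orthogonal components while cross-validated Q2cum improves by
#' more than `q2_tol` (capped at `max_ortho`), then judge the final model
#' by CV-ANOVA at level `alpha`. With the circular (sin, cos) response
#' encoding, cross-validation is run per response column and PRESS/SS are
#' pooled before the F-test; the reported model is fit to the sine
#' column.
#'
#' @param data Time-course tibble.
#' @param group Group label.
#' @param alpha CV-ANOVA significance level (default 0.05).
#' @param max_ortho Cap on orthogonal components (default 3).
#' @param q2_tol Minimum Q2cum improvement to accept another orthogonal
#'   component (default 0.01).
#' @param folds CV folds (default 7).
#' @param y_encoding Passed to [opls_preprocess()].
#' @param log_transform Passed to [opls_preprocess()].
#' @return List of class `opls_verdict`: `significant` (logical),
#'   `n_ortho`, `model` (`opls`), `cv` (`opls_cv`), `anova` (tibble),
#'   `group`, `alpha`.
#' @export
opls_significance <- function(data, group = NULL, alpha = 0.05,
                              max_ortho = 3, q2_tol = 0.01, folds = 7,
                              y_encoding = c("numeric", "circular"),
                              log_transform = FALSE) {
  y_encoding <- match.arg(y_encoding)
  prep <- opls_preprocess(data, group, y_encoding, log_transform)
  ys <- if (is.matrix(prep$y)) prep$y else matrix(prep$y, ncol = 1)

  cv_at <- function(k) {
    cvs <- lapply(seq_len(ncol(ys)), function(j)
      opls_cross_validate(prep$X_raw, ys[, j], n_ortho = k, folds = folds))
    press <- sum(vapply(cvs, function(z) z$press_final, 0))
    ss <- sum(vapply(cvs, function(z) z$ss_total, 0))
    ratio <- 1
    for (z in cvs) ratio <- ratio * prod(z$components$PRESS /
                                           z$components$SS)
    list(cvs = cvs, press = press, ss = ss, q2cum = 1 - ratio)
  }

  best_k <- 0
  cur <- cv_at(0)
  while (best_k < max_ortho) {
    nxt <- tryCatch(cv_at(best_k + 1), error = function(e) NULL)
    if (is.null(nxt) || nxt$q2cum - cur$q2cum <= q2_tol) break
    best_k <- best_k + 1
    cur <- nxt
  }
  cv <- cur$cvs[[1]]
  # pooled CV-ANOVA across response columns
  d1 <- best_k + 1
  nres <- ncol(ys)
  d2 <- nres * nrow(ys) - nres - nres * d1
  f <- if (cur$press >= cur$ss) 0 else
    ((cur$ss - cur$press) / d1) / (cur$press / d2)
  an <- tibble(F_stat = f, df1 = d1, df2 = d2,
               p_value = if (f == 0) 1 else
                 pf(f, d1, d2, lower.tail = FALSE))
  model <- fit_opls(prep$X, ys[, 1], n_ortho = best_k)
  structure(list(significant = an$p_value < alpha, n_ortho = best_k,
                 model = model, cv = cv, anova = an,
                 Q2cum = cur$q2cum, group = group, alpha = alpha,
                 prep = prep),
            class = "opls_verdict")
}

#' @export
print.opls_verdict <- function(x, ...) {
  cat("OPLS time-of-day model",
      if (!is.null(x$group)) paste0("(", x$group, ")"), "\n")
  cat(sprintf("  %d orthogonal component(s), Q2cum = %.3f\n",
              x$n_ortho, x$Q2cum))
  cat(sprintf("  CV-ANOVA F = %.3f (df %d, %d), p = %.4g -> %s\n",
              x$anova$F_stat, x$anova$df1, x$anova$df2, x$anova$p_value,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
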