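#' Assemble the sample-by-feature matrix for multivariate modeling
#'
#' Pivots a long time-course tibble into a samples x features matrix for
#' one group, with rows ordered by (ZT, replicate) so that downstream
#' deterministic fold assignment is reproducible.
#'
#' @param data Time-course tibble (`feature_id`, `sample_id`, `group`,
#'   `zt`, `replicate`, `value`).
#' @param group Group to extract.
#' @return List with `X` (unscaled matrix, rownames = sample ids), `zt`
#'   (numeric vector per row) and `meta` (tibble).
#' @export
timecourse_matrix <- function(data, group = NULL) {
  if (!is.null(group)) data <- data[data$group == group, , drop = FALSE]
  if (nrow(data) == 0) abort("no samples for this group")
  meta <- data |>
    distinct(.data$sample_id, .data$zt, .data$replicate) |>
    arrange(.data$zt, .data$replicate)
  wide <- data |>
    select("feature_id", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "feature_id", values_from = "value")
  wide <- wide[match(meta$sample_id, wide$sample_id), ]
  X <- as.matrix(wide[, -1])
  rownames(X) <- wide$sample_id
  list(X = X, zt = meta$zt, meta = meta)
}

# unit-variance scaling + mean centering; zero-variance columns dropped
scale_uv <- function(X, log_transform = FALSE) {
  if (log_transform) X <- log(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- sdv > 0
  if (!all(keep)) warn(paste(sum(!keep), "zero-variance features dropped"))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  list(X = Xs, center = mu[keep], scale = sdv[keep],
       dropped = colnames(X)[!keep])
}

#' Preprocess a time course for OPLS modeling
#'
#' Selects one group's samples, applies unit-variance scaling and mean
#' centering to the feature columns (optionally after a log transform),
#' and encodes the collection time response: either the ZT hour as a
#' single numeric y (default, mirroring the usual chemometrics workflow)
#' or a circular (sin, cos) pair, since ZT is periodic.
#'
#' @param data Time-course tibble.
#' @param group Group label.
#' @param y_encoding `"numeric"` or `"circular"`.
#' @param log_transform Apply `log()` to values before scaling.
#' @return List of class `opls_data`: `X` (scaled), `X_raw`, `y` (vector,
#'   or 2-column matrix for circular encoding), `zt`, `center`, `scale`,
#'   `dropped`, `meta`.
#' @export
opls_preprocess <- function(data, group = NULL,
                            y_encoding = c("numeric", "circular"),
                            log_transform = FALSE) {
  y_encoding <- match.arg(y_encoding)
  tm <- timecourse_matrix(data, group)
  if (nrow(tm$X) < 8) abort("need at least 8 samples for 7-fold CV")
  sc <- scale_uv(tm$X, log_transform)
  y <- if (y_encoding == "numeric") tm$zt else
    cbind(sin = sin(2 * pi * tm$zt / 24), cos = cos(2 * pi * tm$zt / 24))
  structure(list(X = sc$X, X_raw = tm$X, y = y, zt = tm$zt,
                 center = sc$center, scale = sc$scale,
                 dropped = sc$dropped, meta = tm$meta,
                 y_encoding = y_encoding, log_transform = log_transform),
            class = "opls_data")
}

#' Fit a single-response OPLS model
#'
#' Orthogonal projections to latent structures for one numeric response:
#' the predictive weight is w proportional to X'y; each orthogonal
#' component removes Y-orthogonal X-variation (w_o proportional to
#' p - (w'p) w, t_o = X w_o, deflation X <- X - t_o p_o'), and the final
#' predictive component (LV1) is computed on the deflated matrix.
#' Predictive scores are exactly orthogonal to every orthogonal score by
#' construction.
#'
#' @param X Scaled sample x feature matrix.
#' @param y Numeric response (internally centered).
#' @param n_ortho Number of orthogonal components (>= 0).
#' @return Object of class `opls`: predictive weights/loadings/scores
#'   (`w`, `p`, `t`), y-loading `c`, orthogonal `W_o`, `P_o`, `T_o`,
#'   `R2X_pred`, `R2X_ortho`, `R2Y`, `fitted`, `y_mean`.
#' @export
fit_opls <- function(X, y, n_ortho = 0) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_ortho >= 0)
  if (sd(y) == 0) abort("y is constant")
  rk <- qr(X)$rank
  if (n_ortho >= rk) abort("n_ortho exceeds the rank of X")
  y_mean <- mean(y); yc <- y - y_mean
  ssx <- sum(X^2)
  X0 <- X
  W_o <- P_o <- matrix(0, ncol(X), 0)
  T_o <- matrix(0, nrow(X), 0)
  r2x_ortho <- 0
  if (n_ortho > 0) {
    for (a in seq_len(n_ortho)) {
      w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
      t <- drop(X %*% w)
      p <- drop(crossprod(X, t)) / sum(t^2)
      w_o <- p - drop(crossprod(w, p)) * w
      nw <- sqrt(sum(w_o^2))
      if (nw < 1e-12) abort("no orthogonal variation left to extract")
      w_o <- w_o / nw
      t_o <- drop(X %*% w_o)
      p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
      X <- X - tcrossprod(t_o, p_o)
      W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
      T_o <- cbind(T_o, t_o)
      r2x_ortho <- r2x_ortho + sum(tcrossprod(t_o, p_o)^2) / ssx
    }
  }
  w <- drop(crossprod(X, yc)); w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  p <- drop(crossprod(X, t)) / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  fitted <- y_mean + cc * t
  structure(list(w = w, p = p, t = t, c = cc,
                 W_o = W_o, P_o = P_o, T_o = T_o, n_ortho = n_ortho,
                 R2X_pred = sum(tcrossprod(t, p)^2) / ssx,
                 R2X_ortho = r2x_ortho,
                 R2Y = 1 - sum((yc - cc * t)^2) / sum(yc^2),
                 fitted = fitted, y_mean = y_mean,
                 features = colnames(X0)),
            class = "opls")
}

#' Predict from an OPLS model
#'
#' Applies the stored orthogonal filter sequentially to new (already
#' scaled) data, then the predictive component.
#'
#' @param object An `opls` model.
#' @param newdata Scaled matrix with the model's feature columns.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.opls <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (object$n_ortho > 0) {
    for (a in seq_len(object$n_ortho)) {
      t_o <- drop(X %*% object$W_o[, a])
      X <- X - tcrossprod(t_o, object$P_o[, a])
    }
  }
  drop(object$y_mean + object$c * (X %*% object$w))
}

#' @export
print.opls <- function(x, ...) {
  cat("OPLS model: 1 predictive +", x$n_ortho, "orthogonal component(s)\n")
  cat(sprintf("  R2Y = %.4f  R2X(pred) = %.4f  R2X(ortho) = %.4f\n",
              x$R2Y, x$R2X_pred, x$R2X_ortho))
  invisible(x)
}

#' Principal component analysis of a scaled matrix
#'
#' Thin wrapper around [stats::prcomp()] used as the outlier/quality check
#' before OPLS modeling.
#'
#' @param X Scaled sample x feature matrix.
#' @param k Number of components (>= 1, at most the matrix rank).
#' @return List with `scores`, `loadings` and `explained_variance`
#'   (fractions of total variance).
#' @export
fit_pca <- function(X, k = 2) {
  if (k < 1) abort("k must be >= 1")
  X <- as.matrix(X)
  rk <- qr(X)$rank
  if (k > rk) abort("k exceeds the rank of X")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)])
}
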