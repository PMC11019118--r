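test_that("OPLS with zero orthogonal components reproduces PLS1", {
  set.seed(101)
  n <- 30; p <- 12
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 0.3)
  Xs <- scale(X)[, ]                       # sample-sd UV scaling
  fit <- fit_opls(Xs, y, n_ortho = 0)
  ref <- mixOmics::pls(Xs, matrix(y, dimnames = list(NULL, "y")),
                       ncomp = 1, scale = FALSE, mode = "regression")
  # scores agree up to sign
  sgn <- sign(sum(fit$t * ref$variates$X[, 1]))
  expect_equal(fit$t, sgn * unname(ref$variates$X[, 1]), tolerance = 1e-8)
  expect_equal(unname(fit$w), sgn * unname(ref$loadings$X[, 1]),
               tolerance = 1e-8)
  # fitted values agree exactly (sign cancels)
  pred <- predict(ref, Xs)$predict[, 1, 1]
  expect_equal(fit$fitted, unname(pred), tolerance = 1e-8)
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  set.seed(5)
  X <- scale(matrix(rnorm(40 * 20), 40, 20))[, ]
  y <- rnorm(40)
  for (k in 1:3) {
    fit <- fit_opls(X, y, n_ortho = k)
    for (a in seq_len(k)) {
      expect_lt(abs(sum(fit$t * fit$T_o[, a])), 1e-8)
      # orthogonal scores are also uncorrelated with y by construction
      expect_lt(abs(sum((y - mean(y)) * fit$T_o[, a])) /
                  sqrt(sum((y - mean(y))^2) * sum(fit$T_o[, a]^2)), 1e-8)
    }
  }
})

test_that("a rank-one X built from y is fit perfectly", {
  set.seed(8)
  y <- rnorm(20)
  X <- outer(y - mean(y), rnorm(6))
  fit <- fit_opls(X, y, n_ortho = 0)
  expect_equal(fit$R2Y, 1, tolerance = 1e-10)
  expect_equal(fit$fitted, y, tolerance = 1e-8)
})

test_that("a constructed orthogonal structure is separated from the signal", {
  # X = t y-direction + t_o orthogonal direction; the orthogonal loading
  # overlaps the predictive one in feature space, which is exactly the
  # structure the orthogonal filter is built to strip
  set.seed(13)
  n <- 28
  t_sig <- scale(rnorm(n), scale = FALSE)[, 1]   # centered: X must be too
  t_ort <- residuals(lm(rnorm(n) ~ t_sig))
  P_sig <- c(rnorm(5), rep(0, 5))
  P_ort <- P_sig + c(rep(0, 5), rnorm(5))
  X <- tcrossprod(t_sig, P_sig) + tcrossprod(t_ort, P_ort)
  y <- t_sig
  fit <- fit_opls(X, y, n_ortho = 1)
  # one orthogonal component absorbs the y-orthogonal block entirely
  expect_equal(fit$R2Y, 1, tolerance = 1e-8)
  expect_equal(abs(cor(fit$T_o[, 1], t_ort)), 1, tolerance = 1e-8)
  expect_equal(fit$R2X_pred + fit$R2X_ortho, 1, tolerance = 1e-8)
})

test_that("R2X partitions into predictive + orthogonal + residual", {
  set.seed(21)
  X <- scale(matrix(rnorm(30 * 15), 30, 15))[, ]
  y <- rnorm(30)
  fit <- fit_opls(X, y, n_ortho = 2)
  # reconstruct the residual after removing all modeled structure
  Xd <- X
  for (a in 1:2) {
    t_o <- drop(Xd %*% fit$W_o[, a])
    Xd <- Xd - tcrossprod(t_o, fit$P_o[, a])
  }
  Xres <- Xd - tcrossprod(fit$t, fit$p)
  expect_equal(fit$R2X_pred + fit$R2X_ortho + sum(Xres^2) / sum(X^2), 1,
               tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  X <- scale(matrix(rnorm(20 * 4), 20, 4))[, ]
  expect_error(fit_opls(X, rep(1, 20)), "constant")
  expect_error(fit_opls(X, rnorm(20), n_ortho = 4), "rank")
})

test_that("preprocessing scales features and encodes the response", {
  sim <- simulate_omics(tiny_omics(seed = 3, n_features = 12))
  prep <- opls_preprocess(sim$data, group = "young")
  expect_s3_class(prep, "opls_data")
  expect_equal(nrow(prep$X), 30)                 # 6 ZT x 5 reps
  expect_equal(unname(colMeans(prep$X)), rep(0, ncol(prep$X)),
               tolerance = 1e-12)
  expect_equal(unname(apply(prep$X, 2, sd)), rep(1, ncol(prep$X)),
               tolerance = 1e-12)
  expect_equal(prep$y, prep$zt)
  # circular encoding puts ZT0 and ZT24 at the same point
  prepc <- opls_preprocess(sim$data, group = "young",
                           y_encoding = "circular")
  expect_equal(dim(prepc$y), c(30, 2))
  expect_equal(rowSums(prepc$y^2), rep(1, 30))
  th0 <- c(sin(0), cos(0))
  expect_equal(unname(prepc$y[prepc$zt == 0, ][1, ]), th0)
})

test_that("zero-variance features are dropped with a warning", {
  sim <- simulate_omics(tiny_omics(seed = 4, n_features = 10))
  d <- sim$data
  d$value[d$feature_id == "met_001"] <- 3
  expect_warning(prep <- opls_preprocess(d, group = "young"),
                 "zero-variance")
  expect_equal(prep$dropped, "met_001")
  expect_equal(ncol(prep$X), 9)
})

test_that("fit_pca explains variance fractions that sum below one", {
  set.seed(17)
  X <- scale(matrix(rnorm(25 * 8), 25, 8))[, ]
  pc <- fit_pca(X, k = 3)
  expect_equal(dim(pc$scores), c(25, 3))
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)
  # agreement with prcomp directly
  ref <- prcomp(X)
  expect_equal(abs(pc$scores[, 1]), abs(ref$x[, 1]), tolerance = 1e-10)
  expect_error(fit_pca(X, k = 0), ">= 1")
  expect_error(fit_pca(X, k = 100), "rank")
})
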