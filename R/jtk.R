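#' Cosine reference waveform for JTK rhythm detection
#'
#' Evaluates the 24-h (or other period) cosine reference at observed
#' zeitgeber times for a given peak lag. Values are rounded so that
#' mathematically tied reference points (e.g. ZT4 and ZT20 for lag 0)
#' compare as exact ties.
#'
#' @param zt Numeric vector of zeitgeber times in hours.
#' @param period_hours Rhythm period in hours (default 24).
#' @param lag_hours Peak time of the reference in hours.
#' @return Numeric vector of reference values in \[-1, 1\].
#' @export
jtk_reference <- function(zt, period_hours = 24, lag_hours = 0) {
  round(cos(2 * pi * (zt - lag_hours) / period_hours), 9)
}

#' Kendall correlation of a time course against a cosine reference
#'
#' Computes the Jonckheere-Terpstra-Kendall S statistic: the number of
#' concordant minus discordant pairs between observed values and a cosine
#' reference evaluated at each observation's zeitgeber time. Replicates at
#' the same timepoint share the reference value, giving tied reference
#' ranks. The tie-corrected tau (tau-b) is returned alongside S.
#'
#' @param data Data frame with columns `zt` and `value` (replicates are
#'   additional rows at the same `zt`).
#' @param period_hours,lag_hours Reference waveform parameters.
#' @return One-row tibble with columns `S`, `tau`, `n_obs`, `tied_data`
#'   (TRUE if the values contain ties) and `constant` (TRUE if all values
#'   are identical, in which case `tau = 0` by convention).
#' @examples
#' jtk_statistic(data.frame(zt = c(0, 8, 16), value = c(3, 1, 2)))
#' @export
jtk_statistic <- function(data, period_hours = 24, lag_hours = 0) {
  stopifnot(is.data.frame(data), all(c("zt", "value") %in% names(data)))
  x <- as.numeric(data$value)
  if (length(x) < 4) abort("jtk_statistic() needs at least 4 observations")
  r <- jtk_reference(data$zt, period_hours, lag_hours)
  st <- kendall_s(x, r)
  tibble(
    S = st$S, tau = st$tau, n_obs = length(x),
    tied_data = anyDuplicated(x) > 0,
    constant = length(unique(x)) == 1L
  )
}

# S and tau-b between a data vector and a (possibly tied) reference
kendall_s <- function(x, r) {
  dx <- sign(outer(x, x, "-"))
  dr <- sign(outer(r, r, "-"))
  S <- sum(dx * dr) / 2
  n <- length(x)
  P <- n * (n - 1) / 2
  t_x <- sum(choose(table(x), 2))
  t_r <- sum(choose(table(r), 2))
  denom <- sqrt((P - t_x) * (P - t_r))
  tau <- if (denom == 0) 0 else S / denom
  list(S = S, tau = tau)
}

# Exact null pmf of S for distinct data values permuted against a reference
# with tie-group sizes `tie_sizes`, via Harding's convolution: the number of
# between-group inversions J decomposes as a sum of independent
# Mann-Whitney U(n_i, m_i) variables (group i against all earlier groups),
# and S = 2J - M with M = number of reference-untied pairs.
jtk_null_distribution <- function(tie_sizes) {
  tie_sizes <- as.integer(tie_sizes)
  stopifnot(all(tie_sizes >= 1))
  k <- length(tie_sizes)
  M <- 0L
  pmf <- 1 # point mass at J = 0
  if (k >= 2) {
    for (i in 2:k) {
      m <- sum(tie_sizes[seq_len(i - 1)])
      n <- tie_sizes[i]
      pmf <- convolve_pmf(pmf, mwu_counts(n, m))
      M <- M + n * m
    }
  }
  pmf <- pmf / sum(pmf)
  list(S = 2 * seq.int(0L, M) - M, prob = pmf, M = M)
}

# counts of the Mann-Whitney U(n, m) null distribution over u = 0..n*m,
# i.e. coefficients of the Gaussian binomial [n + m choose n]_q
mwu_counts <- function(n, m) {
  if (n == 0L || m == 0L) return(1)
  # numerator: prod_{i=1..n} (1 - q^(m+i))
  deg <- n * m + n * (n + 1) / 2
  poly <- c(1, numeric(deg))
  for (i in seq_len(n)) {
    k <- m + i
    shifted <- c(numeric(k), poly[seq_len(length(poly) - k)])
    poly <- poly - shifted
  }
  # divide by prod_{i=1..n} (1 - q^i); exact: Q[j] = A[j] + Q[j - k]
  for (i in seq_len(n)) {
    q <- numeric(length(poly) - i)
    for (j in seq_along(q)) {
      q[j] <- poly[j] + if (j > i) q[j - i] else 0
    }
    poly <- q
  }
  poly[seq_len(n * m + 1)]
}

convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (j in seq_along(b)) {
    idx <- seq_along(a) + j - 1L
    out[idx] <- out[idx] + a * b[j]
  }
  out
}

#' Exact one-sided p-value for the JTK S statistic
#'
#' Probability that the S statistic of a uniformly random permutation of
#' distinct data values against a fixed (possibly tied) cosine reference is
#' at least as large as the observed S. Computed from the exact null
#' distribution obtained by dynamic-programming convolution over the
#' reference's tie groups. Valid only for tie-free data values; use
#' [jtk_mc_pvalue()] when the data contain ties.
#'
#' @param kendall_S Observed S statistic.
#' @param tie_sizes Integer vector of reference tie-group sizes (one entry
#'   per distinct reference value, each the number of observations sharing
#'   that value).
#' @param null_dist Optional precomputed null distribution (as returned by
#'   the internal convolution) to avoid recomputation across features.
#' @return One-sided p-value in (0, 1].
#' @examples
#' # n = 3 distinct values against a strictly ordered reference:
#' # maximal S = 3 occurs for exactly 1 of the 3! permutations
#' jtk_exact_pvalue(3, c(1, 1, 1))
#' @export
jtk_exact_pvalue <- function(kendall_S, tie_sizes, null_dist = NULL) {
  nd <- if (is.null(null_dist)) jtk_null_distribution(tie_sizes) else null_dist
  sum(nd$prob[nd$S >= kendall_S])
}

#' Monte-Carlo permutation p-value for tied data values
#'
#' Seeded permutation fallback used when the data values contain ties, in
#' which case the exact distinct-value null is invalid. Reports
#' (1 + #\{S* >= S\}) / (n_perm + 1).
#'
#' @param values Numeric data vector (may contain ties).
#' @param reference Reference vector (same length), ties allowed.
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer seed for the permutation stream.
#' @return One-sided p-value.
#' @export
jtk_mc_pvalue <- function(values, reference, n_perm = 1e5, seed = 1L) {
  n <- length(values)
  stopifnot(length(reference) == n)
  S_obs <- kendall_s(values, reference)$S
  dr <- sign(outer(reference, reference, "-"))
  pairs <- which(upper.tri(dr) & dr != 0, arr.ind = TRUE)
  with_local_seed(seed, {
    perm <- matrix(0, n_perm, n)
    for (b in seq_len(n_perm)) perm[b, ] <- sample(values)
    s_star <- numeric(n_perm)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      s_star <- s_star + sign(perm[, i] - perm[, j]) * dr[i, j]
    }
    (1 + sum(s_star >= S_obs)) / (n_perm + 1)
  })
}
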