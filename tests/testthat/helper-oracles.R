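# Independent brute-force oracles, kept free of the package's internals.

# Kendall S by explicit pair enumeration
brute_kendall_S <- function(x, r) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(r[j] - r[i])
    }
  }
  s
}

# exact p by full enumeration of all permutations of distinct values
enum_pvalue <- function(values, ref, S_obs) {
  perms <- all_perms(length(values))
  S_all <- apply(perms, 1, function(o) brute_kendall_S(values[o], ref))
  mean(S_all >= S_obs)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# direct BH step-up formula: q_(i) = min_{j >= i} m p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# small omics config used across tests
tiny_omics <- function(seed = 1, n_features = 40, n_rhythmic = 6,
                       amplitude = 0.5, cv = 0.1) {
  ids <- sprintf("met_%03d", seq_len(n_features))
  omics_sim_config(
    n_features = n_features,
    reps_per_group = c(young = 5),
    rhythmic_sets = list(young = ids[seq_len(n_rhythmic)]),
    amplitude_rel = c(young = amplitude),
    noise_cv = c(young = cv),
    seed = seed)
}
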