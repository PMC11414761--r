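# Independent brute-force oracles used to cross-check the implementations.

# topological overlap by explicit triple loop
tom_brute <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) shared <- shared + a[i, u] * a[u, j]
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# Benjamini-Hochberg step-up by hand
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables (same margins) no more likely than observed
fisher_enum <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# median-of-ratios size factors written out directly
size_factors_direct <- function(counts) {
  gm <- apply(counts, 1, function(r) exp(mean(log(r))))
  keep <- is.finite(gm) & gm > 0
  apply(counts, 2, function(col) stats::median(col[keep] / gm[keep]))
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# deterministic competition truth table for one double-mutant trio
trio_truth <- function(wx, wy, eps, temperature = 42.2) {
  data.frame(genotype = c("x", "y", "xy"), temperature = temperature,
             w = c(wx, wy, wx * wy + eps), stringsAsFactors = FALSE)
}

# estimate one epistatic deviation from a simulated trio
trio_estimate <- function(wx, wy, eps, seed, replicates = 10) {
  sim <- simulate_competition(trio_truth(wx, wy, eps),
                              replicates = replicates, seed = seed)
  fit <- summarize_fitness(sim$assays)
  rownames(fit) <- fit$genotype
  epistatic_deviation(fit["x", ], fit["y", ], fit["xy", ])
}
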