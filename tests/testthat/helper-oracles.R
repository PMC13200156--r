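# Fixtures and independent oracles shared across tests.

# Random connected weighted undirected graph as an ndm_connectome.
rand_connectome <- function(n, seed, density = 0.3) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on <- stats::runif(sum(ut)) < density
    w[ut][on] <- stats::rlnorm(sum(on), 0, 0.5)
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::components(g)$no == 1 && all(rowSums(w) > 0)) break
  }
  ndm_connectome(w)
}

# Matrix exponential by scaling-and-squaring of a truncated Taylor series;
# independent of the package's spectral path.
expm_series <- function(A, n_terms = 30) {
  k <- max(0, ceiling(log2(max(norm(A, "1"), 1)))) + 1
  As <- A / 2^k
  S <- term <- diag(nrow(A))
  for (i in seq_len(n_terms)) {
    term <- term %*% As / i
    S <- S + term
  }
  for (i in seq_len(k)) S <- S %*% S
  S
}

# Benjamini-Hochberg by brute-force step-up enumeration over all ranks:
# adjusted p at rank i is min over j >= i of m * p_(j) / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# A small cohort with a known design, for closed-form GLM checks.
toy_cohort <- function(s = 20, n = 5, seed = 11) {
  set.seed(seed)
  group <- rep(c("case", "control"), length.out = s)
  tiv <- stats::rnorm(s, 1450, 100)
  values <- matrix(stats::rnorm(s * n, 7, 0.5), s, n) + 0.004 * tiv
  gmv_table(values, group = group, tiv = tiv)
}
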