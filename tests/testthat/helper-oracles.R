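# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles are deliberately naive implementations that share no code
# with the package internals.

# random named count matrix
rand_counts <- function(G = 20, n = 4, lambda = 50, prefix = "g") {
  m <- matrix(rpois(G * n, lambda), G, n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(G)),
                              sprintf("s%02d", seq_len(n))))
  count_matrix(m)
}

# write a genes-x-samples TSV by hand
write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# O(m^2) step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p * m / r
    q[i] <- min(1, min(cand[r >= r[i]]))
  }
  q
}

# exhaustive hypergeometric upper tail: P(X >= ov) for X ~ Hyper(K, N-K, k)
hyper_tail_oracle <- function(ov, K, N, k) {
  total <- choose(N, k)
  hi <- min(K, k)
  if (ov > hi) return(0)
  sum(vapply(ov:hi, function(i) choose(K, i) * choose(N - K, k - i), numeric(1))) / total
}

# exhaustive per-gene membership oracle for the two screens, operating in
# the species-A namespace over an explicit gene universe
screen_oracle <- function(universe_a, map, A_pl, B_pl, A_org, B_org,
                          type = c("shared_coopted", "eutherian_only")) {
  type <- match.arg(type)
  b_of <- function(g) map$gene_b[match(g, map$gene_a)]
  keep <- vapply(universe_a, function(g) {
    b <- b_of(g)
    if (is.na(b)) return(FALSE)
    if (type == "shared_coopted") {
      (g %in% A_pl) && (b %in% B_pl) && (g %in% A_org) && !(b %in% B_org)
    } else {
      (b %in% B_pl) && (g %in% A_org) && !(g %in% A_pl) && !(b %in% B_org)
    }
  }, logical(1))
  sort(universe_a[keep])
}

# naive median-of-ratios reimplementation (loops, no shared code); the
# even-count median midpoint is taken on the log scale, the estimator's
# convention (the midpoint of two ratios is their geometric mean)
size_factor_oracle <- function(x) {
  keep <- apply(x, 1, function(r) all(r > 0))
  sub <- x[keep, , drop = FALSE]
  gm <- apply(sub, 1, function(r) exp(mean(log(r))))
  sf <- apply(sub, 2, function(col) exp(median(log(col / gm))))
  sf / exp(mean(log(sf)))
}

# scaled-down simulation config for fast end-to-end tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_genes = 1500, organ_program_size = 60, early_size = 68,
             late_size = 14, query_early = 18, query_late = 4,
             coopted_size = 20, eutherian_only_size = 25, n_de_genes = 40,
             seed = seed, ...)
}

# profile + call-set builder for stage-similarity tests
profile_of <- function(values, genes, label, species) {
  names(values) <- genes
  expression_profile(values, label, species)
}
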