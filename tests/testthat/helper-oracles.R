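# Independent oracles and fixture builders used across the suite.

# Brute-force two-sided Mann-Whitney p by full enumeration over all
# choose(n1+n2, n1) assignments of the pooled (mid-)ranks to the first group.
# Independent of the package's DP implementation.
mwu_enum_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n1 + n2 + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(n1 + n2, n1)
  ws <- apply(splits, 2, function(i) sum(r[i]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Monte-Carlo permutation p for sizes where enumeration is infeasible.
mwu_mc_p <- function(x, y, n_perm = 20000) {
  n1 <- length(x)
  r <- rank(c(x, y))
  mu <- n1 * (length(r) + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  ws <- replicate(n_perm, sum(sample(r, n1)))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

random_genome <- function(n, seed) {
  withr::with_seed(seed, {
    tn_genome(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    collapse = ""))
  })
}

# library over `sites` with counts drawn once under `seed`
random_library <- function(sites, seed, lambda = 20, occupancy = 0.7,
                           condition = "custom") {
  withr::with_seed(seed, {
    occ <- runif(length(sites)) < occupancy
    counts <- stats::rpois(sum(occ), lambda) + 1
    insertion_library(sites[occ], counts, condition = condition)
  })
}

# small simulated experiment shared by screen/scan tests
small_sim <- function(seed = 11, n_genes = 40, classes = NULL, depth = 50) {
  simulate_tnseq(sim_config(seed = seed, n_genes = n_genes,
                            mean_reads_per_site = depth,
                            gene_classes = classes))
}
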