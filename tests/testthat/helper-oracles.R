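# Independent brute-force oracles, kept free of any package internals.

# geNorm M by direct double loop over gene pairs: M_j is the mean over k != j
# of the SD (n-1) of log2(x_j / x_k) across samples.
oracle_genorm_m <- function(mat) {
  n <- nrow(mat)
  M <- numeric(n)
  for (j in seq_len(n)) {
    v <- c()
    for (k in seq_len(n)) {
      if (k == j) next
      v <- c(v, sd(log2(mat[j, ] / mat[k, ])))
    }
    M[j] <- mean(v)
  }
  names(M) <- rownames(mat)
  M
}

# Stepwise elimination by repeated argmax of the brute-force M; ties broken
# by reverse label order (later label removed first), mirroring the
# documented convention.
oracle_elimination <- function(mat) {
  retained <- rownames(mat)
  elim <- character(0)
  while (length(retained) > 2) {
    M <- oracle_genorm_m(mat[retained, , drop = FALSE])
    worst <- names(M)[M == max(M)]
    worst <- sort(worst, decreasing = TRUE)[1]
    elim <- c(elim, worst)
    retained <- setdiff(retained, worst)
  }
  list(order = elim, final_pair = sort(retained))
}

# Random positive RQ matrix (log-normal entries) with labelled dims.
random_rq_matrix <- function(seed, n_genes = NULL, n_samples = NULL) {
  set.seed(seed)
  if (is.null(n_genes)) n_genes <- sample(3:6, 1)
  if (is.null(n_samples)) n_samples <- sample(4:8, 1)
  m <- matrix(exp(rnorm(n_genes * n_samples, 0, 1)), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# Default 10-gene panel used in recovery checks: 6 stable genes plus 4
# regulated ones (4-fold trend), 16 samples in 4 ordered groups.
recovery_panel_spec <- function(seed) {
  stable <- lapply(1:6, function(i)
    gene_sim_spec(sprintf("stab%02d", i), base_cq = 22 + i %% 3,
                  bio_sd = 0.05))
  regulated <- lapply(1:4, function(i)
    gene_sim_spec(sprintf("reg%02d", i), base_cq = 24 + i %% 3,
                  bio_sd = 0.05, trend_fold = 4))
  cq_sim_spec(genes = c(stable, regulated),
              groups = rep(c("g1", "g2", "g3", "g4"), each = 4),
              n_replicates = 2, loading_sd = 0.3, tech_sd = 0.1, seed = seed)
}

unit_efficiencies <- function(genes) {
  efficiency_set(setNames(rep(1, length(genes)), genes))
}
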