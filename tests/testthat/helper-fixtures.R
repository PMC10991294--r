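# Small in-code fixtures shared across test files.

toy_counts <- function(values, genes = NULL, obs = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(obs)) obs <- sprintf("o%02d", seq_len(ncol(values)))
  count_matrix(values, genes, obs, layer = "raw")
}

random_norm_matrix <- function(n_genes, n_obs, seed) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_genes * n_obs,
                                stats::rlnorm(n_genes * n_obs, 1, 0.8)),
                   n_genes, n_obs,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("o%03d", seq_len(n_obs))))
  counts[, colSums(counts) == 0] <- 1L  # avoid zero-depth observations
  normalize_log_cpm(count_matrix(counts, layer = "raw"))
}

# two well-separated Gaussian-like blobs in expression space
two_blob_norm <- function(n_per = 60, n_genes = 40, shift = 4, seed = 1) {
  set.seed(seed)
  mu <- matrix(5, n_genes, 2 * n_per)
  mu[seq_len(n_genes / 2), seq_len(n_per)] <- 5 + shift
  mu[(n_genes / 2 + 1):n_genes, (n_per + 1):(2 * n_per)] <- 5 + shift
  counts <- matrix(stats::rpois(length(mu), exp(log(mu))), n_genes,
                   2 * n_per,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("c%03d", seq_len(2 * n_per))))
  list(norm = normalize_log_cpm(count_matrix(counts, layer = "raw")),
       labels = rep(0:1, each = n_per))
}

permutation_fixture <- function(n = 120, n_genes = 100, seed = 1) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n * n_genes,
                                matrix(stats::rlnorm(n * n_genes, log(5), 1),
                                       n_genes, n)),
                   n_genes, n,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("c%03d", seq_len(n))))
  perm <- sample(n)
  spatial <- counts[, perm]
  colnames(spatial) <- sprintf("s%03d", seq_len(n))
  list(sc = normalize_log_cpm(count_matrix(counts, layer = "raw")),
       spatial = normalize_log_cpm(count_matrix(spatial, layer = "raw")),
       genes = rownames(counts),
       true_spot = match(seq_len(n), perm))
}
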