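# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Minimal signature table; p defaults to a monotone function of |log2fc|
# and fdr to BH-adjusted p, so tables are always internally valid.
make_table <- function(id, genes, l2fc, p = NULL, fdr = NULL) {
  if (is.null(p)) p <- pmin(1, 2 * pnorm(-abs(l2fc)))
  if (is.null(fdr)) fdr <- p.adjust(p, "BH")
  signature_table(id, genes, l2fc, p, fdr)
}

# Collection from a genes x datasets log2FC matrix (full observation).
collection_from_l2fc <- function(mat, chemical = NULL, species = "human") {
  ids <- colnames(mat)
  sigs <- lapply(ids, function(id) make_table(id, rownames(mat), mat[, id]))
  names(sigs) <- ids
  md <- data.frame(dataset_id = ids, study_accession = ids,
                   chemical = chemical %||% rep_len(c("THC", "CBD"), length(ids)),
                   species = species, tissue = "brain",
                   platform = "rnaseq", exposure = "in_vivo",
                   stringsAsFactors = FALSE)
  signature_collection(md, sigs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pure-noise collection: n_genes x n_datasets iid Normal log2FCs.
noise_collection <- function(n_genes = 100, n_datasets = 6, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_datasets, sd = sd), n_genes, n_datasets,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("d%02d", seq_len(n_datasets))))
    collection_from_l2fc(m)
  })
}

# Two-cluster planted config used by several recovery tests.
two_cluster_config <- function(seed, n_genes = 500, n_per = 10,
                               scale = 1.0, noise_sd = 0.5) {
  synthetic_config(
    n_datasets = 2L * n_per, n_genes = n_genes,
    cluster_spec = list(list(label = "A", n = n_per, scale = scale),
                        list(label = "B", n = n_per, scale = scale, anti = "A")),
    n_template_genes = max(50L, n_genes %/% 5L),
    noise_sd = noise_sd, n_consistent_genes = 0L, seed = seed)
}

# Independent brute-force binomial upper tail P(X >= j), X~Bin(n, r).
binom_tail_oracle <- function(j, n, r) {
  k <- j:n
  sum(choose(n, k) * r^k * (1 - r)^(n - k))
}
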