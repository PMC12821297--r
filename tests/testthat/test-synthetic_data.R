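test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_datasets = 5, cluster_spec = list(
    list(label = "A", n = 6, scale = 1))), "exceed")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(missing_rate_by_platform = c(rnaseq = 1)),
               "missing_rate")
  expect_error(synthetic_config(cluster_spec = list(
    list(label = "A", n = 2, scale = 1), list(label = "A", n = 2, scale = 1))),
    "duplicated cluster label")
})

test_that("equal seeds give bit-identical collections", {
  cfg <- synthetic_config(n_datasets = 8, n_genes = 120, seed = 33,
                          cluster_spec = list(list(label = "A", n = 4, scale = 1)),
                          n_consistent_genes = 5)
  a <- generate_collection(cfg)
  b <- generate_collection(cfg)
  expect_identical(a, b)
  c2 <- generate_collection(synthetic_config(n_datasets = 8, n_genes = 120, seed = 34,
                          cluster_spec = list(list(label = "A", n = 4, scale = 1)),
                          n_consistent_genes = 5))
  expect_false(identical(a$collection, c2$collection))
})

test_that("pure noise gives null cross-dataset correlations", {
  cfg <- synthetic_config(n_datasets = 10, n_genes = 400, cluster_spec = list(),
                          n_consistent_genes = 0,
                          missing_rate_by_platform = c(rnaseq = 0), seed = 5)
  col <- generate_collection(cfg)$collection
  nm <- build_matrix(col, presence_threshold = NULL, top_k = 400L)
  rho <- spearman_matrix(nm)
  off <- rho[upper.tri(rho)]
  # mean off-diagonal Spearman within +-3 standard errors of 0
  se <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off)), 3 * se + 1e-3)
})

test_that("planted clusters correlate within more than between", {
  gen <- generate_collection(two_cluster_config(seed = 1))
  nm <- impute_matrix(build_matrix(gen$collection, presence_threshold = NULL,
                                   top_k = 500L), "median")
  rho <- spearman_matrix(nm)
  lab <- gen$truth$cluster_assignment[colnames(rho)]
  same <- outer(lab, lab, "==") & upper.tri(rho)
  diff <- outer(lab, lab, "!=") & upper.tri(rho)
  expect_gt(mean(rho[same]), mean(rho[diff]))
  # anti-correlated template pair: between-cluster correlations negative
  expect_lt(mean(rho[diff]), 0)
})

test_that("null p-values are uniform and FDR columns are BH-monotone", {
  cfg <- synthetic_config(n_datasets = 2, n_genes = 2000, cluster_spec = list(),
                          n_consistent_genes = 0,
                          missing_rate_by_platform = c(rnaseq = 0), seed = 11)
  col <- generate_collection(cfg)$collection
  for (tab in col$signatures) {
    expect_gt(stats::ks.test(tab$pvalue, "punif")$p.value, 0.01)
    ord <- order(tab$pvalue)
    expect_true(all(diff(tab$fdr[ord]) >= -1e-12))
    expect_true(all(tab$fdr >= tab$pvalue - 1e-12))
  }
})

test_that("platform masking drops whole genes at the configured rate", {
  cfg <- synthetic_config(n_datasets = 4, n_genes = 200, cluster_spec = list(),
                          n_consistent_genes = 0,
                          missing_rate_by_platform = c(rnaseq = 0.05, microarray = 0.25),
                          seed = 2)
  col <- generate_collection(cfg)$collection
  sizes <- vapply(col$signatures, nrow, 1L)
  expected <- ifelse(col$metadata$platform == "rnaseq", 190L, 150L)
  expect_equal(unname(sizes), expected)
})

test_that("planted consistent genes carry their direction in >=90% of datasets", {
  cfg <- synthetic_config(n_datasets = 20, n_genes = 300, cluster_spec = list(),
                          n_consistent_genes = 10, consistent_effect = 2,
                          missing_rate_by_platform = c(rnaseq = 0), seed = 8)
  gen <- generate_collection(cfg)
  carriers <- gen$truth$consistent_carriers
  expect_true(all(lengths(carriers) >= 0.9 * 20))
  dir <- gen$truth$consistent_genes
  for (g in names(dir)) {
    signs <- vapply(gen$collection$signatures, function(t) sign(t$log2fc[t$gene == g]), 0)
    expect_gte(mean(signs == dir[[g]]), 0.9)
  }
})

test_that("gene set generator plants detectable enrichment and writes valid GMT", {
  genes <- sprintf("G%04d", 1:1000)
  truth <- list(consistent_genes = setNames(rep(1, 50), genes[1:50]))
  gs <- generate_gene_sets(genes, n_sets = 10, set_size = 50,
                           enriched_fraction = 0.2, truth = truth, seed = 3)
  expect_length(gs$enriched, 2L)
  expect_true(all(lengths(gs$library$sets) == 50))
  # enriched sets overlap the planted genes far above chance (2.5/50)
  ov <- vapply(gs$library$sets[gs$enriched], function(s)
    length(intersect(s, names(truth$consistent_genes))), 0L)
  expect_true(all(ov >= 30))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs$library, path)
  back <- read_gmt(path)
  expect_identical(back$sets, gs$library$sets)
  # enriched_fraction 0 -> overlaps at chance level
  gs0 <- generate_gene_sets(genes, n_sets = 10, set_size = 50,
                            enriched_fraction = 0, truth = truth, seed = 3)
  ov0 <- vapply(gs0$library$sets, function(s)
    length(intersect(s, names(truth$consistent_genes))), 0L)
  expect_lt(mean(ov0), 10)
})

test_that("network generator honors hub construction rules", {
  genes <- sprintf("G%03d", 1:200)
  deg <- genes[1:20]
  net <- generate_network(genes, n_edges = 100,
                          planted_hubs = list(list(gene = "G100", size = 10,
                                                   deg_fraction = 1.0)),
                          deg_set = deg, seed = 4)
  nb <- neighborhood(net, "G100")
  expect_length(nb, 10L)
  expect_equal(length(intersect(names(nb), deg)), 10L)
  key <- paste(pmin(net$node_a, net$node_b), pmax(net$node_a, net$node_b))
  expect_false(any(duplicated(key)))
  expect_false(any(net$node_a == net$node_b))
  expect_error(generate_network(genes, planted_hubs = list(
    list(gene = "a", size = 2, deg_fraction = 0), list(gene = "a", size = 2, deg_fraction = 0))),
    "duplicate planted hub")
  empty <- generate_network(genes, n_edges = 0, seed = 1)
  expect_equal(nrow(empty), 0L)
})

test_that("marker generator places intervals and shifts trait windows", {
  genes <- sprintf("G%02d", 1:20)
  md <- generate_marker_data(genes, trait_gene_set = genes[1:5], effect = 3,
                             n_markers = 2000, seed = 6)
  gm <- md$gene_models
  expect_true(all(gm$start < gm$end))
  expect_true(all(gm$start[-1] >= gm$end[-nrow(gm)]))   # non-overlapping
  scores <- map_markers(md$markers, gm, window = 50000)
  expect_gt(mean(scores[genes[1:5]]), mean(scores[genes[6:20]]))
  # effect 0 -> trait and background gene scores from the same distribution
  md0 <- generate_marker_data(genes, trait_gene_set = genes[1:5], effect = 0,
                              n_markers = 2000, seed = 6)
  s0 <- map_markers(md0$markers, md0$gene_models, window = 50000)
  expect_gt(stats::ks.test(s0[genes[1:5]], s0[genes[6:20]])$p.value, 0.01)
})
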