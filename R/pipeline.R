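#' Pipeline run configuration
#'
#' Collects every stage threshold at its documented default: per-dataset
#' DEG significance FDR < 0.05; pathway filter FDR < 0.05 with >= 5
#' overlapping DEGs; RRA robustness score < 0.05; directional
#' consistency > 0.70; gene presence >= 0.70 of datasets; top 2500 most
#' variable genes; 10000 MSEA permutations; wKDA FDR < 0.05. Either a
#' [synthetic_config()] (`simulate`) or an input directory of TSVs
#' (`input_dir`, as written by [write_collection()]) must be supplied.
#'
#' @param simulate optional [synthetic_config()]
#' @param input_dir optional directory with metadata.tsv + signatures
#' @param gmt optional GMT path (ignored when simulating: a planted
#'   library is generated)
#' @param network_path optional edge-list TSV (ditto)
#' @param fdr_deg,fdr_pathway,min_overlap,rra,consistency,presence,top_k,msea_perm,msea_window,wkda_fdr,wkda_perm
#'   stage thresholds; defaults as documented above
#' @param seed integer master seed
#' @param outdir output directory
#' @return a `run_config` list
#' @export
run_config <- function(simulate = NULL, input_dir = NULL, gmt = NULL,
                       network_path = NULL,
                       fdr_deg = 0.05, fdr_pathway = 0.05, min_overlap = 5L,
                       rra = 0.05, consistency = 0.70, presence = 0.70,
                       top_k = 2500L, msea_perm = 10000L, msea_window = 50000L,
                       wkda_fdr = 0.05, wkda_perm = 1000L,
                       seed = 1L, outdir = tempfile("xsigmeta_run_")) {
  if (is.null(simulate) && is.null(input_dir))
    stopf("provide either a simulation config or an input directory")
  for (nm in c("fdr_deg", "fdr_pathway", "rra", "consistency", "presence"))
    check_fraction(get(nm), nm)
  structure(list(simulate = simulate, input_dir = input_dir, gmt = gmt,
                 network_path = network_path, fdr_deg = fdr_deg,
                 fdr_pathway = fdr_pathway, min_overlap = as.integer(min_overlap),
                 rra = rra, consistency = consistency, presence = presence,
                 top_k = as.integer(top_k), msea_perm = as.integer(msea_perm),
                 msea_window = as.integer(msea_window), wkda_fdr = wkda_fdr,
                 wkda_perm = as.integer(wkda_perm), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' JSON keys mirror the [run_config()] arguments; a `simulate` object is
#' passed to [synthetic_config()]. (JSON is used as the config dialect —
#' it is a strict YAML subset and round-trips numerics exactly.)
#'
#' @param path JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    if (!is.null(sim$cluster_spec) && is.data.frame(sim$cluster_spec))
      sim$cluster_spec <- lapply(seq_len(nrow(sim$cluster_spec)), function(i)
        Filter(Negate(is.na), as.list(sim$cluster_spec[i, ])))
    raw$simulate <- do.call(synthetic_config, sim)
  }
  do.call(run_config, raw)
}

.log_stage <- function(report, stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
  report$log <- c(report$log, sprintf("[%s] %s", stage, msg))
  report
}

#' Run the full meta-analysis pipeline
#'
#' Stages: simulate-or-ingest, per-dataset DEG counting, KS comparison
#' of DEG counts between chemicals, rank normalization and matrix
#' assembly, imputation, Spearman correlation, cluster calling, 2-D
#' embedding, RRA meta-analysis (overall, direction-agnostic, plus
#' per-direction within each called cluster), directional recurrence,
#' per-dataset pathway ORA with recurrence counting, MSEA, and wKDA.
#' Stages whose inputs are unavailable (no gene sets / markers /
#' network in ingest mode) are skipped with a logged notice. Every
#' stage writes its TSV outputs under `config$outdir`, and a
#' machine-readable `summary.json` collects headline numbers. Identical
#' config + seed gives identical outputs.
#'
#' @param config a [run_config()]
#' @return the run report (named list), invisibly; also written as JSON
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(log = character(), thresholds = config[
    c("fdr_deg", "fdr_pathway", "min_overlap", "rra", "consistency",
      "presence", "top_k", "msea_perm", "msea_window", "wkda_fdr", "wkda_perm")],
    seed = config$seed)

  # --- inputs -------------------------------------------------------
  truth <- NULL; library <- NULL; network <- NULL; marker_data <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    gen <- generate_collection(sim)
    collection <- gen$collection
    truth <- gen$truth
    genes <- sort(unique(unlist(lapply(collection$signatures, function(s) s$gene))))
    gs <- generate_gene_sets(genes, truth = truth, seed = sim$seed + 1L)
    library <- gs$library
    truth$enriched_sets <- gs$enriched
    deg_pool <- names(truth$consistent_genes)
    hubs <- list(list(gene = genes[1], size = 10L, deg_fraction = 0.8))
    network <- generate_network(genes, n_edges = 4L * length(genes) %/% 2L,
                                planted_hubs = hubs, deg_set = deg_pool,
                                seed = sim$seed + 2L)
    truth$key_drivers <- vapply(hubs, `[[`, "", "gene")
    trait_genes <- deg_pool
    marker_data <- generate_marker_data(genes, trait_gene_set = trait_genes,
                                        effect = 3, seed = sim$seed + 3L)
    truth$trait_gene_set <- trait_genes
    write_collection(collection, file.path(config$outdir, "collection"))
    write_gmt(library, file.path(config$outdir, "gene_sets.gmt"))
    write_network(network, file.path(config$outdir, "network.tsv"))
    write_tsv(marker_data$markers, file.path(config$outdir, "markers.tsv"))
    write_tsv(marker_data$gene_models, file.path(config$outdir, "gene_models.tsv"))
    report <- .log_stage(report, "simulate",
                         sprintf("generated %d datasets x %d genes", sim$n_datasets, sim$n_genes))
  } else {
    collection <- read_collection(config$input_dir)
    if (!is.null(config$gmt)) library <- read_gmt(config$gmt)
    if (!is.null(config$network_path)) network <- read_network(config$network_path)
    report <- .log_stage(report, "ingest",
                         sprintf("read %d datasets from %s", length(collection), config$input_dir))
  }

  # --- DEG counts & KS ---------------------------------------------
  counts <- t(vapply(collection$signatures, count_significant,
                     c(n_up = 0L, n_down = 0L), fdr_threshold = config$fdr_deg))
  deg_counts <- data.frame(dataset_id = rownames(counts), counts,
                           total = rowSums(counts), row.names = NULL,
                           stringsAsFactors = FALSE)
  write_tsv(deg_counts, file.path(config$outdir, "deg_counts.tsv"))
  report$deg_counts <- stats::setNames(deg_counts$total, deg_counts$dataset_id)
  report <- .log_stage(report, "count", sprintf("%d datasets counted", nrow(deg_counts)))

  chem <- collection$metadata$chemical
  if (length(unique(chem)) == 2L) {
    split_counts <- split(deg_counts$total, chem)
    ks <- ks_compare(split_counts[[1]], split_counts[[2]])
    report$ks <- list(groups = names(split_counts), D = ks$D, p = ks$p,
                      method = ks$method)
    report <- .log_stage(report, "ks",
                         sprintf("%s vs %s: D=%.3f p=%.3g", names(split_counts)[1],
                                 names(split_counts)[2], ks$D, ks$p))
  }

  # --- normalization, clustering -----------------------------------
  nm <- build_matrix(collection, presence_threshold = config$presence,
                     top_k = config$top_k)
  nm_imp <- impute_matrix(nm, method = "median")
  write_matrix(nm_imp, file.path(config$outdir, "normalized_matrix.tsv"))
  report <- .log_stage(report, "normalize",
                       sprintf("matrix %d genes x %d datasets", nrow(nm), ncol(nm)))

  corr <- spearman_matrix(nm_imp)
  utils::write.table(round(corr, 10), file.path(config$outdir, "correlation.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  clusters <- call_clusters(corr)
  write_tsv(cluster_table(clusters), file.path(config$outdir, "clusters.tsv"))
  report$clusters <- lapply(clusters$clusters, function(cl)
    cl[c("label", "members", "merge_height", "positive_fraction")])
  report <- .log_stage(report, "cluster", sprintf("%d cluster(s) called", length(clusters$clusters)))

  emb <- embed_2d(nm_imp, n_neighbors = min(5L, ncol(nm_imp) - 1L))
  write_tsv(emb, file.path(config$outdir, "embedding.tsv"))

  # --- meta-consistency --------------------------------------------
  rra_all <- run_rra(collection, mode = "any_direction", score_threshold = config$rra)
  write_tsv(rra_all, file.path(config$outdir, "rra_overall.tsv"))
  robust <- rra_all$gene[rra_all$robust]
  report$n_meta_degs <- length(robust)
  report <- .log_stage(report, "rra", sprintf("%d robust meta-DEGs (score < %g)",
                                              length(robust), config$rra))
  for (cl in clusters$clusters) {
    sub <- signature_collection(
      collection$metadata[collection$metadata$dataset_id %in% cl$members, , drop = FALSE],
      collection$signatures[cl$members])
    rra_cl <- run_rra(sub, mode = "per_direction", score_threshold = config$rra)
    write_tsv(rra_cl, file.path(config$outdir, sprintf("rra_cluster_%s.tsv", cl$label)))
  }

  rec <- recurrence(collection, fdr_threshold = config$fdr_deg,
                    consistency_threshold = config$consistency)
  write_tsv(rec, file.path(config$outdir, "recurrence.tsv"))
  report$n_consistent_genes <- sum(rec$consistent)
  report <- .log_stage(report, "recurrence",
                       sprintf("%d recurrent genes, %d consistent", nrow(rec), sum(rec$consistent)))

  # --- enrichment ---------------------------------------------------
  if (!is.null(library)) {
    per_ds <- list()
    for (id in names(collection$signatures)) {
      tab <- collection$signatures[[id]]
      universe <- tab$gene
      for (dir in c("up", "down")) {
        deg <- if (dir == "up") tab$gene[tab$fdr < config$fdr_deg & tab$log2fc > 0]
               else tab$gene[tab$fdr < config$fdr_deg & tab$log2fc < 0]
        if (length(deg) == 0L) next
        enr <- enrich_library(deg, library, universe = universe,
                              fdr_threshold = config$fdr_pathway,
                              min_overlap = config$min_overlap)
        enr$dataset_id <- id
        enr$direction <- dir
        per_ds[[paste(id, dir)]] <- enr
      }
    }
    if (length(per_ds)) {
      all_enr <- do.call(rbind, per_ds)
      write_tsv(all_enr, file.path(config$outdir, "enrichment.tsv"))
      prec <- pathway_recurrence(per_ds)
      write_tsv(prec, file.path(config$outdir, "pathway_recurrence.tsv"))
      report$n_recurrent_pathways <- nrow(prec)
      report <- .log_stage(report, "enrich",
                           sprintf("%d set-dataset tests, %d recurrent sets",
                                   nrow(all_enr), nrow(prec)))
    } else {
      report <- .log_stage(report, "enrich", "no DEG lists; skipped")
    }
  } else {
    report <- .log_stage(report, "enrich", "no gene-set library; skipped")
  }

  # --- MSEA ---------------------------------------------------------
  if (!is.null(marker_data) && length(robust) > 0) {
    scores <- map_markers(marker_data$markers, marker_data$gene_models,
                          window = config$msea_window)
    msea <- msea_test(list(meta_degs = robust),
                      list(trait1 = scores), n_perm = config$msea_perm,
                      seed = config$seed + 10L)
    write_tsv(msea, file.path(config$outdir, "msea.tsv"))
    report$msea <- msea[, c("deg_set", "trait", "z", "pvalue", "fdr")]
    report <- .log_stage(report, "msea", sprintf("%d pair(s) tested", nrow(msea)))
  } else {
    report <- .log_stage(report, "msea", "no marker data; skipped")
  }

  # --- wKDA ---------------------------------------------------------
  if (!is.null(network) && length(robust) > 0) {
    kd <- run_wkda(network, list(meta_degs = robust), n_perm = config$wkda_perm,
                   seed = config$seed + 20L, fdr_threshold = config$wkda_fdr)
    write_tsv(kd, file.path(config$outdir, "wkda.tsv"))
    report$n_key_drivers <- sum(kd$significant)
    report$top_key_driver <- if (nrow(kd)) kd$node[1] else NA_character_
    report <- .log_stage(report, "wkda",
                         sprintf("%d significant key driver(s)", sum(kd$significant)))
  } else {
    report <- .log_stage(report, "wkda", "no network; skipped")
  }

  if (!is.null(truth)) report$truth <- truth
  summary_path <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(report[setdiff(names(report), "truth")], summary_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- .log_stage(report, "done", sprintf("summary written to %s", summary_path))
  invisible(report)
}
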