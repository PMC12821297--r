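#' Configuration for the synthetic signature generator
#'
#' Describes the world the generator emulates: a collection of
#' post-differential-expression summary tables whose log2 fold changes
#' carry latent cluster templates, globally consistent planted genes,
#' platform-dependent gene coverage, and a z-test p-value model.
#'
#' `cluster_spec` is a list of entries `list(label=, n=, scale=, anti=)`;
#' `anti` (optional) names an earlier cluster whose template is negated,
#' producing an anti-correlated cluster pair. Datasets beyond the summed
#' cluster sizes are unclustered pure-noise datasets.
#'
#' `noise_sd` is the per-replicate noise SD; the signature-level noise on
#' a log2 fold change is `noise_sd / sqrt(group_size)`, so the generated
#' p-values `2 * pnorm(-|log2fc| * sqrt(group_size) / noise_sd)` are
#' exactly uniform under zero signal.
#'
#' @param n_datasets,n_genes collection dimensions
#' @param cluster_spec list of cluster descriptors (see Details)
#' @param n_template_genes genes carrying each cluster template
#'   (default: a fifth of `n_genes`)
#' @param noise_sd per-replicate noise SD on log2FC (default 0.5)
#' @param missing_rate_by_platform named fractions in \[0,1): genes absent
#'   per platform (dataset-level masking)
#' @param n_consistent_genes planted globally consistent genes
#' @param consistent_effect additive |log2FC| of planted consistent genes
#' @param consistent_dataset_fraction fraction of datasets carrying each
#'   planted effect (default 0.95, i.e. >= 90% as required)
#' @param group_size nominal replicate count in the p-value model
#' @param seed integer seed; equal seeds give bit-identical collections
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_datasets = 24L,
                             n_genes = 2000L,
                             cluster_spec = list(
                               list(label = "C1", n = 10L, scale = 1.0),
                               list(label = "C2", n = 10L, scale = 1.0, anti = "C1")),
                             n_template_genes = NULL,
                             noise_sd = 0.5,
                             missing_rate_by_platform = c(rnaseq = 0.05, microarray = 0.25),
                             n_consistent_genes = 30L,
                             consistent_effect = 1.5,
                             consistent_dataset_fraction = 0.95,
                             group_size = 6L,
                             seed = 1L) {
  n_template_genes <- n_template_genes %||% max(1L, n_genes %/% 5L)
  for (nm in c("n_datasets", "n_genes", "n_template_genes", "group_size"))
    if (!is_count(get(nm)) || get(nm) <= 0) stopf("'%s' must be a positive count", nm)
  if (!is_count(n_consistent_genes)) stopf("'n_consistent_genes' must be a count")
  for (r in missing_rate_by_platform) check_fraction(r, "missing_rate_by_platform", allow_one = FALSE)
  check_fraction(consistent_dataset_fraction, "consistent_dataset_fraction")
  if (noise_sd <= 0) stopf("'noise_sd' must be positive")
  labels <- vapply(cluster_spec, `[[`, "", "label")
  if (anyDuplicated(labels)) stopf("duplicated cluster label")
  if (sum(vapply(cluster_spec, `[[`, 0, "n")) > n_datasets)
    stopf("cluster member counts exceed n_datasets")
  if (n_template_genes > n_genes) stopf("n_template_genes exceeds n_genes")
  structure(list(n_datasets = as.integer(n_datasets), n_genes = as.integer(n_genes),
                 cluster_spec = cluster_spec,
                 n_template_genes = as.integer(n_template_genes),
                 noise_sd = noise_sd,
                 missing_rate_by_platform = missing_rate_by_platform,
                 n_consistent_genes = as.integer(n_consistent_genes),
                 consistent_effect = consistent_effect,
                 consistent_dataset_fraction = consistent_dataset_fraction,
                 group_size = as.integer(group_size), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic signature collection with planted truth
#'
#' For each dataset d in cluster c, `log2fc(g,d) = scale_c * T_c(g) + eps`
#' where `T_c` is a Normal(0,1) template on a random subset of
#' `n_template_genes` genes and `eps ~ N(0, (noise_sd/sqrt(group_size))^2)`.
#' Planted consistent genes add a fixed directional effect in
#' `consistent_dataset_fraction` of the datasets. P-values follow the
#' Gaussian z-test surrogate `2 * pnorm(-|log2fc| sqrt(group_size)/noise_sd)`,
#' FDR is Benjamini-Hochberg within each dataset, and whole genes are
#' masked per dataset at the platform's missing rate.
#'
#' @param config a [synthetic_config()]
#' @return list with elements `collection` (a [signature_collection()]) and
#'   `truth` (cluster assignment, consistent gene directions, and the
#'   template gene ids per cluster)
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    ids <- sprintf("DS%03d", seq_len(config$n_datasets))
    eff_sd <- config$noise_sd / sqrt(config$group_size)

    # dataset-level assignment: clusters first, remainder unclustered noise
    assignment <- rep(NA_character_, config$n_datasets)
    scales <- rep(0, config$n_datasets)
    pos <- 1L
    templates <- list()
    for (cs in config$cluster_spec) {
      if (!is.null(cs$anti)) {
        if (is.null(templates[[cs$anti]])) stopf("anti reference '%s' not defined yet", cs$anti)
        templates[[cs$label]] <- -templates[[cs$anti]]
      } else {
        tmpl <- numeric(config$n_genes)
        on <- sample.int(config$n_genes, config$n_template_genes)
        tmpl[on] <- stats::rnorm(config$n_template_genes)
        templates[[cs$label]] <- tmpl
      }
      idx <- seq.int(pos, pos + cs$n - 1L)
      assignment[idx] <- cs$label
      scales[idx] <- cs$scale
      pos <- pos + cs$n
    }

    template_genes <- unique(unlist(lapply(templates, function(t) genes[t != 0])))
    pool <- setdiff(genes, template_genes)
    if (length(pool) < config$n_consistent_genes) pool <- genes
    consistent <- if (config$n_consistent_genes > 0)
      sort(sample(pool, config$n_consistent_genes)) else character()
    direction <- stats::setNames(
      rep_len(c(1, -1), length(consistent)), consistent)
    n_carry <- ceiling(config$consistent_dataset_fraction * config$n_datasets)
    carriers <- lapply(consistent, function(g) sort(sample.int(config$n_datasets, n_carry)))
    names(carriers) <- consistent

    platforms <- rep_len(names(config$missing_rate_by_platform), config$n_datasets)
    chemicals <- rep_len(c("THC", "CBD"), config$n_datasets)

    sigs <- vector("list", config$n_datasets)
    for (d in seq_len(config$n_datasets)) {
      base <- if (!is.na(assignment[d])) scales[d] * templates[[assignment[d]]] else 0
      l2fc <- base + stats::rnorm(config$n_genes, 0, eff_sd)
      for (g in consistent)
        if (d %in% carriers[[g]])
          l2fc[match(g, genes)] <- l2fc[match(g, genes)] +
            direction[[g]] * config$consistent_effect
      p <- 2 * stats::pnorm(-abs(l2fc) * sqrt(config$group_size) / config$noise_sd)
      rate <- config$missing_rate_by_platform[[platforms[d]]]
      keep <- rep(TRUE, config$n_genes)
      n_mask <- floor(rate * config$n_genes)
      if (n_mask > 0) keep[sample.int(config$n_genes, n_mask)] <- FALSE
      fdr <- bh_adjust(p[keep])
      sigs[[d]] <- signature_table(ids[d], genes[keep], l2fc[keep], p[keep], fdr)
    }
    names(sigs) <- ids

    md <- data.frame(
      dataset_id = ids,
      study_accession = sprintf("SYN%05d", seq_len(config$n_datasets)),
      chemical = chemicals,
      species = "human",
      tissue = rep_len(c("brain", "liver", "blood"), config$n_datasets),
      platform = platforms,
      exposure = rep_len(c("in_vivo", "in_vitro"), config$n_datasets),
      route = "oral", sex = "mixed", dose = "10mg/kg", duration = "7d",
      n_treatment = config$group_size, n_control = config$group_size,
      stringsAsFactors = FALSE)

    truth <- list(
      cluster_assignment = stats::setNames(assignment, ids),
      consistent_genes = direction,
      consistent_carriers = carriers,
      template_genes = lapply(templates, function(t) genes[t != 0]),
      enriched_sets = character(), key_drivers = character(),
      trait_gene_set = character())
    list(collection = signature_collection(md, sigs), truth = truth)
  })
}

#' Generate a GMT-style gene-set library with planted enrichment
#'
#' `n_sets * enriched_fraction` sets (rounded) are sampled preferentially
#' from the planted consistent genes in `truth` (a `planted_weight`
#' fraction of each enriched set's members, capped by availability); all
#' other members and all other sets are uniform draws from `genes`.
#'
#' @param genes universe of gene identifiers
#' @param n_sets,set_size library shape
#' @param enriched_fraction fraction of sets planted as enriched
#' @param truth truth list from [generate_collection()]
#' @param planted_weight fraction of an enriched set drawn from the
#'   planted consistent genes (default 0.8)
#' @param seed integer seed
#' @return list: `library` (a [gene_set_library()]) and `enriched`
#'   (character vector of truly enriched set names)
#' @export
generate_gene_sets <- function(genes, n_sets = 20L, set_size = 50L,
                               enriched_fraction = 0.1, truth,
                               planted_weight = 0.8, seed = 1L) {
  if (set_size > length(genes)) stopf("set_size exceeds number of genes")
  check_fraction(enriched_fraction, "enriched_fraction")
  withr::with_seed(seed, {
    n_enriched <- round(n_sets * enriched_fraction)
    planted <- intersect(names(truth$consistent_genes), genes)
    sets <- vector("list", n_sets)
    names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
    for (i in seq_len(n_sets)) {
      if (i <= n_enriched && length(planted)) {
        k <- min(length(planted), round(planted_weight * set_size))
        core <- sample(planted, k)
        rest <- sample(setdiff(genes, core), set_size - k)
        sets[[i]] <- sort(c(core, rest))
      } else {
        sets[[i]] <- sort(sample(genes, set_size))
      }
    }
    list(library = gene_set_library(sets, universe = genes),
         enriched = names(sets)[seq_len(n_enriched)])
  })
}

#' Generate a weighted gene network with planted hubs
#'
#' Background edges are uniform random gene pairs with weight 1 (no
#' self-loops, no duplicate unordered pairs). Each planted hub is
#' connected to a neighborhood of the requested size in which a
#' `deg_fraction` share of neighbors belongs to `deg_set`.
#'
#' @param genes node universe
#' @param n_edges background edge count
#' @param planted_hubs list of `list(gene=, size=, deg_fraction=)`
#' @param deg_set genes counted as DEGs when wiring hub neighborhoods
#' @param seed integer seed
#' @return a [gene_network()]
#' @export
generate_network <- function(genes, n_edges = 2000L, planted_hubs = list(),
                             deg_set = character(), seed = 1L) {
  hubs <- vapply(planted_hubs, `[[`, "", "gene")
  if (anyDuplicated(hubs)) stopf("duplicate planted hub")
  for (h in planted_hubs)
    if (h$size > length(genes) - 1L) stopf("hub neighborhood exceeds n_genes - 1")
  withr::with_seed(seed, {
    edges <- data.frame(node_a = character(), node_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
    for (h in planted_hubs) {
      n_deg <- round(h$size * h$deg_fraction)
      deg_pool <- setdiff(intersect(deg_set, genes), h$gene)
      bg_pool <- setdiff(genes, c(deg_set, h$gene))
      nb <- c(sample(deg_pool, min(n_deg, length(deg_pool))),
              sample(bg_pool, h$size - min(n_deg, length(deg_pool))))
      edges <- rbind(edges, data.frame(node_a = h$gene, node_b = nb, weight = 1,
                                       stringsAsFactors = FALSE))
    }
    if (n_edges > 0) {
      # background edges avoid hub nodes so planted neighborhoods stay exact;
      # oversample, canonicalize, dedupe against self and hub edges
      bg_genes <- setdiff(genes, hubs)
      m <- 0L
      want <- n_edges
      seen <- paste(pmin(edges$node_a, edges$node_b),
                    pmax(edges$node_a, edges$node_b))
      out_a <- character(0); out_b <- character(0)
      while (m < want) {
        a <- sample(bg_genes, 2L * (want - m), replace = TRUE)
        b <- sample(bg_genes, 2L * (want - m), replace = TRUE)
        ok <- a != b
        a <- a[ok]; b <- b[ok]
        key <- paste(pmin(a, b), pmax(a, b))
        new <- !(key %in% seen) & !duplicated(key)
        a <- a[new]; b <- b[new]; key <- key[new]
        take <- seq_len(min(length(a), want - m))
        out_a <- c(out_a, a[take]); out_b <- c(out_b, b[take])
        seen <- c(seen, key[take])
        m <- length(out_a)
      }
      edges <- rbind(edges, data.frame(node_a = out_a, node_b = out_b,
                                       weight = 1, stringsAsFactors = FALSE))
    }
    gene_network(edges)
  })
}

#' Generate a synthetic marker (GWAS-like) table and gene models
#'
#' Genes receive non-overlapping intervals on one synthetic chromosome
#' (`start = (i-1) * spacing`, length `gene_length`, 0-based half-open).
#' Markers are placed uniformly along the chromosome; every marker's null
#' association score is `-log10(U)` with U ~ Uniform(0,1), and markers
#' falling within `window` bp of a gene in `trait_gene_set` have their
#' score shifted up by `effect`.
#'
#' @param genes gene identifiers
#' @param trait_gene_set genes carrying planted associations
#' @param effect additive shift on -log10 p for trait-window markers
#' @param n_markers marker count
#' @param gene_length,spacing interval layout in bp (defaults keep 50 kb
#'   windows of adjacent genes disjoint: spacing > gene_length + 2*window)
#' @param window assignment window in bp (default 50000)
#' @param seed integer seed
#' @return list: `markers` (marker_id, chrom, pos, score), `gene_models`
#'   (chrom, start, end, gene), `genome_length`
#' @export
generate_marker_data <- function(genes, trait_gene_set = character(),
                                 effect = 3, n_markers = 5000L,
                                 gene_length = 10000L, spacing = 120000L,
                                 window = 50000L, seed = 1L) {
  if (spacing < gene_length) stopf("spacing must be >= gene_length (non-overlapping intervals)")
  withr::with_seed(seed, {
    n <- length(genes)
    start <- (seq_len(n) - 1L) * spacing
    gm <- data.frame(chrom = "chr1", start = start, end = start + gene_length,
                     gene = genes, stringsAsFactors = FALSE)
    genome_length <- n * spacing + window
    pos <- sort(sample.int(genome_length, n_markers, replace = TRUE)) - 1L
    score <- -log10(stats::runif(n_markers))
    trait <- gm[gm$gene %in% trait_gene_set, , drop = FALSE]
    if (nrow(trait) > 0 && effect != 0) {
      in_window <- rep(FALSE, n_markers)
      for (i in seq_len(nrow(trait)))
        in_window <- in_window |
          (pos >= trait$start[i] - window & pos < trait$end[i] + window)
      score[in_window] <- score[in_window] + effect
    }
    markers <- data.frame(marker_id = sprintf("M%06d", seq_len(n_markers)),
                          chrom = "chr1", pos = pos, score = score,
                          stringsAsFactors = FALSE)
    list(markers = markers, gene_models = gm, genome_length = genome_length)
  })
}
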