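#' Gene-set library container
#'
#' Named, non-empty gene sets (genes unique within a set) with an
#' optional explicit universe.
#'
#' @param sets named list of character vectors
#' @param universe optional explicit gene universe
#' @return a `gene_set_library`
#' @export
gene_set_library <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("gene sets must be named")
  if (anyDuplicated(names(sets))) stopf("duplicated set name")
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) stopf("empty gene set(s): %s", paste(empty, collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets, universe = universe), class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library: %d sets (sizes %d-%d)%s\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              if (is.null(x$universe)) "" else
                sprintf(", universe %d genes", length(x$universe))))
  invisible(x)
}

#' Read / write GMT gene-set libraries
#'
#' Standard GMT: one set per line, tab-separated fields set name,
#' description, then member genes.
#'
#' @param path file path
#' @param library a [gene_set_library()]
#' @param descriptions optional named character of set descriptions
#' @return `read_gmt`: a `gene_set_library`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("GMT line with fewer than 3 fields: %.40s", ln)
    sets[[f[1]]] <- f[-(1:2)]
  }
  gene_set_library(sets)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  lines <- vapply(names(library$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, library$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# one-sided hypergeometric upper tail P(X >= overlap)
hyper_tail_p <- function(overlap, set_size, list_size, universe_size) {
  if (overlap <= 0) return(1)
  stats::phyper(overlap - 1, set_size, universe_size - set_size, list_size,
                lower.tail = FALSE)
}

#' Fisher-exact over-representation of a DEG list in one gene set
#'
#' One-sided (enrichment) hypergeometric tail:
#' `p = P(overlap >= observed)` for a list of size n drawn from a
#' universe of size N containing a set of size K. Inputs are intersected
#' with the universe first.
#'
#' @param deg_list character vector of DEGs
#' @param gene_set character vector, the set being tested
#' @param universe character vector; must be non-empty
#' @param name optional set name carried into the result
#' @return one-row data.frame (set, overlap, set_size, list_size,
#'   universe_size, pvalue)
#' @export
fisher_ora <- function(deg_list, gene_set, universe, name = "set") {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("empty universe")
  deg <- intersect(unique(as.character(deg_list)), universe)
  set <- intersect(unique(as.character(gene_set)), universe)
  ov <- length(intersect(deg, set))
  p <- if (length(deg) == 0L) 1 else
    hyper_tail_p(ov, length(set), length(deg), length(universe))
  data.frame(set = name, overlap = ov, set_size = length(set),
             list_size = length(deg), universe_size = length(universe),
             pvalue = p, stringsAsFactors = FALSE)
}

#' Test a DEG list against every set in a library
#'
#' Runs [fisher_ora()] per set, BH-adjusts p-values across the library,
#' and labels each set `significant` when `fdr < fdr_threshold` and the
#' overlap is at least `min_overlap` (defaults 0.05 and 5, the "FDR < 5%
#' and >= 5 overlapping DEGs" rule). A `tier` column applies the
#' targeted-panel convention on raw p: significant (p < 0.05),
#' suggestive (p < 0.10), ns.
#'
#' @param deg_list character vector of DEGs
#' @param library a [gene_set_library()]
#' @param universe explicit universe; defaults to the library's, else
#'   the union of set members and the DEG list
#' @param fdr_threshold,min_overlap significance filter (0.05, 5)
#' @return data.frame, one row per set, sorted by p-value
#' @export
enrich_library <- function(deg_list, library, universe = NULL,
                           fdr_threshold = 0.05, min_overlap = 5L) {
  universe <- universe %||% library$universe %||%
    unique(c(unlist(library$sets), deg_list))
  rows <- lapply(names(library$sets), function(nm)
    fisher_ora(deg_list, library$sets[[nm]], universe, name = nm))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out$significant <- out$fdr < fdr_threshold & out$overlap >= min_overlap
  out$tier <- ora_tier(out$pvalue)
  out[order(out$pvalue, out$set), , drop = FALSE]
}

ora_tier <- function(p) {
  ifelse(p < 0.05, "significant", ifelse(p < 0.10, "suggestive", "ns"))
}

#' Tier per-dataset results for a fixed targeted gene set
#'
#' For a single panel (e.g. an endocannabinoid-system gene set) tested
#' once per dataset, labels each dataset significant (p < 0.05),
#' suggestive (0.05 <= p < 0.10) or ns, and tabulates tiers by a
#' grouping column (e.g. brain vs peripheral tissue) when present.
#'
#' @param per_dataset_results data.frame with columns `dataset_id`,
#'   `pvalue`, and optionally `tissue_class`
#' @return list: `table` (input + `tier`), `summary` (tier counts,
#'   by tissue_class if available)
#' @export
ecs_tiers <- function(per_dataset_results) {
  df <- per_dataset_results
  if (!all(c("dataset_id", "pvalue") %in% names(df)))
    stopf("need columns dataset_id, pvalue")
  df$tier <- ora_tier(df$pvalue)
  summary <- if ("tissue_class" %in% names(df))
    as.data.frame(table(tissue_class = df$tissue_class, tier = df$tier),
                  stringsAsFactors = FALSE)
  else
    as.data.frame(table(tier = df$tier), stringsAsFactors = FALSE)
  list(table = df, summary = summary)
}

#' Count how often each set is significantly enriched across datasets
#'
#' Given per-dataset enrichment tables labeled with a dataset id and the
#' DEG direction they were computed from ("up"/"down"), counts for each
#' set the datasets in which it passed the significance filter, split by
#' direction. Sets never significant are absent.
#'
#' @param per_dataset_enrichments list of data.frames as returned by
#'   [enrich_library()], each carrying `dataset_id` and `direction`
#'   columns
#' @return data.frame (set, n_up, n_down, total), total descending
#' @export
pathway_recurrence <- function(per_dataset_enrichments) {
  all <- do.call(rbind, per_dataset_enrichments)
  if (is.null(all) || !nrow(all))
    return(data.frame(set = character(), n_up = integer(),
                      n_down = integer(), total = integer()))
  if (!all(c("dataset_id", "direction") %in% names(all)))
    stopf("enrichment tables must carry dataset_id and direction columns")
  sig <- all[all$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(set = character(), n_up = integer(),
                      n_down = integer(), total = integer()))
  counts <- stats::aggregate(
    list(n = sig$dataset_id),
    by = list(set = sig$set, direction = sig$direction),
    FUN = function(x) length(unique(x)))
  wide <- data.frame(set = unique(counts$set), stringsAsFactors = FALSE)
  for (dir in c("up", "down")) {
    m <- counts[counts$direction == dir, ]
    wide[[paste0("n_", dir)]] <-
      ifelse(wide$set %in% m$set, m$n[match(wide$set, m$set)], 0L)
  }
  wide$total <- wide$n_up + wide$n_down
  wide[order(-wide$total, wide$set), , drop = FALSE]
}
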