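#' Construct a per-dataset DE signature table
#'
#' The pipeline's atomic input: one study's gene-level differential
#' expression summary (log2 fold change, p-value, BH FDR). Gene
#' identifiers must be unique within a table, log2fc finite, and p/FDR
#' inside \[0, 1\].
#'
#' @param dataset_id scalar identifier for the dataset
#' @param gene character vector of gene identifiers
#' @param log2fc numeric, finite log2 fold changes (treatment vs control)
#' @param pvalue,fdr numeric in \[0, 1\]
#' @return a `signature_table` (data.frame with a `dataset_id` attribute)
#' @export
signature_table <- function(dataset_id, gene, log2fc, pvalue, fdr) {
  df <- data.frame(gene = as.character(gene), log2fc = as.numeric(log2fc),
                   pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                   stringsAsFactors = FALSE)
  validate_signature_table(df, dataset_id)
  attr(df, "dataset_id") <- as.character(dataset_id)
  class(df) <- c("signature_table", "data.frame")
  df
}

validate_signature_table <- function(df, dataset_id = "<unnamed>") {
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup))
    stopf("dataset %s: duplicated gene identifier(s): %s",
          dataset_id, paste(utils::head(dup, 5), collapse = ", "))
  if (any(!is.finite(df$log2fc)))
    stopf("dataset %s: non-finite log2fc values", dataset_id)
  for (col in c("pvalue", "fdr")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad))
      stopf("dataset %s: %s outside [0,1] at row %d (gene %s)",
            dataset_id, col, bad[1], df$gene[bad[1]])
  }
  invisible(df)
}

#' @describeIn signature_table accessor for the dataset identifier
#' @param x a `signature_table`
#' @export
dataset_id <- function(x) attr(x, "dataset_id")

#' Read / write a signature table as TSV
#'
#' Columns `gene`, `log2fc`, `pvalue`, `fdr`; tab-separated, header
#' required, UTF-8, '.' decimal. A write-then-read round trip is the
#' identity up to numeric formatting (~1e-15 relative). Malformed rows are
#' rejected with row-indexed diagnostics; a missing column is a format
#' error.
#'
#' @param path file path
#' @param id dataset identifier; defaults to the file name without extension
#' @return `read_signature`: a [signature_table()]
#' @export
read_signature <- function(path, id = NULL) {
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  df <- read_tsv_strict(path, required = c("gene", "log2fc", "pvalue", "fdr"),
                        numeric_cols = c("log2fc", "pvalue", "fdr"))
  signature_table(id, df$gene, df$log2fc, df$pvalue, df$fdr)
}

#' @rdname read_signature
#' @param table a [signature_table()]
#' @export
write_signature <- function(table, path) {
  out <- as.data.frame(table)[, c("gene", "log2fc", "pvalue", "fdr")]
  out$log2fc <- format(out$log2fc, digits = 17, trim = TRUE, scientific = FALSE)
  out$pvalue <- format(out$pvalue, digits = 17, trim = TRUE)
  out$fdr <- format(out$fdr, digits = 17, trim = TRUE)
  write_tsv(out, path)
}

.platforms <- c("rnaseq", "microarray")
.exposures <- c("in_vivo", "in_vitro")

validate_metadata <- function(md) {
  req <- c("dataset_id", "chemical", "species", "tissue", "platform", "exposure")
  missing <- setdiff(req, names(md))
  if (length(missing))
    stopf("metadata: missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(md$dataset_id))
    stopf("metadata: duplicated dataset_id")
  if (!all(md$platform %in% .platforms))
    stopf("metadata: platform must be one of: %s", paste(.platforms, collapse = ", "))
  if (!all(md$exposure %in% .exposures))
    stopf("metadata: exposure must be one of: %s", paste(.exposures, collapse = ", "))
  invisible(md)
}

#' Bundle signature tables with study metadata
#'
#' A `signature_collection` pairs a study-metadata table (one row per
#' dataset: chemical, species, tissue, platform, exposure, ...) with a
#' named list of [signature_table()]s. The two must describe exactly the
#' same dataset_ids.
#'
#' @param metadata data.frame of per-dataset metadata
#' @param signatures named list of `signature_table`s, names = dataset_ids
#' @return a `signature_collection`
#' @export
signature_collection <- function(metadata, signatures) {
  validate_metadata(metadata)
  if (is.null(names(signatures)) || any(names(signatures) == ""))
    stopf("signatures must be a named list keyed by dataset_id")
  extra <- setdiff(names(signatures), metadata$dataset_id)
  absent <- setdiff(metadata$dataset_id, names(signatures))
  if (length(extra) || length(absent))
    stopf("metadata/signature mismatch; missing tables: [%s], missing metadata: [%s]",
          paste(absent, collapse = ","), paste(extra, collapse = ","))
  signatures <- signatures[metadata$dataset_id]
  structure(list(metadata = metadata, signatures = signatures),
            class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("signature_collection: %d datasets, %d-%d genes per table\n",
              length(x$signatures),
              min(vapply(x$signatures, nrow, 1L)),
              max(vapply(x$signatures, nrow, 1L))))
  invisible(x)
}

#' @export
length.signature_collection <- function(x) length(x$signatures)

#' Write / read a collection as a directory of TSVs
#'
#' `metadata.tsv` plus one `<dataset_id>.tsv` per signature.
#'
#' @param collection a [signature_collection()]
#' @param dir directory (created if needed)
#' @return `read_collection`: a `signature_collection`
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(collection$metadata, file.path(dir, "metadata.tsv"))
  for (id in names(collection$signatures))
    write_signature(collection$signatures[[id]], file.path(dir, paste0(id, ".tsv")))
  invisible(dir)
}

#' @rdname write_collection
#' @export
read_collection <- function(dir) {
  md <- read_tsv_strict(file.path(dir, "metadata.tsv"), required = "dataset_id")
  for (col in c("n_treatment", "n_control"))
    if (col %in% names(md)) md[[col]] <- as.integer(md[[col]])
  sigs <- lapply(md$dataset_id, function(id)
    read_signature(file.path(dir, paste0(id, ".tsv")), id = id))
  names(sigs) <- md$dataset_id
  signature_collection(md, sigs)
}

#' Construct an ortholog map
#'
#' Rows of (source_gene, source_species, human_gene), keyed on the first
#' two columns. Used to lift non-human signatures onto human symbols.
#'
#' @param source_gene,source_species,human_gene character vectors
#' @return data.frame of class `ortholog_map`
#' @export
ortholog_map <- function(source_gene, source_species, human_gene) {
  df <- data.frame(source_gene = as.character(source_gene),
                   source_species = as.character(source_species),
                   human_gene = as.character(human_gene),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$human_gene)) || any(is.na(df$human_gene)))
    stopf("ortholog_map: empty human_gene target")
  key <- paste(df$source_gene, df$source_species, sep = "\r")
  if (anyDuplicated(key)) stopf("ortholog_map: duplicated (source_gene, source_species) key")
  class(df) <- c("ortholog_map", "data.frame")
  df
}

.human_species <- c("human", "homo sapiens")

#' Harmonize a collection onto human gene symbols
#'
#' Signatures from non-human species are mapped through an
#' [ortholog_map()]. When several source genes collapse onto one human
#' gene, the row with the smallest p-value wins (ties: largest |log2fc|,
#' then lexicographically smallest source gene). Genes with no mapping
#' are dropped, with a warning reporting the total dropped count.
#' Harmonization is idempotent: a collection already harmonized is
#' returned unchanged.
#'
#' @param collection a [signature_collection()]
#' @param map an [ortholog_map()]
#' @return harmonized `signature_collection` (gene axis = human symbols)
#' @export
harmonize <- function(collection, map) {
  if (isTRUE(attr(collection, "harmonized"))) return(collection)
  md <- collection$metadata
  n_dropped <- 0L
  sigs <- lapply(seq_len(nrow(md)), function(i) {
    id <- md$dataset_id[i]
    sp <- tolower(md$species[i])
    tab <- as.data.frame(collection$signatures[[id]])
    if (sp %in% .human_species)
      return(signature_table(id, tab$gene, tab$log2fc, tab$pvalue, tab$fdr))
    sub <- map[map$source_species == md$species[i], , drop = FALSE]
    hg <- sub$human_gene[match(tab$gene, sub$source_gene)]
    keep <- !is.na(hg)
    n_dropped <<- n_dropped + sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    src <- tab$gene
    tab$gene <- hg[keep]
    if (nrow(tab) > 1) {
      # collapse many-to-one: min p, then max |log2fc|, then source gene name
      ord <- order(tab$gene, tab$pvalue, -abs(tab$log2fc), src)
      tab <- tab[ord, , drop = FALSE]
      tab <- tab[!duplicated(tab$gene), , drop = FALSE]
    }
    signature_table(id, tab$gene, tab$log2fc, tab$pvalue, tab$fdr)
  })
  names(sigs) <- md$dataset_id
  if (n_dropped > 0)
    warnf("harmonize: dropped %d unmapped gene row(s)", n_dropped)
  out <- signature_collection(md, sigs)
  attr(out, "harmonized") <- TRUE
  out
}

#' Count significant DEGs in a table
#'
#' A gene is an up-DEG when `fdr < fdr_threshold` and `log2fc > 0`, a
#' down-DEG when `fdr < fdr_threshold` and `log2fc < 0`. Genes with
#' log2fc exactly 0 have no direction and are counted in neither. The
#' default threshold 0.05 is the FDR < 5% significance rule.
#'
#' @param table a [signature_table()]
#' @param fdr_threshold significance cutoff on FDR (default 0.05)
#' @return named integer vector `c(n_up = , n_down = )`
#' @export
count_significant <- function(table, fdr_threshold = 0.05) {
  sig <- table$fdr < fdr_threshold
  c(n_up = sum(sig & table$log2fc > 0),
    n_down = sum(sig & table$log2fc < 0))
}
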