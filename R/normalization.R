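#' Rank-normalize a signature's log2 fold changes to \[-1, 1\]
#'
#' RNA-seq and microarray studies report fold changes on different
#' scales, so each dataset is standardized by within-sign ranks: positive
#' log2FCs are ranked ascending and scaled to (0, 1\] as `rank / n_pos`
#' (largest fold change -> 1); negative log2FCs get `-rank / n_neg` where
#' rank 1 is the negative value closest to zero, so the most
#' downregulated gene -> -1; exact zeros map to 0. Within each sign
#' group the mapping is strictly monotone in log2fc and depends on ranks
#' only; ties share the mean of their ranks.
#'
#' @param table a [signature_table()]
#' @return named numeric vector (genes) with values in \[-1, 1\]
#' @export
rank_normalize <- function(table) {
  x <- table$log2fc
  out <- numeric(length(x))
  pos <- x > 0
  neg <- x < 0
  if (any(pos)) out[pos] <- rank(x[pos], ties.method = "average") / sum(pos)
  if (any(neg)) out[neg] <- -rank(-x[neg], ties.method = "average") / sum(neg)
  stats::setNames(out, table$gene)
}

#' Build the genes x datasets normalized fold-change matrix
#'
#' Applies [rank_normalize()] to every dataset, assembles the union gene
#' axis (missing cells NA), optionally drops genes observed in fewer
#' than `presence_threshold` of the datasets, then keeps the `top_k`
#' genes by variance of the normalized values (NA cells excluded from
#' the variance; ties broken by gene name for determinism). Defaults
#' mirror the large mixed-collection filters: presence >= 70%, top 2500
#' most variable genes. Pass `presence_threshold = NULL` to skip
#' presence filtering (single-chemical mode).
#'
#' @param collection a [signature_collection()]
#' @param presence_threshold fraction of datasets a gene must be present
#'   in, or NULL to skip (default 0.70)
#' @param top_k number of most-variable genes retained (default 2500)
#' @return numeric matrix of class `normalized_matrix`, genes x datasets,
#'   cells in \[-1, 1\] or NA
#' @export
build_matrix <- function(collection, presence_threshold = 0.70, top_k = 2500L) {
  if (length(collection$signatures) < 2L) stopf("need at least 2 datasets")
  if (!is.null(presence_threshold)) check_fraction(presence_threshold, "presence_threshold")
  norm <- lapply(collection$signatures, rank_normalize)
  genes <- sort(unique(unlist(lapply(norm, names))))
  mat <- matrix(NA_real_, length(genes), length(norm),
                dimnames = list(genes, names(norm)))
  for (j in seq_along(norm)) mat[names(norm[[j]]), j] <- norm[[j]]
  if (!is.null(presence_threshold)) {
    present <- rowMeans(!is.na(mat))
    mat <- mat[present >= presence_threshold, , drop = FALSE]
  }
  if (nrow(mat) > top_k) {
    v <- apply(mat, 1, stats::var, na.rm = TRUE)
    ord <- order(-v, rownames(mat))
    mat <- mat[sort(ord[seq_len(top_k)]), , drop = FALSE]
  }
  if (nrow(mat) < 2L) stopf("fewer than 2 genes retained after filtering")
  class(mat) <- c("normalized_matrix", class(mat))
  mat
}

#' Impute missing cells of a normalized matrix
#'
#' `median`: each missing cell takes the median of its gene's observed
#' values. `knn`: each missing cell takes the weighted mean of the gene's
#' values in the `k` datasets most correlated (Spearman, pairwise
#' complete) with the target dataset among those observing the gene;
#' weights are the positive parts of the correlations, falling back to an
#' unweighted mean when no correlation is positive. Observed cells are
#' never changed and the output stays within \[-1, 1\].
#'
#' @param matrix a `normalized_matrix` (genes x datasets)
#' @param method "median" or "knn"
#' @param k neighbor count for knn (default 5)
#' @return matrix of the same shape with no missing cells
#' @export
impute_matrix <- function(matrix, method = c("median", "knn"), k = 5L) {
  method <- match.arg(method)
  all_missing <- rownames(matrix)[rowSums(!is.na(matrix)) == 0L]
  if (length(all_missing))
    stopf("gene(s) with all cells missing: %s",
          paste(utils::head(all_missing, 5), collapse = ", "))
  if (!anyNA(matrix)) return(matrix)
  out <- matrix
  if (method == "median") {
    med <- apply(matrix, 1, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(out))) {
      miss <- is.na(out[, j])
      out[miss, j] <- med[miss]
    }
  } else {
    cors <- suppressWarnings(
      stats::cor(unclass(matrix), method = "spearman", use = "pairwise.complete.obs"))
    for (j in seq_len(ncol(out))) {
      miss <- which(is.na(matrix[, j]))
      for (i in miss) {
        obs <- which(!is.na(matrix[i, ]))
        rho <- cors[obs, j]
        rho[is.na(rho)] <- -Inf
        nn <- obs[order(-rho)][seq_len(min(k, length(obs)))]
        w <- pmax(cors[nn, j], 0)
        w[is.na(w)] <- 0
        out[i, j] <- if (sum(w) > 0) sum(w * matrix[i, nn]) / sum(w)
                     else mean(matrix[i, nn])
      }
    }
  }
  out
}

#' Write / read a normalized matrix as TSV
#'
#' First column `gene`, remaining columns dataset ids; missing cells are
#' empty fields.
#'
#' @param matrix a `normalized_matrix`
#' @param path file path
#' @return `read_matrix`: a `normalized_matrix`
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read_tsv_strict(path, required = "gene")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene
  class(m) <- c("normalized_matrix", class(m))
  m
}
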