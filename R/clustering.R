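#' Pairwise Spearman correlation between dataset signatures
#'
#' Columns (datasets) of the normalized fold-change matrix are compared
#' by Spearman rank correlation (ties by mean rank). A constant column
#' has undefined correlation; its off-diagonal cells are recorded as NA
#' with a warning. The diagonal is exactly 1.
#'
#' @param matrix a `normalized_matrix` (genes x datasets), usually imputed
#' @return square symmetric correlation matrix, unit diagonal
#' @export
spearman_matrix <- function(matrix) {
  if (ncol(matrix) < 2L) stopf("need at least 2 datasets")
  x <- unclass(matrix)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warnf("constant column(s): correlation undefined (NA) for %s",
          paste(colnames(x)[which(sds == 0)], collapse = ", "))
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  rho
}

#' Call dataset clusters from a correlation dendrogram
#'
#' Agglomerative clustering on distance `1 - rho`. The dendrogram is cut
#' at `height_cutoff`; the resulting groups are kept as clusters only if
#' they have at least `min_size` members and their within-cluster
#' pairwise correlations are dominated by positive values
#' (`positive_fraction >= dominance`). When `height_cutoff` is NULL it is
#' placed in the middle of the largest gap between consecutive merge
#' heights, the natural "same main branch" cut for a correlation
#' dendrogram.
#'
#' @param corr correlation matrix from [spearman_matrix()] (no NA cells)
#' @param linkage "average" (default) or "complete"
#' @param height_cutoff dendrogram cut height (> 0), or NULL for the
#'   largest-gap default
#' @param min_size minimum cluster size (default 3)
#' @param dominance minimum fraction of positive within-cluster
#'   correlations (default 0.9)
#' @return object of class `dataset_clusters`: list with `clusters` (each
#'   label, members, merge_height, positive_fraction), `assignment`
#'   (named vector, NA = unclustered), `height_cutoff` used
#' @export
call_clusters <- function(corr, linkage = c("average", "complete"),
                          height_cutoff = NULL, min_size = 3L, dominance = 0.9) {
  linkage <- match.arg(linkage)
  if (!is.null(height_cutoff) && height_cutoff <= 0)
    stopf("height_cutoff must be positive")
  if (anyNA(corr)) stopf("correlation matrix contains NA cells")
  check_fraction(dominance, "dominance")
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = linkage)
  if (is.null(height_cutoff)) {
    h <- sort(hc$height)
    if (length(h) == 1L) {
      height_cutoff <- h / 2
    } else {
      gaps <- diff(h)
      i <- which.max(gaps)
      height_cutoff <- (h[i] + h[i + 1]) / 2
    }
  }
  grp <- stats::cutree(hc, h = height_cutoff)
  coph <- as.matrix(stats::cophenetic(hc))
  clusters <- list()
  assignment <- stats::setNames(rep(NA_character_, ncol(corr)), colnames(corr))
  sizes <- sort(table(grp), decreasing = TRUE)
  lab_i <- 0L
  for (g in names(sizes)) {
    members <- colnames(corr)[grp == as.integer(g)]
    if (length(members) < min_size) next
    sub <- corr[members, members]
    off <- sub[upper.tri(sub)]
    pf <- mean(off > 0)
    if (pf < dominance) next
    lab_i <- lab_i + 1L
    label <- sprintf("K%d", lab_i)
    clusters[[label]] <- list(
      label = label, members = members,
      merge_height = max(coph[members, members]),
      positive_fraction = pf)
    assignment[members] <- label
  }
  structure(list(clusters = clusters, assignment = assignment,
                 height_cutoff = height_cutoff, linkage = linkage,
                 hclust = hc),
            class = "dataset_clusters")
}

#' @export
print.dataset_clusters <- function(x, ...) {
  cat(sprintf("dataset_clusters: %d cluster(s) at height cutoff %.3f\n",
              length(x$clusters), x$height_cutoff))
  for (cl in x$clusters)
    cat(sprintf("  %s: %d members, merge height %.3f, positive fraction %.2f\n",
                cl$label, length(cl$members), cl$merge_height, cl$positive_fraction))
  invisible(x)
}

#' Cluster table for export
#'
#' @param x a `dataset_clusters` object
#' @return data.frame (dataset_id, cluster_label, positive_fraction)
#' @export
cluster_table <- function(x) {
  pf <- stats::setNames(
    vapply(x$clusters, `[[`, 0, "positive_fraction"),
    names(x$clusters))
  data.frame(dataset_id = names(x$assignment),
             cluster_label = unname(x$assignment),
             positive_fraction = unname(pf[x$assignment]),
             stringsAsFactors = FALSE)
}

#' Embed datasets in two dimensions
#'
#' Deterministic 2-D embedding of the dataset signatures using classical
#' multidimensional scaling on Euclidean distances between (imputed)
#' normalized fold-change columns. This stands in for a stochastic
#' neighbor embedding: it is exactly reproducible, identical columns map
#' to coincident points, and planted cluster structure separates
#' (within-cluster embedded distances < between-cluster distances).
#' Axis signs are fixed so the largest-|coordinate| dataset is positive
#' on each axis.
#'
#' @param matrix imputed `normalized_matrix`
#' @param n_neighbors interface-compatibility parameter; the embedding
#'   must have at least `n_neighbors + 1` datasets (default 5)
#' @param seed kept for interface stability; the MDS embedding does not
#'   consume randomness
#' @return data.frame (dataset_id, x, y)
#' @export
embed_2d <- function(matrix, n_neighbors = 5L, seed = 1L) {
  if (ncol(matrix) < n_neighbors + 1L)
    stopf("too few datasets: need at least n_neighbors + 1 = %d", n_neighbors + 1L)
  d <- stats::dist(t(unclass(matrix)))
  xy <- stats::cmdscale(d, k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, 0)[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(xy[, j]))
    if (length(i) && xy[i, j] < 0) xy[, j] <- -xy[, j]
  }
  data.frame(dataset_id = colnames(matrix), x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}
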