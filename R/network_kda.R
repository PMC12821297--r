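#' Undirected weighted gene network from an edge list
#'
#' Validates and stores an edge list: no self-loops, no duplicate
#' unordered pairs, finite positive weights. Edges are treated as
#' undirected.
#'
#' @param edges data.frame (node_a, node_b, weight); a missing weight
#'   column defaults to 1
#' @return a `gene_network` (data.frame with attribute `nodes`)
#' @export
gene_network <- function(edges) {
  if (!all(c("node_a", "node_b") %in% names(edges)))
    stopf("edges need columns node_a, node_b")
  if (is.null(edges$weight)) edges$weight <- 1
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$node_a == edges$node_b)) stopf("self-loop edge(s) present")
  if (any(!is.finite(edges$weight) | edges$weight <= 0))
    stopf("edge weights must be finite and positive")
  key <- paste(pmin(edges$node_a, edges$node_b),
               pmax(edges$node_a, edges$node_b), sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate unordered edge(s) present")
  attr(edges, "nodes") <- sort(unique(c(edges$node_a, edges$node_b)))
  class(edges) <- c("gene_network", "data.frame")
  edges
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(attr(x, "nodes")), nrow(x)))
  invisible(x)
}

#' Read / write a network edge list as TSV
#'
#' Columns node_a, node_b, weight.
#'
#' @param path file path
#' @param network a [gene_network()]
#' @return `read_network`: a `gene_network`
#' @export
read_network <- function(path) {
  df <- read_tsv_strict(path, required = c("node_a", "node_b", "weight"),
                        numeric_cols = "weight")
  gene_network(df)
}

#' @rdname read_network
#' @export
write_network <- function(network, path) {
  write_tsv(as.data.frame(network)[, c("node_a", "node_b", "weight")], path)
}

.as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(network)[, c("node_a", "node_b", "weight")],
    directed = FALSE)
}

#' Weighted neighborhood of a node
#'
#' All nodes reachable from `node` within `depth` edges, excluding the
#' node itself. Each neighbor carries the maximum weight among the first
#' edges of the hub paths that reach it (at depth 1 this is simply its
#' edge weight to the hub).
#'
#' @param network a [gene_network()]
#' @param node node identifier (must be in the network)
#' @param depth maximum path length (default 1, the immediate
#'   subnetwork)
#' @return named numeric vector neighbor -> weight (empty for isolated
#'   nodes)
#' @export
neighborhood <- function(network, node, depth = 1L) {
  nodes <- attr(network, "nodes")
  if (!node %in% nodes) stopf("unknown node: %s", node)
  first <- network[network$node_a == node | network$node_b == node, , drop = FALSE]
  if (!nrow(first)) return(stats::setNames(numeric(0), character(0)))
  nb1 <- ifelse(first$node_a == node, first$node_b, first$node_a)
  w1 <- stats::setNames(first$weight, nb1)
  if (depth == 1L) return(w1)
  g <- .as_igraph(network)
  g_minus <- igraph::delete_vertices(g, node)
  out <- w1
  for (b in nb1) {
    reach <- names(igraph::ego(g_minus, order = depth - 1L, nodes = b)[[1]])
    for (v in setdiff(reach, c(node, b)))
      out[v] <- max(out[v] %|na|% -Inf, w1[[b]], na.rm = TRUE)
  }
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Weighted overlap score of a neighborhood with a DEG set
#'
#' `observed` is the summed weight of neighbors belonging to the DEG
#' set; `expected` is the total neighbor weight times the DEG fraction
#' among all network nodes; `ratio = observed / expected`. The ratio is
#' invariant to rescaling all edge weights, and for unit weights it
#' reduces to the plain overlap-fraction ratio.
#'
#' @param neighbors named weight vector from [neighborhood()]
#' @param deg_set character vector of DEG genes
#' @param deg_fraction fraction of all network nodes in the DEG set
#' @return list (observed, expected, ratio)
#' @export
kd_score <- function(neighbors, deg_set, deg_fraction) {
  if (length(neighbors) == 0L) stopf("empty neighborhood")
  if (deg_fraction <= 0) stopf("deg fraction is 0: no DEGs in network")
  observed <- sum(neighbors[names(neighbors) %in% deg_set])
  expected <- sum(neighbors) * deg_fraction
  list(observed = observed, expected = expected, ratio = observed / expected)
}

#' Weighted key-driver analysis
#'
#' Every node with degree >= `min_degree` is a candidate hub. For each
#' DEG set, the observed weighted overlap of each candidate's
#' depth-`depth` neighborhood is compared with a permutation null in
#' which DEG-set membership is reassigned uniformly over network nodes
#' (exactly size-matched). `z` is the standardized observed overlap and
#' the one-sided p-value is the empirical tail
#' `(1 + #{perm >= obs}) / (n_perm + 1)`; BH adjustment is applied
#' across candidates within each DEG set, and a candidate is a key
#' driver when `fdr < fdr_threshold` (default 0.05). Deterministic for
#' a fixed seed.
#'
#' @param network a [gene_network()]
#' @param deg_sets named list of character vectors
#' @param min_degree candidate threshold (default 5)
#' @param depth neighborhood depth (default 1)
#' @param n_perm permutations (default 1000)
#' @param seed integer seed
#' @param fdr_threshold significance cutoff (default 0.05)
#' @return data.frame (deg_set, node, neighborhood_size,
#'   observed_weighted_overlap, enrichment_ratio, z, pvalue, fdr,
#'   significant), sorted by z descending within deg_set
#' @export
run_wkda <- function(network, deg_sets, min_degree = 5L, depth = 1L,
                     n_perm = 1000L, seed = 1L, fdr_threshold = 0.05) {
  nodes <- attr(network, "nodes")
  if (!length(nodes)) stopf("empty network")
  if (is.null(names(deg_sets))) stopf("deg_sets must be named")
  deg_tab <- c(table(c(network$node_a, network$node_b)))
  candidates <- names(deg_tab)[deg_tab >= min_degree]
  if (!length(candidates)) {
    warnf("no candidate nodes with degree >= %d", min_degree)
    return(data.frame(deg_set = character(), node = character(),
                      neighborhood_size = integer(),
                      observed_weighted_overlap = numeric(),
                      enrichment_ratio = numeric(), z = numeric(),
                      pvalue = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  nbh <- lapply(candidates, function(v) neighborhood(network, v, depth))
  names(nbh) <- candidates
  node_index <- stats::setNames(seq_along(nodes), nodes)
  nb_idx <- lapply(nbh, function(w) node_index[names(w)])
  withr::with_seed(seed, {
    out <- list()
    for (ds in names(deg_sets)) {
      deg <- intersect(unique(deg_sets[[ds]]), nodes)
      m <- length(deg)
      if (m == 0L) stopf("deg_set '%s' shares no genes with the network", ds)
      frac <- m / length(nodes)
      scores <- lapply(nbh, kd_score, deg_set = deg, deg_fraction = frac)
      obs <- vapply(scores, `[[`, 0, "observed")
      perm <- matrix(0, n_perm, length(candidates))
      member <- logical(length(nodes))
      for (i in seq_len(n_perm)) {
        member[] <- FALSE
        member[sample.int(length(nodes), m)] <- TRUE
        perm[i, ] <- vapply(seq_along(candidates), function(ci) {
          w <- nbh[[ci]]
          sum(w[member[nb_idx[[ci]]]])
        }, 0)
      }
      mu <- colMeans(perm)
      sdev <- apply(perm, 2, stats::sd)
      z <- ifelse(sdev > 0, (obs - mu) / sdev, 0)
      pv <- vapply(seq_along(candidates), function(ci)
        (1 + sum(perm[, ci] >= obs[ci] - 1e-12)) / (n_perm + 1), 0)
      fdr <- bh_adjust(pv)
      df <- data.frame(
        deg_set = ds, node = candidates,
        neighborhood_size = lengths(nbh),
        observed_weighted_overlap = obs,
        enrichment_ratio = vapply(scores, `[[`, 0, "ratio"),
        z = z, pvalue = pv, fdr = fdr,
        significant = fdr < fdr_threshold,
        stringsAsFactors = FALSE, row.names = NULL)
      out[[ds]] <- df[order(-df$z, df$node), , drop = FALSE]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
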