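#' Robust rank aggregation rho for one gene
#'
#' Given the gene's normalized ranks (position / list length, in (0, 1\])
#' from the lists where it was observed, out of `n_lists` input lists in
#' total, sorts the ranks ascending r(1) <= ... <= r(k) and returns
#' `rho = min_j P(Beta(j, n_lists - j + 1) <= r(j))` — equivalently the
#' binomial tail `P(X >= j)` with `X ~ Binomial(n_lists, r(j))`. Small
#' rho means the gene sits improbably high across lists. Lists where the
#' gene is unobserved contribute no rank but still count in `n_lists`.
#'
#' @param normalized_ranks numeric in (0, 1\]
#' @param n_lists total number of input lists (>= length of the ranks)
#' @return rho in (0, 1\]
#' @seealso [rra_score()] for the Bonferroni-corrected score
#' @export
rra_rho <- function(normalized_ranks, n_lists) {
  if (!is_count(n_lists) || n_lists < 1) stopf("n_lists must be a positive count")
  r <- as.numeric(normalized_ranks)
  if (length(r) == 0L) return(1)
  if (any(is.na(r) | r <= 0 | r > 1)) stopf("normalized ranks must lie in (0, 1]")
  if (length(r) > n_lists) stopf("more ranks than lists")
  r <- sort(r)
  j <- seq_along(r)
  min(stats::pbeta(r, j, n_lists - j + 1))
}

#' Bonferroni-corrected RRA score
#'
#' `score = min(1, rho * n_lists)`: the minimum beta order-statistic
#' probability multiplied by the number of lists. Genes with score below
#' 0.05 are conventionally called robust meta-DEGs.
#'
#' @inheritParams rra_rho
#' @return score in (0, 1\]
#' @export
rra_score <- function(normalized_ranks, n_lists) {
  min(1, rra_rho(normalized_ranks, n_lists) * n_lists)
}

# Build per-dataset normalized rank lists.
# up:   genes ordered by log2fc descending; down: ascending;
# any:  genes ordered by pvalue ascending.
# Normalized rank = (average-tie rank) / list length.
.rank_list <- function(table, direction) {
  key <- switch(direction,
                up = -table$log2fc,
                down = table$log2fc,
                any = table$pvalue)
  stats::setNames(rank(key, ties.method = "average") / nrow(table), table$gene)
}

#' Run robust rank aggregation across a collection
#'
#' In `per_direction` mode every dataset contributes two full ranked
#' lists — genes by log2fc descending (up) and ascending (down) — and
#' aggregation is run separately per direction, as done within dataset
#' clusters. In `any_direction` mode each dataset contributes one list
#' of genes by p-value ascending, the direction-agnostic overall
#' analysis. Genes absent from a dataset receive no rank there but the
#' beta parameters still use the total list count. Genes are flagged
#' robust when `score < score_threshold` (default 0.05).
#'
#' @param collection a [signature_collection()] (or any named list of
#'   [signature_table()]s via `collection$signatures`)
#' @param mode "per_direction" or "any_direction"
#' @param score_threshold robustness cutoff on the Bonferroni score
#' @return data.frame (gene, rho, score, direction, n_lists, robust),
#'   sorted by score within direction; `n_lists` is the number of lists
#'   in which the gene was observed
#' @export
run_rra <- function(collection, mode = c("per_direction", "any_direction"),
                    score_threshold = 0.05) {
  mode <- match.arg(mode)
  sigs <- collection$signatures
  if (length(sigs) < 2L) stopf("need at least 2 datasets")
  directions <- if (mode == "per_direction") c("up", "down") else "any"
  n_total <- length(sigs)
  res <- list()
  for (dir in directions) {
    lists <- lapply(sigs, .rank_list, direction = dir)
    genes <- sort(unique(unlist(lapply(lists, names))))
    rmat <- matrix(NA_real_, length(genes), n_total,
                   dimnames = list(genes, names(sigs)))
    for (j in seq_along(lists)) rmat[names(lists[[j]]), j] <- lists[[j]]
    rho <- vapply(seq_len(nrow(rmat)), function(i) {
      r <- rmat[i, ]
      rra_rho(r[!is.na(r)], n_total)
    }, 0)
    score <- pmin(1, rho * n_total)
    res[[dir]] <- data.frame(gene = genes, rho = rho, score = score,
                             direction = dir,
                             n_lists = rowSums(!is.na(rmat)),
                             robust = score < score_threshold,
                             stringsAsFactors = FALSE, row.names = NULL)
    res[[dir]] <- res[[dir]][order(res[[dir]]$score, res[[dir]]$gene), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Directional recurrence of significant DEGs across datasets
#'
#' Counts, per gene, the datasets where it is a significant up-DEG and
#' down-DEG (per [count_significant()] membership at `fdr_threshold`).
#' `consistency = max(n_up, n_down) / (n_up + n_down)`; a gene is
#' `consistent` when that fraction strictly exceeds
#' `consistency_threshold` (default 0.70, the ">70% consistent
#' direction" rule). Directional agreement is not required before
#' counting — a gene may recur with opposite signs in different tissues.
#'
#' @param collection a [signature_collection()]
#' @param fdr_threshold per-dataset DEG significance cutoff (default 0.05)
#' @param consistency_threshold strict lower bound on the consistency
#'   fraction (default 0.70)
#' @return data.frame (gene, n_up, n_down, total, consistency,
#'   consistent), sorted by total descending then gene; genes never
#'   significant are omitted
#' @export
recurrence <- function(collection, fdr_threshold = 0.05,
                       consistency_threshold = 0.70) {
  up <- new.env(); down <- new.env()
  bump <- function(env, genes) for (g in genes)
    assign(g, (get0(g, envir = env, ifnotfound = 0L)) + 1L, envir = env)
  for (tab in collection$signatures) {
    sig <- tab$fdr < fdr_threshold
    bump(up, tab$gene[sig & tab$log2fc > 0])
    bump(down, tab$gene[sig & tab$log2fc < 0])
  }
  genes <- sort(unique(c(ls(up), ls(down))))
  if (length(genes) == 0L)
    return(data.frame(gene = character(), n_up = integer(), n_down = integer(),
                      total = integer(), consistency = numeric(),
                      consistent = logical(), stringsAsFactors = FALSE))
  n_up <- vapply(genes, function(g) get0(g, envir = up, ifnotfound = 0L), 0L)
  n_down <- vapply(genes, function(g) get0(g, envir = down, ifnotfound = 0L), 0L)
  total <- n_up + n_down
  consistency <- pmax(n_up, n_down) / total
  out <- data.frame(gene = genes, n_up = n_up, n_down = n_down, total = total,
                    consistency = consistency,
                    consistent = consistency > consistency_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$total, out$gene), , drop = FALSE]
}

#' Consistency call from direction counts
#'
#' The recurrence classifier in isolation: with `n_up` datasets calling
#' a gene significantly up and `n_down` down, the gene is directionally
#' consistent when `max(n_up, n_down) / (n_up + n_down)` strictly
#' exceeds the threshold. E.g. 19 up / 4 down (0.826) and 23 up / 0 down
#' (1.0) are consistent at the default 0.70; 5 up / 5 down is not.
#'
#' @param n_up,n_down non-negative counts
#' @param consistency_threshold default 0.70
#' @return logical
#' @export
consistent_call <- function(n_up, n_down, consistency_threshold = 0.70) {
  total <- n_up + n_down
  ifelse(total > 0, pmax(n_up, n_down) / total > consistency_threshold, FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison of DEG-count distributions
#'
#' `D = sup |ECDF_a - ECDF_b|`. For small samples
#' (`length(a) + length(b) <= 12`) the p-value is exact, by full
#' enumeration of all label arrangements of the pooled values; otherwise
#' the standard asymptotic Kolmogorov tail is used. D depends on ranks
#' only, so it is invariant under a common strictly monotone transform.
#'
#' @param counts_a,counts_b non-empty numeric samples
#' @return list with `D`, `p`, and `method` ("exact" or "asymptotic")
#' @export
ks_compare <- function(counts_a, counts_b) {
  a <- as.numeric(counts_a); b <- as.numeric(counts_b)
  if (length(a) == 0L || length(b) == 0L) stopf("both samples must be non-empty")
  ks_d <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
  }
  D <- ks_d(a, b)
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  if (n <= 12L) {
    pool <- c(a, b)
    idx <- utils::combn(n, n_a)
    d_all <- apply(idx, 2, function(i) ks_d(pool[i], pool[-i]))
    p <- mean(d_all >= D - 1e-12)
    method <- "exact"
  } else {
    t <- sqrt(n_a * n_b / n) * D
    k <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
    method <- "asymptotic"
  }
  list(D = D, p = p, method = method)
}
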