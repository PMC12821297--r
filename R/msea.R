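#' Map genomic markers to genes within a distance window
#'
#' A marker is assigned to a gene when they share a chromosome and the
#' marker position falls in the window-extended, 0-based half-open gene
#' interval: `start - window <= pos < end + window` (so a marker at
#' exactly `end + window` is NOT assigned, one at exactly
#' `start - window` is). Each mapped gene's score is the maximum
#' association score over its assigned markers; genes with no marker are
#' absent from the result. The default window is 50 kb, the standard
#' SNP-to-gene distance rule.
#'
#' @param markers data.frame (marker_id, chrom, pos, score); score is an
#'   association strength on the -log10 p scale, pos >= 0
#' @param genes data.frame (gene, chrom, start, end), 0-based half-open
#' @param window non-negative distance in bp (default 50000)
#' @return named numeric vector: gene -> gene_score
#' @export
map_markers <- function(markers, genes, window = 50000L) {
  if (window < 0) stopf("window must be >= 0")
  if (any(genes$start >= genes$end)) stopf("gene intervals must satisfy start < end")
  if (any(markers$pos < 0) || any(markers$score < 0))
    stopf("marker pos and score must be non-negative")
  out <- numeric(0)
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    m <- markers[markers$chrom == ch, , drop = FALSE]
    if (!nrow(m)) next
    for (i in seq_len(nrow(g))) {
      hit <- m$pos >= g$start[i] - window & m$pos < g$end[i] + window
      if (any(hit)) out[g$gene[i]] <- max(m$score[hit])
    }
  }
  out
}

#' Quantile-threshold chi-square-like enrichment statistic
#'
#' For thresholds `t_j` placed at the given quantiles of the gene-score
#' distribution, compares the observed count of DEG-set genes at or
#' above each threshold, `O_j`, with the expectation under uniform
#' membership, `E_j = |deg_set| * P(score >= t_j)`, and sums the
#' stabilized deviations: `chi = sum_j (O_j - E_j) / sqrt(E_j + kappa)`.
#' Positive chi means the DEG set is enriched for high-scoring
#' (strongly trait-associated) genes; the statistic only depends on
#' scores through threshold membership, so any strictly monotone
#' transform preserving those member sets leaves it unchanged.
#'
#' @param deg_set character vector, subset of `names(gene_scores)`
#' @param gene_scores named numeric vector from [map_markers()]
#' @param quantiles thresholds as fractions in (0,1); default deciles
#'   0.1..0.9
#' @param kappa variance-stabilizing constant (default 1)
#' @return numeric chi
#' @export
msea_statistic <- function(deg_set, gene_scores,
                           quantiles = seq(0.1, 0.9, by = 0.1), kappa = 1) {
  deg <- intersect(unique(deg_set), names(gene_scores))
  if (length(deg) == 0L) stopf("empty deg_set (no overlap with scored genes)")
  if (any(quantiles <= 0 | quantiles >= 1)) stopf("quantiles must lie in (0,1)")
  s <- gene_scores
  t <- stats::quantile(s, probs = quantiles, names = FALSE)
  sd_ <- s[deg]
  chi <- 0
  for (tj in t) {
    O <- sum(sd_ >= tj)
    E <- length(deg) * mean(s >= tj)
    chi <- chi + (O - E) / sqrt(E + kappa)
  }
  chi
}

# Additive decomposition of chi over set members, used for fast
# permutation: with thresholds t (ascending) and set size m fixed,
# chi(set) = sum_{g in set} v(g) - const, where v(g) accumulates
# 1/sqrt(E_j + kappa) over the thresholds gene g passes.
.msea_additive <- function(gene_scores, quantiles, kappa, m) {
  t <- sort(stats::quantile(gene_scores, probs = quantiles, names = FALSE))
  p_j <- vapply(t, function(tj) mean(gene_scores >= tj), 0)
  E <- m * p_j
  w <- 1 / sqrt(E + kappa)
  cw <- c(0, cumsum(w))
  n_pass <- vapply(gene_scores, function(s) sum(s >= t), 0L)
  list(values = stats::setNames(cw[n_pass + 1L], names(gene_scores)),
       const = sum(E * w))
}

#' Permutation-calibrated marker-set enrichment test
#'
#' For every (DEG set, trait) pair: computes the observed
#' [msea_statistic()], generates `n_perm` size-matched uniform random
#' gene sets from the trait's scored universe, approximates the null
#' with a Gaussian fitted to the permuted statistics, and reports
#' `z = (chi_obs - mean) / sd` with one-sided `p = 1 - pnorm(z)`.
#' P-values are BH-adjusted across all pairs; significant iff
#' `fdr < 0.05`. Deterministic for a fixed seed.
#'
#' @param deg_sets named list of character vectors
#' @param gene_scores_by_trait named list of scored-gene vectors (one
#'   per trait, from [map_markers()])
#' @param n_perm permutations per pair (default 10000; >= 100 required)
#' @param seed integer seed
#' @param quantiles,kappa passed to [msea_statistic()]
#' @param fdr_threshold significance cutoff (default 0.05)
#' @return data.frame (deg_set, trait, chi, z, pvalue, fdr, significant)
#' @export
msea_test <- function(deg_sets, gene_scores_by_trait, n_perm = 10000L,
                      seed = 1L, quantiles = seq(0.1, 0.9, by = 0.1),
                      kappa = 1, fdr_threshold = 0.05) {
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  if (is.null(names(deg_sets)) || is.null(names(gene_scores_by_trait)))
    stopf("deg_sets and gene_scores_by_trait must be named")
  withr::with_seed(seed, {
    rows <- list()
    for (trait in names(gene_scores_by_trait)) {
      scores <- gene_scores_by_trait[[trait]]
      n_genes <- length(scores)
      for (ds in names(deg_sets)) {
        deg <- intersect(unique(deg_sets[[ds]]), names(scores))
        if (length(deg) == 0L) stopf("deg_set '%s' has no scored genes for trait '%s'", ds, trait)
        chi_obs <- msea_statistic(deg, scores, quantiles, kappa)
        add <- .msea_additive(scores, quantiles, kappa, length(deg))
        v <- add$values
        m <- length(deg)
        chi_perm <- vapply(seq_len(n_perm), function(i)
          sum(v[sample.int(n_genes, m)]), 0) - add$const
        mu <- mean(chi_perm); sdev <- stats::sd(chi_perm)
        if (sdev == 0) stopf("degenerate scores: zero permutation variance for (%s, %s)", ds, trait)
        z <- (chi_obs - mu) / sdev
        rows[[length(rows) + 1L]] <- data.frame(
          deg_set = ds, trait = trait, chi = chi_obs, z = z,
          pvalue = 1 - stats::pnorm(z), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$fdr <- bh_adjust(out$pvalue)
    out$significant <- out$fdr < fdr_threshold
    out
  })
}
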