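# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

check_fraction <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok)
    stopf("'%s' must be a fraction in [0,%s], got %s", name,
          if (allow_one) "1" else "1)", format(x))
  invisible(x)
}

#' Read a strict TSV table
#'
#' Tab-separated, header required, UTF-8, '.' decimal. Fails with a
#' column-naming error when required columns are absent and a row-indexed
#' parse error when a numeric column contains a non-numeric value.
#'
#' @param path file path
#' @param required character vector of required column names
#' @param numeric_cols columns that must parse as numeric
#' @return data.frame
#' @keywords internal
read_tsv_strict <- function(path, required = character(), numeric_cols = character()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s: missing required column(s): %s", path, paste(missing, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad))
      stopf("%s: non-numeric value '%s' in column '%s' at data row %d",
            path, df[[col]][bad[1]], col, bad[1])
    df[[col]] <- val
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to score planted-cluster recovery. NA labels are treated as their
#' own singleton-free category ("unclustered").
#'
#' @param a,b label vectors of equal length
#' @return numeric scalar in [-1, 1]; 1 means identical partitions
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  a <- addNA(factor(a), ifany = TRUE)
  b <- addNA(factor(b), ifany = TRUE)
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin, named wrapper over [stats::p.adjust()] so every module applies the
#' same multiple-testing rule the pipeline documents (step-up FDR).
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values (FDR), same length/order as `p`
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
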