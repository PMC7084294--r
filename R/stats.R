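#' Pearson product-moment correlation
#'
#' Thin validated wrapper: errors on length mismatch, short vectors and
#' constant input (where the correlation is undefined), and clamps the
#' result to `[-1, 1]` against floating-point rounding.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The sample correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r: length mismatch")
  if (length(x) < 3L) stop("pearson_r: need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("pearson_r: missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: correlation undefined for constant vector")
  }
  max(-1, min(1, stats::cor(x, y)))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Exact test under bivariate normality: `t = r * sqrt((n-2) / (1-r^2))`
#' follows a Student-t distribution with `n - 2` degrees of freedom under
#' the null, and the two-sided tail probability is returned. `|r| = 1`
#' yields `p = 0`.
#'
#' @param r correlation coefficient in `[-1, 1]`.
#' @param n sample count (>= 3).
#' @return Two-sided p-value.
#' @export
#' @examples
#' correlation_pvalue(0.965516179, 6)  # ~0.00176
correlation_pvalue <- function(r, n) {
  if (any(n < 3L)) stop("correlation_pvalue: need n >= 3")
  if (any(abs(r) > 1)) stop("correlation_pvalue: |r| must be <= 1")
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  t <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (cumulative-minimum formulation, capped at
#' 1, returned in input order). `NA` entries are passed through and do not
#' count toward the family size.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric (one-sided Fisher) gene-set enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a target list and a gene set drawn from a finite
#' universe, plus the odds ratio of the 2x2 table (with a Haldane
#' correction of 0.5 added to every cell when any cell is zero).
#'
#' @param target_genes character vector (or set) of genes of interest;
#'   must be a subset of `universe`.
#' @param gene_set character vector; the annotated set, subset of
#'   `universe`.
#' @param universe character vector of all genes considered.
#' @return list with `overlap`, `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(target_genes, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("fisher_enrichment: empty universe")
  target_genes <- unique(as.character(target_genes))
  gene_set <- unique(as.character(gene_set))
  if (length(setdiff(gene_set, universe))) {
    stop("fisher_enrichment: gene_set must be a subset of the universe")
  }
  if (length(setdiff(target_genes, universe))) {
    stop("fisher_enrichment: target_genes must be a subset of the universe")
  }
  n_u <- length(universe)
  n_t <- length(target_genes)
  n_s <- length(gene_set)
  k <- length(intersect(target_genes, gene_set))
  # P(X >= k), X ~ Hypergeometric(universe, set, draws = targets)
  p <- stats::phyper(k - 1L, n_s, n_u - n_s, n_t, lower.tail = FALSE)
  a <- k; b <- n_t - k; cc <- n_s - k; d <- n_u - n_s - n_t + k
  if (min(a, b, cc, d) == 0L) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(overlap = k, odds_ratio = (a * d) / (b * cc), p_value = p)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_test - Ct_ref_test) - (Ct_target_cal - Ct_ref_cal)`;
#' the relative expression of the target in the test sample versus the
#' calibrator sample, normalized to the reference gene, is `2^(-ddCt)`.
#'
#' @param ct_target_test,ct_ref_test cycle thresholds in the test sample
#'   for the target and reference gene.
#' @param ct_target_cal,ct_ref_cal cycle thresholds in the calibrator
#'   sample.
#' @return The relative expression `2^(-ddCt)`.
#' @export
#' @examples
#' ddct_relative_expression(20, 18, 19, 18)  # 0.5
ddct_relative_expression <- function(ct_target_test, ct_ref_test,
                                     ct_target_cal, ct_ref_cal) {
  vals <- c(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(vals))) {
    stop("ddct_relative_expression: Ct values must be finite")
  }
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) stop("read_gmt: malformed GMT line")
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1L), 1L))
}
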