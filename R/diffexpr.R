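#' Two-group differential expression on counts
#'
#' A transparent two-group test implementing the pipeline's DE decision
#' rule. Per-sample size factors are `library size / median library size`
#' over the contrasted samples; normalized values are `count / size factor`.
#' The effect size is `log2((mean_A + 1) / (mean_B + 1))` on normalized
#' group means (pseudocount 1 for stability at zero). The p-value comes from
#' a two-sided Welch unequal-variance test on `log2(normalized + 1)` per
#' feature, and adjusted p-values from Benjamini-Hochberg over all tested
#' features. Features with zero counts in every contrasted sample are
#' excluded from testing and from the BH family. A feature is called
#' differentially expressed when `|log2FC| > de_abs_log2fc_min` and
#' `padj < de_padj_max` (both strict).
#'
#' This engine is deliberately a documented, simple substitute for a
#' negative-binomial GLM: the decision rule and all downstream stages are
#' independent of the engine, which can be swapped behind this interface.
#'
#' @param counts `expression_matrix` of kind `"counts"`.
#' @param contrast character vector `c(groupA, groupB)`; `log2fc` is
#'   oriented A over B.
#' @param config a [pipeline_config()].
#' @return data.frame of class `de_result` with columns `feature_id`,
#'   `base_mean_A`, `base_mean_B` (normalized group means), `log2fc`,
#'   `p_value`, `padj`, `is_de`, `direction` (`up`/`down`/`none`);
#'   attributes `contrast` and `engine`.
#' @export
#' @examples
#' m <- matrix(c(100, 100, 100, 25, 25, 25), 1,
#'             dimnames = list("f", paste0("s", 1:6)))
#' g <- setNames(rep(c("W", "Y"), each = 3), paste0("s", 1:6))
#' # single-feature example: equal library sizes need >1 feature in practice
#' cm <- expression_matrix(rbind(f = m[1, ], ref = 1000 - m[1, ]), "counts", g)
#' test_differential_expression(cm, c("W", "Y"))$log2fc  # log2(101/26)
test_differential_expression <- function(counts, contrast,
                                         config = pipeline_config()) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$kind != "counts") {
    stop("test_differential_expression: input must be counts")
  }
  if (length(contrast) != 2L) {
    stop("test_differential_expression: contrast must name two groups")
  }
  unknown <- setdiff(contrast, unique(counts$groups))
  if (length(unknown)) {
    stop("test_differential_expression: unknown group(s): ",
         paste(unknown, collapse = ", "))
  }
  sel_a <- names(counts$groups)[counts$groups == contrast[1L]]
  sel_b <- names(counts$groups)[counts$groups == contrast[2L]]
  if (length(sel_a) < 2L || length(sel_b) < 2L) {
    stop("test_differential_expression: each group needs >= 2 samples")
  }
  m <- counts$values[, c(sel_a, sel_b), drop = FALSE]

  tested <- rowSums(m) > 0
  m <- m[tested, , drop = FALSE]
  lib <- colSums(counts$values[, c(sel_a, sel_b), drop = FALSE])
  sf <- lib / stats::median(lib)
  v <- sweep(m, 2L, sf, "/")

  va <- v[, sel_a, drop = FALSE]
  vb <- v[, sel_b, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  log2fc <- log2((mean_a + 1) / (mean_b + 1))

  la <- log2(va + 1)
  lb <- log2(vb + 1)
  n1 <- ncol(la); n2 <- ncol(lb)
  m1 <- rowMeans(la); m2 <- rowMeans(lb)
  s1 <- rowSums((la - m1)^2) / (n1 - 1L)
  s2 <- rowSums((lb - m2)^2) / (n2 - 1L)
  se2 <- s1 / n1 + s2 / n2
  p <- rep(NA_real_, nrow(m))
  degenerate <- se2 == 0
  # both groups constant: no sampling variability; equal means -> p = 1,
  # unequal -> p = 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  ok <- !degenerate
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((s1[ok] / n1)^2 / (n1 - 1L) + (s2[ok] / n2)^2 / (n2 - 1L))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)

  padj <- bh_adjust(p)
  is_de <- abs(log2fc) > config$de_abs_log2fc_min & padj < config$de_padj_max
  direction <- ifelse(!is_de, "none", ifelse(log2fc > 0, "up", "down"))

  out <- data.frame(feature_id = rownames(m), base_mean_A = mean_a,
                    base_mean_B = mean_b, log2fc = log2fc, p_value = p,
                    padj = padj, is_de = is_de, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("de_result", "data.frame"),
            contrast = contrast,
            engine = "welch-log2-normalized")
}

#' Write a DE table as TSV
#'
#' The contrast orientation is recorded in a header comment.
#'
#' @param de a `de_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ctr <- attr(de, "contrast")
  writeLines(sprintf("# log2fc orientation: %s over %s (engine: %s)",
                     ctr[1L], ctr[2L], attr(de, "engine")), con)
  utils::write.table(as.data.frame(de), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
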