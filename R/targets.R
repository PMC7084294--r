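# boundary gap between two 1-based inclusive spans: 0 when they overlap,
# otherwise the number of bases strictly between them
.span_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1 - 1L, s1 - e2 - 1L))
}

# correlation + p for a set of (lincRNA row, gene row) pairs of an FPKM
# matrix; constant vectors give r = NA (excluded from the FDR family)
.pair_cor <- function(expr, linc_ids, gene_ids) {
  vals <- expr$values
  miss <- setdiff(unique(c(linc_ids, gene_ids)), rownames(vals))
  if (length(miss)) {
    stop("target prediction: no expression row for feature '", miss[1L], "'")
  }
  n <- ncol(vals)
  x <- vals[linc_ids, , drop = FALSE]
  y <- vals[gene_ids, , drop = FALSE]
  sx <- apply(x, 1L, stats::sd)
  sy <- apply(y, 1L, stats::sd)
  r <- rep(NA_real_, length(linc_ids))
  ok <- sx > 0 & sy > 0
  if (any(ok)) {
    xs <- (x[ok, , drop = FALSE] - rowMeans(x[ok, , drop = FALSE])) / sx[ok]
    ys <- (y[ok, , drop = FALSE] - rowMeans(y[ok, , drop = FALSE])) / sy[ok]
    r[ok] <- pmax(-1, pmin(1, rowSums(xs * ys) / (n - 1L)))
  }
  p <- rep(NA_real_, length(r))
  p[ok] <- correlation_pvalue(r[ok], n)
  list(r = r, p = p, n = n)
}

#' Predict cis-regulated potential target genes
#'
#' Cis candidates of a lincRNA are the protein-coding genes on the same
#' chromosome whose span lies upstream or downstream within a strict
#' boundary gap of `cis_window` (gap 0 when the spans overlap). Every
#' candidate pair is reported with its Pearson correlation across all
#' samples, two-sided p-value and a BH-adjusted value over the cis family;
#' no correlation cutoff is applied to cis pairs. Pairs with a constant
#' expression vector get `r = NA` and are excluded from the FDR family.
#'
#' @param de_lincs `annotation_set` of (DE) lincRNAs.
#' @param coding_genes `annotation_set` of protein-coding genes; gene spans
#'   are used and expression is looked up by `gene_id`.
#' @param expr `expression_matrix` with rows for lincRNA transcript ids and
#'   coding gene ids.
#' @param config a [pipeline_config()].
#' @return data.frame of class `target_edges`: `lincrna_id`, `gene_id`,
#'   `mode = "cis"`, `r`, `p_value`, `fdr`, `distance_bp`, `sign`.
#' @export
predict_cis_targets <- function(de_lincs, coding_genes, expr,
                                config = pipeline_config()) {
  stopifnot(inherits(de_lincs, "annotation_set"),
            inherits(coding_genes, "annotation_set"),
            inherits(expr, "expression_matrix"))
  tx <- de_lincs$transcripts
  genes <- gene_spans(coding_genes)
  pairs <- .cis_pairs(tx, genes, config$cis_window)
  if (nrow(pairs) == 0L) return(.empty_edges())
  cp <- .pair_cor(expr, pairs$lincrna_id, pairs$gene_id)
  out <- data.frame(lincrna_id = pairs$lincrna_id, gene_id = pairs$gene_id,
                    mode = "cis", r = cp$r, p_value = cp$p,
                    fdr = bh_adjust(cp$p), distance_bp = pairs$gap,
                    sign = ifelse(is.na(cp$r), NA_character_,
                                  ifelse(cp$r > 0, "positive", "negative")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lincrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("target_edges", "data.frame"), n_samples = cp$n)
}

# all (lincRNA, gene) pairs with same-chromosome boundary gap < window
.cis_pairs <- function(tx, genes, window) {
  if (nrow(tx) == 0L || nrow(genes) == 0L) {
    return(data.frame(lincrna_id = character(), gene_id = character(),
                      gap = integer(), stringsAsFactors = FALSE))
  }
  # widen lincRNA spans by the window and intersect; strict < on the gap
  lev <- union(unique(tx$chrom), unique(genes$chrom))
  gr_l <- GenomicRanges::GRanges(
    factor(tx$chrom, levels = lev),
    IRanges::IRanges(pmax(1L, tx$start - as.integer(window)),
                     tx$end + as.integer(window)))
  ov <- GenomicRanges::findOverlaps(gr_l, .spans_gr(genes, lev))
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  gap <- .span_gap(tx$start[q], tx$end[q], genes$start[s], genes$end[s])
  keep <- gap < window
  data.frame(lincrna_id = tx$transcript_id[q][keep],
             gene_id = genes$gene_id[s][keep],
             gap = as.integer(gap[keep]), stringsAsFactors = FALSE)
}

.empty_edges <- function() {
  structure(data.frame(lincrna_id = character(), gene_id = character(),
                       mode = character(), r = numeric(),
                       p_value = numeric(), fdr = numeric(),
                       distance_bp = integer(), sign = character(),
                       stringsAsFactors = FALSE),
            class = c("target_edges", "data.frame"))
}

#' Predict trans-regulated potential target genes
#'
#' Tests every (DE lincRNA, protein-coding gene) pair that is not
#' cis-eligible (genes with a same-chromosome boundary gap `< cis_window`
#' are excluded so that the cis and trans modes stay disjoint). The Pearson
#' correlation is computed across all samples; BH adjustment is over the
#' full tested trans family of the run, and a pair becomes a trans edge
#' exactly when `|r| >= trans_abs_r_min` and `fdr < fdr_max`. Constant
#' expression vectors are excluded from the family.
#'
#' @inheritParams predict_cis_targets
#' @param return_all logical; return every tested pair instead of only the
#'   retained edges (retained pairs are flagged in column `retained`).
#' @return data.frame of class `target_edges` with `mode = "trans"` and
#'   `distance_bp = NA`.
#' @export
predict_trans_targets <- function(de_lincs, coding_genes, expr,
                                  config = pipeline_config(),
                                  return_all = FALSE) {
  stopifnot(inherits(de_lincs, "annotation_set"),
            inherits(coding_genes, "annotation_set"),
            inherits(expr, "expression_matrix"))
  tx <- de_lincs$transcripts
  genes <- gene_spans(coding_genes)
  if (nrow(tx) == 0L || nrow(genes) == 0L) return(.empty_edges())
  pairs <- expand.grid(lincrna_id = tx$transcript_id,
                       gene_id = unique(genes$gene_id),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cis <- .cis_pairs(tx, genes, config$cis_window)
  if (nrow(cis)) {
    cis_key <- paste(cis$lincrna_id, cis$gene_id, sep = "\r")
    pairs <- pairs[!(paste(pairs$lincrna_id, pairs$gene_id, sep = "\r") %in%
                       cis_key), , drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(.empty_edges())
  cp <- .pair_cor(expr, pairs$lincrna_id, pairs$gene_id)
  fdr <- bh_adjust(cp$p)
  retained <- !is.na(cp$r) & abs(cp$r) >= config$trans_abs_r_min &
    fdr < config$fdr_max
  out <- data.frame(lincrna_id = pairs$lincrna_id, gene_id = pairs$gene_id,
                    mode = "trans", r = cp$r, p_value = cp$p, fdr = fdr,
                    distance_bp = NA_integer_,
                    sign = ifelse(is.na(cp$r), NA_character_,
                                  ifelse(cp$r > 0, "positive", "negative")),
                    retained = retained, stringsAsFactors = FALSE)
  if (!return_all) {
    out <- out[out$retained, setdiff(names(out), "retained"), drop = FALSE]
  }
  out <- out[order(out$lincrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("target_edges", "data.frame"), n_samples = cp$n)
}

#' Tally differentially expressed potential target genes per lincRNA
#'
#' A target gene is a DEPTG of a lincRNA when some edge links them and the
#' gene is differentially expressed. Edges with positive correlation sign
#' count as upregulated targets, negative as downregulated; for every
#' lincRNA, `up + down = total`.
#'
#' @param edges a `target_edges` data.frame (cis, trans or both combined).
#' @param de_genes a `de_result` for the protein-coding genes.
#' @return data.frame of class `deptg_summary` sorted by lincRNA id:
#'   `lincrna_id`, `n_deptgs`, `n_up`, `n_down`.
#' @export
classify_deptgs <- function(edges, de_genes) {
  de_ids <- de_genes$feature_id[de_genes$is_de]
  keep <- edges$gene_id %in% de_ids & !is.na(edges$sign)
  e <- edges[keep, , drop = FALSE]
  # a gene supported by both a cis and a trans edge counts once per mode
  e <- e[!duplicated(paste(e$lincrna_id, e$gene_id, e$mode, sep = "\r")), ,
         drop = FALSE]
  lincs <- sort(unique(edges$lincrna_id))
  out <- data.frame(
    lincrna_id = lincs,
    n_deptgs = vapply(lincs, function(l) sum(e$lincrna_id == l), integer(1L)),
    n_up = vapply(lincs, function(l)
      sum(e$lincrna_id == l & e$sign == "positive"), integer(1L)),
    n_down = vapply(lincs, function(l)
      sum(e$lincrna_id == l & e$sign == "negative"), integer(1L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("deptg_summary", "data.frame"))
}
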