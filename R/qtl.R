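#' Co-localize lincRNA loci with QTL intervals
#'
#' Intersects the transcript spans of (differentially expressed) lincRNAs
#' with QTL intervals: one record per (lincRNA, QTL) pair sharing at least
#' one genomic position on the same chromosome, with the size of the shared
#' region in bp. With `dedupe_qtls = TRUE` each QTL is reported at most once
#' (attributed to the lincRNA with the largest overlap, ties by lincRNA id).
#'
#' @param de_lincs `annotation_set` of lincRNAs (transcript spans are used
#'   as loci).
#' @param qtls a `qtl_set` from [read_qtl_bed()].
#' @param dedupe_qtls logical; collapse multiple lincRNA hits per QTL.
#' @return data.frame with `lincrna_id`, `qtl_id`, `chrom`, `trait_name`,
#'   `trait_class`, `overlap_bp`.
#' @export
colocalize_qtl <- function(de_lincs, qtls, dedupe_qtls = FALSE) {
  stopifnot(inherits(de_lincs, "annotation_set"))
  tx <- de_lincs$transcripts
  empty <- data.frame(lincrna_id = character(), qtl_id = character(),
                      chrom = character(), trait_name = character(),
                      trait_class = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(tx) == 0L || nrow(qtls) == 0L) return(empty)
  ov <- .find_span_overlaps(tx, qtls)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  if (length(q) == 0L) return(empty)
  bp <- pmin(tx$end[q], qtls$end[s]) - pmax(tx$start[q], qtls$start[s]) + 1L
  out <- data.frame(lincrna_id = tx$transcript_id[q],
                    qtl_id = qtls$qtl_id[s],
                    chrom = qtls$chrom[s],
                    trait_name = qtls$trait_name[s],
                    trait_class = qtls$trait_class[s],
                    overlap_bp = as.integer(bp),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lincrna_id, out$qtl_id), , drop = FALSE]
  rownames(out) <- NULL
  if (dedupe_qtls && nrow(out)) {
    ord <- order(out$qtl_id, -out$overlap_bp, out$lincrna_id)
    out <- out[ord, , drop = FALSE][!duplicated(out$qtl_id[ord]), ,
                                    drop = FALSE]
    out <- out[order(out$lincrna_id, out$qtl_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Summarize QTL co-localizations by trait class, chromosome and trait
#'
#' Counts overlaps in total, those with a fat-deposition trait class
#' (`IMF` or `fat_other`) and those with class `IMF`, plus per-chromosome
#' fat-associated counts and per-trait-name counts. Percentages
#' (`100 * fat / total` and `100 * imf / fat`) are retained at full
#' precision and printed at one decimal; they are `NA` when the denominator
#' is zero.
#'
#' @param overlaps output of [colocalize_qtl()].
#' @return list of class `qtl_summary` with `total_overlaps`,
#'   `fat_overlaps`, `imf_overlaps`, `pct_fat_of_total`,
#'   `pct_imf_of_fat`, `fat_by_chrom` (named integer vector),
#'   `by_trait_name` (named integer vector).
#' @export
summarize_qtl <- function(overlaps) {
  total <- nrow(overlaps)
  is_fat <- overlaps$trait_class %in% c("IMF", "fat_other")
  is_imf <- overlaps$trait_class == "IMF"
  fat <- sum(is_fat)
  imf <- sum(is_imf)
  fat_by_chrom <- if (fat) {
    tab <- table(overlaps$chrom[is_fat])
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0L), character(0L))
  by_trait <- if (total) {
    tab <- sort(table(overlaps$trait_name), decreasing = TRUE)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0L), character(0L))
  structure(list(
    total_overlaps = total,
    fat_overlaps = fat,
    imf_overlaps = imf,
    pct_fat_of_total = if (total > 0L) 100 * fat / total else NA_real_,
    pct_imf_of_fat = if (fat > 0L) 100 * imf / fat else NA_real_,
    fat_by_chrom = fat_by_chrom,
    by_trait_name = by_trait
  ), class = "qtl_summary")
}

#' @export
print.qtl_summary <- function(x, ...) {
  fmt_pct <- function(p) if (is.na(p)) "NA" else sprintf("%.1f%%", p)
  cat("<qtl_summary>\n")
  cat(sprintf("  total overlaps:          %d\n", x$total_overlaps))
  cat(sprintf("  fat-associated overlaps: %d (%s of total)\n",
              x$fat_overlaps, fmt_pct(x$pct_fat_of_total)))
  cat(sprintf("  IMF-content overlaps:    %d (%s of fat-associated)\n",
              x$imf_overlaps, fmt_pct(x$pct_imf_of_fat)))
  if (length(x$fat_by_chrom)) {
    cat("  fat-associated by chromosome:\n")
    for (nm in names(x$fat_by_chrom)) {
      cat(sprintf("    %-8s %d\n", nm, x$fat_by_chrom[[nm]]))
    }
  }
  if (length(x$by_trait_name)) {
    cat("  top trait names:\n")
    for (nm in utils::head(names(x$by_trait_name), 10L)) {
      cat(sprintf("    %-40s %d\n", nm, x$by_trait_name[[nm]]))
    }
  }
  invisible(x)
}

#' Write QTL summary as TSV
#'
#' @param x a `qtl_summary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qtl_summary <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("metric\tvalue", con)
  writeLines(sprintf("total_overlaps\t%d", x$total_overlaps), con)
  writeLines(sprintf("fat_overlaps\t%d", x$fat_overlaps), con)
  writeLines(sprintf("imf_overlaps\t%d", x$imf_overlaps), con)
  writeLines(sprintf("pct_fat_of_total\t%s",
                     ifelse(is.na(x$pct_fat_of_total), "NA",
                            format(x$pct_fat_of_total))), con)
  writeLines(sprintf("pct_imf_of_fat\t%s",
                     ifelse(is.na(x$pct_imf_of_fat), "NA",
                            format(x$pct_imf_of_fat))), con)
  for (nm in names(x$fat_by_chrom)) {
    writeLines(sprintf("fat_by_chrom:%s\t%d", nm, x$fat_by_chrom[[nm]]), con)
  }
  for (nm in names(x$by_trait_name)) {
    writeLines(sprintf("trait:%s\t%d", nm, x$by_trait_name[[nm]]), con)
  }
  invisible(path)
}
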