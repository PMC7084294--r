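#' Classify candidate transcripts as intergenic or gene-overlapping
#'
#' A candidate is intergenic exactly when its transcript span (first to last
#' exonic position) shares no genomic position with any reference gene span
#' on the same chromosome. Overlap is strand-agnostic, so antisense or
#' intronic candidates inside a gene locus are not intergenic. Candidates on
#' chromosomes absent from the reference are trivially intergenic (with a
#' warning). Output order equals the candidate input order.
#'
#' @param candidates `annotation_set` of candidate transcripts.
#' @param reference `annotation_set` of reference genes (gene spans are the
#'   union of each gene's transcript spans).
#' @return data.frame with `transcript_id`, `label`
#'   (`"intergenic"`/`"overlapping"`) and list-column
#'   `overlapping_gene_ids` (sorted, empty for intergenic candidates).
#' @export
classify_transcripts <- function(candidates, reference) {
  stopifnot(inherits(candidates, "annotation_set"),
            inherits(reference, "annotation_set"))
  ctx <- candidates$transcripts
  if (nrow(ctx) == 0L) {
    return(data.frame(transcript_id = character(), label = character(),
                      overlapping_gene_ids = I(list()),
                      stringsAsFactors = FALSE))
  }
  genes <- gene_spans(reference)
  novel_chrom <- setdiff(unique(ctx$chrom), unique(genes$chrom))
  if (length(novel_chrom)) {
    warning("classify_transcripts: candidate chromosome(s) absent from ",
            "reference (trivially intergenic): ",
            paste(novel_chrom, collapse = ", "))
  }
  hits_by_cand <- vector("list", nrow(ctx))
  if (nrow(genes) > 0L) {
    ov <- .find_span_overlaps(ctx, genes)
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    if (length(q)) {
      sp <- split(genes$gene_id[s], q)
      for (nm in names(sp)) {
        hits_by_cand[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
      }
    }
  }
  n_hits <- lengths(hits_by_cand)
  hits_by_cand[n_hits == 0L] <- list(character(0L))
  data.frame(
    transcript_id = ctx$transcript_id,
    label = ifelse(n_hits > 0L, "overlapping", "intergenic"),
    overlapping_gene_ids = I(hits_by_cand),
    stringsAsFactors = FALSE
  )
}

#' Write classification labels as TSV
#'
#' @param labels output of [classify_transcripts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_class_labels <- function(labels, path) {
  df <- data.frame(
    transcript_id = labels$transcript_id,
    label = labels$label,
    overlapping_gene_ids = vapply(labels$overlapping_gene_ids,
                                  paste, character(1L), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
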