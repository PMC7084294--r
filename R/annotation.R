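#' Exon-structured transcript annotation set
#'
#' The central annotation container: a validated collection of
#' exon-structured transcript models. Coordinates are 1-based inclusive
#' throughout the package (GTF convention); BED input is converted at the
#' I/O boundary. Strand is one of `"+"`, `"-"` or `"*"` (unstranded, treated
#' as matching either strand in overlap operations).
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`; one row per exon. Exons of a transcript must
#'   lie on a single chromosome and strand and must not overlap each other.
#' @param biotypes optional named character vector (names = transcript ids)
#'   assigning a biotype; transcripts without an entry get `"candidate"`.
#'   Valid biotypes: `protein_coding`, `lincRNA_known`, `lincRNA_novel`,
#'   `candidate`, `other`.
#'
#' @return An object of class `annotation_set`: a list with
#'   * `transcripts`: one row per transcript (`transcript_id`, `gene_id`,
#'     `chrom`, `strand`, `biotype`, `start`, `end`, `length`, `exon_count`),
#'     where `start`/`end` span all exons and `length` is the exonic length
#'     (sum of exon widths);
#'   * `exons`: the validated, sorted exon table.
#' @export
#' @examples
#' ex <- data.frame(transcript_id = "T1", gene_id = "G1", chrom = "chr1",
#'                  start = c(100, 300), end = c(199, 399), strand = "+")
#' aset <- annotation_set(ex)
#' aset$transcripts$length  # 200
annotation_set <- function(exons, biotypes = NULL) {
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(exons))
  if (length(miss)) {
    stop("annotation_set: missing exon columns: ", paste(miss, collapse = ", "))
  }
  exons <- as.data.frame(exons)[req]
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) {
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     biotype = character(), start = integer(),
                     end = integer(), length = integer(),
                     exon_count = integer(), stringsAsFactors = FALSE)
    return(structure(list(transcripts = tx, exons = exons),
                     class = "annotation_set"))
  }
  if (any(!exons$strand %in% c("+", "-", "*"))) {
    stop("annotation_set: strand must be one of '+', '-', '*'")
  }
  if (any(exons$start < 1L)) stop("annotation_set: exon start < 1")
  if (any(exons$end < exons$start)) {
    bad <- which(exons$end < exons$start)[1L]
    stop("annotation_set: exon end < start for transcript '",
         exons$transcript_id[bad], "'")
  }

  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  byt <- split(seq_len(nrow(exons)), exons$transcript_id)

  tx_ids <- names(byt)
  n <- length(tx_ids)
  gene <- chrom <- strand <- character(n)
  start <- end <- len <- nex <- integer(n)
  for (i in seq_len(n)) {
    idx <- byt[[i]]
    e <- exons[idx, , drop = FALSE]
    if (length(unique(e$chrom)) != 1L) {
      stop("annotation_set: transcript '", tx_ids[i],
           "' has exons on multiple chromosomes")
    }
    if (length(unique(e$strand)) != 1L) {
      stop("annotation_set: transcript '", tx_ids[i],
           "' has exons on multiple strands")
    }
    if (length(unique(e$gene_id)) != 1L) {
      stop("annotation_set: transcript '", tx_ids[i],
           "' maps to multiple gene_ids")
    }
    if (nrow(e) > 1L) {
      if (any(e$start[-1L] == e$start[-nrow(e)] &
              e$end[-1L] == e$end[-nrow(e)])) {
        stop("annotation_set: duplicate exon for transcript '", tx_ids[i], "'")
      }
      if (any(e$start[-1L] <= e$end[-nrow(e)])) {
        stop("annotation_set: overlapping exons for transcript '",
             tx_ids[i], "'")
      }
    }
    gene[i] <- e$gene_id[1L]
    chrom[i] <- e$chrom[1L]
    strand[i] <- e$strand[1L]
    start[i] <- min(e$start)
    end[i] <- max(e$end)
    len[i] <- sum(e$end - e$start + 1L)
    nex[i] <- nrow(e)
  }

  bt <- rep("candidate", n)
  if (!is.null(biotypes)) {
    valid <- c("protein_coding", "lincRNA_known", "lincRNA_novel",
               "candidate", "other")
    if (any(!biotypes %in% valid)) {
      stop("annotation_set: invalid biotype value(s): ",
           paste(unique(setdiff(biotypes, valid)), collapse = ", "))
    }
    hit <- match(tx_ids, names(biotypes))
    bt[!is.na(hit)] <- biotypes[hit[!is.na(hit)]]
  }

  tx <- data.frame(transcript_id = tx_ids, gene_id = gene, chrom = chrom,
                   strand = strand, biotype = bt, start = start, end = end,
                   length = len, exon_count = nex, stringsAsFactors = FALSE)
  tx <- tx[order(tx$transcript_id), , drop = FALSE]
  rownames(tx) <- NULL
  structure(list(transcripts = tx, exons = exons), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d transcripts / %d genes / %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  tab <- table(x$transcripts$biotype)
  for (nm in names(tab)) cat(sprintf("  %-15s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Subset an annotation set by transcript id
#'
#' @param aset an `annotation_set`.
#' @param transcript_ids character vector of transcript ids to keep.
#' @return An `annotation_set` with only the requested transcripts.
#' @export
subset_transcripts <- function(aset, transcript_ids) {
  stopifnot(inherits(aset, "annotation_set"))
  keep <- aset$exons$transcript_id %in% transcript_ids
  annotation_set(aset$exons[keep, , drop = FALSE],
                 biotypes = stats::setNames(aset$transcripts$biotype,
                                            aset$transcripts$transcript_id))
}

#' Per-gene genomic spans
#'
#' Collapses an annotation set to one span per (gene, chromosome): the
#' minimal interval covering every exon of the gene's transcripts.
#'
#' @param aset an `annotation_set`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_spans <- function(aset) {
  stopifnot(inherits(aset, "annotation_set"))
  tx <- aset$transcripts
  if (nrow(tx) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(tx$gene_id, tx$chrom, sep = "\r")
  idx <- split(seq_len(nrow(tx)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(gene_id = tx$gene_id[i[1L]], chrom = tx$chrom[i[1L]],
               start = min(tx$start[i]), end = max(tx$end[i]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene_id, out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# GRanges over transcript (or arbitrary) spans; strand deliberately dropped:
# all overlap operations in the pipeline are strand-agnostic.
.spans_gr <- function(df, levels = unique(df$chrom)) {
  GenomicRanges::GRanges(
    factor(df$chrom, levels = levels),
    IRanges::IRanges(df$start, df$end))
}

# strand-agnostic overlap with a shared seqlevels universe, so disjoint
# chromosome sets do not trigger seqinfo merge warnings
.find_span_overlaps <- function(df1, df2, ...) {
  lev <- union(unique(df1$chrom), unique(df2$chrom))
  GenomicRanges::findOverlaps(.spans_gr(df1, lev), .spans_gr(df2, lev), ...)
}
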