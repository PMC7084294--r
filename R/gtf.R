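#' Read an annotation set from a GTF file
#'
#' Parses exon features from a tab-separated GTF file into an
#' [annotation_set()]. Only rows whose feature column equals `"exon"` are
#' used; every exon row must carry `transcript_id` and `gene_id` attributes.
#'
#' @param path path to a GTF file (plain text).
#' @param biotype_attribute attribute key from which to take the transcript
#'   biotype (default `"biotype"`); transcripts without the attribute get
#'   biotype `"candidate"`.
#' @return An `annotation_set`.
#' @export
read_gtf <- function(path, biotype_attribute = "biotype") {
  if (!file.exists(path)) stop("read_gtf: file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(annotation_set(data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character())))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("read_gtf: malformed GTF line ", lineno[which(nf < 9L)[1L]],
         ": expected 9 tab-separated fields, found ", nf[which(nf < 9L)[1L]])
  }
  m <- do.call(rbind, fields)
  is_exon <- m[, 3L] == "exon"
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]
  if (nrow(m) == 0L) {
    stop("read_gtf: no exon features in ", path)
  }
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop("read_gtf: non-numeric coordinate at line ", lineno[bad])
  }
  if (any(end < start)) {
    bad <- which(end < start)[1L]
    stop("read_gtf: end < start at line ", lineno[bad])
  }
  attrs <- m[, 9L]
  get_attr <- function(key) {
    pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
    mm <- regmatches(attrs, regexec(pat, attrs))
    vapply(mm, function(g) if (length(g) >= 3L) g[3L] else NA_character_,
           character(1L))
  }
  tid <- get_attr("transcript_id")
  gid <- get_attr("gene_id")
  if (anyNA(tid)) {
    stop("read_gtf: missing transcript_id attribute at line ",
         lineno[which(is.na(tid))[1L]])
  }
  if (anyNA(gid)) {
    stop("read_gtf: missing gene_id attribute at line ",
         lineno[which(is.na(gid))[1L]])
  }
  strand <- m[, 7L]
  strand[strand == "."] <- "*"

  bt <- get_attr(biotype_attribute)
  biotypes <- NULL
  if (!all(is.na(bt))) {
    per_tx <- tapply(bt, tid, function(v) {
      v <- unique(v[!is.na(v)])
      if (length(v) > 1L) stop("read_gtf: conflicting biotype for transcript")
      if (length(v)) v else NA_character_
    })
    per_tx <- per_tx[!is.na(per_tx)]
    if (length(per_tx)) biotypes <- unlist(per_tx)
  }

  annotation_set(
    data.frame(transcript_id = tid, gene_id = gid, chrom = m[, 1L],
               start = start, end = end, strand = strand,
               stringsAsFactors = FALSE),
    biotypes = biotypes
  )
}

#' Write an annotation set as GTF
#'
#' Writes one `exon` row per exon with `transcript_id`, `gene_id` and
#' `biotype` attributes. [read_gtf()] of the output reproduces the same
#' `annotation_set`.
#'
#' @param aset an `annotation_set`.
#' @param path output file path.
#' @param source source field for column 2 (default `"lincpipe"`).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(aset, path, source = "lincpipe") {
  stopifnot(inherits(aset, "annotation_set"))
  ex <- aset$exons
  bt <- stats::setNames(aset$transcripts$biotype,
                        aset$transcripts$transcript_id)
  strand <- ex$strand
  strand[strand == "*"] <- "."
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s";',
    ex$chrom, source, ex$start, ex$end, strand, ex$gene_id,
    ex$transcript_id, unname(bt[ex$transcript_id]))
  writeLines(lines, path)
  invisible(path)
}
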