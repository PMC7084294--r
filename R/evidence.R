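#' Read a per-transcript evidence table
#'
#' The evidence table carries the external evidence consumed by the filter
#' cascade: coding-potential scores computed on both strands and the best
#' (smallest) E-values from a protein-domain search and from one or more
#' protein-database searches. Columns: `transcript_id`, `cpc_fwd`,
#' `cpc_rev`, `best_domain_evalue`, and any number of
#' `best_hit_evalue_<db>` columns. An empty cell means "no hit" and is
#' stored as `NA`; stored E-values must be strictly positive.
#'
#' @param path TSV file path.
#' @return data.frame of class `evidence_bundle` with one row per
#'   transcript; attribute `db_columns` names the protein-database columns.
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) stop("read_evidence_table: file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  evidence_bundle(df)
}

#' Construct an evidence bundle from a data.frame
#'
#' @param df data.frame with the columns described in
#'   [read_evidence_table()].
#' @return data.frame of class `evidence_bundle`.
#' @export
evidence_bundle <- function(df) {
  req <- c("transcript_id", "cpc_fwd", "cpc_rev", "best_domain_evalue")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("evidence_bundle: missing column(s): ", paste(miss, collapse = ", "))
  }
  db_cols <- grep("^best_hit_evalue_", names(df), value = TRUE)
  df$transcript_id <- as.character(df$transcript_id)
  if (anyDuplicated(df$transcript_id)) {
    stop("evidence_bundle: duplicate transcript_id")
  }
  for (col in c("cpc_fwd", "cpc_rev", "best_domain_evalue", db_cols)) {
    v <- df[[col]]
    if (is.character(v)) v[v == ""] <- NA
    df[[col]] <- as.numeric(v)
  }
  if (anyNA(df$cpc_fwd) || anyNA(df$cpc_rev)) {
    stop("evidence_bundle: coding-potential scores must be present for every transcript")
  }
  for (col in c("best_domain_evalue", db_cols)) {
    bad <- !is.na(df[[col]]) & df[[col]] <= 0
    if (any(bad)) {
      stop("evidence_bundle: non-positive E-value in '", col,
           "' for transcript '", df$transcript_id[which(bad)[1L]], "'")
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("evidence_bundle", "data.frame"),
            db_columns = db_cols)
}

#' Write an evidence bundle as TSV
#'
#' @param ev an `evidence_bundle`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(ev, path) {
  stopifnot(inherits(ev, "evidence_bundle"))
  utils::write.table(as.data.frame(ev), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
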