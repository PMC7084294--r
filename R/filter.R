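#' The six-stage lincRNA filter cascade
#'
#' Applies the identification cascade to candidate transcripts, in fixed
#' stage order:
#'
#' 1. `intergenic` — keep candidates labelled intergenic by
#'    [classify_transcripts()];
#' 2. `structure` — keep transcripts with `exon_count >= min_exons` and
#'    exonic `length >= min_length`;
#' 3. `cpc` — keep transcripts whose coding-potential score is
#'    `< cpc_max` on both strands (or either, under `cpc_rule = "any"`);
#' 4. `domain` — drop transcripts with a protein-domain hit at
#'    `E < evalue_max`;
#' 5. `protein_db` — drop transcripts with a hit at `E < evalue_max` in any
#'    protein database;
#' 6. `expression` — keep transcripts with `FPKM >= fpkm_min` in at least
#'    one sample.
#'
#' A candidate that survives the intergenic stage but lacks an evidence
#' record or an FPKM row is an error, never a silent pass.
#'
#' @param candidates `annotation_set` of candidate transcripts.
#' @param class_labels output of [classify_transcripts()] for `candidates`.
#' @param evidence an `evidence_bundle`.
#' @param fpkm an `expression_matrix` of kind `"FPKM"`.
#' @param config a [pipeline_config()].
#' @return list with `lincrnas` (an `annotation_set` of retained
#'   transcripts) and `report` (a `filter_report`: per-stage input/retained
#'   counts plus the ids removed at each stage).
#' @export
filter_lincrnas <- function(candidates, class_labels, evidence, fpkm,
                            config = pipeline_config()) {
  stopifnot(inherits(candidates, "annotation_set"),
            inherits(evidence, "evidence_bundle"),
            inherits(fpkm, "expression_matrix"))
  if (fpkm$kind != "FPKM") stop("filter_lincrnas: fpkm matrix must be kind FPKM")
  tx <- candidates$transcripts
  stages <- c("intergenic", "structure", "cpc", "domain", "protein_db",
              "expression")
  removed <- stats::setNames(vector("list", length(stages)), stages)
  n_input <- n_retained <- stats::setNames(integer(length(stages)), stages)

  alive <- tx$transcript_id

  # stage 1: intergenic
  lab <- class_labels$label[match(alive, class_labels$transcript_id)]
  if (anyNA(lab)) {
    stop("filter_lincrnas: no classification label for transcript '",
         alive[which(is.na(lab))[1L]], "'")
  }
  keep <- lab == "intergenic"
  n_input["intergenic"] <- length(alive)
  removed$intergenic <- alive[!keep]
  alive <- alive[keep]
  n_retained["intergenic"] <- length(alive)

  need_evidence <- function(ids) {
    miss <- setdiff(ids, evidence$transcript_id)
    if (length(miss)) {
      stop("filter_lincrnas: no evidence record for transcript '",
           miss[1L], "'")
    }
  }
  need_fpkm <- function(ids) {
    miss <- setdiff(ids, rownames(fpkm$values))
    if (length(miss)) {
      stop("filter_lincrnas: no FPKM row for transcript '", miss[1L], "'")
    }
  }
  need_evidence(alive)
  need_fpkm(alive)

  # stage 2: structure
  i <- match(alive, tx$transcript_id)
  keep <- tx$exon_count[i] >= config$min_exons &
    tx$length[i] >= config$min_length
  n_input["structure"] <- length(alive)
  removed$structure <- alive[!keep]
  alive <- alive[keep]
  n_retained["structure"] <- length(alive)

  # stage 3: coding potential
  j <- match(alive, evidence$transcript_id)
  fwd_ok <- evidence$cpc_fwd[j] < config$cpc_max
  rev_ok <- evidence$cpc_rev[j] < config$cpc_max
  keep <- if (config$cpc_rule == "both") fwd_ok & rev_ok else fwd_ok | rev_ok
  n_input["cpc"] <- length(alive)
  removed$cpc <- alive[!keep]
  alive <- alive[keep]
  n_retained["cpc"] <- length(alive)

  # stage 4: protein-domain homology
  j <- match(alive, evidence$transcript_id)
  dom <- evidence$best_domain_evalue[j]
  keep <- is.na(dom) | dom >= config$evalue_max
  n_input["domain"] <- length(alive)
  removed$domain <- alive[!keep]
  alive <- alive[keep]
  n_retained["domain"] <- length(alive)

  # stage 5: protein-database homology (any database)
  j <- match(alive, evidence$transcript_id)
  db_cols <- attr(evidence, "db_columns")
  hit <- rep(FALSE, length(alive))
  for (col in db_cols) {
    v <- evidence[[col]][j]
    hit <- hit | (!is.na(v) & v < config$evalue_max)
  }
  n_input["protein_db"] <- length(alive)
  removed$protein_db <- alive[hit]
  alive <- alive[!hit]
  n_retained["protein_db"] <- length(alive)

  # stage 6: expression
  if (length(alive)) {
    fp <- fpkm$values[alive, , drop = FALSE]
    keep <- apply(fp, 1L, function(v) any(v >= config$fpkm_min))
  } else {
    keep <- logical(0L)
  }
  n_input["expression"] <- length(alive)
  removed$expression <- alive[!keep]
  alive <- alive[keep]
  n_retained["expression"] <- length(alive)

  report <- structure(list(
    stages = data.frame(stage = stages, n_input = as.integer(n_input),
                        n_retained = as.integer(n_retained),
                        stringsAsFactors = FALSE),
    removed = removed
  ), class = "filter_report")

  list(lincrnas = subset_transcripts(candidates, alive), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-11s %6d -> %6d  (removed %d)\n",
                x$stages$stage[i], x$stages$n_input[i],
                x$stages$n_retained[i],
                x$stages$n_input[i] - x$stages$n_retained[i]))
  }
  invisible(x)
}

#' Write a filter report as TSV
#'
#' One row per removed transcript plus per-stage counts in a header comment.
#'
#' @param report a `filter_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(report$stages))) {
    writeLines(sprintf("# %s\tinput=%d\tretained=%d",
                       report$stages$stage[i], report$stages$n_input[i],
                       report$stages$n_retained[i]), con)
  }
  writeLines("stage\ttranscript_id", con)
  for (st in names(report$removed)) {
    ids <- report$removed[[st]]
    if (length(ids)) writeLines(paste(st, ids, sep = "\t"), con)
  }
  invisible(path)
}

#' Assign known/novel status by exonic overlap with a lincRNA database
#'
#' A retained lincRNA is `known` when some database lincRNA on the same
#' chromosome shares at least `min_overlap_fraction` of the candidate's
#' exonic length (shared exonic positions, strand-agnostic); otherwise it is
#' `novel`. This coordinate-overlap rule stands in for a sequence search
#' against the database.
#'
#' @param lincs `annotation_set` of retained lincRNAs.
#' @param linc_db `annotation_set` of database lincRNAs (with exon
#'   structure).
#' @param min_overlap_fraction overlap fraction threshold in (0, 1];
#'   defaults to the value in `config`.
#' @param config a [pipeline_config()].
#' @return data.frame with `transcript_id`, `status` (`known`/`novel`),
#'   `best_overlap_fraction`, `best_db_match` (NA when none).
#' @export
assign_known_novel <- function(lincs, linc_db,
                               min_overlap_fraction = NULL,
                               config = pipeline_config()) {
  stopifnot(inherits(lincs, "annotation_set"),
            inherits(linc_db, "annotation_set"))
  frac <- if (is.null(min_overlap_fraction)) config$min_overlap_fraction
          else min_overlap_fraction
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1) {
    stop("assign_known_novel: min_overlap_fraction must be in (0, 1]")
  }
  ctx <- lincs$transcripts
  out <- data.frame(transcript_id = ctx$transcript_id,
                    status = rep("novel", nrow(ctx)),
                    best_overlap_fraction = rep(0, nrow(ctx)),
                    best_db_match = rep(NA_character_, nrow(ctx)),
                    stringsAsFactors = FALSE)
  if (nrow(ctx) == 0L || nrow(linc_db$exons) == 0L) return(out)

  ce <- lincs$exons
  de <- linc_db$exons
  ov <- .find_span_overlaps(ce, de)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  if (length(q) == 0L) return(out)
  shared <- pmin(ce$end[q], de$end[s]) - pmax(ce$start[q], de$start[s]) + 1L
  key <- paste(ce$transcript_id[q], de$transcript_id[s], sep = "\r")
  tot <- tapply(shared, key, sum)
  pair <- do.call(rbind, strsplit(names(tot), "\r", fixed = TRUE))
  cand_len <- ctx$length[match(pair[, 1L], ctx$transcript_id)]
  frac_obs <- as.numeric(tot) / cand_len
  # best database match per candidate
  ord <- order(pair[, 1L], -frac_obs)
  first <- !duplicated(pair[ord, 1L])
  best <- data.frame(transcript_id = pair[ord, 1L][first],
                     frac = frac_obs[ord][first],
                     db = pair[ord, 2L][first], stringsAsFactors = FALSE)
  m <- match(out$transcript_id, best$transcript_id)
  hit <- !is.na(m)
  out$best_overlap_fraction[hit] <- best$frac[m[hit]]
  out$best_db_match[hit] <- best$db[m[hit]]
  out$status[hit & out$best_overlap_fraction >= frac] <- "known"
  out
}

#' Summarize transcript classes
#'
#' Computes, for each class (novel lincRNA, known lincRNA, protein-coding):
#' mean transcript length (sum of exon widths), mean exon length pooled over
#' all exons of the class, mean exon number per transcript, and mean FPKM
#' (per-transcript mean across samples, averaged over transcripts). Empty
#' classes are reported with `n = 0` and `NA` means.
#'
#' @param novel,known,coding `annotation_set`s of the three disjoint classes.
#' @param fpkm `expression_matrix` of kind `"FPKM"`; mean FPKM is computed
#'   over the transcripts of a class that have a row in the matrix.
#' @return data.frame of class `characterization_summary` with one row per
#'   class.
#' @export
characterize_sets <- function(novel, known, coding, fpkm) {
  stopifnot(inherits(fpkm, "expression_matrix"))
  ids <- list(novel_lincRNA = novel, known_lincRNA = known,
              protein_coding = coding)
  all_ids <- unlist(lapply(ids, function(a) a$transcripts$transcript_id))
  if (anyDuplicated(all_ids)) {
    stop("characterize_sets: classes must be disjoint")
  }
  one <- function(aset, label) {
    tx <- aset$transcripts
    if (nrow(tx) == 0L) {
      return(data.frame(class = label, n = 0L,
                        mean_transcript_length = NA_real_,
                        mean_exon_length = NA_real_,
                        mean_exon_number = NA_real_,
                        mean_fpkm = NA_real_, stringsAsFactors = FALSE))
    }
    ex <- aset$exons
    present <- intersect(tx$transcript_id, rownames(fpkm$values))
    mf <- if (length(present)) {
      mean(rowMeans(fpkm$values[present, , drop = FALSE]))
    } else NA_real_
    data.frame(class = label, n = nrow(tx),
               mean_transcript_length = mean(tx$length),
               mean_exon_length = mean(ex$end - ex$start + 1),
               mean_exon_number = mean(tx$exon_count),
               mean_fpkm = mf, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(one, ids, names(ids)))
  rownames(out) <- NULL
  structure(out, class = c("characterization_summary", "data.frame"))
}
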