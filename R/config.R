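#' Pipeline thresholds and keyword configuration
#'
#' Central container for every threshold used by the pipeline, with the
#' comparison direction of each rule fixed by the filtering semantics:
#' transcripts are retained when `exon_count >= min_exons` and
#' `length >= min_length`; coding-potential scores must be `< cpc_max` (on
#' both strands by default); a homology hit is significant when its E-value
#' is `< evalue_max`; a transcript survives the expression stage when its
#' FPKM is `>= fpkm_min` in at least one sample; a gene is a cis neighbour
#' when the boundary gap is `< cis_window`; a trans edge requires
#' `|r| >= trans_abs_r_min` and `fdr < fdr_max`; a feature is differentially
#' expressed when `|log2FC| > de_abs_log2fc_min` and `padj < de_padj_max`.
#'
#' @param min_exons minimum exon count retained by the structure stage.
#' @param min_length minimum transcript length (nt) retained by the
#'   structure stage.
#' @param cpc_max coding-potential scores must be strictly below this value
#'   (negative scores indicate non-coding).
#' @param cpc_rule `"both"` (default) requires both strand scores below
#'   `cpc_max`; `"any"` requires at least one.
#' @param evalue_max strict upper bound defining a significant homology hit.
#' @param fpkm_min minimum FPKM required in at least one sample.
#' @param cis_window strict upper bound (nt) on the lincRNA-gene boundary
#'   gap for cis candidacy.
#' @param trans_abs_r_min inclusive lower bound on `|r|` for trans edges.
#' @param fdr_max strict upper bound on BH-adjusted p for trans edges.
#' @param de_abs_log2fc_min strict lower bound on `|log2FC|` for DE calls.
#' @param de_padj_max strict upper bound on adjusted p for DE calls.
#' @param min_overlap_fraction exonic-overlap fraction (of the candidate's
#'   exonic length) at or above which a candidate matches a database lincRNA.
#' @param imf_keywords,fat_keywords lower-cased substrings used to classify
#'   QTL trait names (checked in that order; first match wins).
#' @param rng_seed integer seed recorded with the configuration.
#'
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$cis_window
pipeline_config <- function(min_exons = 2L,
                            min_length = 200L,
                            cpc_max = 0,
                            cpc_rule = c("both", "any"),
                            evalue_max = 1e-5,
                            fpkm_min = 0.5,
                            cis_window = 1e5,
                            trans_abs_r_min = 0.95,
                            fdr_max = 0.05,
                            de_abs_log2fc_min = 1,
                            de_padj_max = 0.05,
                            min_overlap_fraction = 0.5,
                            imf_keywords = c("intramuscular fat", "imf"),
                            fat_keywords = c("fat", "backfat", "leaf fat"),
                            rng_seed = 1L) {
  cpc_rule <- match.arg(cpc_rule)
  num <- list(min_exons = min_exons, min_length = min_length,
              cpc_max = cpc_max, evalue_max = evalue_max,
              fpkm_min = fpkm_min, cis_window = cis_window,
              trans_abs_r_min = trans_abs_r_min, fdr_max = fdr_max,
              de_abs_log2fc_min = de_abs_log2fc_min,
              de_padj_max = de_padj_max,
              min_overlap_fraction = min_overlap_fraction)
  for (nm in names(num)) {
    if (!is.numeric(num[[nm]]) || length(num[[nm]]) != 1L ||
        !is.finite(num[[nm]])) {
      stop("pipeline_config: '", nm, "' must be a single finite number")
    }
  }
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1) {
    stop("pipeline_config: 'min_overlap_fraction' must be in (0, 1]")
  }
  if (length(imf_keywords) == 0L || length(fat_keywords) == 0L) {
    stop("pipeline_config: keyword lists must be non-empty")
  }
  structure(c(num, list(
    cpc_rule = cpc_rule,
    imf_keywords = tolower(imf_keywords),
    fat_keywords = tolower(fat_keywords),
    rng_seed = as.integer(rng_seed)
  )), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in setdiff(names(x), c("imf_keywords", "fat_keywords"))) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-22s %s\n", "imf_keywords",
              paste(x$imf_keywords, collapse = ", ")))
  cat(sprintf("  %-22s %s\n", "fat_keywords",
              paste(x$fat_keywords, collapse = ", ")))
  invisible(x)
}
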