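# One-candidate filter fixture with controllable properties; returns the
# stage at which the transcript was removed ("retained" if it survives).
run_one <- function(exons = 2L, length = 400L, cpc = c(-1, -1),
                    domain_e = NA_real_, nr_e = NA_real_,
                    fpkm_row = rep(1, 6), intergenic = TRUE,
                    config = pipeline_config()) {
  per <- length %/% exons
  lens <- c(rep(per, exons - 1L), length - per * (exons - 1L))
  starts <- 1000L + cumsum(c(0L, utils::head(lens, -1L) + 500L))
  cand <- annotation_set(data.frame(
    transcript_id = "X", gene_id = "X", chrom = "chr9",
    start = starts, end = starts + lens - 1L, strand = "+",
    stringsAsFactors = FALSE))
  labels <- data.frame(
    transcript_id = "X",
    label = if (intergenic) "intergenic" else "overlapping",
    overlapping_gene_ids = I(list(if (intergenic) character(0) else "G")),
    stringsAsFactors = FALSE)
  ev <- evidence_bundle(data.frame(
    transcript_id = "X", cpc_fwd = cpc[1], cpc_rev = cpc[2],
    best_domain_evalue = domain_e, best_hit_evalue_nr = nr_e,
    stringsAsFactors = FALSE))
  fp <- make_expr(list(X = fpkm_row), "FPKM")
  res <- filter_lincrnas(cand, labels, ev, fp, config)
  if (nrow(res$lincrnas$transcripts) == 1L) return("retained")
  names(Filter(length, res$report$removed))[1L]
}

# Expression fixture with exactly constructed sample correlations between
# one shared lincRNA profile and a set of gene profiles.
cor_expr <- function(linc_ids, gene_r, n = 6, seed = 61) {
  set.seed(seed)
  rows <- list()
  base <- stats::rnorm(n)
  for (l in linc_ids) rows[[l]] <- 10 + base
  for (g in names(gene_r)) {
    xs <- (base - mean(base)) / stats::sd(base)
    z <- stats::rnorm(n)
    zr <- z - mean(z) - xs * sum((z - mean(z)) * xs) / sum(xs^2)
    zs <- (zr - mean(zr)) / stats::sd(zr)
    r <- gene_r[[g]]
    rows[[g]] <- 10 + r * xs + sqrt(1 - r^2) * zs
  }
  make_expr(rows)
}
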