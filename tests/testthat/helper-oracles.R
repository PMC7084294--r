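# Brute-force oracles and fixture builders shared across the suite.
# Oracles deliberately use naive position-set / summation definitions,
# independent of the package's interval-tree and closed-form code paths.

# annotation set of single-exon transcripts from a span table
make_span_aset <- function(ids, chrom, start, end, gene = ids,
                           strand = "+") {
  annotation_set(data.frame(
    transcript_id = ids, gene_id = gene, chrom = chrom,
    start = start, end = end, strand = strand, stringsAsFactors = FALSE))
}

# random multi-exon transcripts on small coordinates
rand_exon_aset <- function(n, max_coord = 5000, max_exons = 4,
                           prefix = "T") {
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(seq_len(max_exons), 1L)
    pos <- sort(sample(seq_len(max_coord), 2L * k))
    data.frame(transcript_id = paste0(prefix, i),
               gene_id = paste0(prefix, i),
               chrom = sample(c("c1", "c2"), 1L),
               start = pos[seq(1L, 2L * k, 2L)],
               end = pos[seq(2L, 2L * k, 2L)],
               strand = sample(c("+", "-"), 1L),
               stringsAsFactors = FALSE)
  })
  annotation_set(do.call(rbind, rows))
}

# position-set membership oracle: for each candidate span, the gene ids
# whose spans share at least one genomic position
bf_overlap_gene_ids <- function(cand, genes) {
  lapply(seq_len(nrow(cand)), function(i) {
    hits <- character(0L)
    pos_c <- seq.int(cand$start[i], cand$end[i])
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != cand$chrom[i]) next
      if (length(intersect(pos_c, seq.int(genes$start[j], genes$end[j])))) {
        hits <- c(hits, genes$gene_id[j])
      }
    }
    sort(unique(hits))
  })
}

# all-pairs position-set intersection oracle for interval tables
bf_pair_overlaps <- function(a, b, a_id = "a_id", b_id = "b_id") {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    pos_a <- seq.int(a$start[i], a$end[i])
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      shared <- length(intersect(pos_a, seq.int(b$start[j], b$end[j])))
      if (shared > 0L) {
        out <- rbind(out, data.frame(a = a[[a_id]][i], b = b[[b_id]][j],
                                     bp = shared, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# literal step-up definition of the BH adjustment
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min((m / seq.int(i, m)) * p[ord][seq.int(i, m)]))
  }
  q
}

# hypergeometric upper tail by explicit combination sums
bf_hyper_tail <- function(n_universe, n_set, n_target, k) {
  if (k > min(n_set, n_target)) return(0)
  i <- seq.int(k, min(n_set, n_target))
  sum(choose(n_set, i) * choose(n_universe - n_set, n_target - i)) /
    choose(n_universe, n_target)
}

# 6-sample two-group expression matrix from a list of row vectors
make_expr <- function(rows, kind = "FPKM", groups = NULL) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(groups)) {
    groups <- stats::setNames(rep(c("A", "B"), each = ncol(m) / 2),
                              colnames(m))
  }
  expression_matrix(m, kind, groups)
}
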