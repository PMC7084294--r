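test_that("each filter rule behaves per its comparison direction at the boundary", {
  # structure: exon_count >= 2, length >= 200
  expect_equal(run_one(exons = 1L), "structure")
  expect_equal(run_one(exons = 2L), "retained")
  expect_equal(run_one(length = 199L), "structure")
  expect_equal(run_one(length = 200L), "retained")
  # coding potential: strict < 0 on both strands
  expect_equal(run_one(cpc = c(0, -1)), "cpc")
  expect_equal(run_one(cpc = c(-0.1, -0.1)), "retained")
  # domain homology: significant only when E < 1e-5 (strict)
  expect_equal(run_one(domain_e = 1e-5), "retained")
  expect_equal(run_one(domain_e = 0.999e-5), "domain")
  # protein-database homology: same rule, any database
  expect_equal(run_one(nr_e = 1e-5), "retained")
  expect_equal(run_one(nr_e = 0.999e-5), "protein_db")
  # expression: FPKM >= 0.5 in at least one sample
  expect_equal(run_one(fpkm_row = c(0.5, 0, 0, 0, 0, 0)), "retained")
  expect_equal(run_one(fpkm_row = rep(0.49, 6)), "expression")
  # intergenic gate
  expect_equal(run_one(intergenic = FALSE), "intergenic")
})

test_that("the coding-potential rule honours the both/any switch", {
  any_cfg <- pipeline_config(cpc_rule = "any")
  expect_equal(run_one(cpc = c(0.5, -1), config = any_cfg), "retained")
  expect_equal(run_one(cpc = c(0.5, 0.5), config = any_cfg), "cpc")
  expect_equal(run_one(cpc = c(0.5, -1)), "cpc")  # default: both strands
})

test_that("the cascade partitions its input and chains stage counts", {
  set.seed(31)
  b <- generate_dataset(generator_config(rng_seed = 31))
  labels <- classify_transcripts(b$candidates, b$reference)
  res <- filter_lincrnas(b$candidates, labels, b$evidence, b$fpkm)
  st <- res$report$stages
  expect_equal(st$n_input[-1L], st$n_retained[-nrow(st)])
  expect_true(all(diff(st$n_input) <= 0))
  n_removed <- sum(lengths(res$report$removed))
  expect_equal(nrow(res$lincrnas$transcripts) + n_removed, st$n_input[1L])
  removed_ids <- unlist(res$report$removed, use.names = FALSE)
  expect_equal(anyDuplicated(c(removed_ids,
                               res$lincrnas$transcripts$transcript_id)), 0L)
})

test_that("missing evidence or expression for a surviving candidate errors", {
  cand <- make_span_aset("X", "chr1", c(1000), c(1999))
  labels <- data.frame(transcript_id = "X", label = "intergenic",
                       overlapping_gene_ids = I(list(character(0))))
  ev <- evidence_bundle(data.frame(transcript_id = "Y", cpc_fwd = -1,
                                   cpc_rev = -1, best_domain_evalue = NA))
  fp <- make_expr(list(X = rep(1, 6)), "FPKM")
  expect_error(filter_lincrnas(cand, labels, ev, fp),
               "no evidence record for transcript 'X'")
  ev2 <- evidence_bundle(data.frame(transcript_id = "X", cpc_fwd = -1,
                                    cpc_rev = -1, best_domain_evalue = NA))
  fp2 <- make_expr(list(Y = rep(1, 6)), "FPKM")
  expect_error(filter_lincrnas(cand, labels, ev2, fp2),
               "no FPKM row for transcript 'X'")
})

test_that("known/novel assignment follows the exonic-overlap fraction", {
  cand <- make_span_aset("L1", "chr1", 1, 100)
  # database transcript sharing exactly 40 of the candidate's 100 positions
  db <- make_span_aset("D1", "chr1", 1, 40)
  expect_equal(assign_known_novel(cand, db)$status, "novel")
  expect_equal(assign_known_novel(cand, db,
                                  min_overlap_fraction = 0.3)$status, "known")
  frac <- assign_known_novel(cand, db)$best_overlap_fraction
  expect_equal(frac, 0.4)
  # identical coordinates: fraction 1, known
  expect_equal(assign_known_novel(cand, cand)$status, "known")
  # database on another chromosome: novel
  db2 <- make_span_aset("D1", "chr7", 1, 100)
  expect_equal(assign_known_novel(cand, db2)$status, "novel")
  expect_error(assign_known_novel(cand, db, min_overlap_fraction = 1.5),
               "\\(0, 1\\]")
})

test_that("overlap fractions use exonic positions, not spans", {
  # candidate: exons 1-100 and 901-1000 (exonic length 200, span 1000)
  cand <- annotation_set(data.frame(
    transcript_id = "L1", gene_id = "L1", chrom = "chr1",
    start = c(1, 901), end = c(100, 1000), strand = "+"))
  # database lincRNA covering the intron only: no exonic overlap
  db <- make_span_aset("D1", "chr1", 200, 800)
  expect_equal(assign_known_novel(cand, db)$status, "novel")
  # database copy of exon 1 only: fraction 0.5 -> known at default
  db2 <- make_span_aset("D2", "chr1", 1, 100)
  expect_equal(assign_known_novel(cand, db2)$status, "known")
})

test_that("class characterization matches direct recomputation", {
  two <- make_span_aset(c("a", "b"), "c1", c(1, 1001), c(500, 1700))
  one <- annotation_set(data.frame(
    transcript_id = "k1", gene_id = "k1", chrom = "c1",
    start = c(2000, 2500), end = c(2099, 2799), strand = "+"))
  fp <- make_expr(list(a = rep(2, 6), b = rep(4, 6), k1 = rep(1, 6)), "FPKM")
  cs <- characterize_sets(two, one, annotation_set(data.frame(
    transcript_id = character(0), gene_id = character(0),
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0))), fp)
  novel <- cs[cs$class == "novel_lincRNA", ]
  expect_equal(novel$mean_transcript_length, 600)
  expect_equal(novel$mean_fpkm, 3)
  known <- cs[cs$class == "known_lincRNA", ]
  expect_equal(known$mean_exon_length, 200)
  expect_equal(known$mean_exon_number, 2)
  coding <- cs[cs$class == "protein_coding", ]
  expect_equal(coding$n, 0L)
  expect_true(is.na(coding$mean_transcript_length))
})

test_that("characterization of simulated transcripts equals raw exon-list math", {
  set.seed(32)
  aset <- rand_exon_aset(50, prefix = "N")
  fp <- make_expr(stats::setNames(
    lapply(1:50, function(i) runif(6, 0, 10)),
    aset$transcripts$transcript_id), "FPKM")
  empty <- subset_transcripts(aset, character(0))
  cs <- characterize_sets(aset, empty, empty, fp)
  row <- cs[cs$class == "novel_lincRNA", ]
  ex <- aset$exons
  expect_equal(row$mean_transcript_length, mean(aset$transcripts$length))
  expect_equal(row$mean_exon_length, mean(ex$end - ex$start + 1))
  expect_equal(row$mean_exon_number,
               mean(table(ex$transcript_id)[aset$transcripts$transcript_id]))
  expect_equal(row$mean_fpkm,
               mean(rowMeans(fp$values[aset$transcripts$transcript_id, ])))
  expect_error(characterize_sets(aset, aset, empty, fp), "disjoint")
})

test_that("FPKM formula, conservation identity and guards", {
  g <- stats::setNames(rep(c("A", "B"), each = 2), paste0("s", 1:4))
  m <- matrix(c(10, 999990, 0, 1000000, 5, 999995, 1, 999999), 2, 4,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  cm <- expression_matrix(m, "counts", g)
  fp <- fpkm_from_counts(cm, c(a = 1000, b = 50000))
  expect_equal(fp$values["a", "s1"], 10)   # 10 reads / 1 kb / 1 M
  expect_equal(fp$values["a", "s2"], 0)
  # conservation: sum_f FPKM * length / 1e9 == 1 per sample
  set.seed(33)
  m2 <- matrix(rpois(80, 50) + 1, 20, 4,
               dimnames = list(paste0("f", 1:20), paste0("s", 1:4)))
  lens <- stats::setNames(sample(200:5000, 20), paste0("f", 1:20))
  fp2 <- fpkm_from_counts(expression_matrix(m2, "counts", g), lens)
  expect_equal(unname(colSums(fp2$values * lens[rownames(fp2$values)]) / 1e9),
               rep(1, 4))
  expect_error(fpkm_from_counts(cm, c(a = 1000, b = 0)), "non-positive")
  m3 <- m; m3[, 1] <- 0
  expect_error(fpkm_from_counts(expression_matrix(m3, "counts", g),
                                c(a = 1000, b = 1000)), "zero library size")
})
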