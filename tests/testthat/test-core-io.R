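test_that("GTF exons aggregate into validated transcript models", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t100\t199\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t300\t399\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'
  ), gtf)
  aset <- read_gtf(gtf)
  tx <- aset$transcripts
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$exon_count, 2L)
  expect_equal(tx$length, 200L)
  expect_equal(c(tx$start, tx$end), c(100L, 399L))
})

test_that("malformed GTF rows are rejected with a line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t100\t199\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tx\texon\t500\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T2";'
  ), gtf)
  expect_error(read_gtf(gtf), "end < start at line 2")

  writeLines("chr1\texon\t100\t199", gtf)
  expect_error(read_gtf(gtf), "9 tab-separated fields")
})

test_that("a transcript with exons on two chromosomes fails validation", {
  ex <- data.frame(transcript_id = "T1", gene_id = "G1",
                   chrom = c("chr1", "chr2"), start = c(1, 1),
                   end = c(10, 10), strand = "+")
  expect_error(annotation_set(ex), "multiple chromosomes")
  ex2 <- data.frame(transcript_id = "T1", gene_id = "G1", chrom = "chr1",
                    start = c(1, 1), end = c(10, 10), strand = "+")
  expect_error(annotation_set(ex2), "duplicate exon")
})

test_that("GTF round trip reproduces the annotation set", {
  set.seed(11)
  aset <- rand_exon_aset(30)
  path <- tempfile(fileext = ".gtf")
  write_gtf(aset, path)
  back <- read_gtf(path)
  expect_equal(back$transcripts, aset$transcripts)
  expect_equal(back$exons, aset$exons)
})

test_that("transcript length equals brute-force covered-position count", {
  set.seed(12)
  aset <- rand_exon_aset(100)
  for (id in aset$transcripts$transcript_id) {
    ex <- aset$exons[aset$exons$transcript_id == id, ]
    covered <- length(unique(unlist(Map(seq.int, ex$start, ex$end))))
    expect_identical(
      aset$transcripts$length[aset$transcripts$transcript_id == id],
      as.integer(covered))
  }
})

test_that("expression matrices validate sign, integrality and groups", {
  g <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  m <- matrix(0, 2, 6, dimnames = list(c("f1", "f2"), paste0("s", 1:6)))
  em <- expression_matrix(m, "counts", g)
  expect_equal(unname(colSums(em$values)), rep(0, 6))

  m2 <- m; m2[1, 2] <- -1
  expect_error(expression_matrix(m2, "counts", g), "negative value")
  m3 <- m; m3[2, 3] <- 2.5
  expect_error(expression_matrix(m3, "counts", g),
               "non-integer count at feature 'f2', sample 's3'")
  expect_error(expression_matrix(m, "counts", g[-1]),
               "missing from group map")
  # FPKM kind accepts fractional values
  expect_s3_class(expression_matrix(m3, "FPKM", g), "expression_matrix")
})

test_that("expression matrix TSV round trip preserves values", {
  g <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  set.seed(13)
  m <- matrix(rpois(30, 20), 5, 6,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  em <- expression_matrix(m, "counts", g)
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path, "counts", g)
  expect_equal(back$values, em$values)
  expect_equal(back$groups, em$groups)
})

test_that("QTL BED records convert coordinates and classify traits", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t0\t5000\tIntramuscular fat content",
    "chr1\t999\t2000\tAverage backfat thickness",
    "chr1\t0\t100\tTeat number"
  ), bed)
  q <- read_qtl_bed(bed)
  expect_equal(q$start, c(1L, 1000L, 1L))
  expect_equal(q$end, c(5000L, 2000L, 100L))
  expect_equal(q$trait_class, c("IMF", "fat_other", "non_fat"))

  writeLines("chr1\t100\t100\tsome trait", bed)
  expect_error(read_qtl_bed(bed), "end <= start")
  writeLines("chr1\t0\t100\t ", bed)
  expect_error(read_qtl_bed(bed), "empty trait")
})

test_that("BED round trip preserves 0-based half-open coordinates", {
  bed <- tempfile(fileext = ".bed")
  lines <- c("chr2\t0\t150\tLeaf fat weight\tQ1",
             "chr3\t12345\t99999\tLoin muscle area\tQ2")
  writeLines(lines, bed)
  q <- read_qtl_bed(bed)
  bed2 <- tempfile(fileext = ".bed")
  write_qtl_bed(q, bed2)
  expect_identical(readLines(bed2), lines)
})

test_that("evidence tables validate E-values and reject duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "transcript_id\tcpc_fwd\tcpc_rev\tbest_domain_evalue\tbest_hit_evalue_nr",
    "T1\t-1.5\t-0.2\t\t0.01",
    "T2\t-0.5\t-2.2\t1e-08\t"
  ), path)
  ev <- read_evidence_table(path)
  expect_true(is.na(ev$best_domain_evalue[1]))
  expect_equal(ev$best_domain_evalue[2], 1e-8)
  expect_equal(attr(ev, "db_columns"), "best_hit_evalue_nr")

  bad <- data.frame(transcript_id = c("T1", "T1"), cpc_fwd = -1,
                    cpc_rev = -1, best_domain_evalue = NA)
  expect_error(evidence_bundle(bad), "duplicate")
  bad2 <- data.frame(transcript_id = "T1", cpc_fwd = -1, cpc_rev = -1,
                     best_domain_evalue = 0)
  expect_error(evidence_bundle(bad2), "non-positive E-value")
})

test_that("threshold configuration validates its inputs", {
  expect_error(pipeline_config(cis_window = Inf), "finite")
  expect_error(pipeline_config(min_overlap_fraction = 0), "\\(0, 1\\]")
  expect_error(pipeline_config(imf_keywords = character(0)), "non-empty")
  expect_equal(pipeline_config(cpc_rule = "any")$cpc_rule, "any")
})
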