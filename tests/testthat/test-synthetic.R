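test_that("correlated pairs achieve the target sample correlation exactly", {
  p <- generate_correlated_pair(1, 6, seed = 81)
  expect_equal(stats::cor(p$x, p$y), 1)
  p <- generate_correlated_pair(0.97, 6, seed = 82)
  expect_equal(stats::cor(p$x, p$y), 0.97, tolerance = 1e-10)
  p <- generate_correlated_pair(-0.5, 100, seed = 83)
  expect_equal(stats::cor(p$x, p$y), -0.5, tolerance = 1e-10)
  expect_error(generate_correlated_pair(0.5, 2), "n >= 3")
  expect_error(generate_correlated_pair(1.5, 6), "<= 1")
})

test_that("identical seeds produce byte-identical bundles", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_dataset(generator_config(rng_seed = 84), dir = d1)
  generate_dataset(generator_config(rng_seed = 84), dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 9L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generated bundles pass core validation without warnings", {
  d <- tempfile()
  b <- generate_dataset(generator_config(rng_seed = 85), dir = d)
  expect_no_warning({
    cand <- read_gtf(file.path(d, "candidates.gtf"))
    ref <- read_gtf(file.path(d, "reference.gtf"))
    db <- read_gtf(file.path(d, "lincdb.gtf"))
    ev <- read_evidence_table(file.path(d, "evidence.tsv"))
    gm <- utils::read.delim(file.path(d, "groups.tsv"))
    grp <- stats::setNames(gm$group, gm$sample)
    cm <- read_expression_matrix(file.path(d, "counts.tsv"), "counts", grp)
    fp <- read_expression_matrix(file.path(d, "fpkm.tsv"), "FPKM", grp)
    q <- read_qtl_bed(file.path(d, "qtl.bed"))
  })
  expect_equal(cand$transcripts, b$candidates$transcripts)
  expect_equal(cm$values, b$counts$values)
  expect_equal(q$start, b$qtls$start)
  expect_equal(q$trait_class, b$qtls$trait_class)
})

test_that("the filter cascade recovers exactly the planted lincRNAs", {
  b <- generate_dataset(generator_config(rng_seed = 86))
  truth <- b$truth
  labels <- classify_transcripts(b$candidates, b$reference)
  res <- filter_lincrnas(b$candidates, labels, b$evidence, b$fpkm)
  retained <- res$lincrnas$transcripts$transcript_id
  planted <- c(truth$linc_ids_known, truth$linc_ids_novel)
  expect_setequal(retained, planted)     # precision = recall = 1
  for (st in names(truth$decoys)) {
    expect_true(all(truth$decoys[[st]] %in% res$report$removed[[st]]),
                label = paste("decoys at stage", st))
  }
  kn <- assign_known_novel(res$lincrnas, b$linc_db)
  expect_setequal(kn$transcript_id[kn$status == "known"],
                  truth$linc_ids_known)
  expect_setequal(kn$transcript_id[kn$status == "novel"],
                  truth$linc_ids_novel)
})

test_that("planted QTL hits are exactly the co-localization output", {
  b <- generate_dataset(generator_config(rng_seed = 87))
  de_set <- subset_transcripts(b$candidates, b$truth$de_linc_ids)
  ov <- colocalize_qtl(de_set, b$qtls)
  expect_equal(paste(ov$lincrna_id, ov$qtl_id),
               paste(b$truth$qtl_hits$lincrna_id, b$truth$qtl_hits$qtl_id))
  expect_equal(ov$trait_class, b$truth$qtl_hits$trait_class)
})

test_that("planted trans pairs are recovered exactly at the 0.95 cutoff", {
  b <- generate_dataset(generator_config(rng_seed = 88))
  de_set <- subset_transcripts(b$candidates, b$truth$de_linc_ids)
  tr <- predict_trans_targets(de_set, b$reference, b$fpkm)
  tp <- b$truth$trans_pairs
  expect_setequal(paste(tr$lincrna_id, tr$gene_id),
                  paste(tp$lincrna_id, tp$gene_id))
  m <- match(paste(tr$lincrna_id, tr$gene_id),
             paste(tp$lincrna_id, tp$gene_id))
  expect_equal(tr$r, tp$target_r[m], tolerance = 1e-9)
  # planted cis pairs reappear with their exact correlations
  cis <- predict_cis_targets(de_set, b$reference, b$fpkm)
  cp <- b$truth$cis_pairs
  mc <- match(paste(cp$lincrna_id, cp$gene_id),
              paste(cis$lincrna_id, cis$gene_id))
  expect_false(anyNA(mc))
  expect_equal(cis$r[mc], cp$target_r, tolerance = 1e-9)
  expect_equal(cis$distance_bp[mc], cp$gap_bp)
})

test_that("planted fold changes are recovered with high sensitivity", {
  # low-dispersion condition: the 3 vs 3 design is otherwise underpowered
  hits <- 0L; n_planted <- 0L
  for (s in 1:20) {
    b <- generate_dataset(generator_config(rng_seed = 800 + s,
                                           nb_dispersion = 0.01))
    de <- test_differential_expression(b$counts, c("Wei", "Yorkshire"))
    planted <- names(b$truth$de_feature_log2fc)
    hits <- hits + sum(de$is_de[match(planted, de$feature_id)], na.rm = TRUE)
    n_planted <- n_planted + length(planted)
  }
  expect_gte(hits / n_planted, 0.9)
})

test_that("degenerate configurations are handled or rejected", {
  cfg <- generator_config(rng_seed = 89, n_lincs_known = 0L,
                          n_lincs_novel = 0L, n_decoys_per_stage = 0L,
                          n_cis_lincs = 0L, n_trans_lincs = 0L,
                          n_trans_targets_per_linc = 0L,
                          n_qtls_per_de_linc = 0L)
  b <- generate_dataset(cfg)
  expect_equal(nrow(b$candidates$transcripts), 0L)
  expect_equal(nrow(b$truth$trans_pairs), 0L)
  labels <- classify_transcripts(
    b$candidates, b$reference)
  expect_equal(nrow(labels), 0L)
  expect_error(generator_config(rng_seed = 90, n_cis_lincs = 4L,
                                n_lincs_known = 2L, n_lincs_novel = 1L),
               "more planted DE lincRNAs")
  expect_error(generator_config(rng_seed = 91, samples_per_group = 2L,
                                n_trans_lincs = 3L),
               "too many trans lincRNAs")
  expect_error(generator_config(), "rng_seed is mandatory")
  expect_error(generate_dataset(generator_config(
    rng_seed = 92, chrom_lengths = stats::setNames(rep(2e6, 5),
                                                   paste0("chr", 1:5)))),
    "too short")
})
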