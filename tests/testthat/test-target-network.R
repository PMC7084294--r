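test_that("cis candidacy follows the strict 100-kb boundary gap", {
  lincs <- make_span_aset("L1", "chr1", 200000, 205000)
  genes <- make_span_aset(c("G1.t", "G2.t", "G3.t", "G4.t"), "chr1",
                          c(290000, 305001, 304999, 201000),
                          c(300000, 310000, 309999, 202000),
                          gene = c("G1", "G2", "G3", "G4"))
  expr <- cor_expr("L1", c(G1 = 0.9, G2 = 0.9, G3 = 0.9, G4 = 0.5))
  cis <- predict_cis_targets(lincs, genes, expr)
  # G1: gap 84,999 (in); G2: gap exactly 100,000 (out, strict <);
  # G3: gap 99,998 (in); G4: overlapping, gap 0 (in)
  expect_setequal(cis$gene_id, c("G1", "G3", "G4"))
  expect_equal(cis$distance_bp[cis$gene_id == "G1"], 84999L)
  expect_equal(cis$distance_bp[cis$gene_id == "G4"], 0L)
  # cis pairs are reported with r and p regardless of correlation strength
  expect_equal(cis$r[cis$gene_id == "G4"], 0.5)
  expect_equal(cis$p_value, correlation_pvalue(cis$r, 6))
})

test_that("trans edges require |r| >= 0.95 and FDR < 0.05, cis pairs excluded", {
  lincs <- make_span_aset("L1", "chr1", 200000, 205000)
  genes <- make_span_aset(paste0("G", 1:5, ".t"), "chr1",
                          c(290000, 2e6, 3e6, 4e6, 5e6),
                          c(300000, 2.01e6, 3.01e6, 4.01e6, 5.01e6),
                          gene = paste0("G", 1:5))
  expr <- cor_expr("L1", c(G1 = 0.99, G2 = 0.97, G3 = 0.94, G4 = -0.97,
                           G5 = 0.1))
  tr <- predict_trans_targets(lincs, genes, expr)
  # G1 is cis-eligible and must not appear despite r = 0.99
  expect_setequal(tr$gene_id, c("G2", "G4"))
  expect_equal(tr$sign[tr$gene_id == "G4"], "negative")
  expect_equal(tr$sign[tr$gene_id == "G2"], "positive")
  all_pairs <- predict_trans_targets(lincs, genes, expr, return_all = TRUE)
  expect_false("G1" %in% all_pairs$gene_id)
  expect_equal(nrow(all_pairs), 4L)
  # |r| rule is inclusive at 0.95 and 0.94 fails it whatever its fdr
  g3 <- all_pairs[all_pairs$gene_id == "G3", ]
  expect_false(g3$retained)
  expect_equal(g3$r, 0.94)
})

test_that("trans selection is invariant to feature order", {
  lincs <- make_span_aset("L1", "chr1", 200000, 205000)
  set.seed(62)
  starts <- 2e6 + (1:20) * 1e5 * 3
  genes <- make_span_aset(paste0("G", 1:20, ".t"), "chr1", starts,
                          starts + 5e4, gene = paste0("G", 1:20))
  rs <- stats::setNames(c(rep(0.99, 4), runif(16, -0.5, 0.5)),
                        paste0("G", 1:20))
  expr <- cor_expr("L1", rs)
  tr1 <- predict_trans_targets(lincs, genes, expr)
  perm <- sample(nrow(expr$values))
  expr2 <- expression_matrix(expr$values[perm, ], "FPKM", expr$groups)
  tr2 <- predict_trans_targets(lincs, genes, expr2)
  expect_equal(tr1[order(tr1$gene_id), c("gene_id", "r", "fdr")],
               tr2[order(tr2$gene_id), c("gene_id", "r", "fdr")])
  # post-hoc audit of the thresholds on the retained set
  expect_true(all(abs(tr1$r) >= 0.95 & tr1$fdr < 0.05))
})

test_that("constant expression vectors are excluded from the FDR family", {
  lincs <- make_span_aset("L1", "chr1", 200000, 205000)
  genes <- make_span_aset(c("G1.t", "G2.t"), "chr1", c(250000, 2e6),
                          c(260000, 2.01e6), gene = c("G1", "G2"))
  expr <- cor_expr("L1", c(G1 = 0.9, G2 = 0.9))
  vals <- expr$values
  vals["G1", ] <- 5  # constant
  expr <- expression_matrix(vals, "FPKM", expr$groups)
  cis <- predict_cis_targets(lincs, genes, expr)
  expect_true(is.na(cis$r[cis$gene_id == "G1"]))
  expect_true(is.na(cis$fdr[cis$gene_id == "G1"]))
})

test_that("DEPTG tallies split by edge sign and conserve totals", {
  edges <- structure(data.frame(
    lincrna_id = c("L1", "L1", "L1", "L1", "L2"),
    gene_id = c("G1", "G2", "G3", "G4", "G1"),
    mode = "trans", r = c(0.99, 0.98, -0.97, 0.99, -0.99),
    p_value = 1e-4, fdr = 1e-3, distance_bp = NA_integer_,
    sign = c("positive", "positive", "negative", "positive", "negative"),
    stringsAsFactors = FALSE), class = c("target_edges", "data.frame"))
  de <- structure(data.frame(
    feature_id = c("G1", "G2", "G3", "G4"),
    is_de = c(TRUE, TRUE, TRUE, FALSE),
    direction = c("up", "up", "down", "none"), stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"))
  s <- classify_deptgs(edges, de)
  expect_equal(s$lincrna_id, c("L1", "L2"))
  expect_equal(s$n_deptgs, c(3L, 1L))      # G4 is not DE
  expect_equal(s$n_up, c(2L, 0L))
  expect_equal(s$n_down, c(1L, 1L))
  expect_equal(s$n_up + s$n_down, s$n_deptgs)
})

test_that("network export writes SIF and round-trippable tables", {
  edges <- structure(data.frame(
    lincrna_id = c("L1", "L1", "L2"), gene_id = c("G1", "G2", "G1"),
    mode = "trans", r = c(0.99, -0.96, 0.97), p_value = 1e-4, fdr = 1e-3,
    distance_bp = NA_integer_,
    sign = c("positive", "negative", "positive"),
    stringsAsFactors = FALSE), class = c("target_edges", "data.frame"))
  dir <- tempfile()
  files <- export_network(edges, dir)
  sif <- readLines(files$sif)
  expect_equal(length(sif), 3L)
  expect_equal(sif[2], "L1\tdown\tG2")
  # degree: G1 is targeted by two lincRNAs -> two SIF lines
  expect_equal(sum(grepl("\\tG1$", sif)), 2L)
  back <- utils::read.delim(files$edges, stringsAsFactors = FALSE)
  expect_equal(back[c("lincrna_id", "gene_id", "sign")],
               as.data.frame(edges)[c("lincrna_id", "gene_id", "sign")])
  nodes <- utils::read.delim(files$nodes, stringsAsFactors = FALSE)
  expect_setequal(nodes$node[nodes$type == "lincRNA"], c("L1", "L2"))

  expect_warning(export_network(rbind(edges, edges[1, ]), dir), "duplicate")
  expect_error(export_network(edges[0, ], dir), "empty edge set")
})
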