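#' Run the full lincRNA analysis pipeline
#'
#' Executes every stage from a single declarative configuration:
#' intergenic classification, the six-stage filter cascade, known/novel
#' assignment, class characterization, differential expression of lincRNAs
#' and protein-coding genes, QTL co-localization, cis and trans target
#' prediction, DEPTG tallies, network export and (optionally) gene-set
#' enrichment of the DEPTGs. All stage outputs are written to
#' `config$out_dir` as TSV/GTF/SIF and a JSON run manifest is produced.
#'
#' The configuration is a named list (or path to a YAML file) with keys:
#' * `out_dir` (required);
#' * either `simulate` (a list of [generator_config()] arguments; the
#'   bundle is generated under `out_dir/synthetic`) or `inputs` (paths:
#'   `candidate_gtf`, `reference_gtf`, `lincdb_gtf`, `evidence_tsv`,
#'   `counts_tsv`, `fpkm_tsv`, `groups_tsv`, `qtl_bed`);
#' * `contrast`: the two group labels, log2FC oriented first over second
#'   (defaults to the two groups in the order they appear);
#' * `thresholds`: a list of [pipeline_config()] overrides;
#' * `run_qtl`: logical (default `TRUE`); when `TRUE` a QTL file must be
#'   available before any computation starts;
#' * `gene_sets_gmt`: optional GMT file for DEPTG enrichment.
#'
#' @param config named list or path to a YAML config file.
#' @return Invisibly, a list with `results` (all in-memory stage outputs)
#'   and `manifest` (config snapshot, input digests, output paths, stage
#'   timings).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("run_pipeline: config needs 'out_dir'")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pcfg <- do.call(pipeline_config, as.list(config$thresholds))
  run_qtl <- if (is.null(config$run_qtl)) TRUE else isTRUE(config$run_qtl)

  ## resolve inputs up front so configuration errors precede computation
  if (!is.null(config$simulate)) {
    gcfg <- do.call(generator_config, config$simulate)
    bundle <- generate_dataset(gcfg, dir = file.path(out_dir, "synthetic"))
    inputs <- bundle$paths
  } else {
    inputs <- config$inputs
    req <- c("candidate_gtf", "reference_gtf", "lincdb_gtf", "evidence_tsv",
             "counts_tsv", "fpkm_tsv", "groups_tsv")
    miss <- setdiff(req, names(inputs))
    if (length(miss)) {
      stop("run_pipeline: missing input path(s): ", paste(miss, collapse = ", "))
    }
    bundle <- NULL
  }
  if (run_qtl && is.null(inputs$qtl_bed)) {
    stop("run_pipeline: QTL stage enabled but no 'qtl_bed' input configured")
  }
  for (nm in setdiff(names(inputs),
                     c("truth_json", "manifest_json"))) {
    if (!file.exists(inputs[[nm]])) {
      stop("run_pipeline: input file not found: ", inputs[[nm]])
    }
  }

  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("run_pipeline: stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  results <- list()
  out <- function(f) file.path(out_dir, f)

  results$candidates <- stage("read_inputs", {
    read_gtf(inputs$candidate_gtf)
  })
  reference <- read_gtf(inputs$reference_gtf)
  linc_db <- read_gtf(inputs$lincdb_gtf)
  evidence <- read_evidence_table(inputs$evidence_tsv)
  gm <- utils::read.delim(inputs$groups_tsv, stringsAsFactors = FALSE)
  group_map <- stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
  counts <- read_expression_matrix(inputs$counts_tsv, "counts", group_map)
  fpkm <- read_expression_matrix(inputs$fpkm_tsv, "FPKM", group_map)
  qtls <- if (run_qtl) read_qtl_bed(inputs$qtl_bed, pcfg) else NULL

  contrast <- config$contrast
  if (is.null(contrast)) contrast <- unique(unname(group_map))[1:2]

  results$class_labels <- stage("classify", {
    classify_transcripts(results$candidates, reference)
  })
  write_class_labels(results$class_labels, out("class_labels.tsv"))

  filt <- stage("filter", {
    filter_lincrnas(results$candidates, results$class_labels, evidence,
                    fpkm, pcfg)
  })
  results$filter_report <- filt$report
  write_filter_report(filt$report, out("filter_report.tsv"))

  results$known_novel <- stage("known_novel", {
    assign_known_novel(filt$lincrnas, linc_db, config = pcfg)
  })
  status <- stats::setNames(results$known_novel$status,
                            results$known_novel$transcript_id)
  lincs <- annotation_set(
    filt$lincrnas$exons,
    biotypes = stats::setNames(
      ifelse(status == "known", "lincRNA_known", "lincRNA_novel"),
      names(status)))
  results$lincrnas <- lincs
  write_gtf(lincs, out("lincrnas.gtf"))

  known_ids <- names(status)[status == "known"]
  novel_ids <- names(status)[status == "novel"]
  results$characterization <- stage("characterize", {
    characterize_sets(subset_transcripts(lincs, novel_ids),
                      subset_transcripts(lincs, known_ids),
                      reference, fpkm)
  })
  utils::write.table(as.data.frame(results$characterization),
                     out("characterization.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  de_all <- stage("diffexpr", {
    test_differential_expression(counts, contrast, pcfg)
  })
  linc_ids <- lincs$transcripts$transcript_id
  coding_ids <- unique(reference$transcripts$gene_id)
  results$de_lincs <- de_all[de_all$feature_id %in% linc_ids, , drop = FALSE]
  results$de_genes <- de_all[de_all$feature_id %in% coding_ids, , drop = FALSE]
  for (slot in c("de_lincs", "de_genes")) {
    attr(results[[slot]], "contrast") <- contrast
    attr(results[[slot]], "engine") <- attr(de_all, "engine")
    class(results[[slot]]) <- class(de_all)
  }
  write_de_table(results$de_lincs, out("de_lincrnas.tsv"))
  write_de_table(results$de_genes, out("de_genes.tsv"))

  de_linc_ids <- results$de_lincs$feature_id[results$de_lincs$is_de]
  de_linc_set <- subset_transcripts(lincs, de_linc_ids)

  if (run_qtl) {
    results$qtl_overlaps <- stage("qtl", colocalize_qtl(de_linc_set, qtls))
    results$qtl_summary <- summarize_qtl(results$qtl_overlaps)
    utils::write.table(results$qtl_overlaps, out("qtl_overlaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_qtl_summary(results$qtl_summary, out("qtl_summary.tsv"))
  }

  results$cis_edges <- stage("cis_targets", {
    predict_cis_targets(de_linc_set, reference, fpkm, pcfg)
  })
  results$trans_edges <- stage("trans_targets", {
    predict_trans_targets(de_linc_set, reference, fpkm, pcfg)
  })
  utils::write.table(as.data.frame(results$cis_edges),
                     out("cis_targets.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(results$trans_edges),
                     out("trans_targets.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  edges <- rbind(as.data.frame(results$cis_edges),
                 as.data.frame(results$trans_edges))
  results$deptg_summary <- stage("deptgs", {
    classify_deptgs(edges, results$de_genes)
  })
  utils::write.table(as.data.frame(results$deptg_summary),
                     out("deptg_summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (nrow(edges)) {
    results$network_files <- stage("network", {
      export_network(edges, out_dir, "network",
                     de_lincs = results$de_lincs,
                     de_genes = results$de_genes)
    })
  }

  if (!is.null(config$gene_sets_gmt)) {
    sets <- read_gmt(config$gene_sets_gmt)
    de_gene_ids <- results$de_genes$feature_id[results$de_genes$is_de]
    deptg_ids <- unique(edges$gene_id[edges$gene_id %in% de_gene_ids])
    enr <- do.call(rbind, lapply(names(sets), function(nm) {
      gs <- intersect(sets[[nm]], coding_ids)
      fe <- fisher_enrichment(deptg_ids, gs, coding_ids)
      data.frame(gene_set = nm, set_size = length(gs), overlap = fe$overlap,
                 odds_ratio = fe$odds_ratio, p_value = fe$p_value,
                 stringsAsFactors = FALSE)
    }))
    enr$padj <- bh_adjust(enr$p_value)
    results$enrichment <- enr
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## summary report ------------------------------------------------------
  rep_lines <- c(
    "lincRNA pipeline summary",
    "========================",
    sprintf("candidates:            %d", nrow(results$candidates$transcripts)),
    sprintf("retained lincRNAs:     %d (known %d / novel %d)",
            length(linc_ids), length(known_ids), length(novel_ids)),
    sprintf("DE lincRNAs:           %d (up %d / down %d)",
            sum(results$de_lincs$is_de),
            sum(results$de_lincs$direction == "up"),
            sum(results$de_lincs$direction == "down")),
    sprintf("DE coding genes:       %d (up %d / down %d)",
            sum(results$de_genes$is_de),
            sum(results$de_genes$direction == "up"),
            sum(results$de_genes$direction == "down")),
    if (run_qtl) sprintf("QTL overlaps:          %d (fat %d, IMF %d)",
                         results$qtl_summary$total_overlaps,
                         results$qtl_summary$fat_overlaps,
                         results$qtl_summary$imf_overlaps),
    sprintf("cis target pairs:      %d", nrow(results$cis_edges)),
    sprintf("trans target edges:    %d", nrow(results$trans_edges)),
    sprintf("DEPTGs (distinct):     %d",
            length(unique(edges$gene_id[edges$gene_id %in%
              results$de_genes$feature_id[results$de_genes$is_de]]))))
  writeLines(rep_lines[!vapply(rep_lines, is.null, logical(1L))],
             out("summary.txt"))

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    thresholds = unclass(pcfg),
    contrast = contrast,
    inputs = lapply(inputs, identity),
    input_md5 = as.list(tools::md5sum(unlist(inputs[file.exists(
      unlist(inputs))]))),
    outputs = list.files(out_dir, recursive = TRUE),
    stage_timings_s = timings,
    versions = list(lincpipe = as.character(utils::packageVersion("lincpipe")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  if (!is.null(bundle)) results$truth <- bundle$truth
  invisible(list(results = results, manifest = manifest))
}
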