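#' Configuration for the synthetic-data generator
#'
#' Describes a two-group bulk RNA-seq design (default: two breeds, three
#' biological replicates each) with planted ground truth at every pipeline
#' stage: true lincRNAs (known and novel), one decoy per filter stage type,
#' planted differential expression, planted cis neighbour pairs within the
#' cis window, planted trans pairs with exact sample correlations, and QTL
#' intervals placed over the DE lincRNAs.
#'
#' @param rng_seed integer seed; mandatory (there is no wall-clock default).
#' @param n_coding_genes number of protein-coding genes (one transcript
#'   each) in the reference annotation.
#' @param n_lincs_known,n_lincs_novel numbers of true lincRNAs that are
#'   present in / absent from the lincRNA database.
#' @param n_decoys_per_stage decoys failing exactly each of the six filter
#'   stages.
#' @param samples_per_group replicates per group.
#' @param group_labels labels of the two groups.
#' @param chrom_lengths named integer vector of chromosome lengths (nt).
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (`size = 1/dispersion`).
#' @param coding_mu_log_mean,coding_mu_log_sd,linc_mu_log_mean,linc_mu_log_sd
#'   log-normal parameters of baseline count means for coding genes and
#'   lincRNAs.
#' @param de_log2fc magnitude of planted log2 fold changes.
#' @param n_de_coding number of coding genes with planted DE (includes the
#'   trans targets designated as DEPTGs).
#' @param n_cis_lincs number of DE lincRNAs planted next to a coding gene
#'   (each within the cis window); at most `length(cis_r)`.
#' @param cis_r exact sample correlations planted for the cis pairs.
#' @param n_trans_lincs number of DE lincRNAs with planted trans targets.
#' @param n_trans_targets_per_linc planted trans targets per trans lincRNA.
#' @param trans_r magnitude of the exact sample correlation planted for
#'   trans pairs (kept well above the 0.95 cutoff so recovery at n = 6 is
#'   not borderline).
#' @param n_qtls_per_de_linc QTL intervals planted over each DE lincRNA.
#' @param n_background_qtls QTL intervals placed away from every lincRNA.
#' @param frac_imf_qtl,frac_fat_qtl expected fractions of planted QTLs with
#'   an IMF-content trait and with another fat-deposition trait.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(rng_seed,
                             n_coding_genes = 120L,
                             n_lincs_known = 18L,
                             n_lincs_novel = 12L,
                             n_decoys_per_stage = 2L,
                             samples_per_group = 3L,
                             group_labels = c("Wei", "Yorkshire"),
                             chrom_lengths = stats::setNames(
                               rep(3e7, 5), paste0("chr", 1:5)),
                             nb_dispersion = 0.05,
                             coding_mu_log_mean = log(150),
                             coding_mu_log_sd = 0.6,
                             linc_mu_log_mean = log(40),
                             linc_mu_log_sd = 0.5,
                             de_log2fc = 3,
                             n_de_coding = 20L,
                             n_cis_lincs = 3L,
                             cis_r = c(0.96, 0.92, -0.9),
                             n_trans_lincs = 3L,
                             n_trans_targets_per_linc = 5L,
                             trans_r = 0.99,
                             n_qtls_per_de_linc = 3L,
                             n_background_qtls = 20L,
                             frac_imf_qtl = 0.2,
                             frac_fat_qtl = 0.35) {
  if (missing(rng_seed)) stop("generator_config: rng_seed is mandatory")
  cfg <- list(rng_seed = as.integer(rng_seed),
              n_coding_genes = as.integer(n_coding_genes),
              n_lincs_known = as.integer(n_lincs_known),
              n_lincs_novel = as.integer(n_lincs_novel),
              n_decoys_per_stage = as.integer(n_decoys_per_stage),
              samples_per_group = as.integer(samples_per_group),
              group_labels = group_labels,
              chrom_lengths = chrom_lengths,
              nb_dispersion = nb_dispersion,
              coding_mu_log_mean = coding_mu_log_mean,
              coding_mu_log_sd = coding_mu_log_sd,
              linc_mu_log_mean = linc_mu_log_mean,
              linc_mu_log_sd = linc_mu_log_sd,
              de_log2fc = de_log2fc,
              n_de_coding = as.integer(n_de_coding),
              n_cis_lincs = as.integer(n_cis_lincs),
              cis_r = cis_r,
              n_trans_lincs = as.integer(n_trans_lincs),
              n_trans_targets_per_linc = as.integer(n_trans_targets_per_linc),
              trans_r = trans_r,
              n_qtls_per_de_linc = as.integer(n_qtls_per_de_linc),
              n_background_qtls = as.integer(n_background_qtls),
              frac_imf_qtl = frac_imf_qtl,
              frac_fat_qtl = frac_fat_qtl)
  counts <- cfg[grep("^n_", names(cfg))]
  if (any(unlist(counts) < 0L)) stop("generator_config: counts must be >= 0")
  if (cfg$samples_per_group < 2L) {
    stop("generator_config: samples_per_group must be >= 2")
  }
  n_true <- cfg$n_lincs_known + cfg$n_lincs_novel
  if (cfg$n_cis_lincs + cfg$n_trans_lincs > n_true) {
    stop("generator_config: more planted DE lincRNAs than true lincRNAs")
  }
  if (cfg$n_cis_lincs > length(cfg$cis_r)) {
    stop("generator_config: cis_r must supply one correlation per cis lincRNA")
  }
  if (cfg$n_cis_lincs > length(cfg$chrom_lengths)) {
    stop("generator_config: need one chromosome per cis lincRNA")
  }
  nbasis <- 2L * cfg$samples_per_group - 1L
  if (cfg$n_trans_lincs + 2L > nbasis) {
    stop("generator_config: too many trans lincRNAs for the sample size ",
         "(need n_trans_lincs + 2 <= 2*samples_per_group - 1)")
  }
  if (abs(cfg$trans_r) > 1 || any(abs(cfg$cis_r) > 1)) {
    stop("generator_config: correlations must lie in [-1, 1]")
  }
  structure(cfg, class = "generator_config")
}

#' Construct a pair of vectors with an exact sample correlation
#'
#' Draws two independent Gaussian vectors, orthogonalizes the second
#' against the first and recombines them so that the *sample* Pearson
#' correlation equals `r_target` exactly (not merely in expectation). With
#' `|r_target| = 1` the second vector is an affine image of the first.
#'
#' @param r_target target correlation in `[-1, 1]`.
#' @param n vector length (>= 3).
#' @param seed optional integer seed.
#' @return list with numeric vectors `x` and `y`.
#' @export
#' @examples
#' p <- generate_correlated_pair(0.97, 6, seed = 1)
#' cor(p$x, p$y)  # 0.97 exactly (up to floating point)
generate_correlated_pair <- function(r_target, n, seed = NULL) {
  if (n < 3L) stop("generate_correlated_pair: need n >= 3")
  if (abs(r_target) > 1) stop("generate_correlated_pair: |r_target| <= 1")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    x <- stats::rnorm(n)
    z <- stats::rnorm(n)
    xs <- (x - mean(x)) / stats::sd(x)
    zr <- z - mean(z) - xs * sum((z - mean(z)) * xs) / sum(xs * xs) * 1
    if (stats::sd(zr) > 1e-12 && stats::sd(x) > 1e-12) {
      zs <- (zr - mean(zr)) / stats::sd(zr)
      y <- r_target * xs + sqrt(1 - r_target^2) * zs
      return(list(x = x, y = y))
    }
  }
}

# orthonormal basis of the centered subspace of R^n, first direction equal
# to the (balanced) group contrast; columns are exactly orthogonal to 1
.centered_basis <- function(n1, n2) {
  n <- n1 + n2
  raw <- cbind(rep(1, n), c(rep(1, n1), rep(-1, n2)), diag(n))
  q <- qr.Q(qr(raw))[, seq_len(n), drop = FALSE]
  b <- q[, -1L, drop = FALSE]
  # fix signs deterministically: first nonzero entry of each column positive
  for (j in seq_len(ncol(b))) {
    piv <- which(abs(b[, j]) > 1e-9)[1L]
    if (b[piv, j] < 0) b[, j] <- -b[, j]
  }
  b
}

# exon ladder for one transcript starting at `start`
.make_exons <- function(start, n_exons, exon_lens, intron_lens) {
  s <- integer(n_exons); e <- integer(n_exons)
  pos <- as.integer(start)
  for (i in seq_len(n_exons)) {
    s[i] <- pos
    e[i] <- pos + exon_lens[i] - 1L
    pos <- e[i] + (if (i < n_exons) intron_lens[i] else 0L) + 1L
  }
  list(start = s, end = e, span_end = e[n_exons])
}

.trait_pools <- list(
  imf = "Intramuscular fat content",
  fat = c("Average backfat thickness", "Backfat at last rib",
          "Leaf fat weight", "Backfat at tenth rib"),
  non = c("Teat number", "Loin muscle area", "Average daily gain",
          "Body length")
)

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Produces every input the pipeline consumes — reference annotation GTF,
#' lincRNA database GTF, candidate transcript GTF, evidence table, count
#' and FPKM matrices with a sample-group map, and a QTL BED file — plus a
#' machine-readable truth object. All randomness is governed by
#' `config$rng_seed`; identical configurations yield byte-identical files.
#'
#' Planted structure:
#' * true lincRNAs are intergenic, multi-exonic, >= 200 nt, non-coding on
#'   both strands, homology-free and expressed above the FPKM floor;
#' * each filter stage gets decoys failing exactly that stage;
#' * known lincRNAs reappear in the database GTF with jittered exon
#'   boundaries (overlap fraction > 0.5); novel ones are absent;
#' * DE lincRNAs (the cis- and trans-planted ones) and a subset of coding
#'   genes carry planted fold changes in the count matrix;
#' * the FPKM matrix is built from an orthonormal centered basis so every
#'   planted lincRNA-gene sample correlation is *exact*, and every
#'   unplanted pair is structurally bounded away from the trans threshold;
#' * QTL intervals are placed over each DE lincRNA (plus background
#'   intervals overlapping no lincRNA), with trait names drawn from IMF,
#'   other-fat and non-fat pools.
#'
#' @param config a [generator_config()].
#' @param dir output directory for the file bundle (created if needed);
#'   `NULL` skips file output and returns in-memory objects only.
#' @return list of class `synthetic_bundle`: annotation sets (`reference`,
#'   `linc_db`, `candidates`), `evidence`, `counts`, `fpkm`, `qtls`,
#'   `truth` (see below) and `paths`. `truth` carries `linc_ids_known`,
#'   `linc_ids_novel`, `decoys` (stage -> ids), `de_linc_ids`,
#'   `de_feature_log2fc`, `cis_pairs`, `trans_pairs`, `qtl_hits`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$rng_seed)

  chroms <- names(cfg$chrom_lengths)
  nc <- length(chroms)
  n1 <- cfg$samples_per_group
  n <- 2L * n1
  samples <- c(paste0(cfg$group_labels[1L], "_", seq_len(n1)),
               paste0(cfg$group_labels[2L], "_", seq_len(n1)))
  groups <- stats::setNames(rep(cfg$group_labels, each = n1), samples)

  ## ---- coding genes -------------------------------------------------
  gene_slot_pitch <- 250000L
  gene_region_start <- 1000000L
  G <- cfg$n_coding_genes
  gene_rows <- vector("list", G)
  gene_meta <- data.frame(gene_id = character(G), chrom = character(G),
                          start = integer(G), end = integer(G),
                          stringsAsFactors = FALSE)
  for (i in seq_len(G)) {
    ci <- ((i - 1L) %% nc) + 1L
    slot <- ((i - 1L) %/% nc)
    start <- gene_region_start + slot * gene_slot_pitch
    n_ex <- sample(3:8, 1L)
    ex <- .make_exons(start, n_ex, sample(100:400, n_ex, replace = TRUE),
                      sample(500:3000, n_ex - 1L, replace = TRUE))
    if (ex$span_end > cfg$chrom_lengths[ci]) {
      stop("generate_dataset: chromosome '", chroms[ci],
           "' too short for ", G, " coding genes")
    }
    gid <- sprintf("PCG%04d", i)
    gene_rows[[i]] <- data.frame(
      transcript_id = paste0(gid, ".1"), gene_id = gid, chrom = chroms[ci],
      start = ex$start, end = ex$end, strand = if (i %% 2L) "+" else "-",
      stringsAsFactors = FALSE)
    gene_meta[i, ] <- list(gid, chroms[ci], start, ex$span_end)
  }
  ref_exons <- do.call(rbind, gene_rows)
  reference <- annotation_set(
    ref_exons, biotypes = stats::setNames(rep("protein_coding", G),
                                          paste0(gene_meta$gene_id, ".1")))

  ## ---- lincRNAs and decoys ------------------------------------------
  n_true <- cfg$n_lincs_known + cfg$n_lincs_novel
  n_cis <- cfg$n_cis_lincs
  n_trans <- cfg$n_trans_lincs
  stage_names <- c("intergenic", "structure", "cpc", "domain", "protein_db",
                   "expression")
  n_decoys <- cfg$n_decoys_per_stage * length(stage_names)

  linc_region_start <- 12000000L
  linc_slot_pitch <- 300000L
  max_linc_slots <- (min(cfg$chrom_lengths) - 1e6 - linc_region_start) %/%
    linc_slot_pitch
  slots_needed <- ceiling((n_true - n_cis + n_decoys + 6L) / nc)
  if (slots_needed > max_linc_slots) {
    stop("generate_dataset: chromosomes too short for the requested ",
         "number of lincRNAs and decoys")
  }

  mk_id <- local({
    k <- 0L
    function() {
      k <<- k + 1L
      sprintf("MSTRG.%d", k)
    }
  })
  slot_i <- 0L
  next_slot <- function() {
    slot_i <<- slot_i + 1L
    ci <- ((slot_i - 1L) %% nc) + 1L
    list(chrom = chroms[ci],
         start = linc_region_start +
           ((slot_i - 1L) %/% nc) * linc_slot_pitch)
  }
  linc_exons_at <- function(start, short = FALSE, mono = FALSE) {
    if (mono) {
      n_ex <- 1L
      lens <- sample(300:600, 1L)
      intr <- integer(0L)
    } else if (short) {
      n_ex <- 2L
      lens <- c(90L, 90L)  # total 180 < 200
      intr <- sample(200:800, 1L)
    } else {
      n_ex <- sample(2:4, 1L)
      lens <- sample(150:600, n_ex, replace = TRUE)
      intr <- sample(200:800, max(0L, n_ex - 1L), replace = TRUE)
    }
    .make_exons(start, n_ex, lens, intr)
  }
  add_tx <- function(pool, id, chrom, ex, strand) {
    rbind(pool, data.frame(transcript_id = id, gene_id = id, chrom = chrom,
                           start = ex$start, end = ex$end, strand = strand,
                           stringsAsFactors = FALSE))
  }

  cand_exons <- NULL
  true_ids <- character(n_true)
  linc_chrom <- character(n_true)
  linc_span <- matrix(0L, n_true, 2L)

  # cis lincRNAs sit next to partner genes on distinct chromosomes
  cis_pairs <- data.frame(lincrna_id = character(0L), gene_id = character(0L),
                          gap_bp = integer(0L), target_r = numeric(0L),
                          stringsAsFactors = FALSE)
  for (i in seq_len(n_cis)) {
    partner <- gene_meta[i, ]  # genes 1..n_cis lie on distinct chromosomes
    gap <- sample(5000:60000, 1L)
    start <- partner$end + gap + 1L
    ex <- linc_exons_at(start)
    id <- mk_id()
    cand_exons <- add_tx(cand_exons, id, partner$chrom, ex,
                         sample(c("+", "-"), 1L))
    true_ids[i] <- id
    linc_chrom[i] <- partner$chrom
    linc_span[i, ] <- c(start, ex$span_end)
    cis_pairs <- rbind(cis_pairs, data.frame(
      lincrna_id = id, gene_id = partner$gene_id, gap_bp = gap,
      target_r = cfg$cis_r[i], stringsAsFactors = FALSE))
  }
  # remaining true lincRNAs in the intergenic region
  for (i in seq.int(n_cis + 1L, length.out = n_true - n_cis)) {
    sl <- next_slot()
    ex <- linc_exons_at(sl$start)
    id <- mk_id()
    cand_exons <- add_tx(cand_exons, id, sl$chrom, ex, sample(c("+", "-"), 1L))
    true_ids[i] <- id
    linc_chrom[i] <- sl$chrom
    linc_span[i, ] <- c(sl$start, ex$span_end)
  }
  known_ids <- true_ids[seq_len(cfg$n_lincs_known)]
  novel_ids <- setdiff(true_ids, known_ids)
  trans_linc_ids <- true_ids[seq.int(n_cis + 1L, length.out = n_trans)]
  de_linc_ids <- c(true_ids[seq_len(n_cis)], trans_linc_ids)

  # decoys, one flavour per stage
  decoys <- stats::setNames(vector("list", length(stage_names)), stage_names)
  for (st in stage_names) {
    ids <- character(cfg$n_decoys_per_stage)
    for (k in seq_len(cfg$n_decoys_per_stage)) {
      id <- mk_id()
      if (st == "intergenic") {
        host <- gene_meta[sample(seq_len(G), 1L), ]
        ex <- linc_exons_at(host$start + 100L)
        cand_exons <- add_tx(cand_exons, id, host$chrom, ex, "+")
      } else {
        sl <- next_slot()
        ex <- linc_exons_at(sl$start, short = (st == "structure" && k %% 2L == 0L),
                            mono = (st == "structure" && k %% 2L == 1L))
        cand_exons <- add_tx(cand_exons, id, sl$chrom, ex,
                             sample(c("+", "-"), 1L))
      }
      ids[k] <- id
    }
    decoys[[st]] <- ids
  }
  if (is.null(cand_exons)) {
    cand_exons <- data.frame(transcript_id = character(0L),
                             gene_id = character(0L), chrom = character(0L),
                             start = integer(0L), end = integer(0L),
                             strand = character(0L), stringsAsFactors = FALSE)
  }
  cand_ids <- unique(cand_exons$transcript_id)
  candidates <- annotation_set(cand_exons)

  ## ---- lincRNA database (known lincs, jittered) ---------------------
  db_rows <- NULL
  for (i in seq_along(known_ids)) {
    ex <- candidates$exons[candidates$exons$transcript_id == known_ids[i], ]
    lens <- ex$end - ex$start + 1L
    jit <- function(l) as.integer(floor(stats::runif(length(l), 0, 0.15) * l))
    s <- ex$start + jit(lens)
    e <- ex$end - jit(lens)
    db_id <- sprintf("ALDB.%d", i)
    db_rows <- rbind(db_rows, data.frame(
      transcript_id = db_id, gene_id = db_id, chrom = ex$chrom,
      start = s, end = pmax(e, s), strand = ex$strand,
      stringsAsFactors = FALSE))
  }
  # a few database lincRNAs with no counterpart among the candidates
  for (i in seq_len(3L)) {
    sl <- next_slot()
    ex <- linc_exons_at(sl$start)
    db_id <- sprintf("ALDB.%d", length(known_ids) + i)
    db_rows <- rbind(db_rows, data.frame(
      transcript_id = db_id, gene_id = db_id, chrom = sl$chrom,
      start = ex$start, end = ex$end, strand = "+", stringsAsFactors = FALSE))
  }
  linc_db <- annotation_set(db_rows)

  ## ---- evidence table -----------------------------------------------
  ev <- data.frame(transcript_id = cand_ids,
                   cpc_fwd = -stats::runif(length(cand_ids), 0.3, 3),
                   cpc_rev = -stats::runif(length(cand_ids), 0.3, 3),
                   best_domain_evalue = ifelse(
                     stats::runif(length(cand_ids)) < 0.3,
                     stats::runif(length(cand_ids), 1e-4, 1), NA_real_),
                   best_hit_evalue_nr = ifelse(
                     stats::runif(length(cand_ids)) < 0.3,
                     stats::runif(length(cand_ids), 1e-4, 1), NA_real_),
                   best_hit_evalue_uniref90 = ifelse(
                     stats::runif(length(cand_ids)) < 0.3,
                     stats::runif(length(cand_ids), 1e-4, 1), NA_real_),
                   stringsAsFactors = FALSE)
  rownames(ev) <- ev$transcript_id
  ev[decoys$cpc, "cpc_fwd"] <- stats::runif(length(decoys$cpc), 0.5, 2)
  ev[decoys$domain, "best_domain_evalue"] <-
    10^-stats::runif(length(decoys$domain), 6, 9)
  ev[decoys$protein_db, "best_hit_evalue_nr"] <-
    10^-stats::runif(length(decoys$protein_db), 6, 9)
  rownames(ev) <- NULL
  evidence <- evidence_bundle(ev)

  ## ---- counts with planted DE ---------------------------------------
  feature_ids <- c(cand_ids, gene_meta$gene_id)
  mu <- c(stats::rlnorm(length(cand_ids), cfg$linc_mu_log_mean,
                        cfg$linc_mu_log_sd),
          stats::rlnorm(G, cfg$coding_mu_log_mean, cfg$coding_mu_log_sd))
  names(mu) <- feature_ids
  lfc <- stats::setNames(rep(0, length(feature_ids)), feature_ids)
  lfc[de_linc_ids] <- cfg$de_log2fc *
    rep_len(c(1, -1), length(de_linc_ids))

  # trans targets; the first few per lincRNA double as planted DE genes
  trans_pairs <- data.frame(lincrna_id = character(0L),
                            gene_id = character(0L), target_r = numeric(0L),
                            stringsAsFactors = FALSE)
  gi <- n_cis  # skip genes used as cis partners (gene_meta rows 1..n_cis)
  for (t in seq_len(n_trans)) {
    for (k in seq_len(cfg$n_trans_targets_per_linc)) {
      gi <- gi + 1L
      if (gi > G) stop("generate_dataset: not enough coding genes for the ",
                       "requested trans targets")
      sign_k <- if (k %% 4L == 0L) -1 else 1
      trans_pairs <- rbind(trans_pairs, data.frame(
        lincrna_id = trans_linc_ids[t], gene_id = gene_meta$gene_id[gi],
        target_r = sign_k * cfg$trans_r, stringsAsFactors = FALSE))
    }
  }
  de_genes_planned <- unique(c(
    utils::head(trans_pairs$gene_id, min(nrow(trans_pairs), cfg$n_de_coding)),
    utils::head(setdiff(gene_meta$gene_id,
                        c(cis_pairs$gene_id, trans_pairs$gene_id)),
                max(0L, cfg$n_de_coding - nrow(trans_pairs)))))
  de_genes_planned <- utils::head(de_genes_planned, cfg$n_de_coding)
  lfc[de_genes_planned] <- cfg$de_log2fc *
    rep_len(c(1, -1), length(de_genes_planned))

  size <- 1 / cfg$nb_dispersion
  counts_m <- matrix(0L, length(feature_ids), n,
                     dimnames = list(feature_ids, samples))
  for (s in seq_len(n)) {
    grp_sign <- if (s <= n1) 0.5 else -0.5
    mu_s <- mu * 2^(lfc * grp_sign)
    counts_m[, s] <- stats::rnbinom(length(mu_s), mu = mu_s, size = size)
  }
  counts <- expression_matrix(counts_m, "counts", groups)

  ## ---- FPKM with exact planted correlations -------------------------
  # Coordinates in an orthonormal centered basis; basis direction 1 is the
  # group contrast. Trans lincRNAs get single basis directions, cis
  # lincRNAs unit vectors in the plane of the last two directions, planted
  # partners exact mixtures, and all remaining features mixtures whose
  # coordinates are bounded so that no unplanted |r| can reach the trans
  # threshold.
  B <- .centered_basis(n1, n1)
  nb <- ncol(B)  # n - 1 basis directions
  coord <- matrix(0, length(feature_ids), nb,
                  dimnames = list(feature_ids, NULL))
  rand_coord <- function() {
    v <- stats::runif(nb, 0.3, 1) * sample(c(-1, 1), nb, replace = TRUE)
    v / sqrt(sum(v^2))
  }
  for (f in feature_ids) coord[f, ] <- rand_coord()
  for (t in seq_len(n_trans)) {
    coord[trans_linc_ids[t], ] <- 0
    coord[trans_linc_ids[t], t] <- 1
  }
  cis_dims <- c(nb - 1L, nb)
  if (n_cis > 0L) {
    theta <- (15 + 45 * (seq_len(n_cis) - 1L)) * pi / 180
    for (i in seq_len(n_cis)) {
      coord[cis_pairs$lincrna_id[i], ] <- 0
      coord[cis_pairs$lincrna_id[i], cis_dims] <- c(cos(theta[i]),
                                                    sin(theta[i]))
    }
    w <- rep(0, nb)  # residual direction for cis partners: trans dims
    w[seq_len(max(1L, n_trans))] <- 1
    w <- w / sqrt(sum(w^2))
    for (i in seq_len(n_cis)) {
      r <- cfg$cis_r[i]
      coord[cis_pairs$gene_id[i], ] <-
        r * coord[cis_pairs$lincrna_id[i], ] + sqrt(1 - r^2) * w
    }
  }
  if (nrow(trans_pairs) > 0L) {
    u <- rep(0, nb)  # residual direction for trans targets: cis plane
    u[cis_dims] <- 1 / sqrt(2)
    for (i in seq_len(nrow(trans_pairs))) {
      t_idx <- match(trans_pairs$lincrna_id[i], trans_linc_ids)
      e_t <- rep(0, nb); e_t[t_idx] <- 1
      r <- trans_pairs$target_r[i]
      coord[trans_pairs$gene_id[i], ] <- r * e_t + sqrt(1 - r^2) * u
    }
  }
  z <- coord %*% t(B)  # unit-norm centered profiles, one per feature
  base_fpkm <- stats::setNames(
    c(stats::runif(length(cand_ids), 1, 5), stats::runif(G, 5, 50)),
    feature_ids)
  fpkm_m <- base_fpkm * (1 + 0.4 * z)
  # expression decoys: below the floor in every sample, non-constant
  for (id in decoys$expression) {
    fpkm_m[id, ] <- 0.25 * (1 + 0.4 * z[id, ])
  }
  dimnames(fpkm_m) <- list(feature_ids, samples)
  fpkm <- expression_matrix(fpkm_m, "FPKM", groups)

  ## ---- QTLs ----------------------------------------------------------
  draw_trait <- function() {
    u <- stats::runif(1)
    if (u < cfg$frac_imf_qtl) {
      c(sample(.trait_pools$imf, 1L), "IMF")
    } else if (u < cfg$frac_imf_qtl + cfg$frac_fat_qtl) {
      c(sample(.trait_pools$fat, 1L), "fat_other")
    } else {
      c(sample(.trait_pools$non, 1L), "non_fat")
    }
  }
  qtl_rows <- NULL
  qid <- 0L
  de_idx <- match(de_linc_ids, true_ids)
  for (d in seq_along(de_linc_ids)) {
    i <- de_idx[d]
    for (k in seq_len(cfg$n_qtls_per_de_linc)) {
      qid <- qid + 1L
      s <- max(1L, linc_span[i, 1L] - sample(200000:1000000, 1L))
      e <- min(cfg$chrom_lengths[[linc_chrom[i]]],
               linc_span[i, 2L] + sample(200000:2000000, 1L))
      tr <- draw_trait()
      qtl_rows <- rbind(qtl_rows, data.frame(
        qtl_id = sprintf("QTL_%03d", qid), chrom = linc_chrom[i],
        start = as.integer(s), end = as.integer(e), trait_name = tr[1L],
        trait_class = tr[2L], stringsAsFactors = FALSE))
    }
  }
  bg_region_start <- 22000000L
  if (cfg$n_background_qtls > 0L &&
      min(cfg$chrom_lengths) < bg_region_start + 7e6) {
    stop("generate_dataset: chromosomes too short for background QTLs")
  }
  for (k in seq_len(cfg$n_background_qtls)) {
    qid <- qid + 1L
    ci <- ((k - 1L) %% nc) + 1L
    s <- as.integer(round(stats::runif(1, bg_region_start, 28000000)))
    e <- s + as.integer(round(stats::runif(1, 100000, 1000000)))
    tr <- draw_trait()
    qtl_rows <- rbind(qtl_rows, data.frame(
      qtl_id = sprintf("QTL_%03d", qid), chrom = chroms[ci],
      start = s, end = e, trait_name = tr[1L], trait_class = tr[2L],
      stringsAsFactors = FALSE))
  }
  qtls <- structure(qtl_rows, class = c("qtl_set", "data.frame"))

  # planted QTL truth by direct arithmetic over DE lincRNA spans
  hit_rows <- NULL
  for (d in seq_along(de_linc_ids)) {
    i <- de_idx[d]
    ov <- qtls$chrom == linc_chrom[i] & qtls$start <= linc_span[i, 2L] &
      linc_span[i, 1L] <= qtls$end
    if (any(ov)) {
      hit_rows <- rbind(hit_rows, data.frame(
        lincrna_id = de_linc_ids[d], qtl_id = qtls$qtl_id[ov],
        trait_class = qtls$trait_class[ov], stringsAsFactors = FALSE))
    }
  }
  qtl_hits <- if (is.null(hit_rows)) {
    data.frame(lincrna_id = character(0L), qtl_id = character(0L),
               trait_class = character(0L), stringsAsFactors = FALSE)
  } else hit_rows[order(hit_rows$lincrna_id, hit_rows$qtl_id), ,
                  drop = FALSE]
  rownames(qtl_hits) <- NULL

  truth <- list(linc_ids_known = known_ids, linc_ids_novel = novel_ids,
                decoys = decoys, de_linc_ids = de_linc_ids,
                de_feature_log2fc = lfc[lfc != 0],
                cis_pairs = cis_pairs, trans_pairs = trans_pairs,
                qtl_hits = qtl_hits)

  ## ---- file bundle ---------------------------------------------------
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    bt <- stats::setNames(rep("candidate", length(cand_ids)), cand_ids)
    paths <- list(
      reference_gtf = file.path(dir, "reference.gtf"),
      lincdb_gtf = file.path(dir, "lincdb.gtf"),
      candidate_gtf = file.path(dir, "candidates.gtf"),
      evidence_tsv = file.path(dir, "evidence.tsv"),
      counts_tsv = file.path(dir, "counts.tsv"),
      fpkm_tsv = file.path(dir, "fpkm.tsv"),
      groups_tsv = file.path(dir, "groups.tsv"),
      qtl_bed = file.path(dir, "qtl.bed"),
      truth_json = file.path(dir, "truth.json"),
      manifest_json = file.path(dir, "manifest.json"))
    write_gtf(reference, paths$reference_gtf)
    write_gtf(linc_db, paths$lincdb_gtf)
    write_gtf(candidates, paths$candidate_gtf)
    write_evidence_table(evidence, paths$evidence_tsv)
    write_expression_matrix(counts, paths$counts_tsv)
    write_expression_matrix(fpkm, paths$fpkm_tsv)
    utils::write.table(data.frame(sample = samples, group = unname(groups)),
                       paths$groups_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_qtl_bed(qtls, paths$qtl_bed)
    jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest <- list(
      seed = cfg$rng_seed,
      files = lapply(paths[setdiff(names(paths), "manifest_json")],
                     function(p) basename(p)),
      roles = list(
        reference_gtf = "reference annotation (protein-coding genes)",
        lincdb_gtf = "lincRNA database (known lincRNAs, jittered)",
        candidate_gtf = "candidate merged-transcriptome transcripts",
        evidence_tsv = "coding-potential and homology evidence",
        counts_tsv = "simulated fragment counts",
        fpkm_tsv = "FPKM matrix carrying the planted correlations",
        groups_tsv = "sample-to-group map",
        qtl_bed = "QTL intervals (BED, 0-based half-open)",
        truth_json = "planted ground truth"))
    jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  structure(list(reference = reference, linc_db = linc_db,
                 candidates = candidates, evidence = evidence,
                 counts = counts, fpkm = fpkm, qtls = qtls, truth = truth,
                 paths = paths, config = cfg),
            class = "synthetic_bundle")
}
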