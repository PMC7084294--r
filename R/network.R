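#' Export a signed lincRNA-target network
#'
#' Writes the edge set in SIF format (`lincRNA  up|down  gene`, with the
#' relationship taken from the correlation sign) plus a tab-delimited edge
#' attribute table (`mode`, `r`, `fdr`, `sign`) and a node table with node
#' type and, when DE results are supplied, the DE direction. Duplicate
#' edges (same lincRNA, gene and mode) are removed with a warning. The
#' exported edge table re-read with [utils::read.delim()] reproduces the
#' edge set exactly.
#'
#' @param edges a `target_edges` data.frame.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"network"`).
#' @param de_lincs,de_genes optional `de_result` tables used to annotate
#'   node DE direction.
#' @return Invisibly, a named list of the written file paths (`sif`,
#'   `edges`, `nodes`).
#' @export
export_network <- function(edges, dir, prefix = "network",
                           de_lincs = NULL, de_genes = NULL) {
  if (nrow(edges) == 0L) stop("export_network: empty edge set")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  key <- paste(edges$lincrna_id, edges$gene_id, edges$mode, sep = "\r")
  if (anyDuplicated(key)) {
    warning("export_network: removing ", sum(duplicated(key)),
            " duplicate edge(s)")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rel <- ifelse(edges$sign == "positive", "up", "down")
  sif_path <- file.path(dir, paste0(prefix, ".sif"))
  writeLines(sprintf("%s\t%s\t%s", edges$lincrna_id, rel, edges$gene_id),
             sif_path)

  edge_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(
    data.frame(lincrna_id = edges$lincrna_id, gene_id = edges$gene_id,
               mode = edges$mode, r = edges$r, fdr = edges$fdr,
               sign = edges$sign, stringsAsFactors = FALSE),
    edge_path, sep = "\t", quote = FALSE, row.names = FALSE)

  de_dir <- function(ids, de) {
    if (is.null(de)) return(rep(NA_character_, length(ids)))
    de$direction[match(ids, de$feature_id)]
  }
  lincs <- unique(edges$lincrna_id)
  genes <- unique(edges$gene_id)
  nodes <- data.frame(
    node = c(lincs, genes),
    type = c(rep("lincRNA", length(lincs)), rep("gene", length(genes))),
    de_direction = c(de_dir(lincs, de_lincs), de_dir(genes, de_genes)),
    stringsAsFactors = FALSE)
  node_path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(list(sif = sif_path, edges = edge_path, nodes = node_path))
}
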