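#' Feature-by-sample expression matrix with group labels
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). All values must be
#'   non-negative; for `kind = "counts"` they must be integers.
#' @param kind `"counts"` or `"FPKM"`.
#' @param groups named character vector mapping every sample id to a group
#'   label.
#' @return An object of class `expression_matrix`.
#' @export
#' @examples
#' m <- matrix(0, 2, 6, dimnames = list(c("f1", "f2"), paste0("s", 1:6)))
#' g <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
#' expression_matrix(m, "counts", g)
expression_matrix <- function(values, kind = c("counts", "FPKM"), groups) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression_matrix: values must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("expression_matrix: duplicate feature ids")
  }
  if (anyDuplicated(colnames(values))) {
    stop("expression_matrix: duplicate sample ids")
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("expression_matrix: values must be numeric and non-missing")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("expression_matrix: negative value at feature '",
         rownames(values)[bad[1L]], "', sample '", colnames(values)[bad[2L]], "'")
  }
  if (kind == "counts" && any(values != round(values))) {
    bad <- which(values != round(values), arr.ind = TRUE)[1L, ]
    stop("expression_matrix: non-integer count at feature '",
         rownames(values)[bad[1L]], "', sample '", colnames(values)[bad[2L]], "'")
  }
  missing_grp <- setdiff(colnames(values), names(groups))
  if (length(missing_grp)) {
    stop("expression_matrix: sample(s) missing from group map: ",
         paste(missing_grp, collapse = ", "))
  }
  groups <- as.character(groups)[match(colnames(values), names(groups))]
  names(groups) <- colnames(values)
  structure(list(values = values, kind = kind, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$kind))
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix from a delimited file
#'
#' Expects a header row of sample ids and feature ids in the first column.
#'
#' @param path TSV file path.
#' @param kind `"counts"` or `"FPKM"`.
#' @param group_map named character vector mapping sample ids to groups, or
#'   path to a two-column TSV (`sample`, `group`).
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, kind = c("counts", "FPKM"),
                                   group_map) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("read_expression_matrix: file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("read_expression_matrix: need >=1 sample column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (is.character(group_map) && length(group_map) == 1L &&
      file.exists(group_map)) {
    gm <- utils::read.delim(group_map, stringsAsFactors = FALSE)
    group_map <- stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
  }
  expression_matrix(m, kind, group_map)
}

#' Write an expression matrix as TSV
#'
#' @param expr an `expression_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to FPKM
#'
#' FPKM of feature f in sample s is
#' `counts[f, s] * 1e9 / (total_counts[s] * length[f])`: fragments per
#' kilobase of transcript per million mapped fragments.
#'
#' @param counts an `expression_matrix` of kind `"counts"`.
#' @param lengths named numeric vector of transcript lengths (nt) covering
#'   every feature; all lengths must be positive.
#' @return An `expression_matrix` of kind `"FPKM"`.
#' @export
#' @examples
#' m <- matrix(c(10, 999990), 2, 1,
#'             dimnames = list(c("a", "b"), "s1"))
#' cm <- expression_matrix(m, "counts", c(s1 = "A"))
#' fpkm_from_counts(cm, c(a = 1000, b = 5000))$values["a", "s1"]  # 10
fpkm_from_counts <- function(counts, lengths) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$kind != "counts") stop("fpkm_from_counts: input must be counts")
  miss <- setdiff(rownames(counts$values), names(lengths))
  if (length(miss)) {
    stop("fpkm_from_counts: missing length for feature(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  len <- as.numeric(lengths[rownames(counts$values)])
  if (any(len <= 0)) stop("fpkm_from_counts: non-positive length")
  lib <- colSums(counts$values)
  if (any(lib <= 0)) {
    stop("fpkm_from_counts: zero library size for sample '",
         colnames(counts$values)[which(lib <= 0)[1L]], "'")
  }
  fpkm <- sweep(counts$values, 2L, lib, "/")
  fpkm <- sweep(fpkm, 1L, len, "/") * 1e9
  expression_matrix(fpkm, "FPKM",
                    stats::setNames(counts$groups, colnames(counts$values)))
}
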