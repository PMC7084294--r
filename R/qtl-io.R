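#' Read QTL intervals from a BED-like file
#'
#' Expects at least four tab-separated columns: chromosome, start (0-based),
#' end (half-open), trait name; an optional fifth column gives the QTL id
#' (otherwise ids `QTL_1`, `QTL_2`, ... are assigned in file order).
#' Coordinates are converted to the package's internal 1-based inclusive
#' convention (`start + 1`, `end`). Each record gets a deterministic trait
#' class: `IMF` if any of `config$imf_keywords` is a substring of the
#' lower-cased trait name, else `fat_other` if any of `config$fat_keywords`
#' matches, else `non_fat`.
#'
#' @param path BED-like file path.
#' @param config a [pipeline_config()] supplying the keyword lists.
#' @return data.frame of class `qtl_set` with columns `qtl_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), `trait_name`, `trait_class`.
#' @export
read_qtl_bed <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("read_qtl_bed: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(structure(data.frame(qtl_id = character(), chrom = character(),
                                start = integer(), end = integer(),
                                trait_name = character(),
                                trait_class = character(),
                                stringsAsFactors = FALSE),
                     class = c("qtl_set", "data.frame")))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("read_qtl_bed: line ", which(nf < 4L)[1L],
         " has fewer than 4 columns")
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start0 <- as.numeric(vapply(fields, `[[`, character(1L), 2L))
  end0 <- as.numeric(vapply(fields, `[[`, character(1L), 3L))
  trait <- vapply(fields, `[[`, character(1L), 4L)
  if (anyNA(start0) || anyNA(end0)) stop("read_qtl_bed: non-numeric coordinate")
  if (any(end0 <= start0)) {
    stop("read_qtl_bed: end <= start at line ", which(end0 <= start0)[1L])
  }
  if (any(!nzchar(trimws(trait)))) {
    stop("read_qtl_bed: empty trait name at line ",
         which(!nzchar(trimws(trait)))[1L])
  }
  qtl_id <- ifelse(nf >= 5L,
                   vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "",
                          character(1L)),
                   "")
  qtl_id[!nzchar(qtl_id)] <- paste0("QTL_", which(!nzchar(qtl_id)))
  out <- data.frame(qtl_id = qtl_id, chrom = chrom,
                    start = as.integer(start0 + 1), end = as.integer(end0),
                    trait_name = trait,
                    trait_class = classify_trait(trait, config),
                    stringsAsFactors = FALSE)
  structure(out, class = c("qtl_set", "data.frame"))
}

#' Classify QTL trait names by keyword
#'
#' @param trait_name character vector of trait names.
#' @param config a [pipeline_config()] with `imf_keywords`/`fat_keywords`.
#' @return character vector in `{"IMF", "fat_other", "non_fat"}`.
#' @export
classify_trait <- function(trait_name, config = pipeline_config()) {
  low <- tolower(trait_name)
  has_any <- function(x, keys) {
    Reduce(`|`, lapply(keys, function(k) grepl(k, x, fixed = TRUE)),
           accumulate = FALSE, init = rep(FALSE, length(x)))
  }
  ifelse(has_any(low, config$imf_keywords), "IMF",
         ifelse(has_any(low, config$fat_keywords), "fat_other", "non_fat"))
}

#' Write QTL records as a BED-like file
#'
#' Inverse of [read_qtl_bed()]: internal 1-based inclusive intervals are
#' converted back to 0-based half-open, so a read/write round trip
#' preserves the original BED coordinates exactly.
#'
#' @param qtls a `qtl_set` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qtl_bed <- function(qtls, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", qtls$chrom, qtls$start - 1L,
                   qtls$end, qtls$trait_name, qtls$qtl_id)
  writeLines(lines, path)
  invisible(path)
}
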