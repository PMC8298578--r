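#' Read a BED file of intervals or CpG sites
#'
#' BED is 0-based, half-open. With `cpg = TRUE`, every row must span
#' exactly two bases (`end == start + 2`) and is returned as a CpG site at
#' the C position. Positions printed in 1-based coordinates elsewhere can
#' be ingested with `one_based = TRUE`, which subtracts one at the
#' boundary (`pos_1based = pos_0based + 1`).
#'
#' @param path BED file path (3+ tab-separated columns, no header).
#' @param cpg if `TRUE`, validate and return CpG sites; otherwise return
#'   generic intervals (`chrom`, `start`, `end`, optional `name`).
#' @param one_based if `TRUE`, interpret the start column as 1-based
#'   (converted internally to 0-based).
#' @param on_array array-membership flag for returned CpG sites.
#' @return A site table ([cpg_sites()]) when `cpg = TRUE`, else a
#'   `data.frame` of intervals.
#' @export
read_bed <- function(path, cpg = FALSE, one_based = FALSE, on_array = FALSE) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    empty <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        stringsAsFactors = FALSE)
    if (cpg) return(cpg_sites(character(0), integer(0)))
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stopf("malformed BED line %d in %s: fewer than 3 columns",
          which(nf < 3)[1], path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stopf("malformed BED line %d in %s: non-integer coordinates",
                         bad[1], path)
  if (one_based) {
    start <- start - 1L
    end <- end - 1L
  }
  short <- which(end <= start)
  if (length(short)) stopf("invalid BED line %d in %s: end <= start",
                           short[1], path)
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA_character_)
  iv <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   stringsAsFactors = FALSE)
  if (!cpg) return(iv)
  wrong <- which(iv$end != iv$start + 2L)
  if (length(wrong)) stopf("BED line %d in %s: CpG rows must have end = start + 2",
                           wrong[1], path)
  # BED score column (5) carries the array-membership flag when present
  if (all(nf >= 5)) {
    on_array <- vapply(fields, function(f) f[[5]], "") == "1"
  }
  cpg_sites(iv$chrom, iv$start, on_array = on_array)
}

#' Write intervals or CpG sites to BED
#'
#' @param x a site table (columns `chrom`, `pos`) or interval table
#'   (columns `chrom`, `start`, `end`).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_bed <- function(x, path) {
  if ("pos" %in% names(x)) {
    out <- data.frame(x$chrom, x$pos, x$pos + 2L)
    if ("on_array" %in% names(x)) {
      out$name <- x$site_id
      out$score <- as.integer(x$on_array)
    }
  } else {
    out <- data.frame(x$chrom, x$start, x$end)
    if ("name" %in% names(x) && !all(is.na(x$name))) out$name <- x$name
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-CpG prediction records to TSV
#'
#' One row per CpG with a header; numeric columns survive a round trip to
#' at least six decimal places.
#'
#' @param records `data.frame` of prediction records (must contain
#'   `site_id`).
#' @param path output path.
#' @param allow_empty write a header-only file when `records` has no rows.
#' @return `path` invisibly.
#' @export
write_scores_tsv <- function(records, path, allow_empty = FALSE) {
  if (!nrow(records) && !allow_empty) {
    stopf("refusing to write empty score table (set allow_empty = TRUE)")
  }
  data.table::fwrite(records, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a prediction-record TSV written by [write_scores_tsv()]
#' @param path file path.
#' @return `data.frame` of records.
#' @export
read_scores_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

# generic TSV-with-header helpers used across the pipeline interfaces
read_tsv <- function(path) as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# matrix <-> TSV with row ids in the first column
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
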