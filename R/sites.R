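#' Construct a table of CpG sites
#'
#' A CpG site is the genomic position of the C of a CG dinucleotide on the
#' forward strand, using 0-based coordinates. Sites carry a stable
#' `site_id` of the form `"chrom:pos"` and an `on_array` flag marking
#' membership on the methylation array (the assayed subset).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based positions of the C.
#' @param on_array logical vector (recycled) flagging array membership.
#' @return A `data.frame` with columns `chrom`, `pos`, `site_id`,
#'   `on_array`, one row per site, ordered by (`chrom`, `pos`).
#' @export
cpg_sites <- function(chrom, pos, on_array = FALSE) {
  if (length(chrom) != length(pos)) stopf("chrom and pos lengths differ")
  pos <- as.integer(pos)
  if (length(pos) && any(pos < 0)) stopf("CpG positions must be >= 0")
  df <- data.frame(
    chrom = as.character(chrom), pos = pos,
    site_id = if (length(pos)) paste0(chrom, ":", pos) else character(0),
    on_array = rep_len(as.logical(on_array), length(pos)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$site_id)) stopf("duplicated site_id in CpG site set")
  df
}

#' Validate CpG sites against a genome
#'
#' Checks that the base at `pos` is C and at `pos + 1` is G (case-insensitive)
#' for every site.
#'
#' @param sites a site table from [cpg_sites()].
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return `TRUE` invisibly; errors on the first violation.
#' @export
validate_sites <- function(sites, genome) {
  for (ch in unique(sites$chrom)) {
    if (!ch %in% names(genome)) stopf("chromosome %s absent from genome", ch)
    s <- sites[sites$chrom == ch, ]
    seq <- as.character(genome[[ch]])
    dinuc <- toupper(substring(seq, s$pos + 1L, s$pos + 2L))
    bad <- which(dinuc != "CG")
    if (length(bad)) {
      stopf("site %s does not sit on a CG dinucleotide (found %s)",
            s$site_id[bad[1]], dinuc[bad[1]])
    }
  }
  invisible(TRUE)
}

#' Enumerate every CpG site in a genome
#'
#' Scans the forward strand for CG dinucleotides and reports the 0-based
#' position of each C. A CpG is its own reverse complement, so the forward
#' scan covers both strands. Soft-masked (lowercase) bases count; `N`
#' breaks a dinucleotide.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param on_array logical flag applied to all enumerated sites.
#' @return A site table as from [cpg_sites()], ordered by (chrom, pos).
#' @export
enumerate_cpgs <- function(fasta, on_array = FALSE) {
  genome <- if (is.character(fasta)) {
    Biostrings::readDNAStringSet(fasta)
  } else {
    fasta
  }
  if (length(genome) == 0) stopf("empty FASTA: no sequences to scan")
  names(genome) <- sub("\\s.*$", "", names(genome))
  hits <- Biostrings::vmatchPattern("CG", genome, fixed = TRUE)
  chroms <- character(0); poss <- integer(0)
  for (i in seq_along(genome)) {
    st <- BiocGenerics::start(hits[[i]]) - 1L  # 1-based match start -> 0-based C
    chroms <- c(chroms, rep(names(genome)[i], length(st)))
    poss <- c(poss, st)
  }
  cpg_sites(chroms, poss, on_array = on_array)
}

# parse "chrom:pos" site ids back to coordinates
parse_site_ids <- function(site_id) {
  m <- regmatches(site_id, regexpr(":[0-9]+$", site_id))
  data.frame(
    chrom = substr(site_id, 1L, nchar(site_id) - nchar(m)),
    pos = as.integer(substring(m, 2L)),
    stringsAsFactors = FALSE
  )
}
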