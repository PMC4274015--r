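#' Normalize DNA sequences
#'
#' Uppercases sequences and checks that they contain only A, C, G or T.
#' Reads containing ambiguity codes (e.g. N) are rejected: the analysis
#' pipeline works on unambiguous base calls only.
#'
#' @param x Character vector of DNA sequences.
#' @return Uppercase character vector, names preserved.
#' @export
norm_seq <- function(x) {
  if (!is.character(x)) stop("sequences must be a character vector")
  out <- toupper(x)
  bad <- grepl("[^ACGT]", out)
  if (any(bad)) {
    stop("non-ACGT character in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (any(!nzchar(out))) stop("empty sequence")
  out
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return Character vector of reverse complements (uppercase).
#' @examples
#' revcomp("AAGCAGTG")  # "CACTGCTT"
#' @export
revcomp <- function(x) {
  .revcomp_cpp(norm_seq(x))
}

# positional mismatches between two equal-length strings
mismatch_count <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("mismatch_count needs equal lengths")
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 70L)
  invisible(path)
}

#' The ancestral Oli sequence
#'
#' The 107-nt single-stranded founder hairpin. Its 3'-terminal tract is
#' reverse-complementary to a tract near the 5' end, so that the molecule can
#' fold back on itself, self-prime and extend its 3' end.
#'
#' @return Length-one named character vector.
#' @export
oli_ancestor <- function() {
  read_fasta(system.file("extdata", "oli_ancestor.fasta", package = "olisim"))
}

#' The qPCR primer pair of the Oli system
#'
#' The forward primer anneals to the extended 3' terminus (it is the reverse
#' complement of the 20-nt new 3' end created by self-primed extension); the
#' reverse primer matches the 25-nt 5'-terminal footprint of the molecule.
#' Only extended molecules carry both footprints, which is what makes
#' fold-or-hold selection work.
#'
#' The published reverse-primer sequence disagrees with the published
#' template footprint at two adjacent positions (an apparent transposition);
#' taken literally, the founder amplicon could never match it exactly, yet
#' the read filtering demands exact primer matches. The default is therefore
#' the template-consistent reading; `printed_rev = TRUE` returns the
#' published variant unchanged.
#'
#' @param printed_rev Return the published reverse-primer variant instead of
#'   the template-consistent one.
#' @return Named character vector with elements `fwd` and `rev`.
#' @export
oli_primers <- function(printed_rev = FALSE) {
  p <- read_fasta(system.file("extdata", "primers.fasta", package = "olisim"))
  names(p) <- sub("\\s.*$", "", names(p))
  c(fwd = unname(p[["fwd"]]),
    rev = unname(if (printed_rev) p[["rev_printed"]] else p[["rev"]]))
}
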