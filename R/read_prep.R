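#' A primer pair with a mismatch tolerance
#'
#' @param fwd Forward primer (binds the extended 3' terminus; the molecule's
#'   3'-terminal footprint is `revcomp(fwd)`).
#' @param rev Reverse primer (matches the molecule's 5'-terminal footprint).
#' @param max_mm Maximum mismatches tolerated per footprint when filtering
#'   reads or deciding primer binding. The default 0 reflects exact-match
#'   filtering; under the stringent annealing used in the protocol a single
#'   mismatch already impairs binding.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(fwd = oli_primers()[["fwd"]],
                        rev = oli_primers()[["rev"]],
                        max_mm = 0L) {
  structure(list(fwd = norm_seq(fwd), rev = norm_seq(rev),
                 max_mm = as.integer(max_mm)),
            class = "primer_pair")
}

# Does a top-strand sequence carry both primer footprints (5' prefix equal to
# the reverse primer, 3' suffix equal to revcomp(forward primer)) within
# max_mm mismatches each? Vectorized over seqs.
binds_both_primers <- function(seqs, primers = primer_pair(),
                               max_mm = primers$max_mm) {
  nf <- nchar(primers$fwd); nr <- nchar(primers$rev)
  foot3 <- revcomp(primers$fwd)
  n <- nchar(seqs)
  ok <- n >= max(nf, nr)
  res <- logical(length(seqs))
  for (i in which(ok)) {
    res[i] <- mismatch_count(substr(seqs[i], 1L, nr), primers$rev) <= max_mm &&
      mismatch_count(substr(seqs[i], n[i] - nf + 1L, n[i]), foot3) <= max_mm
  }
  res
}

#' Filter reads by primer footprints
#'
#' A read is kept iff, in one of its two orientations, the forward primer
#' matches the prefix and the reverse complement of the reverse primer
#' matches the suffix, each within `max_mm` mismatches. This is the only
#' quality gate of the pipeline: reads with poor base calls rarely match
#' both primers and are discarded here.
#'
#' @param reads Character vector of reads (optionally named).
#' @param primers A [primer_pair()].
#' @return The kept subset of `reads` (possibly empty), names preserved.
#' @export
filter_by_primers <- function(reads, primers = primer_pair()) {
  reads <- norm_seq(reads)
  nf <- nchar(primers$fwd); nr <- nchar(primers$rev)
  foot_rev <- revcomp(primers$rev)
  keep <- vapply(reads, function(r) {
    n <- nchar(r)
    if (n < max(nf, nr)) return(FALSE)
    for (o in c(r, revcomp(r))) {
      if (mismatch_count(substr(o, 1L, nf), primers$fwd) <= primers$max_mm &&
          mismatch_count(substr(o, n - nr + 1L, n), foot_rev) <= primers$max_mm)
        return(TRUE)
    }
    FALSE
  }, logical(1L), USE.NAMES = FALSE)
  reads[keep]
}

#' Dereplicate reads into a unique-sequence table
#'
#' Reads are collapsed by exact identity after canonicalizing orientation:
#' the canonical form of a read is the lexicographic minimum of the read and
#' its reverse complement, so a sequence and its reverse complement count as
#' the same molecule. Entries are ordered by decreasing abundance, ties by
#' sequence.
#'
#' @param reads Character vector of reads.
#' @param sample_id Optional identifier (e.g. `c(treatment, transfer)`),
#'   stored as an attribute.
#' @return A `unique_seq_table`: data frame with columns `seq` and `count`.
#' @export
collapse_unique <- function(reads, sample_id = NULL) {
  if (length(reads) == 0L) {
    out <- data.frame(seq = character(0), count = integer(0))
  } else {
    reads <- norm_seq(reads)
    canon <- pmin(reads, revcomp(reads))
    tab <- table(canon)
    out <- data.frame(seq = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$seq), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "sample_id") <- sample_id
  class(out) <- c("unique_seq_table", "data.frame")
  out
}

#' Restriction enzyme definition
#'
#' Offsets follow the `recognition(top/bottom)` convention: the top-strand
#' cut sits `cut_offset_top` bases downstream of the recognition end on the
#' recognition strand.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (top strand, 5'->3').
#' @param cut_offset_top,cut_offset_bottom Non-negative cut offsets.
#' @return Object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top,
                               cut_offset_bottom) {
  if (cut_offset_top < 0 || cut_offset_bottom < 0) stop("offsets must be >= 0")
  recognition <- norm_seq(recognition)
  structure(list(name = name, recognition = recognition,
                 recognition_rc = revcomp(recognition),
                 cut_offset_top = as.integer(cut_offset_top),
                 cut_offset_bottom = as.integer(cut_offset_bottom)),
            class = "restriction_enzyme")
}

#' The two enzymes used to cleave extended Oli 3' ends
#'
#' BsaI, recognition GGTCTC with cut offsets (1/5), and HpyAV, recognition
#' CCTTC with cut offsets (6/5). Both sites sit inside the forward-primer
#' footprint of the extended molecule, so mutations that destroy them also
#' destroy primer binding.
#'
#' @return Named list of two [restriction_enzyme()] objects.
#' @export
oli_enzymes <- function() {
  list(BsaI = restriction_enzyme("BsaI", "GGTCTC", 1L, 5L),
       HpyAV = restriction_enzyme("HpyAV", "CCTTC", 6L, 5L))
}

#' Find top-strand cut coordinates for one enzyme
#'
#' Scans both the sequence and its reverse complement for the recognition
#' motif and reports the top-strand, 0-based, between-base coordinate of the
#' cut implied by `cut_offset_top` on the recognition strand. Cuts that
#' would fall outside the molecule are dropped.
#'
#' @param seq A single DNA sequence.
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted unique integer vector of cut coordinates in `[0, nchar(seq)]`.
#' @export
find_restriction_cuts <- function(seq, enzyme) {
  seq <- norm_seq(seq)
  n <- nchar(seq)
  rec <- enzyme$recognition
  w <- nchar(rec)
  cuts <- integer(0)
  hits <- gregexpr(rec, seq, fixed = TRUE)[[1L]]
  if (hits[1L] != -1L) {
    # recognition at 1-based r..r+w-1; cut offset_top bases after its end
    cuts <- c(cuts, (hits - 1L) + w + enzyme$cut_offset_top)
  }
  hits_rc <- gregexpr(enzyme$recognition_rc, seq, fixed = TRUE)[[1L]]
  if (hits_rc[1L] != -1L) {
    # recognition on the bottom strand, running right-to-left; its top-strand
    # span starts at s, and the bottom-strand cut offset_top bases downstream
    # lies offset_top bases 5' of s on the top strand
    cuts <- c(cuts, (hits_rc - 1L) - enzyme$cut_offset_top)
  }
  cuts <- cuts[cuts >= 0L & cuts <= n]
  sort(unique(as.integer(cuts)))
}

#' Trim a sequence at restriction sites
#'
#' `three_prime` (the default, matching the experiment's purpose of cleaving
#' extended 3' ends): apply the 3'-most cut among all enzymes' cuts located
#' in the 3' half of the molecule, drop the 3' fragment, and repeat until no
#' such cut remains (digestion runs to completion, making the operation
#' idempotent).
#' `all_cuts_keep_longest`: cut at every site on either strand and keep the
#' longest fragment (5'-most on ties); this reproduces an indiscriminate
#' regex trimming, which also cuts at the bottom-strand BsaI site near the
#' 5' end present in every descendant of the founder.
#'
#' @param seq A single DNA sequence.
#' @param enzymes List of [restriction_enzyme()] objects.
#' @param mode `"three_prime"` or `"all_cuts_keep_longest"`.
#' @return The trimmed sequence (unchanged when no site cuts).
#' @export
digest_trim <- function(seq, enzymes = oli_enzymes(),
                        mode = c("three_prime", "all_cuts_keep_longest")) {
  mode <- match.arg(mode)
  seq <- norm_seq(seq)
  if (mode == "three_prime") {
    # dropping the 3' fragment can expose a remaining site whose cut now
    # lies in the (shorter) 3' half, so cut repeatedly to a fixed point;
    # digestion in the experiment likewise runs to completion
    repeat {
      n <- nchar(seq)
      cuts <- unlist(lapply(enzymes, find_restriction_cuts, seq = seq))
      cuts <- cuts[cuts > 0L & cuts < n & cuts >= n / 2]
      if (length(cuts) == 0L) return(seq)
      seq <- substr(seq, 1L, max(cuts))
    }
  }
  n <- nchar(seq)
  cuts <- sort(unique(unlist(lapply(enzymes, find_restriction_cuts, seq = seq))))
  cuts <- cuts[cuts > 0L & cuts < n]
  if (length(cuts) == 0L) return(seq)
  {
    bounds <- c(0L, cuts, n)
    lens <- diff(bounds)
    k <- which.max(lens)
    substring(seq, bounds[k] + 1L, bounds[k + 1L])
  }
}

#' Can k point mutations escape digestion while keeping primer binding?
#'
#' Exhaustively enumerates all sets of at most `k` point substitutions of the
#' extended molecule and asks whether any mutant (i) carries no remaining cut
#' site, on either strand, in its 3' half (so 3'-end digestion leaves it
#' intact) while (ii) both primer footprints retain at most
#' `max_footprint_mm` mismatches. The restriction sites were designed inside
#' the forward-primer footprint precisely so that this is impossible for
#' small k.
#'
#' @param seq_extended The extended (post self-priming) sequence.
#' @param k Maximum number of substitutions (0, 1 or 2; the search is
#'   exhaustive and larger k is refused).
#' @param primers A [primer_pair()].
#' @param enzymes List of [restriction_enzyme()] objects.
#' @param max_footprint_mm Mismatches tolerated per footprint (default 1).
#' @return `TRUE` if some mutant escapes, else `FALSE`.
#' @export
escape_possible_with_k <- function(seq_extended, k,
                                   primers = primer_pair(),
                                   enzymes = oli_enzymes(),
                                   max_footprint_mm = 1L) {
  if (k > 2L) stop("exhaustive enumeration supported for k <= 2 only")
  seq_extended <- norm_seq(seq_extended)
  n <- nchar(seq_extended)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq_extended, "", fixed = TRUE)[[1L]]

  escapes <- function(s) {
    cuts <- unlist(lapply(enzymes, find_restriction_cuts, seq = s))
    cuts <- cuts[cuts > 0L & cuts < n]
    all(cuts < n / 2) &&
      binds_both_primers(s, primers, max_mm = max_footprint_mm)
  }

  if (k >= 0L && escapes(seq_extended)) return(TRUE)
  if (k >= 1L) {
    for (i in seq_len(n)) {
      for (b in setdiff(bases, chars[i])) {
        m <- chars; m[i] <- b
        if (escapes(paste(m, collapse = ""))) return(TRUE)
      }
    }
  }
  if (k >= 2L) {
    # a double mutant can only escape if each existing 3'-half site is hit,
    # and there are two disjoint sites, so restrict the first position to
    # site-covering coordinates and scan the second exhaustively; to stay
    # fully exhaustive we instead enumerate all position pairs.
    for (i in seq_len(n - 1L)) {
      alt_i <- setdiff(bases, chars[i])
      for (j in seq.int(i + 1L, n)) {
        alt_j <- setdiff(bases, chars[j])
        for (bi in alt_i) for (bj in alt_j) {
          m <- chars; m[i] <- bi; m[j] <- bj
          if (escapes(paste(m, collapse = ""))) return(TRUE)
        }
      }
    }
  }
  FALSE
}
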