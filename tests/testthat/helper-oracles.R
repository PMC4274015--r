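# Independent oracles used to pin the package's alignment, stem-search and
# clustering operations. These are deliberately naive implementations.

random_dna <- function(n, len_range = c(10L, 30L)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"),
                 sample(len_range[1L]:len_range[2L], 1L), replace = TRUE),
          collapse = "")
  }, character(1L))
}

# plain full-matrix affine-gap local alignment score (Gotoh, written
# independently of the package's compiled kernel)
sw_oracle <- function(a, b, match = 5, mismatch = -4, open = 20, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in b direction
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# unit-cost edit distance oracle (generalized Levenshtein from base R)
nw_oracle <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# brute-force stem search: longest suffix whose reverse complement occurs
# internally, ending >= 1 base before the suffix start; 5'-most partner
stem_oracle <- function(seq, min_stem = 6L) {
  n <- nchar(seq)
  for (L in rev(seq_len((n - 1L) %/% 2L))) {
    if (L < min_stem) break
    pat <- revcomp(substr(seq, n - L + 1L, n))
    hits <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
    hits <- hits[hits > 0 & hits + L - 1L <= n - L]
    if (length(hits) > 0L) {
      return(list(length = L, partner_start = hits[1L]))
    }
  }
  NULL
}

# all-pairs single-linkage clustering oracle via union-find
single_linkage_oracle <- function(seqs, d, min_len_fraction = 0.87) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1L) {
    dm <- utils::adist(seqs)
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        li <- nchar(seqs[i]); lj <- nchar(seqs[j])
        if (min(li, lj) / max(li, lj) < min_len_fraction) next
        if (dm[i, j] <= d) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
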