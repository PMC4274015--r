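#' Clustering parameters
#'
#' @param max_mismatch Mismatch cutoff d: two sequences belong to the same
#'   cluster when connected by a chain of pairs at edit distance <= d.
#' @param prefilter_identity Nominal identity used by the candidate-pair
#'   prefilter (a reimplementation of the BLAST-based candidate search as a
#'   shared k-mer count bound). It widens the candidate search but never
#'   narrows it below what `max_mismatch` requires, preserving the superset
#'   guarantee.
#' @param min_len_fraction Pairs whose shorter/longer length ratio falls
#'   below this are never merged.
#' @return Object of class `cluster_params`.
#' @export
cluster_params <- function(max_mismatch = 3L, prefilter_identity = 0.97,
                           min_len_fraction = 0.87) {
  stopifnot(max_mismatch >= 1, max_mismatch <= 30,
            prefilter_identity > 0, prefilter_identity <= 1,
            min_len_fraction > 0, min_len_fraction <= 1)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 prefilter_identity = prefilter_identity,
                 min_len_fraction = min_len_fraction),
            class = "cluster_params")
}

#' Exact global edit distance between sequences
#'
#' Unit-cost global (Needleman-Wunsch) distance: substitutions cost 1 and
#' every gapped base costs 1. Symmetric and satisfies the triangle
#' inequality. Vectorized with recycling.
#'
#' @param a,b Character vectors of DNA sequences.
#' @return Integer vector of distances.
#' @export
nw_distance <- function(a, b) {
  .nw_distance_cpp(norm_seq(a), norm_seq(b))
}

# shared k-mer counts between one sequence's k-mer profile and a profile
# matrix; used by the candidate prefilter
shared_kmers <- function(f_row, f_mat) {
  rowSums(pmin(matrix(f_row, nrow(f_mat), length(f_row), byrow = TRUE), f_mat))
}

#' Candidate pairs for clustering
#'
#' A fast shared-k-mer prefilter over all sequence pairs with a provable
#' superset property: by the q-gram bound, two sequences of minimum length
#' Ls at edit distance <= d share at least `(Ls - k + 1) - d k` k-mers, so
#' every pair at distance <= `max_mismatch` (with an admissible length
#' ratio) is emitted. The nominal prefilter identity can only widen the
#' candidate set (distance bound `max(d, (1 - identity) * Ls)`).
#'
#' @param table A `unique_seq_table` (see [collapse_unique()]) or character
#'   vector of sequences.
#' @param params A [cluster_params()].
#' @param k k-mer size for the prefilter.
#' @return Two-column integer matrix of candidate row index pairs (i < j).
#' @export
candidate_pairs <- function(table, params = cluster_params(), k = 4L) {
  seqs <- if (is.data.frame(table)) table$seq else norm_seq(table)
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  lens <- nchar(seqs)
  f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                            width = k)
  out_i <- list(); out_j <- list()
  for (i in seq_len(n - 1L)) {
    j <- seq.int(i + 1L, n)
    ls <- pmin(lens[i], lens[j]); ll <- pmax(lens[i], lens[j])
    ok_len <- ls / ll >= params$min_len_fraction
    d_eff <- pmax(params$max_mismatch,
                  ceiling((1 - params$prefilter_identity) * ls))
    thr <- (ls - k + 1L) - d_eff * k
    need <- which(ok_len)
    if (length(need) == 0L) next
    sh <- shared_kmers(f[i, ], f[j[need], , drop = FALSE])
    hit <- need[sh >= thr[need]]
    if (length(hit) > 0L) {
      out_i[[length(out_i) + 1L]] <- rep.int(i, length(hit))
      out_j[[length(out_j) + 1L]] <- j[hit]
    }
  }
  ii <- unlist(out_i, use.names = FALSE)
  jj <- unlist(out_j, use.names = FALSE)
  if (is.null(ii)) ii <- integer(0)
  if (is.null(jj)) jj <- integer(0)
  cbind(i = ii, j = jj)
}

#' Single-linkage threshold clustering of unique sequences
#'
#' Clusters are the connected components of the graph whose edges join
#' pairs at exact global edit distance at most `max_mismatch` with an
#' admissible length ratio; candidate pairs come from the k-mer prefilter
#' and are verified with [nw_distance()]. Deterministic: cluster ids are
#' assigned in order of each cluster's first row in the table.
#'
#' @param table A `unique_seq_table` or character vector of sequences.
#' @param params A [cluster_params()].
#' @return Object of class `cluster_set`: list with `membership` (integer
#'   cluster id per table row), `n_clusters`, `d`, and the input `table`.
#' @export
cluster_motu <- function(table, params = cluster_params()) {
  seqs <- if (is.data.frame(table)) table$seq else norm_seq(table)
  n <- length(seqs)
  cand <- candidate_pairs(table, params)
  if (nrow(cand) > 0L) {
    dist <- .nw_distance_pairs_cpp(seqs, cand[, 1L], cand[, 2L])
    lens <- nchar(seqs)
    ratio <- pmin(lens[cand[, 1L]], lens[cand[, 2L]]) /
      pmax(lens[cand[, 1L]], lens[cand[, 2L]])
    keep <- dist <= params$max_mismatch & ratio >= params$min_len_fraction
    cand <- cand[keep, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(cand) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(cand)))
  }
  comp <- igraph::components(g)$membership
  # relabel so cluster ids follow first appearance in table order
  relabel <- match(comp, unique(comp))
  structure(list(membership = relabel, n_clusters = max(relabel),
                 d = params$max_mismatch, table = table),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d cluster(s) of %d unique sequence(s) at d = %d\n",
              x$n_clusters, length(x$membership), x$d))
  invisible(x)
}

#' Cluster assignments as a data frame
#'
#' @param x A `cluster_set`.
#' @param row.names,optional,... Passed on conventions; unused.
#' @return Data frame with columns `seq`, `cluster_id`, `d`.
#' @export
as.data.frame.cluster_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  seqs <- if (is.data.frame(x$table)) x$table$seq else x$table
  data.frame(seq = seqs, cluster_id = x$membership, d = x$d)
}

#' Read-depth saturation of cluster counts
#'
#' Subsamples reads without replacement at each depth, dereplicates,
#' clusters at mismatch cutoff `d` and counts clusters, to judge at which
#' read number new sequence clusters stop appearing.
#'
#' @param reads Character vector of reads.
#' @param depths Ascending read depths to probe.
#' @param d Mismatch cutoff.
#' @param seed Integer seed for the subsampling.
#' @param params Optional [cluster_params()]; `d` overrides its cutoff.
#' @return Data frame with columns `depth` and `n_clusters`.
#' @export
saturation_curve <- function(reads, depths, d = 3L, seed = 1L,
                             params = cluster_params(max_mismatch = d)) {
  if (is.unsorted(depths)) stop("depths must be sorted ascending")
  params$max_mismatch <- as.integer(d)
  set.seed(seed)
  res <- vapply(depths, function(dep) {
    if (dep > length(reads)) {
      warning("depth ", dep, " exceeds read count; clamped")
      dep <- length(reads)
    }
    sub <- reads[sample.int(length(reads), dep)]
    cluster_motu(collapse_unique(sub), params)$n_clusters
  }, numeric(1L))
  data.frame(depth = depths, n_clusters = res)
}
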