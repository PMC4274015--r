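#' Smith-Waterman scoring parameters
#'
#' Gap penalties follow the pipeline's convention (gap opening 20,
#' extension 1; a gap of length L costs `gap_open + (L-1) * gap_extend`).
#' Match/mismatch scores are standard DNA scores compatible with those
#' penalties and are configurable.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Penalty for the first base of a gap.
#' @param gap_extend Penalty for each additional gap base.
#' @return Object of class `sw_params`.
#' @export
sw_params <- function(match = 5, mismatch = -4, gap_open = 20, gap_extend = 1) {
  if (gap_open < gap_extend || gap_extend < 0) {
    stop("need gap_open >= gap_extend >= 0")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "sw_params")
}

#' Local alignment score
#'
#' Optimal Smith-Waterman score with affine gaps. Non-negative and
#' symmetric. Vectorized with recycling.
#'
#' @param a,b Character vectors of DNA sequences.
#' @param params An [sw_params()].
#' @return Numeric vector of scores.
#' @export
sw_score <- function(a, b, params = sw_params()) {
  .sw_score_cpp(norm_seq(a), norm_seq(b), params$match, params$mismatch,
                params$gap_open, params$gap_extend)
}

#' Sequence distance annotated on genealogy edges
#'
#' Positional Hamming distance for equal-length pairs; for unequal lengths
#' (indels are common in evolved populations) the number of mismatch plus
#' gap columns of the optimal unit-cost global alignment.
#'
#' @param child,parent DNA sequences (vectorized with recycling).
#' @return Integer vector of distances.
#' @export
edge_distance <- function(child, parent) {
  child <- norm_seq(child); parent <- norm_seq(parent)
  n <- max(length(child), length(parent))
  child <- rep_len(child, n); parent <- rep_len(parent, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- if (nchar(child[i]) == nchar(parent[i])) {
      mismatch_count(child[i], parent[i])
    } else {
      nw_distance(child[i], parent[i])
    }
  }
  out
}

#' Assign a putative ancestor to every child sequence
#'
#' Each child is aligned to every parent with [sw_score()]; the closest
#' match (highest score) is recorded as the child's putative ancestor, with
#' exact score ties broken uniformly at random (seed the R RNG for
#' reproducibility).
#'
#' @param children,parents `unique_seq_table`s (see [collapse_unique()]) or
#'   character vectors.
#' @param params An [sw_params()].
#' @return Data frame with one row per child: `child`, `parent` (row
#'   indices), `child_seq`, `parent_seq`, `score`, `distance`.
#' @export
assign_ancestors <- function(children, parents, params = sw_params()) {
  cs <- if (is.data.frame(children)) children$seq else norm_seq(children)
  ps <- if (is.data.frame(parents)) parents$seq else norm_seq(parents)
  if (length(ps) == 0L) stop("parent set is empty")
  sc <- .sw_score_matrix_cpp(cs, ps, params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
  parent_idx <- integer(length(cs))
  for (i in seq_along(cs)) {
    best <- which(sc[i, ] == max(sc[i, ]))
    parent_idx[i] <- if (length(best) == 1L) best else
      best[sample.int(length(best), 1L)]
  }
  data.frame(child = seq_along(cs), parent = parent_idx,
             child_seq = cs, parent_seq = ps[parent_idx],
             score = sc[cbind(seq_along(cs), parent_idx)],
             distance = edge_distance(cs, ps[parent_idx]))
}

#' Build a genealogy network across sampled transfers
#'
#' Applies [assign_ancestors()] between each consecutive pair of sampled
#' transfers, from the most recent backwards; no ancestors are assigned to
#' the first sample's sequences (they are the founders). Vertices carry the
#' sequence, transfer and abundance; edges run parent to child, annotated
#' with [edge_distance()]. The result is a forest rooted at the founders.
#'
#' @param samples Named or unnamed list of `unique_seq_table`s in transfer
#'   order; names like `"t1"` or the tables' `sample_id` attributes supply
#'   transfer labels, otherwise positions are used.
#' @param params An [sw_params()].
#' @param seed Integer seed for the tie-breaking RNG.
#' @return An [igraph::igraph] object of class `genealogy_graph`.
#' @export
build_genealogy <- function(samples, params = sw_params(), seed = 1L) {
  if (length(samples) < 2L) stop("need at least 2 samples in transfer order")
  transfers <- names(samples)
  if (is.null(transfers)) transfers <- paste0("t", seq_along(samples))
  set.seed(seed)
  vnames <- list(); vseq <- list(); vtransfer <- list(); vcount <- list()
  for (s in seq_along(samples)) {
    tab <- samples[[s]]
    stopifnot(is.data.frame(tab))
    vnames[[s]] <- paste0(transfers[s], "_", seq_len(nrow(tab)))
    vseq[[s]] <- tab$seq
    vtransfer[[s]] <- rep(transfers[s], nrow(tab))
    vcount[[s]] <- tab$count
  }
  edges <- character(0); edist <- integer(0); escore <- numeric(0)
  for (s in rev(seq_len(length(samples) - 1L))) {
    asg <- assign_ancestors(samples[[s + 1L]], samples[[s]], params)
    edges <- c(edges, as.vector(rbind(vnames[[s]][asg$parent],
                                      vnames[[s + 1L]][asg$child])))
    edist <- c(edist, asg$distance)
    escore <- c(escore, asg$score)
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(unlist(vnames),
                     sequence = unlist(vseq),
                     transfer = unlist(vtransfer),
                     count = unlist(vcount))
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, edges, distance = edist, score = escore)
  }
  class(g) <- c("genealogy_graph", class(g))
  g
}

#' Lineage success of a founder
#'
#' The total number of distinct descendants (vertices reachable along
#' parent-to-child edges), excluding the founder itself.
#'
#' @param g A genealogy graph from [build_genealogy()].
#' @param founder Vertex name of a first-transfer sequence.
#' @return Integer descendant count.
#' @export
lineage_success <- function(g, founder) {
  if (!founder %in% igraph::V(g)$name) stop("unknown founder: ", founder)
  length(igraph::subcomponent(g, founder, mode = "out")) - 1L
}

#' Diversity of a founder's surviving descendants
#'
#' Number of distinct final-transfer sequences descending from the founder.
#'
#' @param g A genealogy graph.
#' @param founder Vertex name of a first-transfer sequence.
#' @param final_transfer Transfer label of the final sample (defaults to the
#'   last transfer present in the graph).
#' @return Integer count of final-transfer descendants.
#' @export
founder_diversity <- function(g, founder,
                              final_transfer = utils::tail(unique(igraph::V(g)$transfer), 1L)) {
  if (!founder %in% igraph::V(g)$name) stop("unknown founder: ", founder)
  desc <- as.integer(igraph::subcomponent(g, founder, mode = "out"))
  desc <- setdiff(desc, which(igraph::V(g)$name == founder))
  sum(igraph::V(g)$transfer[desc] == final_transfer)
}

#' Export a genealogy graph
#'
#' GraphML (round-trip safe, Cytoscape-compatible), SIF, or a TSV node+edge
#' table (round-trip safe via [import_graph()]).
#'
#' @param g A genealogy graph.
#' @param path Output file path.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    el <- igraph::as_edgelist(g)
    lines <- if (nrow(el) > 0L) paste(el[, 1L], "pd", el[, 2L]) else character(0)
    iso <- setdiff(igraph::V(g)$name, unique(as.vector(el)))
    writeLines(c(lines, iso), path)
  } else {
    v <- data.frame(type = "node", name = igraph::V(g)$name,
                    transfer = igraph::V(g)$transfer,
                    count = igraph::V(g)$count,
                    sequence = igraph::V(g)$sequence,
                    from = NA, to = NA, distance = NA)
    el <- igraph::as_edgelist(g)
    e <- if (nrow(el) > 0L) {
      data.frame(type = "edge", name = NA, transfer = NA, count = NA,
                 sequence = NA, from = el[, 1L], to = el[, 2L],
                 distance = igraph::E(g)$distance)
    } else NULL
    utils::write.table(rbind(v, e), path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Re-import an exported genealogy graph
#'
#' @param path File written by [export_graph()].
#' @param format `"graphml"` or `"tsv"`.
#' @return An igraph object.
#' @export
import_graph <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    v <- tab[tab$type == "node", ]
    e <- tab[tab$type == "edge", ]
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(v$name, sequence = v$sequence,
                       transfer = as.character(v$transfer), count = v$count)
    if (nrow(e) > 0L) {
      g <- igraph::add_edges(g, as.vector(rbind(e$from, e$to)),
                             distance = e$distance)
    }
  }
  class(g) <- c("genealogy_graph", class(g))
  g
}
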