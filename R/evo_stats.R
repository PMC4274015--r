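#' Per-transfer extinction summary of founder lineages
#'
#' Given the number of transfer-1 founder lineages still present at each
#' sampled transfer, tabulates interval extinctions (losses since the
#' previous sampled transfer), cumulative extinctions and scaled cumulative
#' extinctions (cumulative divided by the founder count, truncated - not
#' rounded - to three decimals, the convention that reproduces the reported
#' summaries exactly).
#'
#' @param n_ancestors Non-increasing positive integer series of surviving
#'   founder-lineage counts, one per sampled transfer; alternatively a list
#'   of per-transfer founder survival sets, or a genealogy graph from
#'   [build_genealogy()] (founder survival is then read off the network).
#' @param transfers Transfer labels, defaults to `c(1, 3, 7, 11)` (recycled
#'   or trimmed to the series length).
#' @return An `extinction_table`: data frame with columns `transfer`,
#'   `n_ancestors`, `n_extinctions`, `cumulative_extinctions`,
#'   `scaled_cumulative`.
#' @export
extinction_table <- function(n_ancestors, transfers = c(1L, 3L, 7L, 11L)) {
  if (inherits(n_ancestors, "igraph")) {
    n_ancestors <- founder_survival_counts(n_ancestors)
  }
  if (is.list(n_ancestors)) n_ancestors <- lengths(n_ancestors)
  n_ancestors <- as.numeric(n_ancestors)
  if (length(n_ancestors) < 2L) stop("need at least 2 transfers")
  if (n_ancestors[1L] <= 0) stop("founder count at the first transfer must be positive")
  if (any(diff(n_ancestors) > 0)) {
    stop("inconsistent series: ancestor counts increase over transfers")
  }
  transfers <- rep_len(transfers, length(n_ancestors))
  ext <- c(0, -diff(n_ancestors))
  cum <- cumsum(ext)
  scaled <- trunc(cum / n_ancestors[1L] * 1000) / 1000
  structure(data.frame(transfer = transfers, n_ancestors = n_ancestors,
                       n_extinctions = ext, cumulative_extinctions = cum,
                       scaled_cumulative = scaled),
            class = c("extinction_table", "data.frame"))
}

#' Founder survival counts from a genealogy network
#'
#' For each transfer present in the graph, the number of first-transfer
#' founders with at least one descendant at that transfer (every founder
#' counts at the first transfer).
#'
#' @param g A genealogy graph from [build_genealogy()].
#' @return Named integer vector of surviving-founder counts per transfer.
#' @export
founder_survival_counts <- function(g) {
  tr <- igraph::V(g)$transfer
  levels <- unique(tr)
  founders <- which(tr == levels[1L])
  vapply(levels, function(t) {
    at_t <- which(tr == t)
    sum(vapply(founders, function(f) {
      any(as.integer(igraph::subcomponent(g, f, mode = "out")) %in% at_t)
    }, logical(1L)))
  }, numeric(1L))
}

#' Check a reported extinction series for internal consistency
#'
#' Flags rows where reported interval extinctions differ from the
#' differences of the ancestor counts (and, consequently, where cumulative
#' and scaled values disagree with recomputation).
#'
#' @param n_ancestors Ancestor-count series.
#' @param reported_extinctions Reported interval extinction series (same
#'   length; the first entry is 0).
#' @param transfers Transfer labels.
#' @return Data frame with the recomputed values, the reported ones and a
#'   logical `consistent` column.
#' @export
check_extinction_consistency <- function(n_ancestors, reported_extinctions,
                                         transfers = c(1L, 3L, 7L, 11L)) {
  tab <- extinction_table(n_ancestors, transfers)
  if (length(reported_extinctions) != nrow(tab)) {
    stop("reported series length does not match the ancestor series")
  }
  tab$reported_extinctions <- as.numeric(reported_extinctions)
  tab$consistent <- tab$n_extinctions == tab$reported_extinctions
  tab
}

# Windowed log-linear fit via prefix sums: returns slope/intercept/r2 of the
# best window (max R2; ties to longer, then later windows) of >= min_len
# cycles among cycles with 0 < y <= hi_frac * plateau, required to touch
# lo_frac * plateau so that the window sits in the late log-linear phase.
best_loglinear_window <- function(cycle, y, min_len = 5L,
                                  lo_frac = 0.1, hi_frac = 0.9) {
  plateau <- max(y)
  ok <- which(y > 0 & y <= hi_frac * plateau)
  if (length(ok) < min_len) return(NULL)
  runs <- split(ok, cumsum(c(1L, diff(ok) != 1L)))
  best <- NULL
  for (run in runs) {
    if (length(run) < min_len) next
    x <- cycle[run]; ly <- log(y[run])
    cx <- cumsum(x); cy <- cumsum(ly); cxx <- cumsum(x^2)
    cxy <- cumsum(x * ly); cyy <- cumsum(ly^2)
    m <- length(run)
    for (a in 1:(m - min_len + 1L)) {
      for (b in (a + min_len - 1L):m) {
        if (!any(y[run[a:b]] >= lo_frac * plateau)) next
        n <- b - a + 1L
        sx <- cx[b] - if (a > 1L) cx[a - 1L] else 0
        sy <- cy[b] - if (a > 1L) cy[a - 1L] else 0
        sxx <- cxx[b] - if (a > 1L) cxx[a - 1L] else 0
        sxy <- cxy[b] - if (a > 1L) cxy[a - 1L] else 0
        syy <- cyy[b] - if (a > 1L) cyy[a - 1L] else 0
        vxx <- sxx - sx^2 / n
        vyy <- syy - sy^2 / n
        vxy <- sxy - sx * sy / n
        slope <- vxy / vxx
        r2 <- if (vyy <= 1e-12) 1 else vxy^2 / (vxx * vyy)
        cand <- list(slope = slope, intercept = (sy - slope * sx) / n,
                     r2 = r2, window = run[a:b], length = n)
        better <- is.null(best) || r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 &&
           (n > best$length ||
            (n == best$length && run[a] > best$window[1L])))
        if (better) best <- cand
      }
    }
  }
  best
}

as_curve <- function(curve) {
  if (is.data.frame(curve)) {
    y_col <- intersect(c("total_copies", "total", "signal"), names(curve))[1L]
    list(cycle = curve$cycle, y = curve[[y_col]])
  } else {
    list(cycle = seq_along(curve) - 1L, y = as.numeric(curve))
  }
}

log_linear_slope <- function(curve, min_r2 = 0.99) {
  cv <- as_curve(curve)
  best <- best_loglinear_window(cv$cycle, cv$y)
  if (is.null(best) || best$r2 < min_r2) {
    stop("no log-linear window of >= 5 cycles with R^2 >= ", min_r2)
  }
  best
}

#' Relative slope (population fitness per PCR cycle)
#'
#' Slope of the log of total signal over the automatically detected
#' log-linear window, standardized by the mean slope of pre-extended
#' standard curves on the same cycle grid. A standard measured against
#' itself has relative slope exactly 1.
#'
#' The window is the maximal-R-squared contiguous run of at least 5 cycles
#' with signal between zero and 90 percent of plateau that reaches at least
#' 10 percent of plateau, so it captures the late log-linear phase while
#' excluding saturation; a fit with R-squared below `min_r2` raises a
#' quality error.
#'
#' @param curve Growth curve: data frame (`cycle`, `total_copies`) or a
#'   numeric signal vector (cycle 0, 1, ...).
#' @param standards A single standard curve or list of standard curves.
#' @param min_r2 Quality threshold for the log-linear fit.
#' @return Relative slope (dimensionless).
#' @export
relative_slope <- function(curve, standards, min_r2 = 0.99) {
  if (is.data.frame(standards) || is.numeric(standards)) {
    standards <- list(standards)
  }
  s <- log_linear_slope(curve, min_r2)$slope
  s_std <- vapply(standards, function(x) log_linear_slope(x, min_r2)$slope,
                  numeric(1L))
  s / mean(s_std)
}

# fractional cycle at which a curve first crosses a signal threshold
# (log-interpolated between bracketing cycles)
cq_at_threshold <- function(curve, threshold) {
  cv <- as_curve(curve)
  i <- which(cv$y >= threshold)[1L]
  if (is.na(i)) stop("curve never reaches the quantification threshold")
  if (i == 1L) return(cv$cycle[1L])
  cv$cycle[i - 1L] + (cv$cycle[i] - cv$cycle[i - 1L]) *
    (log(threshold) - log(cv$y[i - 1L])) / (log(cv$y[i]) - log(cv$y[i - 1L]))
}

#' Quantification-cycle estimate of initial template from a growth curve
#'
#' Standard-curve qPCR quantification: the sample's fractional
#' threshold-crossing cycle (Cq) is compared with that of a pre-extended
#' standard of known input, assuming the standard's amplification
#' efficiency: `estimate = standard_copies * exp(s_std * (Cq_std - Cq))`,
#' where `s_std` is the standard's log-linear slope per cycle. For a
#' population in which only a fraction of molecules self-primed (and hence
#' seeds exponential growth), this estimates the number of those molecules.
#' The threshold defaults to half the smaller plateau, late enough that
#' exponential products dominate the signal but below saturation.
#'
#' @param curve Growth curve as in [relative_slope()].
#' @param standard A pre-extended standard curve on the same cycle grid.
#' @param standard_copies Known input copies of the standard.
#' @param threshold_frac Quantification threshold as a fraction of the
#'   smaller of the two plateaus.
#' @param min_r2 Quality threshold for the standard's log-linear fit.
#' @return Estimated initial copy number.
#' @export
estimate_initial_copies <- function(curve, standard, standard_copies,
                                    threshold_frac = 0.5, min_r2 = 0.99) {
  cs <- as_curve(curve); ss <- as_curve(standard)
  threshold <- threshold_frac * min(max(cs$y), max(ss$y))
  s_std <- log_linear_slope(standard, min_r2)$slope
  dcq <- cq_at_threshold(standard, threshold) - cq_at_threshold(curve, threshold)
  standard_copies * exp(s_std * dcq)
}

#' Proportion of a population able to fold and self-prime
#'
#' Ratio of the qPCR-detected (self-priming) molecule count to the total
#' molecule count measured fluorometrically, clamped at 1 (measurement
#' noise can push the ratio above 1).
#'
#' @param qpcr_estimate Estimated self-priming molecules.
#' @param total_molecules Total molecules.
#' @return Proportion in \[0, 1\].
#' @export
fold_fraction <- function(qpcr_estimate, total_molecules) {
  if (any(qpcr_estimate < 0) || any(total_molecules <= 0)) {
    stop("molecule counts must be non-negative (total positive)")
  }
  pmin(qpcr_estimate / total_molecules, 1.0)
}

#' Genome-length distribution of a unique-sequence table
#'
#' @param table A `unique_seq_table` (see [collapse_unique()]).
#' @param threshold_bp Length threshold in base pairs.
#' @return List with `histogram` (data frame `length`, `count`,
#'   abundance-weighted) and `proportion_over_threshold` (proportion of
#'   reads strictly longer than the threshold).
#' @export
length_stats <- function(table, threshold_bp = 75L) {
  if (threshold_bp < 1L) stop("threshold must be >= 1")
  if (!is.data.frame(table) || nrow(table) == 0L) stop("empty table")
  len <- nchar(table$seq)
  agg <- rowsum(table$count, len)
  hist <- data.frame(length = as.integer(rownames(agg)), count = agg[, 1L])
  rownames(hist) <- NULL
  prop <- sum(table$count[len > threshold_bp]) / sum(table$count)
  list(histogram = hist, proportion_over_threshold = prop)
}
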