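#' Two-state stem thermodynamic parameters
#'
#' A deliberately minimal surrogate for full secondary-structure free-energy
#' minimization: the only structural element scored is the single 3'-terminal
#' stem that enables self-priming. The stem's free energy is
#' \deqn{\Delta G(T) = (L-1)\,\Delta H_{stack} - T (L-1)\,\Delta S_{stack} + \Delta G_{loop},}
#' with L the stem length in base pairs, so \eqn{\Delta G} is strictly
#' increasing in temperature (melting behaviour) whenever
#' `dS_per_stack < 0`.
#'
#' Defaults are nearest-neighbour-like round numbers calibrated so that the
#' ancestral stem is stable (negative \eqn{\Delta G}) at 45-55 degC and
#' unstable at 65 degC and above, matching the designed folding window of
#' the founder hairpin; the 9-bp ancestral stem then melts at about 63 degC.
#'
#' @param dH_per_stack Enthalpy per base-pair stack, kcal/mol (negative).
#' @param dS_per_stack Entropy per stack, kcal/(mol K) (negative).
#' @param loop_penalty_dG Temperature-independent loop closure penalty,
#'   kcal/mol (positive).
#' @param R Gas constant, kcal/(mol K).
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(dH_per_stack = -8.0, dS_per_stack = -0.0225,
                          loop_penalty_dG = 3.5, R = 0.0019872) {
  if (dH_per_stack >= 0) stop("dH_per_stack must be negative")
  if (dS_per_stack >= 0) stop("dS_per_stack must be negative (dG must increase with T)")
  if (loop_penalty_dG <= 0) stop("loop_penalty_dG must be positive")
  structure(list(dH_per_stack = dH_per_stack, dS_per_stack = dS_per_stack,
                 loop_penalty_dG = loop_penalty_dG, R = R),
            class = "thermo_params")
}

#' Convert degrees Celsius to kelvin
#' @param temp_c Temperature in degrees Celsius.
#' @return Temperature in kelvin.
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' Find the 3'-terminal self-priming stem
#'
#' Searches for the longest suffix of the sequence whose reverse complement
#' occurs internally, ending at least one base before the suffix start (so
#' the two spans never overlap and a fold-back is geometrically possible).
#' Only perfect Watson-Crick complementarity is considered: no wobble pairs,
#' no bulges. Ties among partner locations for the winning length are broken
#' in favour of the 5'-most partner.
#'
#' @param seq A single DNA sequence.
#' @param min_stem Minimum acceptable stem length in base pairs (>= 3).
#' @return An object of class `stem` with fields `three_prime_span`,
#'   `partner_span` (1-based inclusive) and `length`, or `NULL` when no
#'   internal complement of at least `min_stem` bases exists.
#' @export
find_self_priming_stem <- function(seq, min_stem = 6L) {
  seq <- norm_seq(seq)
  if (length(seq) != 1L) stop("find_self_priming_stem takes a single sequence")
  if (min_stem < 3L) stop("min_stem must be >= 3")
  n <- nchar(seq)
  hit <- .stem_search_cpp(seq, as.integer(min_stem))
  if (hit[1L] == 0L) return(NULL)
  L <- hit[1L]
  structure(list(three_prime_span = c(n - L + 1L, n),
                 partner_span = c(hit[2L], hit[2L] + L - 1L),
                 length = L),
            class = "stem")
}

#' @export
print.stem <- function(x, ...) {
  cat(sprintf("3'-terminal stem: %d bp; suffix %d-%d paired with %d-%d\n",
              x$length, x$three_prime_span[1L], x$three_prime_span[2L],
              x$partner_span[1L], x$partner_span[2L]))
  invisible(x)
}

#' Free energy of a stem at a given temperature
#'
#' @param stem A `stem` object (see [find_self_priming_stem()]), or a bare
#'   stem length in base pairs.
#' @param temp_k Temperature in kelvin.
#' @param params A [thermo_params()] object.
#' @return Free energy in kcal/mol; strictly increasing in temperature.
#' @export
stem_free_energy <- function(stem, temp_k, params = thermo_params()) {
  L <- if (inherits(stem, "stem")) stem$length else as.integer(stem)
  if (is.na(L) || L < 2L) stop("stem length < 2: free energy undefined")
  if (any(temp_k <= 0)) stop("temperature must be positive kelvin")
  (L - 1) * params$dH_per_stack - temp_k * (L - 1) * params$dS_per_stack +
    params$loop_penalty_dG
}

#' Melting temperature of a stem
#'
#' Root of \eqn{\Delta G(T) = 0}, found by bisection; the closed form is
#' monotone so the root is unique.
#'
#' @inheritParams stem_free_energy
#' @param interval Search interval in kelvin.
#' @return Temperature in kelvin at which the stem free energy crosses zero.
#' @export
stem_melting_temp <- function(stem, params = thermo_params(),
                              interval = c(200, 500)) {
  stats::uniroot(function(T) stem_free_energy(stem, T, params),
                 interval = interval, tol = 1e-9)$root
}

#' Probability of self-priming at a temperature
#'
#' Two-state folded fraction of the best 3'-terminal stem:
#' \eqn{p = 1 / (1 + e^{\Delta G / (R T)})}. Returns 0 when no stem of at
#' least `min_stem` base pairs exists. Non-increasing in temperature.
#'
#' @param seq A single DNA sequence.
#' @param temp_k Temperature in kelvin (vectorized).
#' @param params A [thermo_params()] object.
#' @param min_stem Minimum stem length in base pairs.
#' @return Probability in \[0, 1\] (vector along `temp_k`).
#' @export
p_self_prime <- function(seq, temp_k, params = thermo_params(), min_stem = 6L) {
  if (any(temp_k <= 0)) stop("temperature must be positive kelvin")
  stem <- find_self_priming_stem(seq, min_stem = min_stem)
  if (is.null(stem)) return(rep(0, length(temp_k)))
  dG <- stem_free_energy(stem, temp_k, params)
  1 / (1 + exp(dG / (params$R * temp_k)))
}

#' Extend a sequence by self-primed polymerase copying
#'
#' When the 3' terminus pairs with an internal tract, the polymerase copies
#' the template 5' of the partner span, appending the reverse complement of
#' that prefix to the 3' end. For the ancestral molecule this creates a new
#' 3' end that is the exact binding footprint of the forward qPCR primer.
#'
#' @param seq A single DNA sequence.
#' @param min_stem Minimum stem length in base pairs.
#' @return The extended sequence. If the partner span starts at position 1
#'   there is nothing to copy and the sequence is returned unchanged.
#' @export
extend_by_self_priming <- function(seq, min_stem = 6L) {
  seq <- norm_seq(seq)
  stem <- find_self_priming_stem(seq, min_stem = min_stem)
  if (is.null(stem)) stop("sequence has no self-priming stem: not extendable")
  p0 <- stem$partner_span[1L]
  if (p0 == 1L) return(seq)
  paste0(seq, revcomp(substr(seq, 1L, p0 - 1L)))
}
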