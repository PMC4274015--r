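#' An Oli population
#'
#' A multiset of top-strand sequence genotypes with integer copy counts and
#' an extended/unextended state, the evolving unit of the serial-transfer
#' simulator. Rows with identical `(seq, extended)` are merged.
#'
#' @param seq Character vector of genotype sequences.
#' @param count Non-negative integer copy counts (recycled).
#' @param extended Logical: does the copy carry the self-primed 3' extension?
#' @param transfer Transfer index annotation.
#' @return Object of class `oli_population` (a data frame).
#' @export
oli_population <- function(seq, count, extended = FALSE, transfer = 0L) {
  seq <- norm_seq(seq)
  count <- as.numeric(count)
  if (any(count < 0) || any(count != floor(count))) {
    stop("copy counts must be non-negative integers")
  }
  df <- data.frame(seq = seq, count = count,
                   extended = rep_len(as.logical(extended), length(seq)))
  df <- merge_population(df)
  attr(df, "transfer") <- as.integer(transfer)
  class(df) <- c("oli_population", "data.frame")
  df
}

merge_population <- function(df) {
  key <- paste0(df$extended, "|", df$seq)
  if (anyDuplicated(key)) {
    cnt <- rowsum(df$count, key)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$count <- cnt[match(paste0(df$extended, "|", df$seq), rownames(cnt)), 1L]
  }
  df <- df[df$count > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}

as_population <- function(df, transfer) {
  df <- merge_population(df)
  attr(df, "transfer") <- as.integer(transfer)
  class(df) <- c("oli_population", "data.frame")
  df
}

#' @export
print.oli_population <- function(x, ...) {
  cat(sprintf("Oli population: %d genotype(s), %.0f copies, transfer %d\n",
              nrow(x), sum(x$count), attr(x, "transfer")))
  NextMethod()
}

#' Total copy number of a population
#' @param pop An [oli_population()].
#' @return Total number of molecules.
#' @export
population_size <- function(pop) sum(pop$count)

#' Per-transfer self-priming temperature schedule
#'
#' Eleven transfers. The control regime holds 55 degC throughout; the three
#' change regimes raise the temperature by 15 degC in total, ending at
#' 70 degC, differing only in rate: `sudden` makes a single +15 step at
#' transfer 2, `intermediate` five +3 steps at transfers 2-6 and `slow` ten
#' +1.5 steps at transfers 2-11.
#'
#' @param name One of `"control"`, `"sudden"`, `"intermediate"`, `"slow"`.
#' @return Object of class `temperature_regime` with fields `name`, `temps`.
#' @export
make_regime <- function(name = c("control", "sudden", "intermediate", "slow")) {
  name <- match.arg(name)
  temps <- switch(name,
    control = rep(55, 11L),
    sudden = c(55, rep(70, 10L)),
    intermediate = c(55, 58, 61, 64, 67, rep(70, 6L)),
    slow = 55 + 1.5 * 0:10)
  structure(list(name = name, temps = temps), class = "temperature_regime")
}

#' Per-duplication mutation model
#'
#' Mutations are applied to newly synthesized strands only, one pass per
#' duplication: per-base Bernoulli substitution with a 4x4 spectrum, plus
#' per-base indel events (insertion or deletion, equally likely, of 1 to
#' `max_indel_len` bases). The default rates put the combined per-base rate
#' in the middle of the error-prone polymerase's stated 1-16 per kb range,
#' with a uniform substitution spectrum.
#'
#' @param sub_rate Substitutions per base per duplication.
#' @param indel_rate Indel events per base per duplication.
#' @param spectrum 4x4 substitution probability matrix over ACGT, zero
#'   diagonal, rows summing to 1.
#' @param max_indel_len Maximum indel length in bases.
#' @return Object of class `mutation_model`.
#' @export
mutation_model <- function(sub_rate = 0.008, indel_rate = 0.0008,
                           spectrum = NULL, max_indel_len = 3L) {
  if (sub_rate < 0 || sub_rate > 1 || indel_rate < 0 || indel_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  bases <- c("A", "C", "G", "T")
  if (is.null(spectrum)) {
    spectrum <- matrix(1 / 3, 4L, 4L, dimnames = list(bases, bases))
    diag(spectrum) <- 0
  }
  spectrum <- spectrum[bases, bases]
  if (any(diag(spectrum) != 0) || any(abs(rowSums(spectrum) - 1) > 1e-8)) {
    stop("spectrum must have zero diagonal and rows summing to 1")
  }
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 spectrum = spectrum,
                 spectrum_cum = t(apply(spectrum, 1L, cumsum)),
                 max_indel_len = as.integer(max_indel_len)),
            class = "mutation_model")
}

#' Mutate a sequence
#'
#' Applies one duplication's worth of mutation: substitutions and indels at
#' the model's per-base rates. With `n > 1`, returns `n` independently
#' mutated copies.
#'
#' @param seq A single DNA sequence.
#' @param model A [mutation_model()].
#' @param n Number of independent copies to draw.
#' @return Character vector of length `n`.
#' @export
mutate_seq <- function(seq, model = mutation_model(), n = 1L) {
  seq <- norm_seq(seq)
  L <- nchar(seq)
  k_sub <- stats::rbinom(n, L, model$sub_rate)
  k_ind <- stats::rbinom(n, L, model$indel_rate)
  out <- rep(seq, n)
  hit <- which(k_sub + k_ind > 0L)
  if (length(hit) > 0L) {
    out[hit] <- .mutate_batch_cpp(out[hit], k_sub[hit], k_ind[hit],
                                  model$spectrum_cum, model$max_indel_len)
  }
  out
}

#' Challenge a population to fold and self-prime
#'
#' Each unextended copy independently folds (and extends its 3' end) with
#' the two-state probability of its genotype's best stem at the given
#' temperature; copies that fail remain unchanged. Already-extended copies
#' are left as they are.
#'
#' @param pop An [oli_population()].
#' @param temp_c Self-priming temperature in degrees Celsius.
#' @param thermo A [thermo_params()] object.
#' @param min_stem Minimum stem length in base pairs.
#' @return The population after the folding step (copy total unchanged).
#' @export
self_priming_step <- function(pop, temp_c, thermo = thermo_params(),
                              min_stem = 6L) {
  if (nrow(pop) == 0L) stop("empty population")
  temp_k <- celsius_to_kelvin(temp_c)
  rows <- vector("list", nrow(pop))
  for (i in seq_len(nrow(pop))) {
    if (pop$extended[i]) { rows[[i]] <- pop[i, ]; next }
    p <- p_self_prime(pop$seq[i], temp_k, thermo, min_stem)
    n_ext <- if (p > 0) stats::rbinom(1L, pop$count[i], p) else 0
    out <- pop[i, ]
    out$count <- pop$count[i] - n_ext
    if (n_ext > 0) {
      ext <- data.frame(seq = extend_by_self_priming(pop$seq[i], min_stem),
                        count = n_ext, extended = TRUE)
      out <- rbind(out, ext)
    }
    rows[[i]] <- out
  }
  as_population(do.call(rbind, rows), attr(pop, "transfer"))
}

#' Primer-limited mutagenic PCR
#'
#' Per cycle, every copy of an extended genotype that carries both primer
#' footprints duplicates (exponential growth); every copy present at the
#' start of the PCR that does not carry both footprints templates one new
#' strand per cycle (linear growth). Each new strand consumes one primer
#' from a finite pool and passes through [mutate_seq()]; when the pool is
#' exhausted, growth plateaus (scarce primers are allocated at random in
#' proportion to demand). Newly arisen mutant strands join the exponential
#' class iff they still carry both footprints; otherwise they persist
#' without further replication.
#'
#' @param pop An [oli_population()] (after the self-priming step).
#' @param cycles Number of PCR cycles.
#' @param primer_copies Size of the limiting primer pool.
#' @param model A [mutation_model()]. Use zero rates for error-free PCR.
#' @param primers A [primer_pair()].
#' @param max_primer_mm Mismatches tolerated per footprint for binding.
#' @return List with elements `pop` (the amplified population) and `curve`
#'   (data frame `cycle`, `total_copies`; cycle 0 is the input population).
#' @export
pcr_amplify <- function(pop, cycles = 40L, primer_copies = 5e6,
                        model = mutation_model(), primers = primer_pair(),
                        max_primer_mm = primers$max_mm) {
  if (cycles < 1L) stop("cycles must be >= 1")
  seqs <- pop$seq
  counts <- pop$count
  extended <- pop$extended
  expo <- binds_both_primers(seqs, primers, max_primer_mm)
  # linear templating is restricted to the copies present at PCR start
  lin_founder <- ifelse(expo, 0, counts)
  primers_left <- primer_copies
  curve <- numeric(cycles + 1L)
  curve[1L] <- sum(counts)

  for (cy in seq_len(cycles)) {
    demand <- ifelse(expo, counts, lin_founder)
    D <- sum(demand)
    if (D > 0 && primers_left > 0) {
      if (D <= primers_left) {
        alloc <- demand
      } else {
        alloc <- as.numeric(stats::rmultinom(1L, primers_left, demand))
      }
      primers_left <- primers_left - sum(alloc)
      # batch all newly synthesized strands of this cycle: draw mutation
      # event counts vectorized, then do string surgery only on mutants
      idx <- rep.int(seq_along(alloc), alloc)
      Ls <- nchar(seqs)[idx]
      k_sub <- stats::rbinom(length(idx), Ls, model$sub_rate)
      k_ind <- stats::rbinom(length(idx), Ls, model$indel_rate)
      mut_i <- which(k_sub + k_ind > 0L)
      n_same <- tabulate(idx[k_sub + k_ind == 0L], nbins = length(alloc))
      gain <- which(n_same > 0L & expo)
      counts[gain] <- counts[gain] + n_same[gain]
      # unmutated linear copies: same sequence, but they do not template
      lin_same <- which(n_same > 0L & !expo)
      new_seqs <- seqs[lin_same]; new_counts <- n_same[lin_same]
      new_ext <- extended[lin_same]; new_expo <- rep(FALSE, length(lin_same))
      if (length(mut_i) > 0L) {
        par <- idx[mut_i]
        mut <- .mutate_batch_cpp(seqs[par], k_sub[mut_i], k_ind[mut_i],
                                 model$spectrum_cum, model$max_indel_len)
        new_seqs <- c(new_seqs, mut)
        new_counts <- c(new_counts, rep(1, length(mut)))
        new_ext <- c(new_ext, extended[par])
        # mutants join the exponential class iff both footprints survive
        new_expo <- c(new_expo, binds_both_primers(mut, primers, max_primer_mm))
      }
      if (length(new_seqs) > 0L) {
        seqs <- c(seqs, new_seqs); counts <- c(counts, new_counts)
        extended <- c(extended, new_ext); expo <- c(expo, new_expo)
        lin_founder <- c(lin_founder, rep(0, length(new_seqs)))
      }
    }
    curve[cy + 1L] <- sum(counts)
  }
  out <- as_population(data.frame(seq = seqs, count = counts,
                                  extended = extended),
                       attr(pop, "transfer"))
  list(pop = out,
       curve = data.frame(cycle = 0:cycles, total_copies = curve))
}

#' Digest a population's extended 3' ends
#'
#' Every copy is trimmed with [digest_trim()]; molecules whose cut sites
#' have mutated away survive uncut. Copy totals are conserved. Molecules
#' that are actually cut lose their extended state.
#'
#' @param pop An [oli_population()].
#' @param enzymes List of [restriction_enzyme()] objects.
#' @param mode Trimming mode, see [digest_trim()].
#' @return The digested population.
#' @export
digest_population <- function(pop, enzymes = oli_enzymes(),
                              mode = "three_prime") {
  if (nrow(pop) == 0L) return(pop)
  digested <- if (mode == "three_prime") {
    .digest3_cpp(pop$seq,
                 vapply(enzymes, `[[`, character(1L), "recognition"),
                 vapply(enzymes, `[[`, character(1L), "recognition_rc"),
                 vapply(enzymes, `[[`, integer(1L), "cut_offset_top"))
  } else {
    vapply(pop$seq, digest_trim, character(1L),
           enzymes = enzymes, mode = mode, USE.NAMES = FALSE)
  }
  as_population(data.frame(seq = digested, count = pop$count,
                           extended = pop$extended & digested == pop$seq),
                attr(pop, "transfer"))
}

#' Bottleneck a population
#'
#' Draws `size` copies without replacement (a multivariate hypergeometric
#' sample over genotypes); returns the population unchanged when `size` is
#' at least the copy total.
#'
#' @param pop An [oli_population()].
#' @param size Number of copies to carry forward.
#' @return The sampled population.
#' @export
bottleneck_sample <- function(pop, size) {
  if (nrow(pop) == 0L || sum(pop$count) == 0) stop("empty population")
  if (size < 1L) stop("size must be >= 1")
  total <- sum(pop$count)
  if (size >= total) return(pop)
  remaining <- total
  left <- size
  kept <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    if (left == 0L) break
    k <- stats::rhyper(1L, pop$count[i], remaining - pop$count[i], left)
    kept[i] <- k
    left <- left - k
    remaining <- remaining - pop$count[i]
  }
  as_population(data.frame(seq = pop$seq, count = kept,
                           extended = pop$extended),
                attr(pop, "transfer"))
}

#' Draw sequencing reads from a population
#'
#' Reads are drawn with replacement in proportion to copy counts, with an
#' optional uniform per-base substitution error. Read names carry
#' treatment/transfer/replicate metadata.
#'
#' @param pop An [oli_population()].
#' @param depth Number of reads.
#' @param error_rate Per-base sequencing error rate (default 0).
#' @param treatment,transfer,replicate Metadata recorded in read names.
#' @return Named character vector of reads.
#' @export
sequence_population <- function(pop, depth, error_rate = 0,
                                treatment = "NA",
                                transfer = attr(pop, "transfer"),
                                replicate = 1L) {
  if (depth < 1L) stop("depth must be >= 1")
  if (nrow(pop) == 0L || sum(pop$count) == 0) stop("empty population")
  k <- as.numeric(stats::rmultinom(1L, depth, pop$count))
  reads <- rep(pop$seq, k)
  if (error_rate > 0) {
    err_model <- mutation_model(sub_rate = error_rate, indel_rate = 0)
    reads <- vapply(reads, function(r) mutate_seq(r, err_model, 1L),
                    character(1L), USE.NAMES = FALSE)
  }
  names(reads) <- sprintf("read%06d treatment=%s transfer=%s replicate=%s",
                          seq_along(reads), treatment, transfer, replicate)
  reads
}

#' Configuration of a fold-or-hold selection experiment
#'
#' Defaults are the study conditions of the original selection experiment:
#' 56 replicate populations founded from about 30000 copies of the ancestral
#' molecule, 11 serial transfers, 40 qPCR cycles per transfer limited by
#' 5e6 primer copies, a 1e5-copy bottleneck between transfers and read sets
#' emitted at transfers 1, 3, 7 and 11.
#'
#' @param regime A [make_regime()] object (or regime name).
#' @param n_transfers Number of serial transfers.
#' @param n_replicates Number of replicate populations.
#' @param founding_copies Copies of the ancestor founding each replicate.
#' @param primer_copies Limiting primer pool per transfer.
#' @param qpcr_cycles PCR cycles per transfer.
#' @param bottleneck_size Copies carried between transfers.
#' @param mutation A [mutation_model()].
#' @param thermo A [thermo_params()].
#' @param min_stem Minimum self-priming stem length.
#' @param primers A [primer_pair()].
#' @param max_primer_mm Footprint mismatches tolerated for primer binding.
#' @param seed Integer seed; every random stage derives from it.
#' @param read_depth Reads per sampled transfer.
#' @param sampled_transfers Transfers at which reads are emitted.
#' @param sequencing_error Per-base read error rate.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(regime = make_regime("control"),
                       n_transfers = 11L, n_replicates = 56L,
                       founding_copies = 30000, primer_copies = 5e6,
                       qpcr_cycles = 40L, bottleneck_size = 1e5,
                       mutation = mutation_model(), thermo = thermo_params(),
                       min_stem = 6L, primers = primer_pair(),
                       max_primer_mm = primers$max_mm, seed = 1L,
                       read_depth = 1000L,
                       sampled_transfers = c(1L, 3L, 7L, 11L),
                       sequencing_error = 0) {
  if (is.character(regime)) regime <- make_regime(regime)
  stopifnot(n_transfers >= 1, n_replicates >= 1, founding_copies >= 1,
            primer_copies >= 1, qpcr_cycles >= 1, bottleneck_size >= 1,
            read_depth >= 1)
  if (bottleneck_size > founding_copies + primer_copies) {
    stop("bottleneck_size exceeds the primer-limited carrying capacity")
  }
  if (n_transfers != length(regime$temps)) {
    regime$temps <- rep_len(regime$temps, n_transfers)
  }
  structure(list(regime = regime, n_transfers = as.integer(n_transfers),
                 n_replicates = as.integer(n_replicates),
                 founding_copies = founding_copies,
                 primer_copies = primer_copies,
                 qpcr_cycles = as.integer(qpcr_cycles),
                 bottleneck_size = bottleneck_size, mutation = mutation,
                 thermo = thermo, min_stem = as.integer(min_stem),
                 primers = primers, max_primer_mm = as.integer(max_primer_mm),
                 seed = as.integer(seed), read_depth = as.integer(read_depth),
                 sampled_transfers = as.integer(sampled_transfers),
                 sequencing_error = sequencing_error),
            class = "sim_config")
}

#' Run a fold-or-hold selection experiment
#'
#' For each replicate and transfer: self-priming at the regime temperature,
#' primer-limited mutagenic PCR, restriction digestion, then a bottleneck to
#' the next transfer. Reads are drawn from the digested (pre-bottleneck)
#' population at the sampled transfers, mirroring sequencing of the
#' near-entire surveyed population. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory: writes one FASTA per
#'   (replicate, transfer), `growth_curves.csv` and `manifest.yaml`.
#' @return List with `reads` (list by replicate, then by transfer),
#'   `growth_curves` (replicate, transfer, cycle, total_copies),
#'   `final_populations` (list of [oli_population()]), and `config`.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ancestor <- unname(oli_ancestor())
  reads <- vector("list", cfg$n_replicates)
  finals <- vector("list", cfg$n_replicates)
  gc_rows <- list()
  for (rep_i in seq_len(cfg$n_replicates)) {
    pop <- oli_population(ancestor, cfg$founding_copies, transfer = 0L)
    rep_reads <- list()
    for (t in seq_len(cfg$n_transfers)) {
      pop <- self_priming_step(pop, cfg$regime$temps[t], cfg$thermo,
                               cfg$min_stem)
      amp <- pcr_amplify(pop, cfg$qpcr_cycles, cfg$primer_copies,
                         cfg$mutation, cfg$primers, cfg$max_primer_mm)
      pop <- digest_population(amp$pop)
      attr(pop, "transfer") <- t
      gc_rows[[length(gc_rows) + 1L]] <-
        data.frame(replicate = rep_i, transfer = t,
                   cycle = amp$curve$cycle,
                   total_copies = amp$curve$total_copies)
      if (t %in% cfg$sampled_transfers) {
        rep_reads[[paste0("t", t)]] <-
          sequence_population(pop, cfg$read_depth, cfg$sequencing_error,
                              treatment = cfg$regime$name, transfer = t,
                              replicate = rep_i)
      }
      pop <- bottleneck_sample(pop, cfg$bottleneck_size)
    }
    reads[[rep_i]] <- rep_reads
    finals[[rep_i]] <- pop
  }
  growth <- do.call(rbind, gc_rows)
  out <- list(reads = reads, growth_curves = growth,
              final_populations = finals, config = cfg)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  invisible(out)
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  for (rep_i in seq_along(res$reads)) {
    for (tn in names(res$reads[[rep_i]])) {
      write_fasta(res$reads[[rep_i]][[tn]],
                  file.path(out_dir, sprintf("%s_rep%02d_%s.fasta",
                                             cfg$regime$name, rep_i, tn)))
    }
  }
  utils::write.csv(res$growth_curves,
                   file.path(out_dir, "growth_curves.csv"), row.names = FALSE)
  manifest <- list(regime = cfg$regime$name, temps = cfg$regime$temps,
                   n_transfers = cfg$n_transfers,
                   n_replicates = cfg$n_replicates,
                   founding_copies = cfg$founding_copies,
                   primer_copies = cfg$primer_copies,
                   qpcr_cycles = cfg$qpcr_cycles,
                   bottleneck_size = cfg$bottleneck_size,
                   sub_rate = cfg$mutation$sub_rate,
                   indel_rate = cfg$mutation$indel_rate,
                   max_indel_len = cfg$mutation$max_indel_len,
                   dH_per_stack = cfg$thermo$dH_per_stack,
                   dS_per_stack = cfg$thermo$dS_per_stack,
                   loop_penalty_dG = cfg$thermo$loop_penalty_dG,
                   min_stem = cfg$min_stem,
                   max_primer_mm = cfg$max_primer_mm, seed = cfg$seed,
                   read_depth = cfg$read_depth,
                   sampled_transfers = cfg$sampled_transfers,
                   sequencing_error = cfg$sequencing_error)
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Growth curve of a pre-extended standard
#'
#' Amplifies an all-extended ancestral population of the configured founding
#' size under the configured PCR; the standards' slope is the reference
#' against which population fitness (relative slope) is expressed.
#'
#' @param cfg A [sim_config()].
#' @param founding_copies Starting copies for the standard (defaults to the
#'   configured founding size).
#' @return Growth-curve data frame (`cycle`, `total_copies`).
#' @export
run_standard_curve <- function(cfg, founding_copies = cfg$founding_copies) {
  ext <- extend_by_self_priming(unname(oli_ancestor()), cfg$min_stem)
  pop <- oli_population(ext, founding_copies, extended = TRUE)
  pcr_amplify(pop, cfg$qpcr_cycles, cfg$primer_copies, cfg$mutation,
              cfg$primers, cfg$max_primer_mm)$curve
}
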