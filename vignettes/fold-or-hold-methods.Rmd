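---
title: "Models and methods behind olisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind olisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olisim)
```

olisim simulates and analyses fold-or-hold selection: serial transfers of a
population of short single-stranded DNA hairpins in which only molecules
that fold and self-prime at the imposed temperature seed exponential PCR
amplification. This vignette records the models, the tunable parameters and
the design decisions, so that what the package computes — and what its
passing tests do and do not show — is explicit.

## The two-state stem model

Full secondary-structure prediction (free-energy minimization, partition
functions) is deliberately out of scope. The phenotype under selection is a
single structural element: the stem formed by the 3' terminus pairing with
an internal complementary tract. `find_self_priming_stem()` therefore finds
the longest suffix whose reverse complement occurs internally, ending at
least one base before the suffix start, with ties broken in favour of the
5'-most partner. Only perfect Watson–Crick pairing is considered — no G·T
wobble, no bulges — the simplest model consistent with a designed duplex.

On the 107-nt founder this search returns a 9-bp stem: the designed 8-bp
duplex (suffix bases 100–107 against bases 9–16) plus one flanking A·T pair
(base 99 against base 17) that the design happens to provide. The designed
duplex is contained in the found stem; all downstream consequences
(extension product, restriction cuts) depend only on where the partner
tract *starts*, which is identical.

The stem's stability is scored as
$$\Delta G(T) = (L-1)\,\Delta H_{stack} - T\,(L-1)\,\Delta S_{stack} + \Delta G_{loop},$$
and the probability of self-priming is the two-state folded fraction
$p(T) = 1/(1+e^{\Delta G/RT})$, which is monotone non-increasing in
temperature by construction.

Defaults (`thermo_params()`): ΔH_stack = −8.0 kcal/mol, ΔS_stack =
−0.0225 kcal/(mol·K), ΔG_loop = +3.5 kcal/mol, R = 0.0019872 kcal/(mol·K).
These are nearest-neighbour-like round numbers calibrated against the
founder's designed folding window: the ancestral stem must have ΔG < 0
between 45 and 55 °C and ΔG > 0 at 65 °C and above. With the 9-bp ancestral
stem the defaults put its melting point at 63.0 °C; an entropy of
−0.022 kcal/(mol·K), the more obvious round number, would place melting
above 65 °C and violate the calibration window, which is why the slightly
larger magnitude is the default. `min_stem = 6` discards spurious short
complementarities that would not hold a polymerase in place.

Temperatures are degrees Celsius in the simulator interface and kelvin in
the thermodynamic functions; `celsius_to_kelvin()` converts.

## The primer pair and a transposition in the published reverse primer

The forward primer (20 nt) is the reverse complement of the extension
product's new 3' end; the reverse primer (25 nt) is the molecule's
5'-terminal footprint. The published reverse-primer sequence disagrees with
the published template at two adjacent positions ("...gag acg tag..."
against the template's "...gag acc gag..."), an apparent transposition:
taken literally it can never match the founder amplicon exactly, although
the pipeline it belongs to demands exact primer matches. The package
therefore defaults to the template-consistent reading
(`oli_primers()`), ships the published variant alongside
(`oli_primers(printed_rev = TRUE)`), and uses the same pair consistently in
the simulator, the read filter and the digestion-escape analysis. With this
reading the extended founder carries exact footprints for both primers, as
the selection design requires.

## The serial-transfer simulator

One transfer is: `self_priming_step()` (each copy folds independently with
probability $p(T)$ and, if it folds, is extended), `pcr_amplify()`,
`digest_population()`, then `bottleneck_sample()`. Reads are drawn from the
digested, pre-bottleneck population — the analogue of sequencing the
near-entire surveyed population.

`pcr_amplify()` implements the growth asymmetry: per cycle, every copy of a
genotype carrying **both** primer footprints duplicates; every copy present
at the start of the PCR that lacks a footprint templates one new strand per
cycle (linear growth, the stated behaviour of unextended molecules; the
mechanism is not specified, so +1 copy per founder per cycle is the
modelling choice). Each new strand consumes one primer from a finite pool
(default 5×10⁶); when the pool runs out, scarce primers are allocated
multinomially in proportion to demand and the curve plateaus. Each new
strand passes through the mutation model; mutant daughters join the
exponential class only if both footprints survive, so a single footprint
mutation demotes a lineage — the simulator's rendering of stringent
annealing where one mismatch impairs binding (`max_primer_mm = 0`,
configurable to 1). Mutations are applied only to newly synthesized
strands, one pass per duplication, including inside primer footprints
(where they act as loss of binding rather than as sequence change of the
primer-derived end — an approximation that errs against escape mutants).

The mutation model is per-base Bernoulli substitution with a configurable
4×4 spectrum plus per-base indel events of 1–3 bases. Defaults, 0.008
substitutions and 0.0008 indels per base per duplication, put the combined
rate in the middle of the error-prone polymerase's stated 1–16 per kb
range; the spectrum is uniform because the enzyme's published bias is not
modelled (the matrix is user-configurable).

Copy counts are exact integers throughout — bottlenecks are multivariate
hypergeometric draws, extinction is absolute — and every stage draws from
R's RNG, so a `sim_config()` seed reproduces an experiment bit for bit.

Temperature regimes (`make_regime()`): control holds 55 °C for 11
transfers; the three change regimes end at 70 °C with a total increase of
15 °C — sudden (+15 at transfer 2), intermediate (five +3 steps at
transfers 2–6), slow (ten +1.5 steps). The exact per-transfer timelines of
the original experiment are not published in the main text; stepping from
transfer 2 onward is an assumption and the schedules are overridable.

Default sizes are the study conditions: 56 replicates, ~30 000 founding
copies, 5×10⁶ primer copies, 40 cycles, 10⁵-copy bottlenecks. (The stated
"0.05 pmol ≈ 30 000 molecules" is physically off by orders of magnitude —
0.05 pmol is ~3×10¹⁰ molecules; the simulator uses the stated 30 000.)
Cooperation, recombination and concatemerization are not modelled.

At these defaults a single replicate creates millions of mutant strands per
transfer; the test-suite and example runs therefore use scaled problem
sizes (hundreds of founders, primer pools of 5×10³–1.67×10⁶, 20–35 cycles)
chosen to preserve the structural ratios that matter — primer pool well
above the bottleneck, enough cycles to traverse the log-linear phase —
while keeping rates, temperatures and schedules at their defaults.

## Read preparation

`filter_by_primers()` keeps a read iff, in one orientation, the forward
primer matches the prefix and the reverse primer's footprint matches the
suffix, each within `max_mm` mismatches (default 0, exact matching). This
is the pipeline's only quality gate.

`collapse_unique()` merges exact duplicates after canonicalizing each read
to the lexicographic minimum of itself and its reverse complement — the
orientation merge without naming a canonical strand — and orders by
abundance.

Restriction geometry: BsaI recognizes GGTCTC and cuts 1 base downstream on
the recognition strand; HpyAV recognizes CCTTC and cuts 6 bases downstream.
`find_restriction_cuts()` scans both strands and reports 0-based
between-base top-strand coordinates. `digest_trim()` defaults to
`three_prime` mode — apply the 3'-most cut in the 3' half, drop the
fragment, and repeat to a fixed point (digestion runs to completion) —
because the experiment cleaves extended 3' ends. Trimming at the BsaI site
alone removes exactly the 8-base extension and restores the 107-nt
founder; running both enzymes to completion also takes the single base
between the HpyAV and BsaI cuts, so the steady-state unextended molecule
in simulated transfers is 106 nt, whose re-extension regenerates the same
115-nt amplicon (digestion is therefore idempotent, which the tests pin). Every
descendant of the founder also carries a bottom-strand BsaI site near its
5' end (the GAGACC tract); an indiscriminate regex trimmer would cut there
too and destroy the reverse-primer footprint. Whether the original trimming
did so is unstated, so `all_cuts_keep_longest` mode reproduces that
behaviour on request, but is not the default.

`escape_possible_with_k()` enumerates all ≤ k point substitutions
(exhaustive, k ≤ 2) and asks whether any mutant clears every cut site from
its 3' half while keeping both primer footprints within one mismatch. Both
recognition sites lie inside the forward-primer footprint and do not
overlap each other, so destroying both costs at least two footprint
mismatches — the design that makes escape unviable; the enumeration
confirms no single or double mutant escapes.

## Clustering

`nw_distance()` is the unit-cost global edit distance (substitution 1, each
gap base 1). `cluster_motu()` takes the single-linkage components of the
graph joining pairs at distance ≤ d whose shorter/longer length ratio is at
least `min_len_fraction` (default 0.87, the "percentage of minimum sequence
length" rule read as a merge precondition). Candidates come from a shared
k-mer prefilter with a provable superset property (the q-gram bound): every
pair within d is emitted, which the tests verify against an all-pairs
oracle. The nominal 97 % prefilter identity is treated as a recall
parameter of the candidate search — it can widen but never narrow the
candidate set below what d requires — because a hard 97 % identity bound
would contradict clustering at d up to 30 on ~100-nt sequences.
`saturation_curve()` subsamples reads without replacement at increasing
depths to locate the depth at which new clusters stop appearing.

## Genealogy networks

`assign_ancestors()` aligns every sequence of one sampled transfer against
every sequence of the previous one with affine-gap Smith–Waterman (gap
opening 20, extension 1, a length-L gap costing open + (L−1)·extend — the
convention is pinned by tests) and records the highest-scoring parent, ties
broken uniformly at random under a caller-supplied seed. Match/mismatch
scores are not part of the published pipeline; +5/−4, a standard DNA
scheme compatible with those gap penalties, is the configurable default.
`build_genealogy()` repeats this backwards over the sampled transfers
(nothing is assigned *to* the first sample — the founders), yielding a
forest whose vertices carry sequence, transfer and abundance and whose
edges carry a distance: positional Hamming distance for equal lengths, and
the mismatch-plus-gap column count of the optimal unit-cost global
alignment otherwise (the published annotation says Hamming but indels are
everywhere in evolved populations, so the unequal-length case needs an
extension). `lineage_success()` counts reachable descendants;
`founder_diversity()` counts final-transfer descendants. Graphs export to
GraphML (Cytoscape-compatible), SIF and a TSV node/edge table; GraphML and
TSV re-import losslessly.

Replicates can be pooled before networking (as untagged libraries force) or
analysed per replicate; the package takes whatever `unique_seq_table` list
it is given.

## Population statistics

`extinction_table()` turns a non-increasing series of surviving-founder
counts into interval, cumulative and scaled cumulative extinctions. The
scaled column is cumulative extinctions divided by the transfer-1 founder
count, **truncated** (not rounded) to three decimals — truncation is the
convention that reproduces all of the reported summary values, e.g.
249/257 → 0.968 and 230/257 → 0.894. The reported intermediate-regime
series is internally inconsistent at transfer 7 (1305 − 113 = 1192 lineages
lost, but 1194 are reported, and the cumulative column follows the 1194);
`check_extinction_consistency()` flags this rather than reconciling it, and
the recomputed intermediate values at transfers 7 and 11 (0.932, 0.978)
accordingly differ from the reported ones (0.933, 0.979) in the third
decimal.

`relative_slope()` is fitness per PCR cycle: the slope of log signal over
an automatically detected log-linear window, divided by the mean slope of
pre-extended standards. The window is the maximal-R² contiguous run of at
least 5 cycles with signal in (0, 0.9 × plateau] that reaches 0.1 ×
plateau; ties go to longer, then later windows, and a best fit with
R² < 0.99 raises a quality error. A fraction-of-plateau band of strictly
[0.1, 0.9] would hold fewer than 5 cycles of a doubling curve (0.1 to 0.9
of plateau spans ~3.2 doublings), so the band is one-sided with a
reach-10 % requirement — the interpretation that keeps a standard measured
against itself at exactly 1.0, which the tests pin.

`estimate_initial_copies()` quantifies initial self-priming template the
way qPCR actually does: by comparing fractional threshold-crossing cycles
(Cq) against a pre-extended standard of known input, at a threshold of half
the smaller plateau, using the standard's fitted slope as the efficiency.
(Back-extrapolating the window fit to cycle 0 is biased upward by the
linearly-growing mass of unextended molecules; the Cq route is robust to it
once the threshold sits where exponential products dominate, which needs a
primer pool one to two orders of magnitude above the founding count — the
protocol's own ratio is ~170.) `fold_fraction()` divides that estimate by
the fluorometric total (modelled as exact) and clamps at 1.

`length_stats()` gives the abundance-weighted genome-length histogram and
the proportion of reads longer than a threshold (default 75 bp).

## What the simulator does and does not show

The generator emulates the statistical structure the analysis assumes:
genotype-frequency dynamics under fold-or-hold selection, primer-limited
growth curves, mutation-driven diversification, extinction through
bottlenecks, and read sets with treatment/transfer/replicate metadata. It
does not emulate 454 homopolymer error profiles (a uniform per-base error
knob stands in), polymerase spectrum bias, cooperation/recombination, or —
importantly — amplification-efficiency differences between genotypes: every
both-primer molecule doubles exactly once per cycle regardless of length or
structure.

That last simplification has a visible consequence which the acceptance
test for the fitness contrast measures honestly. In the wet system,
end-point populations in the rising-temperature regimes reached *higher*
relative slopes than the control (values well above 1), which requires
genotypes that amplify faster per cycle than the pre-extended standard —
an efficiency effect (e.g. shorter amplicons amplifying better) outside
the exact-doubling model. In the simulator the relative slope is bounded
near 1 and tracks the fraction of the population that self-primed at the
assay temperature; since no evolvable stem makes folding at 70 °C more
likely than the ancestor's folding at 55 °C, the control mean stays at or
above the rising-regime means and the directional test fails by
construction. The suite keeps that test as specified rather than weakening
it: the red result documents a real boundary of the model, not a defect of
the stages it composes (each of which is verified against oracles or exact
examples elsewhere in the suite).

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open for cut positions and 1-based inclusive
for stem spans (printed that way). Sequences are uppercased on input;
anything outside ACGT is rejected. Deletions never erase a whole molecule
(a single base survives). Empty populations are errors for sampling stages
and no-ops for digestion. `bottleneck_sample()` with `size` at least the
copy total is the identity. Cluster ids and genealogy vertex names are
deterministic given inputs and seeds.
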