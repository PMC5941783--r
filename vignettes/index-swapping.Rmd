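---
title: "Models and methods: simulating, detecting and attributing index swaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating, detecting and attributing index swaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indexhop)
```

# The problem

Pooled libraries sequenced on patterned flow cells with
exclusion-amplification chemistry exchange sample indexes at appreciable
rates: residual free adapter or indexing primer hybridizes to a library
fragment during clustering and extends, stamping the fragment with
another pool member's index. Reported rates range from a few tenths of a
percent to several percent, highest in PCR-free pools (which are barely
diluted and so carry the most free adapter). Under single or
combinatorial dual indexing the consequence is silent read
mis-assignment; under *non-redundant* dual indexing — each sample owning
a private i7 and a private i5 — any single-end swap yields an index
combination absent from the sample sheet and can be filtered.

`indexhop` implements that characterization workflow: a generative
simulator with ground truth, a classifying demultiplexer, combination
and per-tile tabulation, and the two-organism mixture estimator of
per-end swap probabilities.

# The simulator

## Generative model

For each of `n_reads` clusters, independently:

1. **True sample** drawn from the pool by `abundances` (default equal).
2. **Fragment covariates**: insert length from
   Lognormal(`insert_mean_log`, `insert_sd_log`), GC fraction from
   Beta(`gc_beta_a`, `gc_beta_b`).
3. **Per-end swap events**: each end swaps with probability
   `plogis(qlogis(p_swap_end) + swap_length_coeff * z_len +
   swap_gc_coeff * z_gc)`, where `z_len` is the insert length
   standardized on the log scale and `z_gc` the GC fraction standardized
   under its Beta moments. The two ends are independent given the
   covariates; double swaps arise as the product, the minimal model
   consistent with observed double-swap reads.
4. **Replacement index** for a swapping end is drawn from the pool's
   indexes weighted by sample abundance — the *free-adapter model*:
   free-adapter mass tracks library mass, so larger pools make
   cross-sample swaps likelier at the expense of self-swaps.
   Self-replacement is permitted and recorded in the truth table
   (`i7_source`/`i5_source` change only on a swap event), but is
   undetectable downstream: with $S$ equal-abundance samples only a
   fraction $(S-1)/S$ of swap events is visible.
5. **Index sequencing error**: each observed index base substitutes to
   one of the other three bases with probability `index_error_rate`;
   miscalled cycles get `quality_low` (default Q11), all others
   `quality_high` (default Q37). The two-level quality model is
   deliberately simple; it exists to exercise the downstream quality
   filter, not to model instrument quality profiles.
6. **Tile** assigned uniformly over a `surfaces x swaths x tiles` grid
   (default 2 x 2 x 24, a HiSeqX-like lane), reflecting the observed
   near-uniform spatial distribution of swaps.
7. **Chimerism** with probability `chimera_rate_swapped` (default 0.05)
   if either end swapped, else `chimera_rate_base` (default 0.01).

All draws come from one seeded generator in a fixed order, so a
configuration plus seed reproduces byte-identical output.

## Parameter defaults and what they emulate

* `p_swap_i7 = 0.0131`, `p_swap_i5 = 0.0302`: the per-end rates
  estimated for a PCR-free two-organism pool; the i5 end swaps roughly
  twice as often as i7. Both are free parameters — lower them an order
  of magnitude for a PCR-plus-like regime.
* `insert_mean_log = log(350)`, `insert_sd_log = 0.25`: a typical
  PCR-free genome insert distribution (~350 bp median).
* `gc_beta_a = 8`, `gc_beta_b = 11.5`: mean GC ≈ 0.41 with realistic
  spread for human genomic fragments.
* `swap_length_coeff = -0.3`, `swap_gc_coeff = -0.2`: negative
  coefficients make short, AT-rich fragments swap more, the direction
  observed in real swapped populations (shorter inserts, depleted
  high-GC bins). Only the *direction* is empirically grounded; the
  reported summaries give no effect size, so the magnitudes are free
  parameters chosen to produce a visible but moderate shift, and the
  package's directional tests hold for any negative value.
* `index_error_rate = 0.001`: a high-quality index read regime (~Q30
  aggregate error mass concentrated in occasional miscalls).

What the simulator does **not** model: genomic read sequences and
alignment (organism labels come from truth or user annotation, mirroring
the assumption that reads map correctly to their organism of origin),
ExAmp kinetics mechanistically, per-cycle quality decay, or
spatially structured swapping. Passing tests therefore demonstrate the
correctness of the counting and estimation machinery under the stated
model, not that real flow cells obey it.

# Demultiplexing and classification

`classify_reads()` applies three stages in a fixed order, stated
explicitly because the order changes denominators:

1. **Quality**: a read whose i7 *or* i5 index read has mean Phred below
   `min_mean_q = 30` is `LOW_QUALITY` and is excluded before matching,
   so low-quality reads never enter swap statistics. Mean (rather than
   per-base minimum) quality is the declared interpretation of the
   "Q30 or greater" filter.
2. **Matching**: each observed index is compared to its end's list with
   `match_index()`; a unique candidate within `max_mismatch = 1` Hamming
   distance resolves, no candidate gives no-match, and a second
   qualifying candidate makes the call ambiguous. Ambiguity folds into
   `UNDETERMINED` — conservative, no tie-breaking invented. One
   mismatch is safe for sets with pairwise distance ≥ 3.
3. **Pair consistency**: both ends resolving to one sample is
   `MATCHED`; to two different samples, `SWAPPED` with the owning
   samples recorded per end; anything else `UNDETERMINED`. Reads with
   indexes from outside the pool thus never reach the count matrix —
   which is exactly what makes "no outside contamination" an observable
   statement.

A double swap landing on another sample's valid pair is classified
`MATCHED`: it is genuinely indistinguishable at demultiplexing and is
recovered only by the mixture design below.

`swap_rate()` divides off-diagonal by (diagonal + off-diagonal) counts:
the denominator is passing-filter reads whose high-quality index reads
both match pool indexes, excluding undetermined and low-quality reads.

# End attribution in a two-organism mixture

With samples split between two organisms and each read's mapping
organism known, index owners identify the swapped end: a foreign-organism
index must have swapped on, an own-organism index is assumed retained.
Writing $R$ for the read's organism and $O_7, O_5$ for the organisms
owning its resolved indexes:

| pair status | owners | class |
|---|---|---|
| matched | $O_7 = O_5 = R$ | non-swap |
| matched | $O_7 = O_5 \neq R$ | double swap (wrong organism's valid pair) |
| swapped | $O_7 = O_5 = R$ | undetermined end (within-organism swap) |
| swapped | $O_7 \neq R$, $O_5 = R$ | i7 swap |
| swapped | $O_7 = R$, $O_5 \neq R$ | i5 swap |
| swapped | $O_7 \neq R$, $O_5 \neq R$ | double swap |

The estimator allocates the $U$ undetermined-end swaps to the ends in
the ratio of the known counts and credits double swaps to both ends:

$$\hat{T}_7 = \frac{K_7}{K_7+K_5}U + K_7 + D, \qquad
  \hat{T}_5 = \frac{K_5}{K_7+K_5}U + K_5 + D,$$

$$\hat{p}_7 = \hat{T}_7 / N', \qquad \hat{p}_5 = \hat{T}_5 / N', \qquad
  N' = \text{non-swap} + U + K_7 + K_5 + D.$$

The allocation is exact in aggregate
($\hat{T}_7 + \hat{T}_5 = U + K_7 + K_5 + 2D$, a tested invariant) and
unbiased when the within- and cross-organism swap channels share the
same end ratio — true by construction here and plausibly in practice,
since the replacement index does not depend on which end swapped. No
smoothing or prior is applied to the allocation ratio.

Two deliberate reporting choices:

* When an independently tallied total-swapped count is supplied next to
  the component counts, `estimate_attribution()` computes the overall
  swap probability from the supplied totals *and* from the components,
  and the print method flags any discrepancy rather than silently
  choosing — reported tallies and component rows do not always agree.
* Probabilities are kept at full precision; only display rounds
  (half-up, 4 decimals) to match how such tables are printed.

**Known estimator bias.** A read carrying two swap events that is not
classified `DOUBLE_SWAP` (e.g. a detectable cross-organism i7 swap on a
read whose i5 also swapped within its organism) contributes one counted
event where two occurred. At per-end rates of a few percent this biases
the recovered rates down by order $p_7 p_5$ — at the defaults, roughly
0.5% of the estimate, well inside sampling noise at $10^6$ reads. The
parameter-recovery tests account for the larger, structural
undetectability of self-replacement instead: the recoverable rate at
$S$ equal samples is $p (S-1)/S$.

# Index set design and validation

`validate_dual_index_set()` checks, in order: per-end uniqueness (the
definition of non-redundancy), per-end minimum pairwise Hamming distance,
GC window, homopolymer runs, and per-cycle color balance. The ends are
validated separately because swapping is a within-end phenomenon.
Defaults — distance ≥ 3, GC in [0.25, 0.75], homopolymer ≤ 2 — are
conventional synthesis/sequencing robustness values, declared rather
than extracted from any vendor guideline: distance 3 guarantees that
one sequencing error cannot move an index within one mismatch of a
different sample's index.

Color balance is chemistry-specific and configurable: on two-color
instruments G is dark, so each cycle must light the red ({A, C}) and
green ({A, T}) channels somewhere in the set; four-color instruments
need both laser pairs {A, C} and {G, T}. Both rules are plain
predicates over a cycle's base set and can be replaced via
`index_constraints(color_rule = ...)`.

`design_index_set()` uses seeded rejection sampling with greedy
accumulation (budget 10,000 proposals per slot) — simple and reproducible
at the scales that matter (n ≤ 96). Because color balance is a property
of the whole set that a greedy accept/reject step cannot evaluate, a
repair pass follows: single sequences are re-proposed and swapped in
only when they strictly reduce the number of unbalanced cycles, which
converges because adding base diversity to a cycle never unbalances
another. Validation is then re-run as the oracle. Two degenerate cases
worth knowing: a one-sample set cannot satisfy four-color balance (one
base cannot light both laser pairs), so tiny design calls should disable
the balance check; and balance, unlike the pairwise constraints, is not
monotone under deleting entries from a passing set.

# Numerical and implementation choices

* **Problem sizes.** The package's statistical tests run at $10^4$ to
  $2 \times 10^5$ reads; the end-to-end parameter-recovery checks use
  $10^6$ reads over five seeds, matching the scale at which 3-standard-
  error bounds on rates of 1–3% become meaningful. These sizes are the
  package's own validation design.
* **Vectorized in-memory processing.** Reads are columns of a tibble,
  processed whole; at $10^6$ reads this is a few hundred MB at peak and
  far faster in R than streaming record-by-record. Files (FASTQ pairs,
  truth TSVs) are the interface between pipeline stages.
* **Matching** is exact vectorized Hamming comparison over unique
  observed sequences; no seed-and-extend heuristics, so oracle
  equivalence with an exhaustive scan is exact.
* **Tie-breaks**: none — ambiguity at matching is surfaced as
  `UNDETERMINED`, and the estimator refuses allocation when
  $U > 0$ with $K_7 + K_5 = 0$ rather than inventing a ratio.
* **Degenerate inputs**: empty read streams produce valid empty FASTQ
  files and zero-row tibbles; a tally with no qualifying reads makes
  `swap_rate()` an error, not a zero; empty populations in
  `compare_populations()` report `NA` markers, and empty flow-cell tiles
  render blank rates, never zeros.
* **Determinism**: every stochastic function takes a seed and restores
  the caller's RNG state (`withr::with_seed`); pipeline reports are
  identical across runs up to their timestamp.

# Limitations

* The attribution estimator supports exactly two organisms; other
  designs error by intention.
* Organism labels are inputs (simulation truth or annotation); the
  package does not align reads.
* The covariate model is a logistic link in two standardized covariates
  with user-set coefficients; it reproduces observed directions, not
  measured effect sizes.
* Index-error correction beyond unique-within-distance matching
  (e.g. likelihood-based assignment using qualities) is out of scope.
* GC-spectrum comparison uses fixed 0.05-width bins over [0, 1]; very
  small populations leave bins empty (`NA` ratios) rather than being
  smoothed.
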