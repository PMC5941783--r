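# indexhop

Index swapping (index hopping) is a failure mode of pooled sequencing on
patterned flow cells with exclusion-amplification (ExAmp) chemistry
(HiSeqX, HiSeq 4000/3000, NovaSeq): residual free adapter in the pool can
extend a library fragment with another sample's index during clustering,
so the read demultiplexes to the wrong sample. With **non-redundant dual
indexing** — every sample owning an i7 sequence used by no other sample
and an i5 sequence used by no other sample — a single swapped end always
produces an *unexpected* index combination, so swapped reads can be
flagged, counted and filtered instead of silently contaminating other
samples.

`indexhop` is an R toolkit for characterizing this phenomenon. It is
aimed at sequencing-core and methods people who want to (i) design and
validate non-redundant dual-index sets, (ii) quantify swapping in index
read data, and (iii) study swap mechanisms with a fully controlled
simulator. Everything is data-frame-first and pipe-friendly.

## What it computes

For a pool of *S* samples, classified index-read pairs fill an
*S* × *S* count matrix indexed by (i7 owner, i5 owner): the diagonal
holds correctly paired reads, every off-diagonal cell is a detectable
swap. The overall detectable swap rate is

```
p(total swap) = (off-diagonal sum) / (diagonal + off-diagonal sum)
```

over reads passing a mean-Q30 index-quality filter and matching pool
indexes on both ends.

To attribute swaps to a specific adapter end, a pool mixes samples from
two organisms. A read's mapping organism identifies which index stayed
with its fragment, giving counts of known i7 swaps (K7), known i5 swaps
(K5), double swaps (D), and within-organism swaps whose end is
unknowable (U). Undetermined swaps are allocated proportionally:

```
est_i7 = K7/(K7+K5) * U + K7 + D      est_i5 = K5/(K7+K5) * U + K5 + D
p(i7 swap) = est_i7 / N'              p(i5 swap) = est_i5 / N'
```

with N' = non-swapped + U + K7 + K5 + D the qualifying reads. The
allocation conserves events exactly: `est_i7 + est_i5 = U + K7 + K5 + 2D`.

The simulator generates index-read pairs under a free-adapter model —
each end swaps independently at its own rate, the replacement index is
drawn from the pool by abundance (self-replacement is an undetectable
swap) — with per-base index errors and swap-correlated fragment
covariates (shorter inserts, lower GC, more chimerism among swaps).

## Worked example

Design a 6-plex non-redundant set, simulate a pooled run, demultiplex
and tally:

```r
library(indexhop)

sheet <- design_index_set(6, index_constraints(min_hamming = 3), seed = 5)
reads <- simulate_pool(sheet, n_reads = 100000, seed = 42)
classified <- classify_reads(reads, sheet, max_mismatch = 1, min_mean_q = 30)
tally <- tabulate_reads(classified, sheet)
tally
#> Swap tally over 100000 reads (6 samples, 36 index combinations)
#>   matched 96263 | swapped 3726 | undetermined 11 | low quality 0
#>   swap rate (qualifying reads): 0.0373
```

96,263 reads carried their own sample's expected pair; 3,726 carried a
mixed pair of two different samples' indexes (detectable swaps, here
~3.7% because the simulator defaults to PCR-free-like per-end rates of
1.31% and 3.02%); 11 reads failed to match the pool within one mismatch.
`autoplot(tally)` draws the 36-cell combination heatmap,
`plot_tile_rates(tally)` the flow-cell tile map.

Feeding the reference mixture experiment's counts straight into the end
estimator:

```r
att <- estimate_attribution(
  non_swapped = 807029454, undetermined = 17136498,
  known_i7 = 5300327, known_i5 = 12697618, double_swaps = 689363,
  total_pf = 842853260, total_swapped = 34219842)
att
#> Two-organism mixture swap attribution
#>   Qualifying reads (N'):            842,853,260
#>   ...
#>   Estimated total i7 swaps:         11,036,324
#>   Estimated total i5 swaps:         25,476,845
#>   p(i7 swap) = 0.0131   p(i5 swap) = 0.0302   p(total swap) = 0.0406
```

The i5 end swaps about twice as often as i7. `tidy(att)` and
`glance(att)` return the quantities as tibbles.

A full simulated mixture experiment is one call:

```r
sheet24 <- design_index_set(24, index_constraints(min_hamming = 3), seed = 104729)
orgs <- setNames(rep(c("human", "ecoli"), each = 12), sheet24$sample_id)
report <- run_pipeline(sheet24, n_reads = 1e6, organism_of = orgs, seed = 1)
report$attribution
```

A thin command-line wrapper with `design-indexes`, `validate-indexes`,
`simulate`, `demux`, `attribute` and `run` subcommands lives at
`inst/cli/indexhop.R`.

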