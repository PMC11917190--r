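# fourcre

Analysis of one-viewpoint chromosome-conformation (4C-seq) experiments:
from an in-silico NlaIII/DpnII fragment map to called viewpoint
interactions (potential cis-regulatory elements, pCREs), their
shared/gained/lost classification across cell lines, permutation-based
histone-mark overlap enrichment, rebinned correlation analysis, and de
novo k-mer motif discovery. The package is aimed at regulatory-genomics
analysts who have per-fragment 4C read counts (post-alignment) and ChIP
peak sets, and at method developers who need a fully simulated,
ground-truth-known version of such an experiment.

## The model

A 4C viewpoint profile decays with genomic distance. Per valid
NlaIII-DpnII fragment end at signed distance *d* from the viewpoint, the
package models the smoothed, library-size-normalized signal *s(d)* as a
non-increasing background *b(|d|)* plus localized enrichments. The
background is the isotonic (pool-adjacent-violators) least-squares fit

&nbsp;&nbsp;min Σ (s<sub>i</sub> − b<sub>i</sub>)² subject to
b<sub>1</sub> ≥ b<sub>2</sub> ≥ … (per arm, ordered by |d|),

fitted separately upstream and downstream over every fragment within
±1 Mb. A fragment is called interacting when all four criteria hold:

1. its smoothed signal exceeds b in **every** replicate;
2. its replicate-mean signal exceeds 2.5% of b at the viewpoint-adjacent
   fragment;
3. its log-ratio z-score log((s+ε)/(b+ε)) / σ<sub>arm</sub> reaches 3,
   where σ<sub>arm</sub> is the sigma-clipped residual scale;
4. its local coverage score (fraction of covered fragment ends in a
   30-fragment window) reaches the upper quartile.

Called fragments at most 40 bp apart merge into pCREs. Downstream, pCREs
are classified against baseline cell lines (shared / gained / lost),
tested for overlap enrichment against ChIP peak sets by uniform
re-placement permutation (empirical p = (1 + #{null ≥ obs})/(1 + n),
Benjamini-Hochberg FDR across the family), correlated after 100 bp
percentile rebinning, and mined for over-represented 6/7-mers with an
exact binomial tail on duplex occurrences.

Every stage is driven by a seeded simulator (`sim_config()`,
`simulate_genome()`, `simulate_4c_counts()`, `simulate_chip_peaks()`)
that emits FASTA/bedGraph/BED/JSON and plants interactions, site
densities and peak-overlap fractions with known ground truth.

## Worked example

Simulate a 2 Mb locus with two planted interactions (8-fold, ~21
fragments wide) at 600 kb and 1.15 Mb, call interactions, and compare
with the planted truth:

```r
library(fourcre)

cfg <- sim_config(seed = 42, planted_interactions = list(
  list(center = 6e5,    half_width = 10, fold = 8),
  list(center = 1.15e6, half_width = 10, fold = 8)))
genome <- simulate_genome(cfg)
fmap <- filter_fragments(digest(genome), viewpoint = cfg$viewpoint_pos)
fmap
#> NlaIII/DpnII fragment map: 4800 fragments on chrS (2000000 bp)
#>   valid: 2178  blind: 2408  viewpoint: 1e+06

sim <- simulate_4c_counts(fmap, cfg)
profiles <- lapply(names(sim$counts), function(r)
  prepare_profile(sim$counts[[r]], fmap, replicate = r))
replicate_correlation(bin_counts(profiles[[1]]), bin_counts(profiles[[2]]))$r
#> [1] 0.9401978

calls <- call_fragments(profiles)
sum(calls$significant)
#> [1] 61
pcres <- merge_to_pcres(calls, cell_line = "simulated")
evaluate_recovery(pcres, sim$truth, margin = smoothing_margin(fmap))[1:2]
#> $sensitivity
#> [1] 1
#> $precision
#> [1] 0.969697
```

The fragment map keeps 2,178 of 4,800 fragments after removing blind
(same-enzyme-flanked), short (<40 bp) and viewpoint-proximal (±5 kb)
fragments. The two replicates correlate at r = 0.94 over 5 kb bins; the
caller marks 61 of 2,178 candidate fragments, which merge into pCREs
that recover both planted interactions, with 97% of called regions lying
within the smoothing resolution of a planted interaction.

`run_pipeline()` chains all stages (profiles → calls → classes →
enrichment → correlation → motifs) from one seeded YAML/list config and
writes BED/TSV/JSON artifacts plus a manifest;
`inst/scripts/run_pipeline.R` wraps it for the shell.

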