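---
title: "Calling viewpoint interactions and regulatory elements from 4C-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling viewpoint interactions and regulatory elements from 4C-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourcre)
```

# Scope

`fourcre` implements a complete one-viewpoint 4C-seq analysis: fragment-map
construction by in-silico double digestion, viewpoint-profile processing,
interaction calling against a monotone distance-decay background, merging of
interacting fragments into potential cis-regulatory elements (pCREs),
differential (shared/gained/lost) classification across cell lines,
permutation-based overlap enrichment against ChIP peak sets, fixed-width
percentile rebinning with pairwise Pearson correlation, and de novo k-mer
motif over-representation. A seeded simulator generates genomes, replicated
count profiles and peak sets with known ground truth, so every downstream
stage is testable without external data.

Sequencing-read alignment, peak calling from raw ChIP reads, full genomic
annotation hierarchies and motif-database comparison are out of scope: the
package consumes aligned counts (bedGraph/BED) and peak sets (BED), and
emits count matrices rather than database matches.

# The fragment map

4C signal lives on restriction fragments. `digest()` cuts the genome with
NlaIII (CATG) and DpnII (GATC), mirroring enzyme chemistry: NlaIII cuts at
the *end* of its motif (leaving a 3′ CATG overhang), DpnII at the *start*
(5′ GATC overhang). Fragments tile `[0, L)` half-open and 0-based, BED
bit-compatible; each carries its flanking enzymes. When both enzymes cut the
same coordinate (a `CATGGATC` junction), the boundary is labelled with the
primary enzyme.

`filter_fragments()` flags rather than deletes, so filtering is auditable:

* **blind fragments** — flanked by the same enzyme on both sides — carry no
  usable ligation junction;
* fragments **shorter than 40 bp** (length 40 is kept: the filter removes
  strictly smaller fragments);
* fragments overlapping the **viewpoint exclusion zone** (±5 kb) by any
  amount. The zone is half-open, so a fragment starting exactly at
  `viewpoint + 5000` survives. Any-overlap is the conservative reading of
  "within ±5 kb"; midpoint-based exclusion can be emulated by shrinking the
  window.

A valid NlaIII–DpnII fragment has exactly one NlaIII end — the half of the
fragment abutting the NlaIII cut. Reads are accounted per NlaIII fragment
end; a record anywhere within a valid fragment is summed into that end, so a
fragment's signal equals the sum of its end counts.

# Viewpoint profiles

`load_counts()` assigns bedGraph records (or BED read positions) to
fragments by record midpoint, drops records landing in invalid fragments
(logged, never silently), and errors on malformed records with the line
number, on empty input, and when nothing is assignable.

`normalize_profile()` scales to a fixed library size (default 10^6 over
valid ends — "per million ends"; the upstream literature does not fix a
constant, so the default makes profiles comparable across replicates and
the 2.5% viewpoint-fraction criterion scale-free).

`smooth_profile()` applies a centered mean running window of 30 fragment
ends. The even width is split 15 left + self + 14 right; near the array
edges both reaches shrink symmetrically (to `min(i−1, n−i)`), which avoids
propagating missing values into the caller at the cost of less smoothing in
the outermost fragments. A centered (rather than trailing) window was
chosen because interaction calls should not be systematically shifted
toward the viewpoint.

`bin_counts()` sums normalized counts into 5 kb bins across ±1 Mb (400
bins, assignment by end midpoint), the scale used for replicate
reproducibility (`replicate_correlation()`, Pearson's r; an r above ~0.9 is
typical for the simulator's default settings and for deeply sequenced real
libraries).

# The interaction caller

## Background model

4C counts decay with distance but not parametrically so. The background is
therefore the least-squares **non-increasing isotonic regression** of the
replicate-mean smoothed signal on absolute distance, fitted separately per
arm (upstream/downstream), because real viewpoints decay asymmetrically.
The solver is the classical pool-adjacent-violators algorithm
(`pava_nonincreasing()`, weighted); its output is exact, deterministic, and
verified in the test suite against an exhaustive block-partition oracle and
`stats::isoreg`.

## The four criteria

A fragment within ±1 Mb is called interacting if and only if:

1. **Reproducibility** — its smoothed signal exceeds the fitted background
   in *every* replicate (at least two replicates are required; a single
   replicate is an error, not a warning).
2. **Viewpoint fraction** — its replicate-mean smoothed signal exceeds
   2.5% of the fitted background at the viewpoint-adjacent fragment
   (`b_vp`). Testing the observed mean against a fraction of the *fitted*
   viewpoint value makes the criterion reproducible and library-size-free.
3. **Signal-to-noise** — see below.
4. **Local coverage** — the fraction of covered (nonzero raw count)
   fragment ends in a centered 30-fragment window must reach the upper
   quartile of all candidate fragments in the ±1 Mb window. The 30-fragment
   scale matches the smoothing scale; computing the quartile over the
   window (not genome-wide) keeps the criterion local to the analyzed
   region. With saturated coverage the quartile threshold is reached by
   construction and the criterion is inert — it exists to guard sparse
   libraries.

## The signal-to-noise criterion in detail

The source method requires signal "high enough to ensure an adequate
signal-to-noise ratio" without fixing a statistic. Two facts shape the
implementation:

* Overdispersed count noise scales with the mean: under the
  negative-binomial model with dispersion k, the coefficient of variation
  tends to 1/√k for large means, so absolute residuals near the viewpoint
  dwarf those 1 Mb away. A single per-arm residual sd on the linear scale
  is then dominated by the near-viewpoint fragments, and distal
  interactions become undetectable while near-viewpoint noise is called.
  The default criterion therefore scores **log-ratio residuals**
  `log((s+ε)/(b+ε))`, which are variance-stabilized under mean-proportional
  noise. The pseudocount ε is four orders of magnitude below the fitted
  viewpoint background, i.e. negligible everywhere the profile carries
  signal.
* Genuine interactions are part of the residuals and inflate a naive sd —
  the noise scale must be estimated robustly. A median-based scale (MAD)
  fails here because isotonic residuals contain exact zeros (singleton
  PAVA blocks), deflating the estimate. The package instead uses
  **iterative one-sided sigma clipping**: residuals above 3 sd are
  excluded and the sd re-estimated until the kept set stabilizes.
  Clipping only the positive tail removes candidate signal while leaving
  the (roughly symmetric) noise distribution — and hence the false-call
  calibration — essentially untouched.

The default threshold is z ≥ 3 (the three-sigma rule). A one-sided
two-sigma rule cannot keep the per-fragment false-call rate below 1% on
background-only data (≥ 2.3% under any near-Gaussian null); with z = 3 the
measured background-only call rate under the simulator's default
conditions is ~0.6–0.8%. Both the scale (`snr_scale = "linear"`) and the
threshold (`snr_k`) are exposed in `caller_config()`.

## Merging and resolution

Called fragments separated by at most 40 bp merge into pCREs
(`merge_to_pcres()`; a 41 bp gap stays split). Because calls are made on a
30-fragment smoothed profile, no call can be localized more precisely than
about half a smoothing window (~10 kb at the simulator's default fragment
density). `evaluate_recovery()` therefore matches planted interactions to
pCREs after padding the planted intervals by `smoothing_margin()` — calls
on the smear shoulders of a true interaction are attributed to it rather
than counted as false positives, while calls further away still count
against precision.

# Differential classification

`classify_pcres()` anchors classes on the expressing cell line: a pCRE of
the expressing line overlapping (≥ 1 bp by default) any baseline-line pCRE
is **shared**; otherwise **gained**. Baseline pCREs are merged across
baseline lines (so each distinct region counts once) and those overlapping
no expressing-line pCRE are **lost**. The three classes partition the
distinct merged regions across all lines — a property the tests verify
against a brute-force oracle on random region sets. One-bp overlap (not
reciprocal overlap) defines "present in", since region identity across
cell lines is not otherwise defined; `min_overlap` is configurable.

Distance classes split at the pCRE midpoint's absolute distance: near-cis
below 0.2 Mb, medium-cis from 0.2 to 0.5 Mb inclusive (both boundaries
assigned to medium), far-cis beyond 0.5 Mb. Trans pCREs are an error — the
analysis is cis-only by construction. `distance_density()` draws Gaussian
kernel densities per class (each integrating to 1), and
`annotate_promoter()` labels pCREs promoter/exonic/non-coding with
promoter > exonic precedence, using strand-aware TSS windows
(−1000/+100 bp by default).

# Permutation overlap enrichment

`permutation_enrichment()` compares the observed number of query regions
overlapping a reference peak set against a null built by re-placing each
query region uniformly at random in the universe, preserving lengths and
permitting collisions — the simplest exactly-specifiable null. The default
universe is the ±1 Mb analysis window, where the pCREs live. The empirical
p-value uses the add-one estimator `(1 + #{null ≥ obs})/(1 + n)` (10,000
permutations by default), so p is never zero and the test is valid at
finite n; the z-score `(obs − mean_null)/sd_null` is reported alongside
(undefined when the null is degenerate, and reported as such). Depletion
is the mirrored tail; for the discrete null, `p_enr + p_dep ≥ 1`.

Multiple testing is corrected by Benjamini–Hochberg across all tests of
one `enrichment_table()` invocation — the analysis family. FDR < 0.05 is
read as significant. When several ChIP replicates exist for one mark and
cell line, mean z and mean FDR are reported across replicates
(`aggregate_replicates()`).

# Rebinning correlation

`rebin()` tiles a chromosome into 100 bp bins with the ceiling convention
(the final partial bin is kept) — a 170,805,979 bp chromosome yields
exactly 1,708,060 bins. Within each sample, region scores become
standardized percentiles (average-tie rank divided by the region count,
values in (0, 1]); every overlapped bin takes the percentile, maximum on
collision so the strongest signal per locus survives. Percentiles are
computed within-sample, keeping each sample's values comparable regardless
of its score scale. Bins no sample touches are removed (`drop_empty()`,
which also reports sparsity), and `pearson_matrix()` returns the pairwise
correlations with an average-linkage clustering order on 1 − r for
display; zero-variance samples yield missing correlations rather than
errors.

# Oligo motif analysis

`count_oligos()` scans both strands with overlapping windows (windows
containing N are skipped) and collapses each k-mer with its reverse
complement into a canonical class, so one duplex occurrence contributes 2
to its class. `oligo_enrichment()` computes expected counts under an
order-0 background (estimated from the input by default — the usual choice
for small inputs — or user-supplied/uniform) and an upper-tail binomial
p-value. Because occurrences arrive in strand pairs, the binomial tail is
evaluated on duplex occurrences (observed/2 successes in
scanned-positions/2 trials); testing the doubled counts against a binomial
of doubled size would double the variance and overstate significance.
E-values multiply p by the number of canonical classes tested (2,080 for
k = 6; 8,192 for k = 7). Overlapping-occurrence dependence is ignored, as
in classical oligo-analysis — a known, slight miscalibration for
self-overlapping words.

`assemble_matrices()` reduces significant oligos greedily: the pair of
units with the longest exact overlap (≥ k − 2, both orientations
considered) merges first, count-weighted column-wise, until no eligible
pair remains; results serialize to MEME minimal and TRANSFAC-like count
formats. This is a deliberate simplification of full matrix-clustering:
adequate for collapsing near-duplicate oligos, not a substitute for motif
alignment against curated databases.

# The simulator: what it does and does not emulate

`simulate_genome()` draws uniform random DNA, then plants or knocks out
CATG/GATC occurrences by substitution until their densities match the
configured per-kb rates (within ~2%), guaranteeing digestible maps even
for small test genomes. `simulate_4c_counts()` gives fragment end *i* at
distance d the expected count

&nbsp;&nbsp;μ(d) = A · (1 + |d|/s)^(−α),

times the fold-enhancement of any planted interaction covering it, and
draws counts independently per replicate from a negative-binomial with
dispersion k (variance μ + μ²/k; k = ∞ gives Poisson).
`simulate_chip_peaks()` places a controlled fraction of peaks on distinct
query regions and the rest uniformly. All randomness flows from the config
seed; identical configs give byte-identical outputs.

Defaults describe the study conditions the package is validated under,
chosen once as a realistic deeply-sequenced viewpoint: a 2 Mb locus with a
centered viewpoint; 1.2 NlaIII and DpnII sites/kb (about 2,200 valid
fragments in ±1 Mb, i.e. ~900 bp resolution); amplitude 300 with α = 1 and
s = 20 kb (a 40-fold decay from 5 kb to 1 Mb, leaving distal fragments
covered); NB dispersion 5 (strong overdispersion, CV ≈ 0.45); two
replicates. The empirical dispersion of real libraries is not published
for this protocol, so k is a free parameter.

The simulator emulates monotone decay, replicate noise, planted
enrichments and peak-overlap designs. It does **not** emulate
ligation-junction or PCR artifacts, undigested/partially digested
chromatin, mappability gaps, trans contacts, or domain-structured
(TAD-like) backgrounds. Passing recovery tests therefore demonstrate
correctness of the algorithms under the stated noise model, not
performance on every pathology of real libraries.

# Numerical choices and degenerate inputs

* PAVA: exact block pooling, no tolerance parameters; ties in |distance|
  are processed in genomic order.
* Smoothing edges: symmetric shrinkage (see above); profiles shorter than
  the window are an error.
* All-zero profiles cannot be normalized (error); zero-variance binned
  vectors give an undefined replicate correlation, reported as `NA` with a
  warning.
* σ = 0 arms (e.g. constant profiles) make the z-criterion degenerate;
  the caller then falls back to requiring positive excess over the
  background.
* Coverage quantile uses R's default (type 7) quantile; ties at full
  coverage make criterion 4 inert by construction.
* `quantile`-scale percentiles in `rebin()` use average ranks, so tied
  scores share a percentile.
* Distance-density bandwidths fall back to 1% of the (single) distance
  when a class has zero variance.
* Config files reject unknown keys outright rather than ignoring typos.

# Problem sizes used in the tests

The shipped test-suite and acceptance script validate, per run: 200
random vectors (length ≤ 12) against the exhaustive isotonic oracle; 20
simulated loci (2 Mb, ~2,200 valid fragments, 3 planted interactions of
fold 8) plus 20 background-only loci for caller recovery and false-call
rate; 100 random region-set triples for the classification partition; 10
planted-enrichment and 200 null-design permutation runs at 1,000
permutations each; 1,000 random p-vectors for BH monotonicity; a planted
6-mer (20 copies in 2 kb) and 50 uniform 10 kb sequences for oligo
calibration. These sizes were chosen so the full suite exercises every
operating characteristic at Monte-Carlo precision adequate for the
asserted bounds.

# Known limitations

* The caller tests each fragment marginally; no explicit FDR is attached
  to a pCRE (the source method does not either).
* The isotonic background partially absorbs broad near-viewpoint
  interactions into its plateau, shrinking their effective signal — an
  inherent cost of a monotone background shared by all callers of this
  family.
* Uniform-replacement permutation ignores chromatin accessibility and
  masked regions; circular or mask-aware randomization is not
  implemented.
* Oligo p-values ignore word self-overlap dependence.
* The greedy matrix assembly is order-dependent for exact ties (resolved
  deterministically, first pair wins).
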