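---
title: "Methods: landmark peak calling, motif vectorization and cluster-linked expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark peak calling, motif vectorization and cluster-linked expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures implemented in
`peakshift`, the assumptions behind them, the parameters a user may want
to change, and the design choices made where several reasonable options
existed. Nothing here states an empirical result beyond what the test
suite and `scripts/acceptance.R` compute.

## Data model

Coverage is stored *binned*: a depth track is a tibble of
(`chrom`, `bin`, `depth`) with a `bin_size` attribute (default 10 bp),
and a multi-sample experiment adds `sample` and `group` columns
(`"control"` / `"mutant"`). All genomic coordinates exposed by the
package are 0-based half-open, the bedGraph convention; conversions to
the 1-based closed convention of `GenomicRanges` happen only inside IO
and linking code. Strand is ignored for depth and peaks (ChIP coverage
is unstranded); gene strand is retained for reporting only.

Binning replaces per-base resolution for three reasons: the peak model
operates on a smoothed signal anyway, memory stays bounded on long
chromosomes, and a 10-bp bin is far below the width of any peak the
detector can represent. Re-binning of bedGraph intervals uses the
coverage-weighted mean with uncovered basepairs contributing zero, which
conserves total mass (depth × bp) exactly.

## Peak detection

The caller works on the *pooled* track — the per-bin mean across every
sample of both groups. Pooling is symmetric between the groups, so it
cannot bias the subsequent differential classification, and it maximizes
the depth available to detect peaks present in either condition. A
per-group union mode was considered and rejected as the default because
it produces duplicated, slightly shifted intervals that the downstream
[Dp] comparison must then reconcile.

1. **Smoothing.** Centred moving average, window `window_bins` (odd,
   default 5 bins = 50 bp). Edge bins average over the available bins,
   so output length equals input length. The default suppresses Poisson
   noise at backgrounds of a few reads per bin without flattening peaks
   hundreds of bp wide.
2. **Landmarks.** Local minima and maxima of the smoothed signal, plus
   *slope changes*: bin `i` is a landmark when the consecutive first
   differences `s_{i-1}`, `s_i` are both nonzero, share a sign, and
   their ratio exceeds `slope_factor` (default 2) or its reciprocal.
   Zero slopes break eligibility (no division by zero, no landmarks on
   flats). Plateau runs of equal values yield one extremum at the run's
   centre (left-centre on even runs). Track ends always count as minima
   so peaks truncated at contig edges remain representable; an end
   strictly above its neighbour additionally counts as a maximum.
3. **Candidates.** Every triple (start, apex, end) with the apex a
   maximum landmark, the endpoints minimum or slope-change landmarks,
   and the smoothed depth attaining its interval maximum at the apex.
   The baseline is the mean smoothed depth at the two endpoints; the
   candidate's `max_excess` is the apex depth above baseline and its
   `integrated_excess` the sum of positive baseline-subtracted depth
   over the interval.
4. **Filtering.** Strictly `max_excess > 2.5` (depth units) and
   `integrated_excess > 5.0` (depth × bins). Both thresholds are strict
   and boundary values are rejected. By default the 2.5 threshold is
   applied to the baseline-subtracted maximum — the reading under which
   the baselines defined in the previous step actually do something — a
   raw-depth mode is available (`baseline_relative = FALSE`).
5. **One peak per summit.** Many admissible triples share an apex. Among
   them the retained candidate maximizes the *matched-filter score*
   `net_excess / sqrt(width)`, where `net_excess` is the unclipped sum
   of baseline-subtracted depth. Under white noise this ratio is
   proportional to the z-score of the integrated signal, so it selects
   the interval at which the summit is detected most confidently —
   empirically about ±1.5 SD of a Gaussian bump. A rule that maximizes
   `integrated_excess` itself was rejected: because the clipped integral
   accumulates the positive part of noise, it grows without bound with
   interval width over a flat background, and the widest admissible
   candidate always wins. Ties go to the wider, then the leftmost
   candidate. Finally, summits whose interval overlaps a
   higher-scoring kept summit by at least half the shorter interval are
   suppressed; these are secondary noise maxima on the flanks of a
   single underlying peak.

`enumerate_candidates()` is exhaustive and is the object of the
brute-force equivalence tests. `call_peaks()` computes the same
composition at genome scale without materializing every candidate: per
apex, the admissible endpoint ranges are delimited by the nearest
strictly higher bins, scores are prefix-sum arithmetic, and the clipped
integral is evaluated exactly only where its lower bound (the unclipped
sum) cannot already decide the filter. Genome-scale calling caps the
candidate width at `max_width_bins` (default 500 bins = 5 kb at 10-bp
bins), a generous bound for nucleosome-mark peaks; enumeration on small
tracks is unaffected.

## Differential classification

For each peak, `[Dp]` is the mean *unsmoothed* depth over the peak's
bins, first averaged per bin across a group's samples. Smoothing guides
peak geometry only; the group comparison uses the measured depth. With
strict inequalities, a peak is `PEAKS_2_0` when
`[Dp]_ctrl < 0.5 × [Dp]_mut`, `PEAKS_0_5` when
`[Dp]_ctrl > 2 × [Dp]_mut`, else `UNCHANGED`. The formulation avoids
ratios entirely, so zero depths need no special casing: both means zero
is `UNCHANGED`, a zero control with positive mutant depth is `PEAKS_2_0`.

The default compares against the pooled mutant mean — the weakest
consistent reading of "each mutant line" — and `all_lines = TRUE`
requires the inequality against every mutant sample individually.
Swapping the two groups exchanges the two labels exactly (an invariant
the tests assert). Replicate-aware statistical testing is deliberately
out of scope: the rule is a deterministic ratio threshold.

## Motif catalogue and frequency vectors

The built-in finder tests, for each k in `k_range` (default 5–9), every
k-mer observed in the foreground sequences for presence/absence
enrichment against a background (by default the letter-shuffled
foreground, preserving mononucleotide composition). The one-sided Fisher
exact p-value of the 2×2 presence table is computed as the
hypergeometric tail, Bonferroni-corrected over all tested k-mers, with
family-wise level `alpha = 0.01`. Significant k-mers are collapsed
greedily, best p first: a k-mer joins an existing consensus when its
best ungapped alignment over either strand matches in at least
(shorter length − 1) positions; disagreeing overlapping positions
become IUPAC-degenerate letters. An adapter hook (`external =`) lets an
external motif-discovery program replace the built-in finder; its output
consensi enter the same catalogue machinery.

Per-class motif lists are consolidated into one catalogue by
single-linkage grouping under a similarity defined as the maximum, over
ungapped offsets and both strands, of IUPAC-compatible matched positions
divided by the shorter motif's length; groups merge at
`similarity_threshold = 0.8` and are represented by their longest
member. Consolidation is idempotent and ids are reassigned 0..m−1.

Occurrence counting is overlapping and double-stranded:
`count(motif, s) + count(revcomp(motif), s)` on the forward sequence. A
consensus letter matches a sequence base when the letter's IUPAC set
contains that base, so an `N` in the *sequence* matches nothing while
`N` in a *motif* matches any base; windows containing a sequence `N`
are excluded outright. Palindromic motifs therefore count each physical
site twice — a documented property of the convention, not a bug, and
irrelevant to clustering because it scales all vectors alike.
Frequency vectors divide counts by peak length and multiply by 1000
(occurrences per kb), so peak length does not dominate the geometry;
raw-count mode is available. Unchanged peaks are excluded from
vectorization by default — only the two differential classes carry
class-discriminating sequence signal worth clustering.

## Clustering and group-specific clusters

k-means (default k = 8) runs Lloyd iterations from a deterministic
greedy farthest-point initialization: the first centre is drawn from the
seeded RNG, each further centre is the point farthest from its nearest
chosen centre, ties to the lowest index. The best of `n_restarts = 5`
restarts by within-cluster sum of squares wins. Assignment ties go to
the lowest cluster index; an emptied cluster takes the point farthest
from its current centre. The WCSS trace is recorded per iteration and
is non-increasing; at convergence every centroid equals the mean of its
assigned vectors and every vector sits with its nearest centroid — both
asserted to 1e-9 in the tests. Vectors are not standardized by default
(per-kb frequencies share units); a z-score mode exists.

Cluster composition counts each cluster's vectors by differential
origin. A cluster is *group-specific* when one origin's proportion
reaches `purity_min` (default 0.9; set 1 for strictly pure clusters —
"consisting only" of one origin). Its characterizing motifs are the
catalogue entries with the largest centroid coordinates, ties to the
lower motif id. Cluster *indices* are initialization-dependent and
carry no meaning; only purity and centroid content are asserted
anywhere.

The 2-D display projection (`embed_2d()`) is a Laplacian-eigenmap
spectral embedding of a locally scaled Gaussian kNN graph
(`n_neighbors = 15`, auto-shrunk with a warning on small inputs). It is
deterministic, maps duplicate inputs to coincident points, and its
coordinates are display-only — nothing downstream consumes them.

## Expression integration

Fold changes are `(mutant + c) / (control + c)` per mutant line against
the mean control FPKM, with pseudocount `c = 0.1` FPKM guarding zero
division while perturbing ratios of gate-passing genes (control > 10)
by under 1%. A gene is DOWN when its control FPKM exceeds 10 *and* the
ratio is ≤ 0.5 in every mutant line; UP when the ratio is ≥ 2 in every
line. The down threshold mirrors the stated two-fold up rule
symmetrically; both thresholds and the gate are configurable.

Peak-gene links are all same-chromosome pairs whose edge-to-edge gap is
at most 10,000 bp, inclusive, with overlap counting as distance 0.
Distance is measured to the gene body, not the TSS — "within 10 kb of
the peak" anchors at the peak, and the gene body is the less
assumption-laden target; a TSS mode would be a straightforward
extension. The report joins the selected clusters' member peaks with
their linked genes filtered to one regulation direction (default DOWN);
a gene reached through several peaks appears once per peak.

## The synthetic experiment

`simulate_experiment()` generates the study conditions every guarantee
is tested under:

- one 600-kb chromosome, i.i.d. uniform background sequence;
- 50 planted peaks (20 mutant-enriched, 20 control-enriched, 10 shared)
  in 10-kb blocks, width 400 bp, Gaussian expected shape
  (SD = width/4), apex excess 30 reads over a Poisson background of
  mean 2 per bin — roughly 21× the background noise SD, comfortably
  above the 5× regime where detection is expected to work;
- mutant:control excess ratios 4.0 / 0.25 / 1.0 by class, with the
  enriched side carrying the full excess;
- 2 control and 3 mutant ChIP samples (a parent line and three mutant
  lines), independent Poisson noise per sample;
- two planted motifs, `CCCCACCCC` into mutant-enriched peaks and
  `TAGAAATA` into control-enriched peaks, two copies per peak at
  recorded positions;
- a 200-gene FPKM table over 2 control samples and 3 mutant lines:
  control FPKM log-uniform on [1, 1000], down folds U[0.1, 0.4], up
  folds U[2.5, 8], null folds U[0.9, 1.1], log-normal noise
  (sdlog 0.03) on mutant lines. Planted DOWN genes draw their control
  FPKM above the analysis gate (> 10) so the planted truth and the
  recoverable truth coincide; the fold and noise ranges leave every
  class on the correct side of its threshold with several SDs of
  margin;
- gene placement: each mutant-enriched peak receives one DOWN gene at a
  gap of 500–8000 bp, each control-enriched peak one UP gene; all
  remaining genes live in a background region ≥ 12 kb from any peak, so
  "DOWN gene within 10 kb of a mutant-enriched peak" has an unambiguous
  planted answer.

All randomness flows from one seed through deterministic per-component
sub-seeds, so partial re-runs and full runs agree byte-for-byte.

What the generator does *not* emulate — mappability gaps, GC bias,
fragment-length effects, copy-number variation, overlapping or nested
peaks, broad domains, biological replicate variability beyond Poisson
counting noise — bounds what the passing tests show: they validate the
algorithmic contracts and the recovery of well-separated planted
structure, not performance on the pathologies of real chromatin data.
Unit tests run the same generator scaled down (28 peaks on 340 kb,
60 genes) to keep the suite fast; the acceptance checks use the full
conditions above.

## Degenerate inputs and numerical conventions

- Empty bedGraph, overlapping intervals, negative coverage, duplicate
  FASTA headers, non-IUPAC characters, non-numeric FPKM cells and
  unmapped samples are rejected with typed errors.
- FASTA ambiguity codes other than A/C/G/T are stored as N; U becomes T.
- An empty motif catalogue refuses to vectorize (a zero-length feature
  space is a configuration error, not data).
- k-means rejects n < k and all-identical vectors.
- Candidate statistics are reproducible from the smoothed track to
  1e-9; centroid and assignment invariants hold to 1e-9; bedGraph
  round-trips reproduce depths to 1e-9.
- The pipeline manifest is written both on success and on handled
  failure, recording the failing stage; partial stage outputs are kept.

## Known limitations

- The caller has no statistical significance model — thresholds are in
  raw depth units, as the procedure defines, so inputs should be on
  comparable scales across samples (an optional per-sample scale factor
  is the provided knob; none is applied by default because the
  normalization between samples is an explicit open choice).
- The built-in motif finder targets short, high-frequency consensus
  motifs; long or strongly degenerate motifs are better served through
  the external-program adapter.
- Peaks wider than `max_width_bins` are truncated to their best-scoring
  core at genome scale.
- The spectral display embedding preserves neighbourhoods, not global
  distances; it is for orientation only.
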