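# peakshift

Differential histone-mark ChIP-seq analysis built around a landmark-based
peak caller, motif-frequency vectorization and k-means centroid analysis,
with integration of FPKM-filtered expression changes.

## The problem

Comparing a repressive chromatin mark (such as H3K27me3) between a control
cell line and mutant derivatives raises three linked questions: *where*
does coverage change, *what sequence features* distinguish the changed
regions, and *which genes* near those regions respond transcriptionally.
`peakshift` implements that workflow as one reproducible pipeline:

1. **Peak detection.** The per-bin read depth `D(x)`, pooled across all
   samples, is smoothed with a centred moving average. Landmarks are
   local minima, local maxima, and points where consecutive slopes `s_i =
   d[i+1] − d[i]` change by more than two-fold. Every admissible
   (start, apex, end) landmark triple is a candidate peak; with baseline
   `b = (d[start] + d[end]) / 2`, candidates are kept when the maximum
   excess `d[apex] − b > 2.5` and the integrated excess
   `Σ max(0, d − b) > 5.0`, then reduced to one peak per summit.
2. **Differential classification.** For each peak the mean unsmoothed
   depth is computed per group, `[Dp]_ctrl` and `[Dp]_mut`. A peak is
   **Peaks_2.0** when `[Dp]_ctrl < 0.5 · [Dp]_mut`, **Peaks_0.5** when
   `[Dp]_ctrl > 2 · [Dp]_mut`, otherwise unchanged.
3. **Motif vectorization.** Short motifs enriched in each differential
   class (built-in k-mer finder: one-sided Fisher exact on
   presence/absence against shuffled backgrounds, Bonferroni-corrected,
   collapsed into IUPAC consensi) are consolidated into one catalogue;
   every peak becomes a vector of per-kb motif occurrence frequencies,
   counted on both strands.
4. **Clustering.** The vectors are clustered by k-means (default k = 8,
   deterministic farthest-point initialization with restarts). Clusters
   composed predominantly of one differential class are selected and
   characterized by their top centroid motifs.
5. **Expression integration.** Genes with control FPKM > 10 whose
   mutant/control ratio is ≤ 0.5 in every mutant line are *down*;
   ratio ≥ 2 in every line is *up*. Regulated genes within 10 kb of a
   peak in a group-specific cluster form the final report.

A synthetic-data generator (`simulate_experiment()`) plants enrichment
peaks with known mutant:control ratios, class-specific motifs and
regulated genes, so every stage is verifiable against ground truth
without any external data.

## Worked example

```r
library(peakshift)

cfg <- peakshift_config(sim = simulation_config(seed = 1), seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")

table(res$diff_peaks$label)
#> PEAKS_0_5 PEAKS_2_0 UNCHANGED
#>        20        20        10

res$catalog
#>   motif_id consensus k source_class n_merged
#> 1        0 CCCCACCCC 9    PEAKS_2_0        1
#> 2        1  TAGAAATA 8    PEAKS_0_5        1

glance(res$model)
#>       k     n tot_withinss iterations
#> 1     8    40        0.557          2

head(as.data.frame(res$report), 3)
#>   cluster dominant_origin    peak_id chrom peak_start peak_end gene_id direction distance
#> 1       1       PEAKS_0_5 peak_00011  chr1     104090   104590   G0035      DOWN     6709
#> 2       1       PEAKS_0_5 peak_00031  chr1     305630   306130   G0082      DOWN     3767
#> 3       1       PEAKS_0_5 peak_00044  chr1     435740   436210   G0119      DOWN     6574
```

The run recovers all 50 planted peaks (20 mutant-enriched labelled
Peaks_2.0, 20 control-enriched labelled Peaks_0.5, 10 shared unchanged),
rediscovers both planted motifs exactly, and the report's 20 distinct
genes are precisely the planted down-regulated genes lying within 10 kb
of a mutant-enriched peak.

`autoplot(res$model)` draws the centroid motif-frequency profiles,
`plot_cluster_composition(res$composition)` the per-cluster origin
proportions, and `plot_embedding(embed_2d(res$vectors), res$model)` a 2-D
display embedding of the vectors. `tidy()`, `glance()` and `augment()`
expose the k-means fit in broom style.

Real data enter through the same interfaces: `read_depth_bedgraph()`
(per-sample coverage), `read_genome_fasta()`, `read_genes()` (BED6/GFF3),
and `read_fpkm_table()`; see `peakshift_config(inputs = ...)`.

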