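# loophub

Loop-anchor topology of methylation-sensitive CTCF peaks, and their
relationship to nuclear speckles.

## The problem

DNA methylation blocks CTCF binding at a subset of its motifs.  Global
demethylation (e.g. selective DNMT1 inhibition) therefore activates
hundreds-to-thousands of previously masked, *condition-specific* CTCF
peaks.  Three questions follow for anyone with ChIP-seq peak calls, HiChIP
loop lists, Hi-C matrices and a speckle-proximity track (SON Cut&Tag or
TSA-seq) in hand:

1. **Topology** — do the new peaks engage in chromatin loops, and do their
   partner peaks loop unusually often ("highly looping" peaks, the loop
   analogue of superenhancers)?
2. **Position** — are the new peaks and their promiscuous partners close to
   nuclear speckles, and does loop strength track speckle proximity?
3. **Function** — which treatment-responsive genes depend on CTCF, and are
   those the speckle-proximal, CTCF-gaining ones?

`loophub` implements the full analysis as composable, tested R functions:

* condition-specific peak sets (`condition_specific_peaks`, whole-peak
  non-overlap, `bedtools intersect -v -wa` semantics) and midpoint
  annotation with the priority order promoter > TTS > exon > intron >
  intergenic (`annotate_peaks`);
* per-peak distinct-loop counts and maximally-looping-partner statistics
  (`count_distinct_loops`, `max_partner_loops`) after the published loop
  filter FDR < 0.01 and > 4 PETs (`filter_loops`);
* the **tangent cutoff**: peaks ranked by distinct-loop count, rank and
  count scaled to [0, 1], cutoff where the tangent slope reaches 1,
  computed as argmin(y − x); peaks above it are highly looping
  (`call_highly_looping`);
* cross-condition loop strength: FDR / ≥ 8-total-PET /
  replicate-consistency filters (`differential_filters`), per-sample
  CPM and a transparent pseudocount log2 fold-change (`loop_cpm_logfc`),
  Mann-Whitney group comparisons (`stratify_logfc`);
* speckle covariates: binned-signal mapping (`map_binned_signal`,
  unweighted bin mean, 20 kb RPKM bins), equal-count deciles with
  duplicate-edge collapse (`assign_deciles`), and the 90th-percentile
  speckle-association rule (`speckle_associated_peaks`);
* observed/expected contact pileups at 10 kb with blacklist exclusion,
  per-bin strongest-signal dedup and minus-strand reflection
  (`expected_by_distance`, `prepare_centers`, `pileup`);
* differential-gene selection (p-adj < 0.05, |log2FC| > 0.5), z-scored
  K-means clustering (K = 4) with deterministic label ordering, and
  cluster-level CTCF-gain / speckle covariates (`cluster_genes`,
  `annotate_clusters`);
* a truth-labelled synthetic-data generator (`simulate_all`) that plants
  hubs near speckle bins, condition-specific peaks on gene bodies,
  distance-decay contact matrices with loop-pixel enrichment, negative
  binomial replicate PET counts and four expression archetypes — so the
  entire pipeline is testable offline.

## Worked example

```r
library(loophub)
summary <- run_all(simulation_config(seed = 1), outdir = "run1")
```

This simulates a 2 x 20 Mb genome (990 peaks, of which 150
condition-specific and 40 planted hubs; ~1,100 loops; 10 kb contact
matrices; a 400-gene expression table) and runs every stage.  With seed 1
the summary reports, among other things:

```
peaks:     n_condition_specific = 150        (equals the planted truth set)
topology:  cutoff_count = 3, n_highly_looping = 41
           fraction of specific peaks looping = 0.547
diffloops: mean log2FC, specific-anchored loops = 0.231  (planted 0.3)
           mean log2FC, other loops            = -0.014  (planted 0)
           rank-sum p = 0.015
signal:    Pearson r (mean logCPM vs speckle signal) = 0.658
           90th-percentile threshold = 4.05; 131 speckle-associated peaks
clusters:  sizes 52/35/48/6, adjusted Rand vs planted archetypes = 0.914
           the CTCF-dependent, speckle-proximal cluster ranks first on both
           covariates (mean peak log2FC 2.31, mean speckle signal 4.60)
```

Reading: the tangent cutoff lands at 3 distinct loops and recovers 40/40
planted hubs (plus one borderline peak); loops anchored at
condition-specific peaks strengthen by the planted ~0.3 log2 units while
background loops stay flat; loop strength rises monotonically across
speckle-signal deciles; and K-means on the z-scored expression matrix
recovers the four planted archetypes.

`run1/` holds all simulated inputs (BED/BEDPE/bedGraph/GFF3/TSV, dense
matrix container), the annotated peak table and `summary.json` with every
threshold echoed.

The same stages are scriptable from the shell (`exec/loophub`):

```sh
loophub simulate --config sim.cfg --outdir run1 --seed 1
loophub peaks    --cond-a run1/peaks_dmso_r1.bed,run1/peaks_dmso_r2.bed \
                 --cond-b run1/peaks_dnmt1i_r1.bed,run1/peaks_dnmt1i_r2.bed \
                 --genes run1/genes.gff3 --out peaks.tsv
loophub topology --peaks peaks.tsv --loops run1/loops.bedpe --condition dnmt1i --out stats.tsv
```

## Documentation

`vignettes/loophub-methods.Rmd` documents the statistical model behind the
generator, every tunable threshold with its default and origin, the
numerical conventions (half-open coordinates, percentile interpolation,
tie-breaks, pseudocounts), and the known limitations — including one
deliberately red acceptance assertion rooted in the compositionality of
library-total CPM.
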