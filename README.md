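# seCircuit

Super-enhancer calling and transcriptional-regulatory-circuitry mapping
from signal-scored ChIP-seq peak landscapes.

Cell identity is driven by a small set of master transcription factors
whose genes sit under **super-enhancers (SEs)** — stitched clusters of
enhancers carrying exceptionally high cofactor (p300/Mediator) occupancy.
`seCircuit` implements, as a tested and reusable R/Bioconductor-style
package, the downstream analysis that turns called peaks and quantified
expression into an SE-guided regulatory map. It was built with mouse
trophoblast stem cells (TSCs) and their differentiation in mind, but every
stage is parameterized and organism-agnostic. The pipeline starts from
called peaks; alignment and peak calling are out of scope.

## What it computes

* **SE calling (ROSE-style).** Peaks fully contained in TSS exclusion
  zones (±2.5 kb) are dropped; remaining peaks are stitched when their gap
  is ≤ 12.5 kb; stitched regions are ranked by summed signal. With rank
  and signal both rescaled to [0, 1] as *x* and *y*, the cutoff sits at
  argmax(*x* − *y*) — the point where the tangent to the convex ranked
  curve has slope 1 — and regions with signal strictly above the cutoff
  are SEs.
* **Peak-to-gene feature annotation** by the precedence hierarchy
  promoter (|center − TSS| ≤ 2 kb) > upstream (2–20 kb, 5′,
  strand-aware) > intron > exon > intergenic, decided by peak centers.
* **Enhancer–gene assignment** (20 kb upstream + gene body) and the
  moving-average (window 100) association between relative expression
  rank, log2((*a*+1)/(*b*+1)), and per-gene enhancer counts.
* **Multi-TF co-occupancy**: union binding sites from single-linkage
  merging of peak centers within 500 bp, a binary site × factor
  occupancy matrix, pairwise Pearson correlation with average-linkage
  clustering order, and distinct-factor counts per region (e.g. the
  fraction of SEs bound by > 8 TFs).
* **Regulatory network and circuitry**: TF → target edges from binding
  within ±20 kb of the gene body (nearest-TSS fallback otherwise),
  enumeration of autoregulators (A→A), feedback pairs (A⇄B) and
  feed-forward loops (A→B, B→C, A→C), and the set of genes co-occupied by
  > 22 of 27 profiled factors.
* **Time-course classification** of relative expression profiles
  (value / per-gene mean) into four classes — biphasic, decreasing,
  increasing, flat — by hierarchical clustering.
* **Cross-dataset dysregulation screen**: per case/control dataset, top
  and bottom 10% of genes by mean-ratio; SE-gene orthologs extreme in
  ≥ 3 of 5 datasets are reported with their direction.
* **Signal profiling**: depth-normalized (per-million) read densities in
  100-bp bins within ±3 kb of peak centers, region occupancy scores, and
  log2 relative occupancy between two cell states.
* **Synthetic data generators** for every input — peak landscapes with
  planted SE clusters, multi-factor binding universes with a controlled
  co-occupancy rate, archetype time-course expression, and case/control
  cohorts with planted effects — each paired with a ground-truth object,
  so the whole pipeline is testable without downloads.

## Worked example

Call SEs on a synthetic landscape with 10 planted 8-peak clusters hidden
among 200 typical enhancers:

```r
library(seCircuit)

spec  <- syntheticLandscapeSpec(seed = 7)
genes <- generateAnnotation(spec)
land  <- generateEnhancerLandscape(spec, genes)
res   <- callSuperEnhancers(land$peaks, genes)
res
#> SECallResult with 188 stitched regions
#>   superenhancers: 15 (total signal > 18.75, elbow at rank 173)
#>   typical enhancers: 173
assoc <- associateSeGenes(res, genes)
length(unique(assoc$gene))
#> [1] 17
```

All 10 planted clusters are recovered with exact coordinates; the
remaining SEs are the strongest background singletons that fall above the
elbow. The full demo — SE calling, annotation, 27-factor co-occupancy,
network + circuitry, expression analyses, profiling, with a recovery
report scored against generator truth — runs in seconds:

```r
r <- runDemo(seed = 7, outDir = "demo_out")
round(r$report, 3)
#>  n_stitched_regions    n_superenhancers   planted_se_recovery
#>             188.000              15.000                 1.000
#>        se_precision          n_se_genes    frac_se_cooccupied
#>               0.667              17.000                 0.667
#>     n_network_edges n_coregulated_genes      n_autoregulators
#>            4386.000             106.000                17.000
#>    n_feedback_pairs n_feedforward_triads   timecourse_accuracy
#>             139.000            6304.000                 1.000
#>    screen_precision       screen_recall   screen_direction_ok
#>               1.000               1.000                 1.000
#> moving_average_spearman
#>              -0.977
```

`planted_se_recovery = 1` means every planted SE extent was called
exactly; `timecourse_accuracy` is the four-class label recovery;
`screen_precision`/`screen_recall` score the dysregulation screen against
the planted up/down genes; the strongly negative moving-average Spearman
coefficient reproduces the expected coupling between relative expression
rank and enhancer count. `demo_out/` holds one TSV per result plus
`manifest.yaml` with md5 digests of every output; reruns with the same
seed are byte-identical.

`runPipeline(configPath, outDir)` runs the same stages on your own BED /
narrowPeak / refFlat / TSV inputs declared in a YAML configuration (see
`?runPipeline`); a thin command-line wrapper lives at
`inst/scripts/secircuit-demo.R`.

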