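---
title: "Methods: super-enhancer calling and regulatory circuitry mapping"
author: "seCircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer calling and regulatory circuitry mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seCircuit)
```

`seCircuit` maps cell-type-specific regulatory programs from called,
signal-scored ChIP-seq peaks and quantified expression. This vignette is
the package's own account of the models it implements, the parameters
that matter, the numerical choices made where the underlying procedures
are commonly left under-specified, and what the synthetic-data tests do
and do not demonstrate.

## Coordinates and data containers

All files are exchanged in standard formats: BED/narrowPeak for peaks
(0-based half-open), UCSC 11-column refFlat for gene models, TSV for
expression and ortholog tables, BED3 for read placements and repeat
masks. Internally intervals are `GRanges` (1-based closed); derived point
quantities stay on the 0-based scale so that the usual conventions hold
exactly: a peak's center is `floor((start + end) / 2)` of its 0-based
interval, and the TSS of a minus-strand transcript is `txEnd - 1`.
Chromosome names are matched by exact string equality; a validation pass
warns when two inputs share no chromosome names at all (e.g. `chr1`
vs `1`), because every overlap would then silently be empty.

Peak centers, not interval overlaps, decide feature membership
throughout. Binding sites are effectively points at this resolution;
center semantics removes the dependence of annotations on peak length.
narrowPeak summit columns are ignored for the same reason — the analyses
reason about geometric centers, and summits are caller-specific.

Where several transcripts share a gene symbol, gene-level operations
(enhancer counting, target assignment, SE association) use the transcript
with the widest span, ties broken by transcript name; peak-level feature
classification evaluates every transcript.

## Super-enhancer calling

The SE caller follows the ROSE recipe with its published parameter
values:

1. **TSS exclusion** (`tssExclusion`, default 2,500 bp, 0 disables):
   peaks whose interval is *fully contained* in
   `[tss - E, tss + E)` of any transcript are removed before stitching,
   so promoter-proximal signal cannot seed or bridge stitched regions.
   Partial overlaps are kept — a long enhancer reaching into a promoter
   zone is still an enhancer. The filter runs on constituent peaks, not
   on stitched regions, matching the reference implementation's
   semantics.
2. **Stitching** (`stitchDistance`, default 12,500 bp): single-linkage
   merging per chromosome; two peaks join one region iff the gap between
   their intervals is at most the stitch distance. The result is
   independent of input order, idempotent, and conserves summed signal.
   A region's `totalSignal` is the sum of its constituent peak scores;
   whether the original analyses summed per-base coverage or peak scores
   inside stitched regions is not observable from the outside, and peak
   scores keep the module independent of alignment data.
3. **Elbow cutoff**: regions are sorted by ascending total signal; rank
   and signal are rescaled to the unit square as $x$ and $y$, and the
   cutoff index is $\arg\max_i (x_i - y_i)$ — for a convex curve this is
   exactly the point where the slope-1 tangent touches, i.e. the
   standard "tangent line" SE definition made discrete and
   deterministic. Regions with `totalSignal` *strictly above* the cutoff
   signal are SEs, so a region tied with the cutoff stays typical. Ties
   in $x - y$ resolve to the lowest rank (`which.max`), the inclusive
   choice. Degenerate inputs fail loudly: fewer than 3 regions or an
   all-constant signal vector (no elbow exists) are errors, not silent
   empty results.

The elbow's discrete behavior is worth stating: with a heavy-tailed
background signal distribution, the point maximizing $x - y$ can fall a
few ranks below the strongest background region, so the called SE set
typically contains every truly outstanding cluster plus, in some
datasets, a handful of the strongest background singletons. The
package's recovery criterion is accordingly *extent recovery* — every
planted cluster is called as an SE with exactly its stitched
coordinates — and the demo's recovery report also prints the complement
(`se_precision`) so the trade-off is visible rather than hidden.

**SE–gene association** reuses the network assignment rule (gene body
± 20 kb, nearest-TSS fallback) rather than inventing a second, SE-only
rule: one assignment semantics pipeline-wide. An SE overlapping several
extended gene spans associates with all of them; an SE on a chromosome
with no genes is logged and excluded.

## Feature annotation

Each peak receives exactly one feature under the precedence
promoter > upstream > intron > exon > intergenic:

* promoter: `|center - tss| <= promoterHalfwidth` (2,000 bp) on either
  side, both strands;
* upstream: strictly more than the promoter half-width and at most
  `upstreamMax` (20,000 bp) 5′ of the TSS on the gene's strand;
* intron/exon: center inside the gene body, split by exon membership of
  that same transcript. The hierarchy ranks intron above exon, as
  published; regions 3′ of a gene body are intergenic because the
  enumeration has no downstream category.

Among genes granting the winning feature the lexicographically smallest
symbol is reported — an arbitrary but deterministic choice, needed
because a center can sit in two promoters at once.

Target-gene assignment for the network uses the extended span
(`networkWindow`, 20,000 bp) around the gene body; a peak matching no
span falls back to the unique nearest gene by center-to-TSS distance,
with ties broken by distance to the gene-body boundary and then by
symbol. Enhancer counting for the moving-average analysis is narrower by
design — 20 kb strictly 5′ of the TSS plus the gene body, no fallback —
because there an enhancer should only be credited to genes it plausibly
serves, whereas the network rule must assign every binding site
somewhere.

## Co-occupancy

Two peaks from different tracks are the same binding site iff their
centers lie within `overlapWindow` (500 bp, strict inequality) on the
same chromosome. Union sites are the single-linkage closure of this
relation over all factors pooled — chained overlaps merge, which is what
a moving window over the genome produces, and in one dimension the
closure is computed exactly by breaking sorted centers at gaps ≥ the
window. Each union site spans its members' extent and carries the lower
median of member centers as anchor. The occupancy matrix is binary by
construction (a factor either contributed a peak or did not).

Pearson correlation between two binary columns is undefined when either
column is constant; constant factors are reported as `NA` and excluded
from the clustering rather than silently mapped to 0 — a factor bound at
every union site carries no co-occupancy information. Note the boundary
case this implies: two *identical* peak sets compared over only their own
union have two all-ones columns and an undefined correlation; adding any
third factor's sites makes the columns informative and the correlation
exactly 1. Display order comes from average-linkage clustering on
$1 - r$. The union universe is global across all factors by default;
`universe = "pairwise"` restricts each pair's universe to its own two
peak sets, for the alternative reading of pairwise overlap scoring.

## Network and circuitry

Edges follow binding-implies-regulation: (TF, gene) is an edge iff at
least one of the TF's peaks is assigned to the gene; edges carry the
supporting peak indices as evidence. TF nodes are linked to their own
genes through an explicit `tfGeneMap` rather than name equality, since
factor labels and gene symbols routinely differ (`cFos` vs `Fos`).
Motifs are enumerated exhaustively on the TF-restricted graph:
autoregulators from the diagonal, feedback as unordered mutual pairs,
and feed-forward loops as *ordered* triples (A, B, C) of distinct TFs
with A→B, B→C, A→C — the standard FFL count, so a fully connected triad
contributes six. Self-loops never contribute to pair or triad motifs.
The co-regulated gene set applies a strict threshold (> 22 distinct
factors with the default 27-factor design).

## Expression analyses

Relative expression ranks use `log2((a + c)/(b + c))` with pseudocount
`c = 1` expression unit, making zeros harmless and the ranking identical
to the raw-ratio ranking (the transform is monotone); rank ties break
lexicographically so downstream windows are reproducible. The moving
average slides a `maWindow` (100 genes) mean over enhancer counts in
rank order, step 1.

Time-course profiles are divided by the per-gene mean across timepoints
(rows then average exactly to 1; all-zero genes are excluded with a
warning), log2-transformed, and clustered by average-linkage
hierarchical clustering cut at `nClasses` (4). The four class labels are
assigned by matching cluster centroids to archetype templates: the
minimum-variance centroid is flat; the remaining three take the
(biphasic, decreasing, increasing) permutation with maximal total
centroid–template correlation. The clustering distance is **Euclidean on
the log2 relative profiles** by default. This is a deliberate design
choice: a correlation distance is scale- and location-invariant, so a
flat profile — whose log-relative values are pure noise around zero —
presents no shape for it to latch onto (and noiseless flat genes have
zero variance, making $r$ undefined outright). Euclidean distance keeps
flat genes near the origin and separates them cleanly from the
unit-amplitude monotone and biphasic shapes. `distance = "correlation"`
remains available for shape-only clustering of non-flat patterns and
refuses zero-variance profiles by name.

The cross-dataset screen ranks genes per dataset by the pseudocounted
ratio of mean case to mean control expression and takes
`floor(extremeFraction * n)` genes (10%) from each tail — a strict rank
count, not a quantile, so tie handling is explicit. A gene qualifies iff
it is an ortholog of an SE-associated gene and is extreme in at least
`minDatasetHits` (3) datasets; direction is the majority of top vs
bottom appearances, `mixed` on a tie. The comparison is deliberately a
mean ratio, not a test statistic: the screen is a rank-intersection
filter across cohorts, and differential-expression testing is outside
the package's scope.

## Signal profiling

Reads enter as single representative positions (BED start), keeping the
module agnostic of aligner output. Bins are half-open 100-bp intervals
over ±3 kb of each center (offsets at exactly +3,000 are excluded); bin
counts are summed over centers, divided by total reads per million, and
averaged over centers. Profiles are exactly invariant under duplication
of the read multiset, and `relativeOccupancy` is computed as
`log2(a + c) - log2(b + c)` so that swapping the two states negates the
value bit-exactly — an identity that the naive `log2(ratio)` form does
not guarantee in floating point. Profiles are not strand-flipped (peaks
are unstranded).

## Synthetic data: what it emulates, and what it does not

The generators are first-class, tested code, and each returns a truth
object sufficient to score recovery without re-deriving it:

* **Landscape**: 200 isolated typical peaks with Exponential(mean 5)
  signal and 10 planted clusters of 8 peaks within 10 kb, Exponential
  (mean 50) per-peak signal, on one 15-Mb chromosome with a 400-gene
  annotation. The exponential model produces the convex "hockey-stick"
  ranked-signal curve that makes an elbow cutoff meaningful; placement
  uses fixed-width slots so that typical peaks are pairwise more than a
  stitch distance apart, clusters are more than a stitch distance from
  any other peak, and clusters stay clear of TSS exclusion zones (so a
  planted cluster always stitches into exactly one surviving region;
  TSS-exclusion behavior itself is tested on dedicated fixtures).
  Feasibility is checked up front — capacity errors instead of unbounded
  rejection sampling.
* **TF peak sets**: a universe of shared anchor sites (spaced beyond the
  overlap window) at which each factor binds independently with a
  configurable probability, centers jittered ±100 bp, plus
  factor-private sites.
* **Time-course expression**: four positive archetype curves (biphasic,
  decreasing, increasing, flat; 4-fold amplitude) scaled by lognormal
  per-gene baselines with multiplicative lognormal noise.
* **Case/control cohorts**: per-sample `2^(mu + N(0, sd))` around
  gene baselines `mu ~ N(6, 1)` (log2 units), planted genes shifted by
  ±2 in the case arm, shared identities across cohorts.

All generators are pure functions of (spec, seed) and restore the
caller's RNG stream. What passing recovery tests demonstrate is that the
implementations are *correct* under data with the assumed statistical
structure — well-separated signal scales, independent binding,
archetypal expression shapes. Real peak landscapes have correlated
signal, copy-number artifacts, density gradients along chromosomes and
antibody-dependent peak geometry; none of that is emulated, so recovery
rates here say nothing about biological sensitivity or specificity on
real data — only that the algorithms compute what they claim.

## Problem sizes and determinism

The shipped demo and recovery analyses use sizes chosen to exercise
every code path at desk scale: the landscape above, 27 TF tracks
(matching the published 27-factor circuitry design, and making the
">22 factors" gene-set threshold meaningful), 50 genes per expression
class over 7 timepoints at noise s.d. 0.1, five case/control cohorts of
1,000 genes (6 samples per arm, |log2FC| = 2, noise s.d. 0.2), and
20,000 reads for profiling. The full demo is deterministic given its
seed — reruns are byte-identical, with md5 digests of every output
recorded in the run manifest — and `scripts/acceptance.R` recomputes all
headline quantities from scratch under a caller-supplied seed.

## Known limitations

* Signals are taken as provided; there is no input-track subtraction or
  per-base coverage extraction, so `totalSignal` inherits whatever scale
  the peak caller emitted.
* The binding-implies-regulation edge semantics produces no
  activation/repression sign and no strength beyond evidence counts.
* The screen's mean-ratio ranking is not a significance test; genes with
  tiny baseline expression are tempered only by the pseudocount.
* Promoter–enhancer looping data are not integrated; target assignment
  is purely distance-based.
* The "visual inspection" style of weak-peak curation has no
  reproducible rule; the package exposes only an optional minimum-signal
  threshold (`minSignal`, default off).
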