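---
title: "Methods: linking ChIP-seq peaks to gene sets"
author: "peaksets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking ChIP-seq peaks to gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures in `peaksets`, the
assumptions behind them, the numerical choices, and what the synthetic-data
generators do and do not establish about behaviour on real data.

## Coordinate conventions

All user-facing coordinates are BED-style: 0-based, half-open intervals;
summits, TSSs and bin boundaries are single 0-based offsets.  Internally,
interval algebra runs on 1-based closed `IRanges`/`GenomicRanges`; the
conversion (`start + 1`, `end`) happens at one boundary layer so that no
other code reasons about the shift.

## Feature classification

A peak is represented by its summit — the single base of maximal signal —
and classified into exactly one of seven genomic features.  Candidate
regions per gene are:

* **Promoter**: all positions within ±`promoter_window` (default 3000 bp)
  of the TSS, on both strands.  The window is symmetric because promoters
  are defined as a fixed distance up- *and* downstream of the TSS.
* **5′/3′ UTR**: exonic positions outside the CDS on the respective side in
  gene orientation.  Non-coding genes (empty CDS in BED12, thickStart ==
  thickEnd) contribute no UTR candidates; their exons classify as Exon.
* **Exon / Intron**: exonic positions; positions inside the gene span but
  outside every exon.
* **Downstream**: the `downstream_window` (default 3000 bp) past the gene
  end in gene orientation.  A bounded window was chosen over an unbounded
  "everything past 3 kb" reading, which would leave no distal intergenic
  class at all; the boundary between "downstream of a particular gene" and
  "distal intergenic" has to be drawn somewhere, and 3 kb mirrors the
  promoter scale.
* **Distal intergenic**: everything else; the assigned gene is the one with
  the nearest TSS by absolute distance.

Overlaps are resolved by the fixed precedence Promoter > 5′UTR > 3′UTR >
Exon > Intron > Downstream > DistalIntergenic — genic, regulatory
annotations win over structural ones, which matches the spirit of the
standard annotation tools.  Classification by summit (not whole-peak
overlap) guarantees one feature per peak without fractional assignments.
When two genes offer the same winning class, the tie breaks by smaller
|summit − TSS| and then lexicographic gene id, making output fully
deterministic.  `dist_to_tss` is signed in gene orientation (negative =
upstream).

The classifier is implemented as point-in-interval queries
(`findOverlaps`) against the candidate regions; an independent per-position
brute-force oracle in the test suite re-derives the rules directly and is
compared against the classifier on random toy annotations (10,000 random
summits in the acceptance checks, 100% agreement required).

## Overlap (Venn) tables

Peaks of all samples merge when their intervals intersect or are separated
by a gap strictly below `max_gap` (default 1000 bp).  The pairwise rule is
not transitive, so the partition is its single-linkage closure, computed
as `GenomicRanges::reduce(min.gapwidth = max_gap)`.  Each merged region
belongs to exactly one Venn cell — the set of samples contributing at
least one peak.  Interval gap (rather than summit distance) is the
conventional reading of "located less than 1000 bp apart" and makes the
merge monotone in `max_gap`, which the tests exploit as an invariant.

## Chromatin states

Segmentations are consumed as hard per-bin labels on a fixed grid
(default 200 bp, 15-state Roadmap vocabulary).  A summit at position `s`
takes the state of bin `floor(s / bin_size)`.  Bins not covered by any
record carry an `"unannotated"` sentinel; unannotated summits are excluded
from abundance denominators by default (profiles report only model
states), with `include_unannotated = TRUE` to keep them.  How the original
analyses treated such summits is not documented anywhere we know of; the
exclusion-with-override is the conservative choice.

## Hypergeometric feature-bias test

For a gene set's peaks against the all-peaks background, with `k` of the
set's `n` peaks in a feature and `K` of `N` background peaks there,
`p_enrich = P[X ≥ k]` and `p_deplete = P[X ≤ k]` for
`X ~ Hypergeom(N, K, n)`.  Both one-sided tails are reported and both
include the observed point, so `p_enrich + p_deplete ≥ 1`.  Tails are
computed by `phyper`, which sums in a numerically stable way; the test
suite and the acceptance script verify every instance with `N ≤ 12`
against exhaustive enumeration of all `choose(N, n)` draws at 1e-12.

## Bootstrap gene-set peak-count enrichment

"Association" of a peak with a gene is the gene assigned during
classification — all seven features count, distal peaks via nearest TSS.
This is a deliberate, recorded decision: no distance cap is applied, so
the per-gene counts partition the peaks and the summed statistic is well
defined.  The gene universe is the full annotated gene list, not just
genes with peaks, matching the sampling frame "N out of all annotated
genes".

Each of `B` trials (default 10,000) draws `N` distinct genes uniformly
without replacement and sums their peak counts.  Trials consume one
sequential RNG stream from a single root seed; generation is not
parallelized, so a single stream already gives bit-for-bit
reproducibility, and the simpler scheme was preferred over counter-based
substreams.

Both one-sided p-values are always reported (the scientific question is
"significantly high *or* low"), as fitted tails `p_high = 1 − F(obs)`,
`p_low = F(obs)` under a skew-normal fit to the null, and as empirical
tails with add-one correction, `(1 + #{null ≥ obs})/(B + 1)`, with ties
counting toward both tails.  The empirical tails floor at `1/(B+1)`; the
fitted tails extrapolate beyond the null's range, which is the point of
fitting a parametric density to the histogram.

### Skew-normal fitting

The density is `f(x) = (2/ω) φ(z) Φ(αz)`, `z = (x − ξ)/ω`; the CDF is
`Φ(z) − 2T(z, α)` with Owen's T computed by adaptive quadrature (with the
standard reduction to `|a| ≤ 1` for accuracy at large shape).  Fitting is
direct maximum likelihood over `(ξ, log ω, α)` with method-of-moments
starting values (sample skewness clamped inside the attainable range) and
`|α|` capped at 50 to avoid boundary divergence.  Samples with zero
variance set a degenerate flag instead of fitting; optimizer
non-convergence raises an error carrying the method-of-moments values.

The profile likelihood in `α` is flat near symmetry — the Fisher
information for the direct parameterization is singular at `α = 0` — so
the unrestricted MLE of the shape drifts to spurious values (|α| ≈ 0.3–0.6)
even for 10,000 exactly Gaussian draws, while changing the fitted
*distribution* imperceptibly.  The fit therefore compares the
three-parameter estimate against the nested symmetric (`α = 0`, Gaussian)
member of the family by BIC and returns the symmetric fit when the data
carry no real evidence of skew (`select = FALSE` disables this).  Clearly
skewed samples are unaffected: their log-likelihood advantage dwarfs the
`log(n)/2` penalty, as the test on `α = 5` samples verifies.  The MLE
itself is cross-checked in the tests against an independent optimizer on
the same likelihood; calibration of the resulting `p_high` was verified
to be uniform either way.

## Expression analyses

* **Probe collapse**: per gene, the probe with the largest IQR across
  samples is kept; ties break by lexicographic probe id.  Unmapped probes
  are dropped with a logged count; probes mapping to more than one gene
  are an error.
* **Scaling**: gene-wise to mean 0, sample SD 1; zero-variance rows become
  zeros with a warning (they carry no clustering information).
* **Clustering**: complete linkage; Euclidean distance on z-scaled rows
  for expression input, `1 − r` for correlation input.  No metric is
  documented for clustered correlation heatmaps in the analyses this
  package mirrors; `1 − r` is the standard choice.
* **Differential expression**: log2 fold change is the group-mean
  difference on the log2 matrix; significance requires BH-adjusted
  p < 0.05 *and* |log2FC| > 1.5 (both configurable).  The default
  statistic is limma's empirical-Bayes moderated t: with three replicates
  per group the gene-wise variance estimate is too unstable for a plain
  Welch test to recover even strong planted effects at these thresholds
  (median sensitivity ~0.35 in simulations versus ≥0.95 moderated), and
  variance moderation is the established practice for small microarray
  designs.  `method = "welch"` provides the unmoderated alternative for
  designs with enough replication.
* **Gene-set perturbation test**: a one-sided Welch two-sample t of the
  set's per-gene statistics against all measured genes — signed log2 fold
  changes in directed mode (alternative: set upregulated), absolute values
  in undirected mode (alternative: set more perturbed).  Only sets whose
  overlap with measured genes is strictly between 5 and 500 genes are
  tested, for statistical robustness.  This is a deliberately reduced,
  fully specified form of the GAGE-style "set versus all genes"
  comparison; sample-pairing options and two-direction splitting are out
  of scope.
* Missing values are disallowed after load: rows with any missing entry
  are dropped with a logged count, because every downstream statistic
  assumes complete rows.

## Synthetic data: what it emulates, and what it does not

The generators plant known structure so that every analysis stage has a
ground truth:

* **Genome**: non-overlapping, strand-mixed, multi-exon genes on one or
  more chromosomes.  Gene lengths are log-normal (meanlog `log(20000)`,
  sdlog 0.8) with log-normal intergenic spacing (meanlog `log(30000)`,
  sdlog 0.9) — the scale of human gene models, chosen so that the ±3 kb
  promoter and 3 kb downstream windows occupy realistic fractions of gene
  bodies and intergenic space.  (At toy scales where the windows swallow
  most of the geometry, per-gene peak counts become pathologically
  overdispersed and the bootstrap null stops resembling anything seen with
  real annotations.)  About 10% of genes are non-coding.
* **Peaks**: each peak draws a gene (probability ∝ 1, or ∝ ρ for members
  of a designated set — a multiplicative density model, which matches how
  the bootstrap statistic sums per-gene counts and gives a clean power
  dial), then a feature stratum from a weight vector, then a uniform
  position inside that stratum *after higher-precedence regions are carved
  out*.  Generator and classifier share one geometry, so the intended
  stratum is recovered on classification (boundary effects < 1%).  If the
  drawn gene lacks the drawn stratum, the gene is redrawn conditional on
  the feature, keeping the feature marginals exactly at the requested
  weights; only a feature absent from the entire genome redraws the
  feature (both are counted in the truth record).
* **Segmentation**: every bin's state is drawn from an emission
  distribution conditioned on the feature at the bin centre — promoters
  TssA-heavy, transcribed features Tx-heavy, unassociated distal space
  quiescent.
* **Expression**: two anti-correlated gene blocks realized through two
  latent factors with correlation `between/within`, giving within-block
  correlation `within_cor` and cross-block `between_cor` in expectation
  (infeasible combinations, |between| > within, are rejected); planted DE
  genes add a fixed log2 shift to group-2 samples; null genes are pure
  noise.

What passing these tests shows: the algorithms implement their definitions
exactly (oracle equivalence), the bootstrap p-values are calibrated and
powerful under the planted model, and the pipeline is deterministic.  What
they do not show: robustness to everything real data adds — overlapping
transcript isoforms, unassembled contigs, copy-number-distorted peak
densities, segmentation vocabularies that differ from Roadmap's,
non-Gaussian expression noise, batch effects.  The generators deliberately
produce no nucleotide sequence, no motif content and no read-level data.

## Pipeline determinism

Every stage writes TSV/JSON with fixed formatting and a provenance record
(config echo, seeds, package version — no timestamps), so repeated runs
with the same configuration are byte-identical; the acceptance script
hashes all outputs of two `simulate` + `run-all` rounds to confirm it.
Problem sizes there — 2,000-gene genomes with 4,000-peak samples for the
bootstrap experiments, 200 calibration sets, 100 power replicates at
B = 2,000, a 120-gene end-to-end run — were chosen as the smallest sizes
at which the statistical checks have the resolution their thresholds
imply.

## Known limitations

* Transcript-isoform-aware annotation is out of scope; one gene model per
  gene id.
* The association rule has no distance cap; a distal peak is always
  "associated" with its nearest-TSS gene, even when very far away.
* The skew-normal fitted tails extrapolate; for nulls that are strongly
  non-skew-normal the empirical tails (also reported) are the safer
  number.
* `hier_cluster` is quadratic in items; it is meant for signature-scale
  gene sets, not whole transcriptomes.
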