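---
title: "Methods: uTAR discovery from spot-based spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uTAR discovery from spot-based spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utarscan)
```

## The problem

Spot-barcoded spatial transcriptomics assays (Visium-style slides)
capture RNA from archival FFPE tissue, where RNA is cross-linked and
fragmented. Poly(A)-capture chemistry is panel-free and therefore sees
transcripts outside the annotated, probe-targeted gene space — notably
long non-coding RNAs. `utarscan` detects such signal directly from the
alignments: it segments binned genome coverage into transcriptionally
active regions (TARs), splits them into annotated (aTAR) and
unannotated (uTAR) regions, labels uTARs against curated lncRNA
interval sets, quantifies them per spot, and asks which uTARs are
specific to a marker-defined cell population.

Everything is validated against a synthetic-data generator with planted
ground truth, because the interesting guarantees — recovery of planted
loci, correct database labels, calibrated differential expression — are
only checkable when the truth is known.

## Segmentation model

Coverage is computed per contig and strand in non-overlapping 50-bp
bins. Each read contributes exactly once, to the bin containing its 5'
end (leftmost aligned base on `+`, rightmost on `-`). This
single-position anchoring conserves read counts exactly; the final
partial bin of a contig is retained. Anchoring by 5' end rather than
spreading a read over all overlapped bins is a documented choice —
it keeps the binning a measure-preserving map from reads to bins, which
the conservation checks assert on every pipeline run.

Two segmentation modes are provided:

* **`presence`** — a bin is active iff it contains at least one read:
  the literal reading of the calling rule, sensitive to single stray
  reads.
* **`hmm`** (default) — a two-state hidden Markov model on the
  transformed bin counts $y_t = \log(c_t + 1)$, with Gaussian
  emissions $y_t \mid s_t = k \sim \mathcal N(\mu_k, \sigma_k^2)$,
  $k \in \{\text{untranscribed}, \text{transcribed}\}$, fitted by
  Baum-Welch EM and decoded by Viterbi. The Gaussian-on-log-counts
  emission family keeps every EM update in closed form and is
  scale-free across sequencing depths.

One parameter set is fitted per sample, pooling all (contig, strand)
tracks as separate observation sequences; strands are decoded
independently. States are ordered by emission mean, so "transcribed"
is always the high-mean state.

Maximal runs of the transcribed state become TARs with bin-aligned
coordinates; TARs on the same contig and strand separated by at most
500 bp are then merged transitively (gap of exactly 500 merges, 501
does not). Merging is idempotent and the merged coverage is the
bin-count-weighted mean of the members.

### Numerical choices

* **EM initialisation** is deterministic and scale-free: untranscribed
  mean at the 25th percentile of the pooled transformed counts,
  transcribed mean at the 90th (falling back to the maximum when the
  two quantiles coincide, as happens when most bins are zero), both
  variances at the pooled variance, transitions at
  $[[0.95, 0.05], [0.10, 0.90]]$, initial distribution uniform.
* **Variance floor** of $10^{-4}$ on the emission variances: with a
  zero-inflated genome the untranscribed state locks onto exactly-zero
  bins and its within-state variance collapses; the floor keeps the
  likelihood finite while preserving the state's near-degenerate
  character. All forward-backward arithmetic is done in log space, so
  the near-degenerate state cannot underflow.
* **Convergence** at a relative log-likelihood change below $10^{-6}$
  (at most 1,000 iterations; non-convergence warns and returns the
  current parameters). The per-iteration log-likelihood trace is
  retained and is non-decreasing, as EM guarantees.
* **Viterbi ties** are broken toward the untranscribed state, both in
  the per-step predecessor choice and at the terminus. This is the
  conservative direction (fewer false TARs) and makes the decoded path
  the colexicographically smallest maximiser, a property the tests
  exploit by comparing against exhaustive path enumeration on small
  tracks. At machine precision two genuinely different path scores can
  round to the same double; the tests therefore assert that the decoded
  path attains the enumerated maximum exactly, and path identity
  whenever that maximum is unique.

## Classification and database labelling

A merged TAR overlapping an annotated gene by at least one base is an
aTAR; all others are uTARs. Gene overlap is strand-specific by default
(`strand_mode = "ignore"` is available and changes exactly the
opposite-strand-overlap cases); database overlap is always
strand-specific. uTARs are labelled `db1`, `db2`, `both` or `novel`
against two stranded lncRNA interval sets. The one-base threshold is
the least-assuming reading of interval overlap and is configurable
(`min_overlap`); no reciprocal-fraction requirement is imposed.

Cross-sample sharing is defined by connected components of the graph
whose edges join strand-matched overlapping uTARs from different
samples, so "shared by k samples" is well defined under chained
overlaps (A overlaps B, B overlaps C, A and C disjoint: one component
spanning three samples).

## Quantification, QC and normalisation

Reads are assigned to features (genes plus called uTARs) by
strand-matched overlap of the 5' position; multi-hits resolve to the
feature with the longest overlap with the full read, exact ties are
discarded as ambiguous, and barcodes absent from the spot layout count
as off-tissue. The four tallies always sum to the input read count.
QC reports reads and detected features per spot and totals per sample.

Normalisation is a median-scaling log transform,
$\log(1 + c \cdot s / T_j)$ with $T_j$ the spot total and $s$ the
median total — deliberately simple and clearly labelled as the
stand-in for smoothing-based spatial normalisation methods, which are
out of scope here.

## Marker labelling and differential expression

The signature score of a spot is the mean normalised expression of a
marker panel (e.g. a keratinocyte panel). Spots scoring strictly above
the 75th percentile (configurable) are labelled positive; the strict
inequality means a flat score vector labels nothing. The threshold
choice is a convention — there is no canonical definition of "high
marker expression" — and the default matches the keratinocyte-band
geometry of the simulator (below).

Each sufficiently detected feature (detection in at least 5% of spots
by default) is tested for a location difference between labelled and
unlabelled spots with a two-sided Wilcoxon rank-sum test: mid-ranks for
ties; the exact null distribution when both groups have at most eight
spots and no ties are present; otherwise the normal approximation with
tie and continuity correction. A feature with identical values in both
groups gets $p = 1$ by convention. P-values are Benjamini-Hochberg
adjusted, and "significantly differentially expressed" means
$q < 0.05$. BH controls the false discovery *rate*; with a handful of
strong true positives it still admits roughly
$\alpha \cdot m_0 \cdot R/m$ false discoveries per analysis in
expectation, a point that matters when interpreting the end-to-end
tests (below). Spatial concordance between a significant uTAR and the
marker signature is summarised by Spearman rank correlation with a
t-approximation p-value.

## The synthetic-data generator

The generator emulates the geometry of an FFPE spatial run without
simulating nucleotides:

* **Genome and truth loci.** Three 300-kb contigs carry 40 annotated
  genes and 20 unannotated lncRNA loci, placed uniformly at random with
  lengths uniform on 1–10 kb and a minimum same-strand gap of 2,000 bp.
  The gap exceeds the 500-bp merge rule by design, so merging can never
  fuse two distinct truth loci and recovery is well defined.
* **Databases.** 60% of the lncRNA loci are deposited in the first
  reference set and 50% in the second (exact planted intervals), giving
  every combination of `db1`/`db2`/`both`/`novel` truth labels.
* **Spots.** 200 spots on a 20 x 10 grid. The rightmost fifth of the
  columns forms a keratinocyte-like band — a thin epidermal-margin
  geometry — and 5% of labels are flipped to emulate a ragged
  histological boundary. Domains are hard labels; per-spot cell-type
  mixtures are deliberately not modelled (deconvolution is out of
  scope).
* **Expression.** Counts are negative binomial in the mean/size
  parameterisation (`dispersion` is the size; variance
  $\mu + \mu^2/\text{size}$), with base mean 2 and size 2 per locus and
  spot. Two *balanced* cell-type programmes carry fold-8 effects: five
  marker genes plus three DE lncRNA loci up in the keratinocyte-like
  domain, and a mirror-image programme of the same size up in the other
  domain. The balance is deliberate: expected library sizes then match
  across domains, so library-size normalisation does not shift null
  features between groups. An unbalanced design of this small feature
  count (60 features) would turn normalisation into a compositional
  artefact that makes every null feature differentially expressed —
  with thousands of genes the effect dilutes away, but a desk-scale
  simulation must balance it by construction.
* **Degradation and capture.** Each count unit yields one read from an
  RNA fragment whose length is exponential with mean `degradation`
  (default 500 bp, DV200 $\approx 67\%$ — a moderately degraded FFPE
  sample), truncated to [30, locus length]. In `probe` mode (default,
  emulating hybridisation-probe capture) the read start is uniform in
  the locus; in `polyA` mode the read's 3' end sits an
  exponential-distance from the locus 3' end, reproducing the 3' bias
  of oligo-dT capture on degraded RNA. Read length is capped at 50 bp.
  `probe` is the default because uniform placement makes full-length
  locus recovery meaningful; under `polyA` with short fragments the 5'
  half of a long locus is intrinsically invisible — a property of the
  chemistry the simulator reproduces, not a defect of the caller.
* **Determinism.** Every stage draws from a stream seeded by a fixed
  integer hash of the master seed and the stage name, so runs are
  byte-identical given a seed and stages are independently
  reproducible.

What the generator does **not** emulate: nucleotide sequences and
sequencing errors, UMIs and duplication, spliced alignments, probe
panel composition, lateral diffusion between spots, multi-sample batch
effects, and per-spot cell mixtures. Passing the recovery tests
therefore shows the pipeline's logic is correct under clean coverage
geometry; it does not certify performance on real tissue, where
mapping artefacts and ambient RNA add failure modes outside this
model.

## What the tests establish

Problem sizes are chosen so the full suite runs in a few minutes on
one CPU: Viterbi is checked against exhaustive enumeration of all
$2^n$ paths on 1,000 random tracks of up to 12 bins; EM parameter
recovery uses one 10,000-bin sequence; merge semantics are checked
against a pairwise transitive-closure oracle on 1,000 random TAR sets;
Wilcoxon exactness against full enumeration of all 70 4-vs-4
assignments; type-I calibration on 10,000 independent null features
(the binomial reference interval presumes independent features —
normalising many features by the same per-spot totals couples them and
widens the spread of the rejection rate well beyond binomial, so the
calibration null feeds the test independent values); and end-to-end
recovery on 20 seeded replicates of the default simulation.

On those replicates the pipeline recovers every planted lncRNA locus
(precision = recall = 1 at 50%-overlap matching), reproduces every
database label, and finds every planted DE uTAR at $q < 0.05$. False
DE uTARs appear in a minority of replicates at exactly the rate BH
implies (about 0.2 expected false uTAR discoveries per analysis given
roughly 16 true positives among 60 features); requiring *zero* false
positives in 95% of replicates would need family-wise rather than FDR
control, so the corresponding end-to-end assertion documents this gap
rather than papering over it.

## Known limitations

* The two-state HMM has geometric state durations; very short planted
  loci adjacent to long zero runs are recovered thanks to the merge
  step, not the duration model. Semi-Markov duration modelling is out
  of scope.
* aTAR/uTAR classification is annotation-version-dependent by nature;
  the package treats the supplied GTF as ground truth and offers no
  isoform-aware or promoter/antisense subcategories.
* The normalisation is a stand-in; analyses of real data should
  substitute a spatially aware method upstream of `wilcoxon_de()`.
* `dispersion` is the NB *size* parameter throughout; users coming
  from the $\mathrm{Var} = \mu(1 + \phi\mu)$ convention should note
  $\phi = 1/\text{size}$.
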