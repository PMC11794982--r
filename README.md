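# utarscan

Discovery and spatial analysis of unannotated transcribed regions
(uTARs) in spot-barcoded spatial transcriptomics.

## What it is for

Poly(A)-capture spatial transcriptomics of archival FFPE tissue sees
RNA that probe panels cannot: long non-coding RNAs and other
transcription outside the annotated gene space. `utarscan` is for
analysts who want to pull that signal out of the alignments and ask
whether it is cell-type specific. It takes spot-barcoded alignments
(SAM, barcode in the `CB` tag), a gene annotation (GTF), and stranded
lncRNA reference sets (BED6), and produces labelled transcribed
regions, feature x spot count matrices, QC tables, and a differential
expression analysis — plus a synthetic-data generator with planted
ground truth so every stage is testable without patient data.

## The method

1. **Binning.** The genome is split into non-overlapping 50-bp bins;
   each read increments the bin containing its 5' end, per strand.
   Binned counts conserve reads exactly.
2. **Segmentation.** A two-state hidden Markov model with Gaussian
   emissions on log(count + 1) — states *untranscribed* and
   *transcribed* — is fitted by Baum–Welch EM (pooled across contigs
   and strands) and decoded by Viterbi, ties broken toward
   untranscribed. A literal presence rule (bin active iff any read) is
   available as `mode = "presence"`.
3. **Merging.** Transcribed runs become TARs; same-strand TARs no more
   than 500 bp apart are merged transitively.
4. **Classification.** TARs overlapping annotated genes
   (strand-specific, >= 1 base) are aTARs; the rest are uTARs, labelled
   `db1` / `db2` / `both` / `novel` by strand-specific overlap with two
   lncRNA reference sets. Cross-sample sharing is computed by connected
   components over strand-matched overlaps.
5. **Quantification and DE.** Reads are assigned to gene and uTAR
   features by 5'-position overlap; counts are median-scale
   log-normalised; spots are labelled by a marker signature (strict
   upper-quartile rule); each feature is tested with a two-sided
   Wilcoxon rank-sum test (exact for small untied groups, otherwise
   normal approximation with tie and continuity correction) and
   Benjamini–Hochberg adjusted. Spatial concordance of significant
   uTARs with the marker signature is reported as Spearman's rho.

The simulator plants genes and lncRNA loci on a small multi-contig
genome, draws negative-binomial counts (mean/size parameterisation)
with balanced fold-8 cell-type programmes over a two-domain spot grid,
and emits reads through a fragment-length degradation model
(exponential, mean = `degradation`) with poly(A) 3' bias or uniform
probe placement. `dv200()` computes the standard FFPE RNA-quality
metric (% fragments > 200 bases).

## Worked example

```r
library(utarscan)
config <- pipeline_config(seed = 1)   # default study conditions
res <- run_pipeline(config, "utarscan_demo")
```

This simulates 40 genes and 20 lncRNA loci on three 300-kb contigs,
emits ~46,000 degraded-fragment reads (DV200 ~ 67%) over 200 spots,
and runs the full analysis. Key numbers it prints back:

```
TARs called: 60 (40 aTARs, 20 uTARs)
uTARs in a lncRNA database: 85%
uTAR recovery: precision 1.00, recall 1.00; db labels 100% correct
significant DE uTARs (q < 0.05): 6
    feature n1  n2    U        p        q log2fc direction
43 uTAR0003 50 150 7148 7.30e-22 1.46e-20  0.900        up
52 uTAR0012 50 150  583 4.06e-19 3.04e-18 -0.865      down
57 uTAR0017 50 150 6858 1.46e-18 8.82e-18  0.787        up
```

Every planted lncRNA locus is recovered as a uTAR at 50%-overlap
matching (precision and recall 1.0), database membership labels match
the planted flags, and all six loci carrying a planted fold-8
cell-type effect are significant with the planted direction —
`up` means higher in the keratinocyte-marker-labelled spots. Their
spatial patterns track the marker signature (|rho| ~ 0.5 with the
expected signs). The output directory holds the GTF/BED/SAM/bedGraph
artefacts, the MTX count-matrix triplet, QC and DE tables, a
JSON-lines run log with conservation checks, and spot maps of the
signature score and the top uTAR.

A thin CLI wraps the same functions:

```sh
exec/utarscan run --outdir out --seed 1
exec/utarscan simulate --outdir sim --config config.yaml
```

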