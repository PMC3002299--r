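# dggeprof

Quantitative analysis of DGGE community fingerprints: synthetic-standard
anchored lane alignment, band-level diversity and similarity statistics,
and cross-validated discriminant modelling — with a calibrated
synthetic-gel simulator for end-to-end validation.

## The scientific problem

PCR-DGGE separates same-length 16S rRNA V3 amplicons by their
sequence-dependent melting behaviour, so each predominant phylotype of a
faecal bacterial community appears as one band in a gel lane. Comparing
fingerprints between subject groups — here healthy controls (n = 22),
ulcerative colitis (n = 13) and irritable bowel syndrome (n = 11)
patients, each sample loaded in duplicate across gels — requires:

- **Alignment** of lanes within and between gels onto a common Rf grid,
  anchored on a synthetic standard (SS) loaded in ≥4 lanes per gel. The
  package implements the two-stage scheme: per-SS-band polynomial
  correction of within-gel curvature, then piecewise linear
  stretching/shrinking of each inter-anchor block onto the global mean
  anchor positions. Aligned lanes are 1001-point vectors (Rf = i/1000),
  truncated to Rf ∈ [0.09, 0.82] (731 points) and min–max scaled per
  lane.
- **Band statistics**: peak-picked band counts; intensity-weighted
  Shannon diversity H = −Σ pᵢ ln pᵢ over relative band intensities; Dice
  similarity D = 2m/(nₐ+n_b) with a ±0.008 Rf matching tolerance;
  replicate averaging per sample; one-way ANOVA with Bonferroni pairwise
  comparisons; non-parametric similarity summaries (median, IQR).
- **Discrimination**: NIPALS PLS-DA on the lanes × 731 matrix with
  one-hot class indicators, leave-sample-out cross-validation (replicate
  lanes always share a segment; the sample is the statistical unit), a
  y-scrambling permutation test, CVA projection of the PLS scores, and
  loading-based ranking of the discriminant bands.

Because no gel images are deposited for the original cohort, a
first-class simulator (`simulate_channel()`) generates gels whose
pipeline-measured summaries are calibrated to the study's published
values, for both a universal-primer channel and a Bacteroides-specific
channel. The methods vignette
(`vignettes/dgge-fingerprint-workflow.Rmd`) documents the models and
every calibration decision.

## Worked example

```r
library(dggeprof)
report <- run_study(run_config(seed = 1))
print(report)
```

```
== universal channel (96 retained lanes) ==
  control  n=22  bands 44.9 +/- 3.8  Shannon 3.27 +/- 0.11  Dice median 82.6% (IQR 80.5-84.7)
  IBS      n=11  bands 44.5 +/- 6.9  Shannon 3.06 +/- 0.18  Dice median 76.8% (IQR 72.1-78.7)
  UC       n=13  bands 36.5 +/- 5.8  Shannon 2.95 +/- 0.20  Dice median 76.1% (IQR 73.4-78.9)
  band-count ANOVA p = 0.000104; Shannon ANOVA p = 1.7e-06
  PLS-DA CV success 100.0% at 2 component(s); permutation p = 0.004975 (tail 1.02e-09)
== bacteroides channel (96 retained lanes) ==
  UC       n=13  bands 11.5 +/- 3.6  Shannon 2.09 +/- 0.47  Dice median 37.8% (IQR 31.0-43.3)
  control  n=22  bands 14.6 +/- 2.7  Shannon 2.41 +/- 0.25  Dice median 60.6% (IQR 55.2-66.7)
  IBS      n=11  bands 13.2 +/- 3.8  Shannon 2.23 +/- 0.34  Dice median 58.3% (IQR 53.0-61.5)
  band-count ANOVA p = 0.032; Shannon ANOVA p = 0.0331
```

Reading the output: control subjects carry more bands (richer
predominant flora) and higher intensity-weighted diversity than either
patient group; controls also resemble each other more (higher
within-group Dice), while UC patients lose most of the
Bacteroides-channel community (median similarity 37.8% vs 60.6%). The
cross-validated classifier separates the groups far beyond its
permutation null (empirical p at its floor of 1/201, Gaussian-tail
estimate ~1e-9). Any single simulated cohort fluctuates around the
calibration targets — in this seed the 11-subject IBS group happened to
draw a high band-count mean (44.5 against a target of 39); averaging
replicate cohort draws, as the acceptance script does, removes that
sampling noise.

The numbered scripts under `analysis/` run the same workflow in stages
(simulate + align, band statistics, discriminant modelling, full-study
check) and write their tables under `results/`.

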