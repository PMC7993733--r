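---
title: "Methylation quantification and epigenetic age models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation quantification and epigenetic age models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampage)
```

## The problem

Forensic DNA phenotyping increasingly includes chronological-age estimation
from DNA methylation. `ampage` implements the computational side of a
targeted bisulfite amplicon sequencing workflow for an eight-marker,
44-CpG age panel (*ELOVL2*, *MIR29B2CHG*, *KLF14*, *TRIM59*, *FHL2*,
*PDE4C*, *EDARADD*, *ASPA*): calling percent methylation (beta values) per
CpG from paired sequencing reads, the quality-control metrics that guard
those calls, and tissue-specific age-prediction models for blood, buccal
cells and bones built by stepwise multivariable linear regression. A
synthetic cohort and read generator reproduces the measurement artifacts of
such an assay, so every stage is testable without access to donor data.

## Panel geometry

Marker coordinates are GRCh38, 1-based and fully closed, so
`end - start + 1` equals the amplicon length; all eight bundled markers
satisfy this identity (267 bp for *ELOVL2* down to 108 bp for *ASPA*).
Amplicon offsets of CpG sites are 0-based. CpG labels (C1...Cn) follow the
established naming of each marker even where the label order runs against
genomic coordinates (at *ELOVL2* and *MIR29B2CHG* labels ascend toward the
5' end of the amplicon); the package never re-sorts them. *EDARADD* is a
minus-strand amplicon: its reference is stored in sequencing orientation
while CpG genomic positions stay on the top strand.

Only the 15 CpGs that appear in published model tables carry literature
coordinates (`coord_source = "paper"` in the fixture). The remaining 29
target CpGs have synthetic in-amplicon placements consistent with the
per-marker CpG counts (ASPA 1, EDARADD 2, ELOVL2 9, FHL2 10, KLF14 4,
MIR29B2CHG 3, PDE4C 7, TRIM59 8), and the reference sequences themselves
are synthetic: random DNA carrying a CpG dinucleotide exactly at each
target offset and nowhere else. Real reference sequences can be substituted
through the panel file without code changes; none of the package's
arithmetic depends on the synthetic bases beyond their CpG placement.

## Quantification model

Reads are matched against bisulfite-collapsed references: C at a target CpG
becomes Y (reads may carry C or T there), every other C becomes T, so an
unconverted cytosine outside a CpG surfaces as a mismatch. Matching is
end-anchored and ungapped, both mate orientations are tried, and a pair is
assigned to the unique best reference when its mismatch fraction is at most
5 %. This mismatch threshold plus the unique-best-hit rule emulate a
mapping-quality filter of a conventional bisulfite aligner; the matcher is
deliberately not a general aligner (no gaps, no genome-scale search), which
is appropriate because amplicon reads are primer-anchored copies of known
templates.

Per CpG, bases with Phred quality >= 30 are tallied into C/T/other counts.
Where both mates of a pair overlap a CpG each mate contributes one count,
so depths are reported in paired-read units; `fragment_level = TRUE`
switches to counting each fragment once. Beta is `100 * C / (C + T)` -
other bases are excluded from the denominator - and a CpG passes depth QC
at >= 1000 total reads (C + T + other; applying the threshold to total
depth rather than C + T is an interpretation, flagged here). Failing CpGs
keep their beta alongside the fail flag rather than being suppressed.

Conversion efficiency is 100 times the mean reversed beta `T / (C + T)`
over all non-CpG cytosine positions; misincorporation at a CpG is
`100 * other / depth` (the denominator choice makes the rate a per-read
probability; total depth is used because the definition is otherwise open).
Normalized read depth divides each amplicon's depth at one representative
CpG (default C1) by the total coverage; under a perfectly balanced 8-plex
each share is 0.125.

## The synthetic data generator

The generator emulates the study conditions this kind of assay is
characterized under; its defaults are fixed calibrations, not tuning knobs.

* **Age trajectories.** Published evidence constrains direction and range
  but not functional form, so the forms are explicit stand-ins: *ELOVL2*
  follows a saturating power curve `scale * age^0.7` (its non-linearity is
  what motivates power transformation before modelling); *FHL2*, *TRIM59*,
  *PDE4C* and *KLF14* hypermethylate linearly; *MIR29B2CHG*, *EDARADD* and
  *ASPA* hypomethylate. Lifespan spans over ages 1-93 are roughly 50-70
  percentage points for the wide-range markers and ~11 for *KLF14*, the
  panel's narrowest. In bone, *MIR29B2CHG* C2/C3 are age-flat. A 3 % per
  label-index slope jitter keeps CpGs of one marker from being perfectly
  collinear, and between-individual noise defaults to SD 2 %.
* **Technical duplicate noise.** The SD is `1.9 * sqrt(pi) / 2 ~ 1.68 %`,
  chosen so that the expected absolute difference between iid normal
  duplicates, `2 * sigma / sqrt(pi)`, equals the 1.9 % mean duplicate
  difference of an optimized assay of this design; the identity is verified
  numerically in the test suite before being relied on.
* **PCR bias.** `observed = true + b * 4 * t(1 - t)` with `t = true/100`:
  zero at 0 % and 100 %, maximal (`b`) at 50 %. Default signs encode
  overestimation at *MIR29B2CHG* and *EDARADD* and underestimation at
  *ELOVL2*; the +/-3 % amplitude is a free parameter.
* **Input-DNA bottleneck.** `M = round(ng * 300 * 0.6)` template molecules
  (300 diploid copies/ng, 60 % bisulfite recovery - conversion loses a
  substantial fraction of input); the methylated-template fraction is drawn
  binomially from M before any read sampling, which is why 1 ng
  quantification is unreliable no matter the sequencing depth.
* **Reads.** Primer-anchored pairs; with 2 x 150 geometry the interiors of
  the 267 bp and 215 bp amplicons are covered by one mate only,
  reproducing the coverage dip of the longest amplicons on short-read kits.
  Conversion failures (default probability 0.002 per cytosine) and uniform
  substitution errors (6e-4 per base, giving a ~0.04 % misincorporation
  rate) are applied per molecule; qualities are constant Phred 37.

What the generator does not model: PCR cycle-level amplification, chimeras
and primer dimers, indels, and run-to-run batch shifts. Tests passing on
synthetic data therefore demonstrate the correctness of the arithmetic and
the estimators under the stated noise model, not robustness to every
artifact of real libraries.

## Modelling procedure

Training follows the classical forensic-clock recipe:

1. **Curve estimation.** Per CpG, the linear-fit R^2 of age against raw
   methylation is compared with age against `meth^k` over the grid k = 0.5
   to 3.0 in steps of 0.1 (the literature reports that power transformation
   fits *ELOVL2* best but not the exponent, hence a grid); ties go to
   identity. The transform applies to the methylation predictor, not the
   age response.
2. **Univariate screening.** Simple regression of age on each (transformed)
   CpG; the standardized coefficient equals the Pearson correlation and is
   reported with t, p and R^2.
3. **Stepwise selection by probability of F.** Entry of the smallest
   partial-F p-value below `p_enter` = 0.05, removal of any included
   predictor above `p_remove` = 0.10 (SPSS-style defaults; `p_enter <=
   p_remove` guarantees termination). Partial F per coefficient (= t^2) is
   used; for single-predictor entry this is equivalent to the F-change
   test. The final model is refit by OLS. When nothing enters, an explicit
   empty-model object is returned rather than an error.
4. **Evaluation.** MAE overall and in age categories 1-20, 21-40, 41-60
   and >60 years (the last two bounds are conventional in this literature;
   the first two are the preceding 20-year bins and are overridable), plus
   the Pearson correlation of absolute error with age. Category MAEs
   weighted by category n reconstruct the overall MAE exactly.

Train/test splitting stratifies on age quartile x sex with
largest-remainder allocation, mirroring cohort designs that keep age and
sex distributions comparable (e.g. 160 samples split 112/48). Samples
lacking data at a candidate CpG are dropped mechanically per fit, which
reproduces the familiar situation of a training set shrinking by one when a
single sample fails QC at a model CpG.

Predictions are affine in the transformed predictors and deliberately not
clamped to a plausible age range; a reporting layer may annotate
out-of-range values. Model JSON files carry a panel checksum so applying a
model to calls from a different panel fails loudly.

**Assay equivalence.** To compare two assays measuring the same standards,
the package regresses one assay's betas on the other's per marker and
jointly tests (intercept, slope) = (0, 1): the restricted model is the
identity line, so `F = ((RSS0 - RSS1)/2) / (RSS1/(n - 2))` with
`RSS0 = sum((b - a)^2)`, and p-values are Bonferroni-corrected across
markers. The implementation is checked in the tests against
`car::linearHypothesis` as an independent oracle.

## Numerical choices and degenerate inputs

* Beta is undefined (NA) when C + T = 0; normalized depths are NA when
  total coverage is 0; empty age categories report NA MAE with n = 0.
* Collinearity in `fit_model()` is detected on the predictor correlation
  matrix (reciprocal condition number below 1e-10) and names the worst
  pair; `stepwise_select()` skips entries that would make the design
  near-singular.
* The equivalence F-test handles perfect fits explicitly (RSS1 = 0): an
  exact identity gives F = 0, an exact offset gives F = Inf.
* Zero-variance predictors are excluded from screening and selection with
  a flag rather than an error.
* All stochastic functions accept a seed and restore the caller's RNG
  state; per-sample substreams are derived deterministically from the
  master seed so cohorts are reproducible element-wise.

## Problem sizes used in the checks

The shipped verification uses problem sizes chosen to make the binomial and
Monte-Carlo tolerances meaningful at desk scale: 100,000 read pairs for the
conversion-efficiency calibration (99.8 % expectation, 99.6 % floor),
100,000 pairs per amplicon for the 0.5 % quantification-fidelity bound
(about 3 binomial SDs at that depth), 20 datasets for the stepwise versus
exhaustive best-subset comparison, 50 seeds of 112-sample cohorts for
informative-CpG recovery, and 50 replicates per DNA input (1/20/200 ng) for
the dilution-variance ordering.

## Known limitations

* The age-trajectory forms and their parameters are plausible stand-ins;
  real per-CpG trajectories differ between tissues in ways the generator
  only sketches, so trained-model coefficients on synthetic cohorts are not
  comparable to published coefficients (the underlying cohort data are not
  public).
* The read matcher assumes primer-anchored, full-overlap amplicon reads;
  adapter read-through, trimming artifacts and indels are out of scope.
* Negative-control contamination review remains a manual step; the package
  only reports numeric QC rates.
* Stepwise selection inherits the known optimism of data-driven predictor
  selection; the exhaustive-subset oracle bound is verified in tests up to
  10 candidates.
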