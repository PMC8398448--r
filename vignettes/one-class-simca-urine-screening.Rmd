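---
title: "One-class SIMCA screening of untargeted urine metabolomes"
author: "metaboSIMCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class SIMCA screening of untargeted urine metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboSIMCA)
```

## The problem

Fentanyl and its analogues are potent, taken at low doses, and cleared
quickly: by the time a urine sample is collected, the parent drug and its
direct metabolites may be undetectable by targeted assays. The idea this
package implements is to look instead at the *indirect* footprint —
systematic alterations of the urinary metabolome that accompany fentanyl
exposure — in untargeted LC-HRMS peak tables. Detection then becomes a
one-class classification problem: model the metabolic profile of
fentanyl-positive samples and ask, for a new sample, whether it falls
inside that class's acceptance region.

The full workflow is: peak-table ingestion, sparsity filtering, batch
normalization, replicate screening, removal of all features attributable
to administered drugs themselves, one-class SIMCA with discriminant-power
variable selection per chromatographic mode (reverse phase and HILIC),
and a serial fusion of the two modes' decisions.

## The model

### PCA with T²/Q diagnostics

All latent modelling is principal component analysis fitted by singular
value decomposition of the centered (and optionally Pareto- or
auto-scaled) intensity matrix. For a K-component model of an $n \times p$
matrix, component variances are eigenvalues of the sample covariance
($n-1$ denominator). A projected run is summarised by two distances:

* Hotelling $T^2 = \sum_k t_k^2/\lambda_k$, the Mahalanobis distance of
  its scores inside the model plane, with the critical value
  $T^2_{lim} = \frac{K(n-1)(n+1)}{n(n-K)} F_{1-\alpha}(K, n-K)$;
* the Q residual (squared norm of the part of the run the model cannot
  reconstruct), with the Jackson–Mudholkar critical value computed from
  the discarded eigenvalues, falling back to a moment-matched
  $g\chi^2_h$ when the Jackson–Mudholkar terms degenerate.

Loadings carry a deterministic sign (largest-magnitude entry positive) so
fits are reproducible across platforms. Model order is explored with
venetian-blinds cross-validation: runs ordered by (batch, injection
order), run $i$ in fold $i \bmod F$. The PRESS uses naive row projection
— held-out rows are projected onto loadings fitted without them, with the
centering taken from the full table. This choice makes the $K=0$ PRESS
exactly the total centered sum of squares and matches the behaviour of
the commercial chemometrics tools this family of analyses is usually run
in; it is known to bias PRESS optimistically, which is acceptable here
because model order is ultimately chosen by the classification RMSECV
(below), not by PRESS.

### One-class SIMCA

The classifier models a single target class (fentanyl-positive samples).
Training, per chromatographic mode:

1. **Class scaling.** Centering and scaling (Pareto for RP, autoscaling
   for HILIC by default) are fitted on the class runs only — each class
   carries its own preprocessing, as in classical SIMCA.
2. **Discriminant power.** For each feature $j$,
   $dp_j = \sqrt{s^2_{out,j} / s^2_{in,j}}$, where $s^2_{out,j}$ is the
   mean squared residual of out-of-class runs under the class model and
   $s^2_{in,j}$ is the *cross-validated* mean squared residual of the
   class's own runs (leave-one-out up to class size 30, 10-fold venetian
   blinds beyond). Cross-validating the denominator avoids the deflation
   a self-fitted residual would cause. Under exchangeability $dp$
   concentrates near 1; features are retained when $dp$ strictly exceeds
   the threshold (1.5 for RP, 4.5 for HILIC by default). The class model
   used inside the dp computation has `dpK = 4` components by default —
   the order of the reference RP model — and is exposed as an argument.
3. **Model order by RMSECV.** For each candidate K, venetian-blinds
   cross-validation over the class runs refits scaling and PCA without
   each fold and scores the held-out runs. Two error curves are
   recorded: a reconstruction form (root mean squared residual) and a
   classification form, the root mean square of the *distance
   shortfall* $\max(0, d - d_{lim})$ — zero for a run accepted by the
   acceptance rule, positive in proportion to how far outside it falls.
   Selection uses the classification form (the reference analysis picks
   its model by class-membership performance), ties going to the
   smallest K.
4. **Acceptance rule.** A run with reduced distances
   $T^2_r = T^2/T^2_{lim}$ and $Q_r = Q/Q_{lim}$ is accepted iff
   $d = \sqrt{T^2_{r}{}^2 + Q_r^2} \le \sqrt{2}$, boundary inclusive —
   the combined reduced-distance convention of the PLS_Toolbox family;
   the limit is configurable.

Cross-validated confusion summaries hold out class runs fold by fold
(feature selection and K fixed, scaling and PCA refitted) and project
out-of-class runs onto the full model. Sensitivity and specificity are
reported as integer percentages rounded half-up, the convention under
which 23/24 prints as 96% and 42/57 as 74%.

### Serial fusion

The two modes are fused serially: a sample is positive only if the RP
model accepts it *and* the HILIC model accepts it; RP-negative samples
are never re-evaluated. The fused false-positive set is exactly the
intersection of the two models' false-positive sets, so the fused rate
can never exceed either single-mode rate. Samples excluded by replicate
screening in one mode are not fused (no decision exists for them there).

## Preprocessing choices

* **Sparsity filter**: a feature is retained when detected (nonzero) in
  at least 15% of non-blank runs, boundary inclusive (the rule removes
  features detected in *less than* 15%). Blank injections are excluded
  from the denominator.
* **Batch normalization**: RP batches use the spiked internal standard
  (fentanyl-D5) in QC injections — each QC's ratio to the grand-mean QC
  area is a correction factor, and every run is divided by the factor of
  the nearest *preceding* QC in injection order within its batch
  (per-QC ratios, not a drift interpolation). HILIC batches use pooled
  urine injections the same way, with the pool run's mean intensity over
  features as its profile summary. Both corrections are invariant to
  batch relabeling.
* **Replicate screening**: a mean-centered 2-component PCA is fitted on
  all study runs; a replicate is flagged only when it leaves the T²/Q
  acceptance region (either 95% limit exceeded) *and* its score-space
  distance to its sample's replicate centroid exceeds 3 times the median
  within-sample replicate distance. The second condition makes this a
  *replicate* screen: a sample whose replicates agree is never flagged,
  however unusual its profile. (A pure "both limits exceeded" rule
  fails on exactly the case it exists for: a gross outlier rotates PC1
  toward itself, collapsing its own Q residual — the classic masking
  effect.) Unflagged replicates are averaged; samples left with fewer
  than two replicates are excluded with a warning. The screening PCA is
  fitted globally (the alternative, per-class fits, is not used; which
  runs entered the original screening fit is not documented in the
  reference workflow).
* **Log transform**: $x \mapsto \log_{10}(x + \varepsilon)$ with
  $\varepsilon$ the smallest nonzero intensity of the table, recorded in
  provenance. Scaling always follows the log transform when both are
  requested.
* **Control subtraction** (in vitro): the feature-wise mean over control
  runs is subtracted from every run. In the urine workflow the default
  order is subtract-then-scale, configurable, since the reference
  description is ambiguous on this point.
* Zeros code "not detected" throughout; no missing-value imputation.

## The synthetic study generator

No urine or cell-culture data are publicly deposited for this workflow,
so the package ships a generator that emits peak tables with the
statistical structure the analysis assumes, and the ground truth to
verify recovery. Study-condition defaults:

* **Design**: 81 samples (18 control / 24 fentanyl / 12 opioids / 27
  other drugs) × 3 technical replicates, in 3 batches with a QC opening
  each batch and recurring every 10 study injections; a 12-treatment ×
  4-collection-time × 2-repetition in vitro design (96 runs). The two
  chromatographic modes share samples and layout but have independent
  feature spaces and noise streams.
* **Features**: 2000 per mode — the scale of a sparsity-filtered
  untargeted urine table (the raw vendor exports cap at 7000 features, of
  which roughly a third survive the 15% rule).
* **Signal**: the fentanyl fingerprint is a *low-rank* latent shift —
  60 features in 4 correlated blocks, each sample expressing each block
  with activation $\mathcal{N}(1, 0.2)$, a fixed sign per feature and
  log2 magnitude 2; an opioid-shared shift (40 features, magnitude 1)
  applies to both the fentanyl and opioids groups; each non-control
  group also expresses 15 class-exclusive parent-drug features, which
  exist to exercise exclusion lists. Fingerprint features draw their
  baselines from the well-detected abundance range: a marker sitting at
  the detection limit would be censored away and could never have been
  discovered in the first place.
* **Nuisance**: log-normal feature baselines (log-mean 11, log-SD 1.5),
  per-sample biological variation (log-SD 0.4), technical replicate
  noise (log-SD 0.1), per-batch multiplicative factors
  $e^{\mathcal{N}(0,\,0.3)}$, and detection-limit zeroing of the lowest
  30% of urine intensities. Internal-standard QC areas have a 5% CV.
* **Determinism**: one seed drives named substreams (layout, baselines,
  effects, batch, replicate, QC) per output table, so identical configs
  are bitwise reproducible and the RP table is unchanged by whether the
  HILIC table is generated.

The effect sizes are a *calibration*, not an inference: nothing in the
reference analysis quantifies the fingerprint's magnitude, so the
defaults were chosen once so that the cross-validated RP model lands at
the published operating point (≈96% sensitivity at ≥70% specificity)
under the study design above, and are documented here as such. Two
honest differences from clinical data follow. First, synthetic
specificity is essentially 100%: the planted opioid-shared and
fentanyl-specific sets are disjoint by construction, so no out-of-class
sample carries a partial fentanyl fingerprint, whereas real cohorts
(co-administration, polydrug use, diet, medication) produced ~26% false
positives. Second, the generator plants no retention-time structure, no
adducts or isotopes, and no correlated drift within batches — passing
tests show the pipeline recovers the structure it models, not that it
would survive every artifact of real acquisitions.

## Numerical and degenerate-input choices

* Variance uses the $n-1$ denominator everywhere; constant features get
  a zero scale entry and pass through scaling as all-zero columns.
* `fitPCA()` refuses K above `min(n-1, p)` or above the numerical rank;
  the internal cross-validation refits instead cap K at the achievable
  rank of the fold (zero-inflated features can go constant within a
  fold).
* When a model uses the full rank, Q residuals are ~0 and the Q limit is
  0; reduced Q is defined as 0 for runs with Q below 1e-8 and Inf
  otherwise.
* Features whose cross-validated in-class residual is exactly zero get
  `dp = Inf` (reported, and selected by any finite threshold).
* RMSECV ties choose the smallest K. Exclusion matching and the
  acceptance rule are boundary-inclusive.
* m/z matching tolerance defaults to 5 ppm and rt tolerance to 0.5 min —
  the alignment tolerances of the upstream peak processing.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full study design (81 ×
3 runs, 2000 features per mode) for the headline recovery checks, and
scaled-down tables (hundreds of features) for unit-level properties;
these sizes keep a complete run in the low tens of seconds while leaving
the design identical to the study conditions. The null-calibration check
of the acceptance rule is run with `dp_threshold = 0`: selecting the
upper tail of a *null* discriminant-power distribution is itself an
overfitted filter (out-of-class runs are then rejected for reasons the
selection manufactured), so the rule's calibration is measured without
selection.

## Known limitations

* Discriminant-power selection is greedy and univariate; with thousands
  of null features a tail above any threshold survives, and the
  resulting model inherits that selection bias. The reference analysis
  shares this property.
* One-class SIMCA as implemented has no probabilistic membership; the
  √2 limit is a convention, not a calibrated error rate.
* The pipeline starts at peak tables: no raw spectra, peak picking,
  retention-time alignment, adduct/isotope handling, or metabolite
  identification.
* PRESS by naive row projection is optimistic; use the classification
  RMSECV (the default) for model-order choice.
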