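---
title: "Methods: urinary 1H-NMR bucketing, OPLS-DA and borderline-aware evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary 1H-NMR bucketing, OPLS-DA and borderline-aware evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urinmr)
```

## The problem

Discriminating neuropathic pain (NP, arising from a lesion of the nervous
system) from nociceptive pain (NC, arising from tissue damage) is clinically
difficult, and questionnaire-based scores are noisy. A urinary
^1^H-NMR metabolomic profile offers an objective readout: urine spectra are
reduced to a bucket table, pairwise discriminant models are fitted between
the pain classes and matched controls (C), and the models' membership
predictions are evaluated against the clinical diagnosis as gold standard.

`urinmr` implements that workflow end to end — bucketing, normalization,
the latent-variable engine, validation, and the contingency-table
evaluation — together with a synthetic spectrum generator so every stage is
testable with known ground truth and no external data.

## Spectral bucketing and normalization

Processed spectra are integrated over consecutive buckets of equal width
(0.04 ppm) across 0.5–9.5 ppm; the 4.50–6.50 ppm window is excluded whole
(water suppression artifacts and the broad urea resonance), and each
sample's bucket areas are normalized to a total of 100 to remove dilution
differences between urine samples.

Numerical choices:

* **Bucket convention.** Buckets are left-closed/right-open; an exclusion
  window removes every overlapping bucket whole, never partially. This
  yields the closed-form counts 225 (no exclusion), 175 (water/urea) and
  168 (additionally the mannitol window, below).
* **Integration.** Bucket areas are trapezoidal integrals of the linear
  interpolant, implemented as a precomputed linear map from axis
  intensities to bucket areas (`bin_weights()`), so binning a cohort is a
  single matrix product. Negative bucket totals (possible with baseline
  noise) are floored at 0; raw intensities are *not* floored, preserving
  the noise statistics inside each bucket. Because flooring can only add
  mass, the exact bucket-sum/total-integral identity holds for noise-free
  spectra and is asserted there.
* **Mannitol.** Mannitol is a common excipient of drugs used in pain
  treatment; its multiplet (3.62–3.90 ppm) tracks medication, not biology.
  The default pipeline drops that window *before* fitting and re-normalizes
  the remaining buckets to 100 (re-normalization keeps rows comparable; a
  flag skips it, since it is not unambiguously part of the original
  procedure).

## The latent-variable engine

All latent-variable computations are written out explicitly (NIPALS); SVD
appears only as a test oracle.

* **Scaling.** Columns are mean-centered and Pareto-scaled (divided by the
  square root of the column standard deviation) by default, for PCA and
  (O)PLS-DA alike — one consistent default, overridable to unit-variance or
  centering only. Constant columns are centered only and flagged. Inside
  cross-validation the scaling is refitted on each training fold; anything
  else leaks test information into the model.
* **PLS-DA.** Pairwise discrimination regresses a 0/1 dummy (class A = 1)
  on the bucket table by NIPALS PLS1.
* **OPLS-DA.** The orthogonal variant first extracts `n_ortho` components
  orthogonal to the dummy (Trygg–Wold orthogonal filtering) and then fits
  exactly one predictive component on the filtered matrix, so between-class
  separation is forced into the first component and orthogonal components
  express intra-class variability only. For a single response this is a
  rotation of PLS1: the fitted values of 1 predictive + k orthogonal OPLS
  equal those of (k+1)-component PLS1, an identity the test suite asserts
  to 1e-8 on random matrices.
* **R²Y and Q²Y.** R²Y = 1 − RSS/TSS on the training fit. Q²Y is its
  cross-validated analogue, 1 − PRESS/TSS over out-of-fold predictions from
  stratified folds (default 7, the convention of the commercial package the
  field uses; folds are built per class and dealt round-robin from a seeded
  shuffle so both classes appear in every fold, with the fold count reduced
  when a class is smaller than the fold count). A large R²Y − Q²Y gap
  (> 0.3) flags overfitting.
* **Component count.** `select_n_ortho()` scans 0..max and returns the
  smallest orthogonal count whose Q²Y is within 0.01 of the maximum —
  additional components beyond that only add noise.
* **Permutation test.** Class labels are shuffled (identity permutation
  excluded), the model and its Q²Y recomputed per draw, and the p-value
  computed with the add-one estimator (1 + #{Q²_perm ≥ Q²_obs})/(n + 1),
  which cannot return 0. The study's reference size is n = 400; the test
  suite uses 99 to keep the default run short (identical machinery, smaller
  Monte-Carlo resolution).
* **Loadings diagnostics.** Per bucket, `magnitude` is the covariance with
  the predictive score and `reliability` the corresponding correlation;
  reliability surfaces small but consistent signals that covariance under
  Pareto scaling underweights. Positive values point toward the class
  coded 1.

## Membership calls and the contingency table

OPLS-DA predictions are continuous on the dummy scale. A value above 0.65
indicates membership, below 0.35 non-membership, and the band between is
borderline/uncertain; boundary values count as borderline (the thresholds
are strict inequalities). The conservative evaluation deems borderline
calls wrong attributions: borderline affected samples are counted with the
false negatives, borderline unaffected with the false positives — the raw
borderline counts are always reported separately so the alternative
readings can be audited. A midpoint mode applies a single 0.5 cut instead;
because it can only turn wrong-by-construction calls into possibly-correct
ones, its accuracy is never lower, a property the suite asserts.

Metrics are the standard ratios (sensitivity TP/(TP+FN), specificity
TN/(TN+FP), PPV, NPV, accuracy); zero-denominator ratios are reported as
`NA`, never 0. Significance is the exact two-tailed Fisher test computed by
enumerating the hypergeometric support under fixed margins and summing the
probabilities of tables no more probable than the observed one (the
"probability ≤ observed" convention; a doubling-rule variant sits behind a
flag).

The contingency table is built from the fitted model's membership
predictions of the samples — the convention of the commercial package the
field reports with, under which accuracy tracks R²Y. The stricter
out-of-fold predictions are kept in every report (`cv_predictions`) for
readers who prefer them.

## The synthetic cohort generator

The generator exists to give every downstream stage a test bed with known
ground truth. It emulates:

* a dense ppm axis (0.5–9.5 at 0.002 ppm, ≥ 20 points per bucket) with
  Lorentzian lineshapes at standard urine assignment positions (peak
  centers are chosen off the 0.04-ppm bucket-edge grid so a metabolite's
  mass is not split between buckets by construction);
* log-normal between-subject metabolite levels; class structure as a
  multiplicative fold-change on the NP class mean for choline,
  phosphocholine, citrate, alanine and taurine (defaults 2.0, 1.8, 1.5,
  1.5, 1.5);
* an optional mannitol signal present only in pain samples (NP and NC),
  emulating the medication excipient;
* per-sample log-normal dilution (CV 0.2) — the motivation for total-area
  normalization — and additive Gaussian spectral noise (sd 0.02);
* cohort sizes defaulting to the study's 25 NP / 12 NC / 37 C, with
  controls tagged `C-NP`/`C-NC` in design order to stand in for the study's
  age/gender-matched control subsets (matching covariates themselves are
  not simulated, so the tags are consumed, never recomputed).

No field data informs the within-class variance: the study reports none, so
the coefficients of variation (0.10–0.20 per metabolite) are free
parameters. They are pinned by the package's own acceptance surface — a
two-fold choline elevation at 25 + 25 samples must constitute a strong,
unambiguously detectable signal (Q²Y ≥ 0.8) while cohorts with all folds at
1.0 stay at chance (Q²Y ≤ 0.2) — and then frozen. Consequences of this
choice, not separately tuned: the NP-vs-NC model recovers all five elevated
metabolites in the top ten discriminant buckets at the fixed seeds the
tests use, though the weakest effect (alanine at fold 1.5) sits near the
boundary of that ranking across arbitrary seeds, competing with the
Lorentzian tail of the strong choline singlet in the adjacent bucket and
with high-variance background buckets (creatinine, hippurate).

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: FIDs and phase/baseline errors, pH-dependent
chemical-shift drift (citrate in particular moves with urinary pH), peak
overlap beyond the fixed library, non-Gaussian technical artifacts, and any
real biological covariance between metabolites. Synthetic results
demonstrate the *machinery* (bucketing, model, validation, evaluation), not
clinical performance.

Because NC samples receive no metabolite fold-changes, the synthetic
NC-vs-C contrast is null once mannitol is excluded — the pipeline reports
an honest near-zero Q²Y there, unlike the study's real data where NC also
differed from controls.

## Problem sizes and determinism

Everything is deterministic given the seed: cohort generation, fold
assignment, permutation draws (child seeds are derived arithmetically from
the master seed, kept below 2^31). The default test suite simulates
cohorts of 10–50 samples, uses 99 permutations, 50 null seeds for the Q²Y
null check and 20 for the permutation-p null check; `scripts/acceptance.R`
runs the full study-sized cohort (74 samples, 168 buckets after
exclusions) with n = 400 permutations per model. These sizes are the
package's own choice of a compact but statistically meaningful test bed.

## Known limitations

* Two-class models only; no multi-class discrimination, O2PLS or
  VIP-based variable selection.
* No peak alignment/warping or probabilistic-quotient normalization;
  bucketing assumes shift-stable spectra.
* The borderline-to-cell assignment (affected → FN, unaffected → FP) is a
  documented convention; the raw borderline counts are the primitive data.
* Q²Y depends on the fold layout; with very small classes (e.g. 12 NC) the
  fold count shrinks and Q²Y becomes noticeably seed-dependent, mirroring
  the instability the field reports for small cohorts.

## A worked run

```{r example, eval = FALSE}
design <- cohort_design(seed = 7)          # study-sized synthetic cohort
cohort <- generate_cohort(design)
mat <- bin_cohort(cohort)                  # 175 buckets, rows sum to 100
report <- run_all(mat, n_perm = 99, seed = 7)
print(report)
rank_discriminants(report$models$np_vs_nc,
                   annotation = library_annotation(), top = 10)
```
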