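---
title: "Detecting command-following in fNIRS with Riemannian covariance decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting command-following in fNIRS with Riemannian covariance decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsaware)
```

## The problem

Patients with disorders of consciousness may be aware but unable to show it
behaviourally. A bedside test for *command following* asks the patient to
perform a mental-imagery task on cue and then asks the data whether the brain
responded. `nirsaware` implements such a test for functional near-infrared
spectroscopy (fNIRS): if short trials of motor--speech imagery (IMAGERY) can be
decoded from trials of rest (NO-IMAGERY) above chance, the dataset is evidence
of responsiveness; if not, the data are consistent with unresponsiveness.

The paradigm is a blocked event-related design: a run starts with a 40-s
baseline, followed by six blocks of five trials alternating between IMAGERY
and NO-IMAGERY. Each trial is a 1-s auditory cue, a 2-s task window and 15 s
of rest; a run lasts 580 s at a 6.94 Hz sampling rate, and a dataset pools two
runs, giving 30 trials per condition. The montage covers left fronto-parietal
cortex with nine sources and eight detectors: 18 long (3-cm) channels and one
short (1-cm) channel that sees only scalp physiology.

## The decoding model

Decoding never assumes a canonical haemodynamic response; each trial is
represented by a structured covariance matrix instead.

1. **Preprocessing.** Raw two-wavelength intensities are converted to optical
   densities, `od(t) = -ln(I(t)/mean(I))`; motion artifacts are repaired by
   temporal derivative distribution repair (TDDR); scalp physiology is removed
   by regressing each long channel on the same-wavelength short-channel trace;
   the modified Beer--Lambert law (partial path length factor 6) yields HbO and
   HbR concentration changes; a zero-phase second-order Butterworth band-pass
   is applied; epochs span 0--12 s post cue onset and are linearly detrended.
   Analyses run separately for HbO, HbR, and both stacked ("channel doubling").

2. **Trial covariances.** Per cross-validation fold, class-average prototypes
   `P` are computed from the training trials; xDAWN spatial filters (f per
   class, f in {2, 4, 6}) maximise evoked-to-total power; each trial is
   augmented as `[P_IMAGERY; P_NO-IMAGERY; X_i]` after filtering (4f rows) so
   its covariance also encodes trial-to-prototype similarity; covariances are
   OAS-shrunk towards a scaled identity (trace preserved, shrinkage in [0, 1]).

3. **Tangent-space classification.** Covariances live on the manifold of
   symmetric positive definite matrices with the affine-invariant metric
   `d(A,B) = ||log(A^{-1/2} B A^{-1/2})||_F`. The Fréchet mean of the training
   covariances anchors a tangent-space map; the resulting vectors (dimension
   `D(D+1)/2`, D = 4f) are classified by L2-regularised logistic regression
   (inverse regularisation C in {1, 10, 100, 1000}).

4. **Selection and inference.** A stratified five-fold cross-validation scores
   each of the 12 (f, C) configurations on one shared fold assignment; the
   best mean accuracy is the observed statistic. Its permutation null shuffles
   the trial labels and re-runs *the entire analysis* — fold stratification,
   prototype and filter fitting, covariance estimation, tangent mapping,
   classification and hyperparameter selection — so that the null statistic is
   distributed exactly like the observed one under exchangeability. The
   empirical p-value is `(1 + #(null >= observed))/(1 + N)`. The dataset is
   labelled RESPONSIVE when the minimum p-value over HbO, HbR and combined
   falls strictly below alpha = 0.05.

Because the selected accuracy is a best-of-twelve maximum, it sits well above
50% even on unresponsive data; this selection optimism is the empirical
"chance level" the permutation null reproduces. During development we
compared this to a cheaper null that refits only the selected configuration:
on simulated unresponsive data that variant was severely anti-conservative
(its nulls lack the selection maximum), so re-selection inside the null is the
package default; `null_method = "fixed"` remains available for comparison.

### Sequential curtailment

`permutation_pvalue(alpha_stop =)` and the `early_stop` diagnosis option
implement decision-equivalent curtailment: with N permutations and threshold
alpha, significance requires fewer than `ceiling(alpha (N+1))` null values at
or above the observed accuracy, so once that count is reached the remaining
permutations cannot change the label and are skipped. Curtailed p-values are
reported from the permutations actually run and are conservative (always at
or above alpha); significant results always run the full N. A second,
diagnosis-level shortcut (`sequential`) skips the permutation nulls of the
remaining chromophore sets once one exact p-value has fallen below alpha:
further p-values can only lower the minimum, so the RESPONSIVE label is
already determined; skipped sets still report their selected model and
accuracy, with `p_value = NA`. Both shortcuts are off by default; the
acceptance script enables them.

## The synthetic-data generator

Real recordings from the study paradigm are not redistributable, so the
package ships a forward simulator that every downstream stage is tested
against:

* **Evoked response:** a canonical double-gamma HRF (peak 6 s, undershoot
  16 s, ratio 1/6) convolved with the 2-s task boxcar of every IMAGERY trial,
  scaled by a smooth unimodal spatial profile across long channels, with
  Gaussian per-trial amplitude jitter (sd 0.25). HbR mirrors HbO at ratio
  -1/3 with a 1-s lag. UNRESPONSIVE runs carry no evoked component at all.
* **Systemic physiology:** one shared time course of Mayer waves (0.5 uM at
  0.095 Hz), cardiac pulsation (0.2 uM at 1.1 Hz) and linear drift
  (0.001 uM/s), entering every channel with a random gain in [0.7, 1.3] —
  including the short channel (gain 1), which carries nothing else, so
  short-channel regression has the correct target.
* **Local vasomotion:** independent AR(1) noise per long channel
  (stationary sd 0.35 uM HbO, half for HbR, coefficient 0.97 at 6.94 Hz).
  This is the component that genuinely limits decoding, because it is neither
  task-locked nor removable via the short channel.
* **Optics:** Beer--Lambert forward model onto two wavelengths (760/850 nm by
  default — the device class does not publish its wavelengths, so these are
  conventional values with a bundled extinction table) with multiplicative
  white measurement noise (fractional sd 5e-4) and unit baseline intensity.

The default evoked amplitude (0.5 uM peak HbO) was calibrated once so that
the grid-search-selected cross-validation accuracy on a two-run RESPONSIVE
dataset is approximately 0.8 under the default noise model, the operating
point at which the detection claims are evaluated.

What the generator does *not* emulate: optode-scalp coupling variation,
anatomical light propagation, motion artifacts beyond injected test spikes,
non-stationary alertness effects, or inter-subject variability. Passing tests
therefore demonstrate the correctness and calibration of the analysis chain
under a plausible physiological model, not clinical performance on patients.

## Numerical choices

* **Band-pass edges.** The source protocol's filter description ("low-pass
  and high-pass cut-offs at 0.1 and 0.4 Hz") defines an empty band if read
  literally, and a 0.1-Hz high-pass would suppress the 1/18 Hz trial
  fundamental. The default passband is [0.01, 0.4] Hz, both edges
  configurable; the filter is applied forward and backward (zero phase,
  effective order four) with odd-reflection padding and steady-state initial
  conditions so constant inputs map exactly to zero.
* **TDDR** follows the published robust-reweighting algorithm per
  channel/wavelength (Tukey biweight on the low-pass derivative, tolerance
  1e-8, at most 50 iterations). On pathological zero-noise input its noise
  scale collapses and sparse evoked responses are themselves attenuated;
  tests of the linear-chain inverse therefore disable it (`tddr.enabled`).
* **Epochs** are 0-based and inclusive: samples `round(onset fs)` through
  `round(onset fs) + floor(12 fs)`, i.e. 84 samples at 6.94 Hz; the linear
  trend is fitted on the full epoch.
* **Matrix functions** use symmetric eigendecompositions with an eigenvalue
  floor of 1e-12. The Fréchet mean iterates the tangent-space fixed point
  from the arithmetic-mean start until the step norm drops below 1e-8 (at
  most 50 iterations); the iterate sequence is Anderson-accelerated (depth 3,
  with a positive-definite safeguard), which does not change the fixed point
  or the stopping criterion. Inside the cross-validation pipeline the
  reference is converged to 1e-6 — tangent features move by less than that,
  far below the 1/12 per-fold accuracy granularity.
* **xDAWN** solves the generalized eigenproblem of evoked versus total
  covariance by Cholesky whitening with a relative jitter of 1e-10 (escalated
  only if the total covariance is numerically singular, with a warning);
  filters are normalised to unit total power. Prototypes are reduced by their
  own class's filters, trials by all 2f filters, in the fixed row order
  [P_IMAGERY; P_NO-IMAGERY; trial].
* **Logistic regression** is solved by Newton iterations in the row space of
  the training features (thin SVD), tolerance 1e-6, intercept unpenalised.
* **Ties** in the grid resolve to the smallest f, then the smallest C; null
  accuracies equal to the observed one count against significance (`>=` with
  a 1e-12 guard), which is conservative.
* **Fold assignment** shuffles within class under a seed and deals
  round-robin; all 12 configurations share one assignment. Under label
  permutation the folds are re-stratified on the shuffled labels, because
  stratification is part of the procedure being permuted; keeping the
  original folds would unbalance them and bias the null downward.
* **Determinism.** Every stochastic step (simulation, folds, permutations)
  derives from explicit integer seeds; identical seeds give bit-identical
  results end to end.

## Problem sizes

The test suite and the acceptance script evaluate, per dataset, two simulated
580-s runs (60 trials), a 12-configuration grid search and 99-permutation
nulls for each of the three chromophore sets. The suite checks sensitivity on
9 RESPONSIVE datasets and specificity plus the null chance level on a fleet
of 28 UNRESPONSIVE datasets; the acceptance script uses 9 RESPONSIVE and 30
UNRESPONSIVE datasets (reporting the sizes alongside the values). These sizes
keep a single-CPU evaluation to tens of minutes while leaving the binomial
uncertainty of the reported fractions a few percentage points.

## Limitations

* The permutation test treats trials as exchangeable; slow autocorrelated
  physiology induces mild dependence between trials of the same run, which
  the block-alternating design limits but does not remove.
* The min-P combination over three correlated feature sets is used without
  multiplicity correction, exactly as in the decision rule it implements; its
  family-wise error is bounded by the sum of the per-test levels and is
  measured empirically by the specificity suite.
* Curtailed p-values are bounds, not estimates; re-run with `early_stop =
  FALSE` for exact values.
* The simulator's spatial profile is a fixed smooth bump; real activation
  topographies vary, and xDAWN's advantage will vary with them.
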