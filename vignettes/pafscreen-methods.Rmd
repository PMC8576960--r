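---
title: "Methods: P-wave morphology, HRV, and CART ensembles for PAF screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: P-wave morphology, HRV, and CART ensembles for PAF screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Paroxysmal atrial fibrillation (PAF) is intermittent: between episodes the
rhythm is sinus, and an ECG taken at a routine visit usually shows nothing a
clinician can flag. The premise of this package is that the atrial substrate
that predisposes to PAF leaves quantitative traces in non-episode ECG — in
the morphology of the P-wave (atrial depolarization) and in the
beat-to-beat structure of the RR-interval series — and that these traces
can be pooled by an ensemble classifier into a usable screening signal.

The pipeline has three stages:

1. **P-wave morphology (6 parameters).** After R-peak detection and P-wave
   delineation, the direct parameters are the wave width PW (ms), amplitude
   PA (mV) and onset-to-peak time PD (ms). The wave is additionally fitted
   with the Gaussian model \(y(i) = A e^{-((i-C)/W)^2}\), \(i = 1,\dots,D\),
   by a hybrid Taguchi-genetic algorithm (HTGA), contributing \(A, C, W\).
2. **Heart rate variability (25 parameters).** Eleven time-domain
   statistics, seven frequency-domain band powers from Welch and Burg-AR
   spectra of the cubic-spline-resampled tachogram, and seven nonlinear
   measures (Poincaré SD1/SD2/SD2:SD1, approximate and sample entropy, DFA
   \(\alpha_1, \alpha_2\)).
3. **Classification.** Bagging, AdaBoost, and two-layer Stacking ensembles
   of CART trees (100 members, complexity parameter 0.1), evaluated by
   stratified tenfold cross-validation with seven indicators plus AUROC.

## Delineation policy

No delineation algorithm is canonical at 128 Hz, so the package fixes a
deterministic, testable policy:

* R-peaks: 5–15 Hz band-pass, derivative, squaring, 150 ms
  moving-window integration, adaptive threshold at a quarter of the 99th
  percentile, refinement to the raw-signal maximum, 200 ms refractory
  period. On noiseless synthetic rhythms the detector recovers ground-truth
  peaks within ±1 sample.
* P-search window: 250 ms to 60 ms before each R-peak. The baseline is the
  median of the window's first 20 ms; the P-peak is the maximum above
  baseline; onset and offset are the crossings of 5 % of the local P
  amplitude. Beats are *dropped, never imputed* when the amplitude is below
  0.05 mV, a fiducial leaves the window, or the beat sits within 300 ms of
  a record boundary.
* Subject-level aggregation of all per-beat P parameters is the median,
  for robustness against residual delineation outliers.

## The HTGA Gaussian fit

The fit minimizes the sum of squared errors over the segment's own 1-based
sample grid. The genetic search uses size-2 tournament selection, the
Taguchi orthogonal-array crossover, per-gene Gaussian mutation, and
elitism; the crossover lays the two-level L4(2³) array over the three
factors (A, C, W), scores each run by the signal-to-noise ratio
\(\eta = -10\log_{10}(\mathrm{SSE} + 10^{-12})\), and assembles the child
from the per-factor level with the larger mean SNR. L4 is the smallest
standard two-level array accommodating three factors.

Defaults: population 50, 100 generations, crossover rate 0.8, mutation
rate 0.1, bounds \(A \in [0, 2\max|y|]\), \(C \in [1, D]\),
\(W \in [0.5, D]\). Mutation perturbations start at 10 % of each
parameter's range and shrink by 5 % per generation; the annealing gives
the search a fine-refinement phase that pure constant-scale mutation
lacks, which is what brings median parameter recovery on noiseless
segments under 2 % relative error. The factor-wise SNR child is *not*
guaranteed to be the best of the \(2^3\) parent-gene combinations — with
strong C–W interaction it picks the brute-force optimum only about half
of the time — but it is always one of the eight, never the worst, and
beats both parents in roughly three quarters of random pairings; elitism
makes the best-ever SSE non-increasing regardless.

Per subject, at most 20 evenly spaced retained beats are fitted (a
runtime/robustness trade-off; the median over 20 beats is already stable
against the per-beat noise in the fitted parameters) and the medians of
\(A, C, W\) are reported.

## HRV parameter conventions

Where conventions diverge, the package fixes these (all config-exposed):

* Sample (n−1) standard deviations throughout.
* pNN50 denominator: successive-difference pairs (N−1), the dominant
  HRV-toolkit convention; a config flag switches to interval count.
* Histogram bin width for the triangular index and TINN: 7.8125 ms
  (1/128 s), the sampling resolution of the target recordings. TINN comes
  from an exhaustive search over triangle bases with the apex pinned at
  the histogram mode, ties broken toward the narrower base.
* Min/Max heart rate: extremes of per-minute-windowed mean heart rate,
  falling back to beat-wise extremes for records under a minute.
* Tachogram: cubic-spline interpolation at 4 Hz, mean removed before
  spectral estimation. Welch: 256-sample (64 s) Hann segments, 50 %
  overlap, per-segment mean detrending. AR: Burg, order 16. The reported
  band powers come from the Welch estimate; the AR estimate is retained
  for diagnostics.
* Bands: VLF [0, 0.04), LF [0.04, 0.15), HF [0.15, 0.4] Hz, integrated
  by the trapezoid rule with the PSD interpolated at the exact band edges,
  so TP = VLF + LF + HF holds additively and nLF + nHF = 1 exactly.
  LF/HF with zero HF power is reported missing, not infinite.
* Entropies: m = 2, r = 0.2 × SDNN, Chebyshev distance; ApEn
  self-match-inclusive (Pincus), SampEn self-match-excluding
  (Richman–Moorman, −log(A/B), undefined when A or B is 0).
* DFA: first-order detrending, \(\alpha_1\) over boxes 4–16,
  \(\alpha_2\) over 16–64 beats.

### DFA finite-size correction

Raw first-order DFA is biased at the small box sizes of the short range:
even for uncorrelated noise the expected fluctuation does not follow the
asymptotic \(\sqrt{n/15}\) law near \(n = 4\), which inflates the fitted
short-range slope to ≈ 0.58 instead of 0.5. The package therefore rescales
\(F(n)\) by the *exact* white-noise expectation, computed from the
Frobenius norm of the composition of the cumulative-sum operator with the
linear-detrending residual projector. After rescaling, uncorrelated input
has expected slope 0.5 at every box size and integrated noise stays near
1.5; the correction factor tends to 1 as \(n\) grows, so long-range slopes
are essentially untouched. `dfa(..., bias_correction = FALSE)` restores
the raw estimator.

## Ensembles

CART (rpart) is the base learner, grown permissively (minsplit 2,
minbucket 1) so that cost-complexity pruning at cp = 0.1 alone governs
tree size. PAF is the positive class everywhere; vote and probability
ties break toward PAF, favoring screening sensitivity.

* **Bagging**: bootstrap resample → tree; a member whose accuracy on its
  own resample is ≤ 0.5 is discarded and redrawn (50-redraw budget);
  unweighted majority vote, score = PAF vote fraction.
* **AdaBoost** (AdaBoost.M1 completion of the weighted-bootstrap
  procedure): uniform initial weights; weighted bootstrap resample;
  members with weighted accuracy ≤ 0.5 redrawn; correct samples' weights
  multiplied by \(\beta = \varepsilon/(1-\varepsilon)\) and renormalized
  to sum 1; member vote weight \(\log(1/\beta)\), with \(\beta\) floored
  at \(10^{-10}\) for error-free members.
* **Stacking**: layer-1 = bagging + adaboost trained on all training
  data; the meta-features fed to the logistic-regression meta-model are
  *out-of-fold* layer-1 scores (internal 5-fold), so the meta-learner
  never sees in-sample layer-1 optimism. A config switch restores the
  naive in-sample variant.

Missing feature values are median-imputed with medians fit on the
training folds only; trees themselves need no feature scaling and the
meta-model consumes scores in [0, 1].

Evaluation pools the confusion matrix and scores across the stratified
tenfold split (with 100 subjects, pooled counts match the 2-decimal
granularity of the published comparison table; per-fold accuracies are
retained). Both F1 conventions are computed: the printed F1 values of the
comparison table this pipeline mirrors are reproducible only as the
harmonic mean of NPV and specificity (negative-class convention) given
the printed sensitivity/specificity on a 50/50 cohort, so that is the
headline `F1` column, with the standard positive-class F1 alongside.

## The synthetic cohort

`synth_cohort()` emulates the target regime: single-lead 128 Hz,
30-minute records, 50 PAF + 50 normal. Each beat renders P as an *exact*
Gaussian (so the fitting stage has analytic ground truth), a narrow
biphasic QRS, and a wide T-bump; the RR series is
mean + 0.1 Hz LF sinusoid + 0.25 Hz HF sinusoid + AR(1) noise, with a
"shuffle fraction" knob that permutes part of the noise sequence —
preserving the marginal distribution while scrambling short-range
correlation, which raises entropy and flattens DFA \(\alpha_1\).
Measurement noise is white Gaussian, sd 0.01 mV.

The frozen class differences follow the direction reported for
atrial-substrate remodelling: the PAF class has lower P amplitude
(0.10 vs 0.15 mV), wider P-waves (width parameter 37 vs 29 ms), reduced
HF and raised LF oscillation amplitude (8/25 vs 20/15 ms), smaller AR
noise scale (20 vs 35 ms), and shuffle fraction 0.4 vs 0. Effect sizes
were calibrated once against the full pipeline so that stacking reaches
cross-validated AUROC ≥ 0.9, then frozen; changing them is a breaking
change to the test suite. `default_class_params(effect_scale = 0)` yields
a null cohort with identically distributed classes, used to verify that
cross-validated accuracy collapses to chance.

What the generator does *not* emulate: ectopic beats and artifacts,
biphasic or notched P-waves, respiration-driven nonstationarity, baseline
wander, or real AF episodes. Passing tests on this cohort therefore
demonstrate the correctness and discriminative mechanics of the pipeline,
not clinical performance; published headline numbers on the real archive
depend on preprocessing details outside this package's scope.

## Problem sizes and determinism

Tests and the acceptance script run the full default cohort
(100 × 30 min) for the end-to-end property, a 300 s-per-record null
cohort (class-identical generators make record length immaterial to the
chance-level check), 50 noiseless segments for fit recovery, n = 2000
series for DFA, and n = 100–200 series for the brute-force oracle
comparisons. Every stochastic step — generation, GA, resampling,
fold assignment — flows from explicit seeds through an RNG-state-
preserving wrapper, so all results are bit-reproducible from (spec,
seed), and two runs with the same seed return identical models, folds
and reports.

## Known limitations

* The delineator assumes upright monophasic P-waves on lead II; inverted
  or biphasic P morphology is dropped rather than modelled.
* WFDB-layout input is not read directly; records enter as the package's
  plain-text sample format (one sample per line with `# fs=` headers) or
  as RR-interval text files.
* AR spectral decomposition into per-pole component powers, feature
  selection, and confidence intervals on the evaluation metrics are out
  of scope.
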