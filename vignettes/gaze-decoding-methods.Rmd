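---
title: "Methods: eyelid-strain gaze decoding and digital strabismus diagnosis"
author: "gazeStrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eyelid-strain gaze decoding and digital strabismus diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A thin resistive strain-sensing array worn on the upper eyelid carries
three sensing units oriented at 0°, 45° and 90°. Eye rotation deforms
the eyelid; the deformation couples into each unit as a mechanical
strain $\varepsilon_u$, and each unit transduces strain linearly into a
relative resistance change,

$$\frac{\Delta R}{R} = G\,\varepsilon, \qquad G = 0.169,$$

with the gauge factor $G$ valid up to 15 % strain. The biomechanical
structure the package encodes is directional: upward gaze *compresses*
the upper eyelid, so the 90°-unit signal is negative during elevation
and positive during depression; horizontal gaze drives the 0° unit
(leftward negative, rightward positive under the package convention,
with nasal/temporal resolved per eye side downstream); the 45° unit
responds to both axes. Strain magnitude grows monotonically with gaze
angle, reaching at most 4 % of strain for downward gaze and 11 % for
the other directions at the 18° reference angle. These bounds and
polarities — not any tissue mechanics — are what the simulator
reproduces.

# The simulator and what it does (not) emulate

`generateRecording()` composes, per annotated gaze event, a
raised-cosine ramp–hold–return strain profile (ramp 0.15 s by default)
whose hold-phase amplitude is linear in gaze angle,
$\varepsilon_u = g_u\,(\theta/18°)\,\varepsilon_{\max}$, with signed
unit couplings $g_u$ from the per-direction priors
(`defaultDirectionPriors()`). Oblique directions combine the two
adjacent cardinal strain fields vectorially (scaled by $1/\sqrt2$),
since no oblique strain fields are reported. Transduction is linear
with saturation at the sensor's 15 % range; white measurement noise
(SD $10^{-3}$ in $\Delta R/R$ units, roughly 10–20 % of a mid-range
event peak) and a sub-0.5 Hz sinusoidal baseline wander are added in
the resistance domain. Blinks are 0.3-s biphasic pulses on all three
channels at 1.5 × the largest directional amplitude (clipped at the
sensor's measurable range — the physical sensor saturates, and
clipping also keeps the transduced signal within
$G\,\varepsilon_{\max}$); facial-expression artifacts are 1–2 s slow
multi-channel waveforms with randomized per-channel gains and signs,
so neither artifact follows any directional polarity pattern.

**Event regime.** The decodable content of an AC-coupled channel is
the movement transient: a zero-phase 0.5 Hz high-pass removes any
sustained fixation plateau, and for holds much longer than the filter
time constant the rebound at gaze return grows as large as the onset
lobe, destroying the polarity information the whole system rests on.
The generator therefore defaults to brief look-and-return movements
(hold 0.25–0.45 s, amplitudes 5–15°, recurring at 0.1–1 Hz), the
transient-dominated regime in which the device's published waveforms
live. Under these defaults the simple polarity rule classifies about
72–77 % of windows correctly — the regime reported for that baseline —
while the learned model operates near ceiling.

**Individual differences.** Each simulated subject carries a fixed
multiplicative log-normal gain on all directional strain (SD 0.15 by
default), a small baseline offset, and stratification attributes (age
group, sex, eyelid phenotype). `generateRecording()` additionally
accepts a per-unit `channelScale`, modelling attachment variability (a
misplaced array couples to each unit differently); the few-shot
calibration experiments use it (per-channel log-normal SD 0.2) because
a purely scalar gain shift is largely neutralized by the trained
regressor and leaves nothing for calibration to learn.

What the simulator does *not* emulate: finite-element tissue
mechanics, eyelid-shape idiosyncrasies, electrode drift
nonstationarity, or the waveform diversity of real subjects. Passing
benchmarks on this generator therefore demonstrates that the decoding
stack recovers the encoded structure under the stated noise — not
clinical performance. The published clinical accuracies belong to an
undeposited patient dataset and are deliberately not reproduced.

# Preprocessing

Recordings are high-pass filtered with a 4th-order Butterworth at
0.5 Hz applied forward–backward (`signal::filtfilt`), giving zero
phase (event peaks are not shifted) and squared magnitude response;
DC is rejected below $10^{-6}$, 0.05 Hz baseline wander by more than
40 dB, and the 2 Hz movement band is flat within 1 dB. Filtering
precedes segmentation. Windows of 2.0 s (100 samples at the 50 Hz
default rate — the paper's movement content is below 1 Hz, so 50 Hz
oversamples safely) are centered on annotated event onsets; windows
clipped at recording edges are dropped.

Each 3-channel window is expanded to the 10-channel model input: the
three raw unit signals; the three pairwise channel differences
$s_0{-}s_{45}$, $s_{45}{-}s_{90}$, $s_0{-}s_{90}$; the three lag-1
time differences (zero-padded at the first sample); and the lag-$K$
difference of the channel mean with $K = \mathrm{round}(0.2\,\mathrm{s}
\times f_s)$, capturing a longer deformation timescale. The exact
10-channel recipe is not printed anywhere in the source material; this
set is one consistent reading of "channel difference and time
difference" and is isolated behind `expandToTenChannels()` so
alternatives are drop-in. Normalization is channel-wise division by a
training-set scale (95th percentile of absolute values) with *no
centering* — polarity is the physiological signal and must survive.

# The models

**Direction classifier.** A two-block Inception-style 1-D CNN
(`classifierSpec()`): each block applies a kernel-1 bottleneck to 32
channels, three parallel length-preserving bias-free convolutions with
kernels 17/7/3 (32 filters each), and a max-pool (kernel 3, stride 1)
branch followed by a kernel-1 convolution to 32 channels; the four
branches concatenate to 128 channels, followed by affine batch
normalization and a rectifier. Global average pooling and an affine
head produce the class scores. No residual shortcuts: the canonical
architecture inserts them every third block, depth 2 never reaches
one, and the printed 65,156-parameter count is consistent only without
them. Bias-free convolutions with affine normalization are likewise
required for the count to land exactly
(320+17408+7168+3072+320+256 in block 1; 4096+27648+4096+256 in block
2; 516 for the 4-class head). The 9-class variant swaps the head
(65,801 parameters) and is trained independently of the 4-class model.

**Angle regressors.** One independent four-layer MLP per direction
class (input 10, hidden 256/128/64, output 1; 44,033 parameters),
fitted only to that class's samples and reached at inference through
the *predicted* class. The regressor input is the signed extremum of
each of the 10 expanded channels — the feature map between window and
MLP is not printed; only the 10-input/44,033-parameter constraint is,
and signed extrema preserve both amplitude (angle) and polarity
(direction) information. Features and targets are standardized
internally; the oblique mode (output 2) minimizes Euclidean gaze-point
distance. Dropout 0.2 is applied after each hidden rectifier (the
printed material names dropout but not its placement or rate).

**Training.** Adam, initial learning rate $10^{-3}$, 20 epochs;
"adjusted dynamically" is realized as cosine decay (any seeded, logged
schedule would do). Splits are stratified by class; all randomness
(init, shuffling, dropout) flows through one seed, so training is
reproducible run-to-run on a fixed thread count. The network engine is
a compact array implementation (convolutions as im2col GEMMs with the
unroll/scatter in compiled code, hand-derived gradients); no deep
learning framework is involved. Regressors are tiny, so their default
epoch budget (150 in the pipeline helper) exceeds the classifier's.

**Baselines.** The polarity rule classifies from the signed extrema of
the 0°/90° units alone (dominant-unit sign → class, below threshold →
uncertain). KNN-DTW uses unconstrained dynamic time warping with
absolute-difference local cost, summed over channels, majority vote
with distance tie-break. On the 4-direction cohort the templates are
as stereotyped as the queries and KNN-DTW is *not* disadvantaged —
the benchmark where the learned model must beat it is therefore the
nine-category cohort (8 directions + merged blink/expression class),
the same dataset family on which that comparison was originally made;
variable-shape artifacts and oblique/cardinal amplitude ratios there
penalize template matching.

**Few-shot calibration.** `fewShotCalibrate()` fine-tunes *all*
weights of the classifier and each regressor at 0.1 × the base
learning rate for a small fixed budget (25 full-batch epochs for the
classifier, 600 for each regressor — budgets chosen by pilot
calibration on synthetic subjects: longer budgets overfit the 8–20
calibration points). It requires 2–5 labeled windows per cardinal
position and returns an adapted copy, leaving the input models
untouched. The monotonicity experiment uses nested calibration subsets
(the two samples used at $k=2$ are contained in the $k=3$ set, and so
on), which isolates the effect of added samples from resampling noise.

# The digitized Hess screen test

The chart is a tangent plane at 0.5 m with 5° grid steps; the nine
cardinal positions sit at 0°/±15° (the tested field is "generally
15°"; the physical screen's curved tangent-scale lines and 30° outer
field are not modelled). `buildHessChart()` averages repeated decoded
gaze points per position (the clinical protocol averages six
repetitions). Diagnosis follows the symmetry/size/position reading as
explicit threshold judgments (the published description names the
analysis but not the numbers; all three thresholds are exposed in
`hessThresholds()`):

1. *Symmetry*: paralytic when min/max chart area < 0.85 (shoelace
   area of the eight outer points ordered by target bearing);
2. *Size*: the paretic eye owns the smaller field;
3. *Position*: the mean measured-minus-target shift of the deviating
   eye, thresholded at 2°, labels eso/exo (temporal shift → exo,
   nasal → eso, resolved per eye side) and hyper/hypo;
4. *Muscle*: the implicated extraocular muscle is the one whose action
   field (adduction → medial rectus, abduction → lateral rectus,
   elevation-in-abduction → superior rectus, elevation-in-adduction →
   inferior oblique, depression-in-abduction → inferior rectus,
   depression-in-adduction → superior oblique; pure up/down map to the
   primary vertical movers) contains the position of maximal
   underaction, measured as the radial shortfall along the
   center→target direction (robust to lateral noise). Only
   single-muscle localization is automated; the ranked underaction
   table accompanies the report.

`generatePalsyChart()` produces the textbook single-muscle patterns
(labelled synthetic throughout) used as regression fixtures: maximal
underaction in the muscle's field, half as much at the ring
neighbours, plus the resting deviation the palsy produces.
`coverUncoverInterpret()` reads the refixation movement of the sensed
eye during fellow-eye cover from the *onset transient* (the signed
extremum in a 0.5-s window after the first suprathreshold excursion) —
on an AC-coupled channel a sustained deviation has no steady-state
signature — and maps abduction → esotropia, adduction → exotropia,
downward → hypertropia, upward → hypotropia, with the covered fellow
eye as fixating eye.

# Agreement statistics

`iccAbsoluteAgreement()` is the two-way random-effects,
absolute-agreement, single-measurement ICC from the two-way ANOVA mean
squares, with the standard F-based 95 % interval — the conventional
form for method comparison (the source names only "ICC").
`blandAltman()` returns bias and 95 % limits of agreement
$\bar d \pm 1.96\,s_d$ with approximate confidence intervals on the
limits (variance $s_d^2(1/n + 1.96^2/(2(n-1)))$). `foldedEcdf()` folds
the empirical CDF at one half using the Hazen plotting position
$(i-0.5)/n$, peaking at the median. `stratifiedAgreement()` applies
both per stratum with a pooled row; strata below the estimation
minimum (3 pairs; 5 for intervals) are flagged rather than dropped.
Whether the original analysis pooled the nine positions across
patients as independent observations is not stated; the module
computes on whatever pairing the caller supplies.

# Numerical choices and degenerate inputs

* Strain beyond the sensor range is an error in `strainToResistance()`
  but saturates (clips) inside the generator, as the physical sensor
  does.
* Ties in the polarity rule resolve in favour of the vertical unit;
  ties in window extrema take the earliest sample; KNN-DTW vote ties
  take the class with the smaller summed distance.
* Batch-normalization running statistics are seeded from the first
  training batch (a cold start from (0, 1) would need hundreds of
  steps to reach the $10^{-3}$-scale signal statistics).
* Zero-variance agreement input is a degenerate-input error for the
  ICC; a zero per-channel scale falls back to 1 in
  `fitNormalization()`.
* All stochastic entry points take a seed and restore the caller's RNG
  state.

# Problem sizes used in the checks

The packaged benchmarks run at desk scale, chosen as the smallest
sizes at which the studied effects are stable: the 4-direction cohort
uses 5,000 windows from 7 subjects with a 50/50 split; the
nine-category comparison uses 3,000 windows (KNN-DTW evaluated on a
seeded 400-template/250-query subsample, since the full quadratic
comparison adds nothing but time); the few-shot experiment uses 10
synthetic subjects with 60 held-out windows each; filter and oracle
checks use closed-form or brute-force references on short inputs.

# Known limitations

* The 10-channel expansion is one reconstruction of an underspecified
  recipe; all downstream results are conditional on it.
* The regressor extrapolates poorly outside the trained amplitude
  range (predictions compress), which is precisely why subject
  calibration is part of the workflow.
* Oblique strain fields are a vector-combination assumption.
* The Hess module assumes the sensed eye is the deviating one during
  cover–uncover, mirroring the published narrative; torsion and
  multi-muscle patterns are not localized.
* Agreement statistics assume exchangeable pairs; repeated measures
  within patient are not modelled (no mixed-effects agreement).
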