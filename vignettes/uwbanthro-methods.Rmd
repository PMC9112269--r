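---
title: "Methods: noncontact anthropometry from IR-UWB radar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noncontact anthropometry from IR-UWB radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A person stands still for five seconds in a small room instrumented with
three impulse-radio ultrawideband (IR-UWB) radar sensors: one at the ceiling
centre (2.5 m), two on opposite walls 1 m above the floor. Each sensor
records 20 frames per second; each frame samples the received echo along
fast time at 23.328 GS/s, so one range bin spans
`c / (2 f_s) = 6.4 mm` of round-trip distance. From these recordings the
package estimates seven anthropometric parameters: standing height by
classical signal processing (the ceiling sensor ranges to the top of the
head), and height, weight, BMI and four body-composition percentages by a
convolutional network that regresses on images formed from the radar
buffers.

`uwbanthro` implements the whole chain, plus a synthetic-data generator, so
every stage is testable without access to a clinical cohort.

## Received-signal model and the synthetic generator

A frame from sensor $i$ at slow time $n$ is modelled as a superposition of
delayed, scaled copies of the transmitted pulse over the scattering paths,
plus static clutter and white Gaussian receiver noise:

$$x_{i,n}[k] = \sum_{m} A_{m,i} \, S[k - \tau_{m,i}(n)] + c_i[k] + N[k].$$

Choices behind each term:

* **Pulse template** `pulse_model()`: a Gaussian-modulated cosine at
  8.748 GHz with the envelope width matched to the 1.5 GHz bandwidth through
  the Gaussian FWHM relation. The template is a continuous function of the
  fractional bin offset and is evaluated directly at $k-\tau$, which places
  echoes at sub-bin delays exactly (no interpolation error).
* **Breathing**: respiratory chest motion moves path delays sinusoidally
  (default 4 mm at 0.3 Hz, random phase per acquisition). Each path carries a
  `breath_gain`: 1 for torso paths, 0.3 for the head — the head sways less
  than the chest but is not static, which is what makes it detectable at all
  after background subtraction.
* **Clutter** `default_clutter()`: a few strong, perfectly static wall and
  furniture echoes (amplitudes 2-4x the body echoes) plus a decaying
  baseline. Clutter dominating the target is the regime the background
  filter exists for.
* **Noise**: zero-mean white Gaussian, `noise_sd = 0.02` against body-echo
  amplitudes of order 1; chosen so single-frame detection is comfortably
  above the noise floor while per-bin statistics still matter for threshold
  calibration.
* **Body size -> echo coupling.** Torso and shoulder amplitudes scale with
  the Mosteller body surface area `sqrt(h_cm * w_kg / 3600)` (the monotone
  stand-in for radar cross section). Two further couplings carry the
  anthropometric information through the imaging stage:
  1. the **head** echo amplitude is held at the cohort-median scale
     (adult head cross sections vary little), so the head/torso brightness
     ratio encodes body size and survives the joint 8-bit rescaling, which
     cancels any common amplitude factor;
  2. the **wall sensors range to the skin surface**: the chest-echo delay is
     shortened by the anteroposterior torso half-depth, modelled as
     `0.095 m + 0.004 m * (BMI - 22.8)` (clamped to 6-18 cm), so girth is
     encoded positionally at 6.4 mm resolution.
* **Body composition -> signal**: the percentages modulate the amplitude of
  a secondary torso reflection through a documented linear map
  (`composition_gain()`), with different coefficient sets per sensor. Four
  percentages project onto three observables, so they are identifiable only
  jointly with their population correlations; this coupling is an assumption
  — nothing in the physics of a surface-reflecting radar pins down how
  bioimpedance-style quantities shape the echo.

What the generator does **not** emulate: posture variation, limb motion,
multipath ghosts, antenna patterns, mutual sensor interference, or any true
electromagnetic scattering. Passing recovery tests on these simulations
therefore demonstrates that the pipeline's inference machinery works when
its assumptions hold; it does not certify clinical accuracy.

Every stochastic step is a pure function of an integer seed
(`with_seed()` discipline), so recordings, cohorts and fits are bit- (or at
worst float-) reproducible.

## Clutter removal

The exponential background filter keeps a running clutter estimate
$C_n = \alpha C_{n-1} + (1-\alpha) x_n$ with $\alpha = 0.95$ and subtracts
it. The defining equations list the subtraction line before the update line,
leaving the order ambiguous; the package's default is the *literal* reading
(update first, then subtract, so $y_n = \alpha (x_n - C_{n-1})$), with the
subtract-then-update variant available as `order = "legacy"`. The two differ
exactly by the factor $\alpha$ on step inputs — a regression test pins the
default. The filter state is initialised with the first frame, so a fully
static scene yields exactly zero residuals; `init = "zero"` gives the
closed-form geometric decay $\|y_n\| = \alpha^n \|y_0\|$ used as a
machine-precision test.

The envelope is the magnitude of the analytic signal along the range axis,
computed by zeroing the negative-frequency half of the FFT (no installed
package exposes a Hilbert transform, so it is implemented directly and
tested against the constant-envelope property of a cosine).

## CA-CFAR height estimation

The threshold is calibrated from $N_c$ empty-room envelope frames. The
source equations assign the symbol $\sigma$ to the mean and $\mu$ to the
standard deviation — almost certainly a typo, but not certainly. Both
conventions ship: the default `standard` threshold is
$T[k] = \mu[k] + \beta\sigma[k]$ (mean plus $\beta$ sample standard
deviations, ddof 1), and `convention = "literal"` gives
$\beta\mu[k] + \sigma[k]$ under the stated symbol meanings. $\beta$ defaults
to 3 (never printed in the source protocol); `min_run = 2` consecutive bins
suppress single-bin noise spikes.

Two practical points about threshold detectors that the package documents
rather than hides:

* **Leading-edge bias.** The envelope crosses the threshold on the rising
  edge of the pulse, several bins before its centre; with a zero-variance
  (noise-free) calibration the threshold collapses to zero and the crossing
  point is set by numerical leakage, arbitrarily far ahead. `estimate_height`
  therefore refines each frame's first crossing to the envelope peak within
  a 36-bin window — below the ~46-bin head-shoulder separation, so the
  shoulder echo cannot capture the refinement — and floors the threshold at
  5% of the frame's envelope peak (`floor_frac`), which is inert whenever a
  real noise floor exists.
* **Aggregation.** Per-frame ranges are aggregated by the median over the
  5-s window (mode available); frames without a detection are dropped, and
  more than 50% missing is an error, not a silent answer.

Height follows as `room_height - range`. On a noiseless 30-subject synthetic
cohort the estimate lands within one range bin of the truth; with default
noise the cohort RMSE stays under 2 cm.

## Imaging

The CNN consumes, per acquisition, three images built deterministically:

1. crop the first 100 frames x 400 bins of residuals per sensor (5 s at
   20 fps; 400 bins span ~2.56 m);
2. rescale the *stacked* triple linearly to 0-255 with one global min/max
   (per-sensor normalisation is available behind a flag; the joint reading
   preserves cross-sensor amplitude ratios). Rounding is half-up; a
   constant stack maps to zeros;
3. colour-map through a 256-entry jet-like table (grayscale also shipped);
4. bilinear corner-aligned resize to 227 x 227 x 3, rounded back to 8-bit.

Images stay lossless end to end (PNG on disk); a JPEG stage would make the
numeric path depend on a lossy codec and break byte-level reproducibility.

## The late-fusion CNN

One network per anthropometric parameter. Per sensor branch:
`depth` blocks of 3x3 valid convolution -> ReLU -> 2x2 average pooling
(stride 2, floor). Branch weights are *not* shared — each sensor sees the
body from a different aspect. The flattened branch outputs are concatenated
(the CAT layer), passed through one fully connected ReLU layer and a
single-unit linear head. Flattened-vector concatenation (rather than
feature-map concatenation) is used because a fully connected layer follows
immediately.

Defaults follow the stated hyperparameters: 3 hidden blocks, filter size 3,
learning rate 0.001, minibatch 8, 60 epochs, MSE loss. Unstated pieces are
the package's choices: 16 filters, FC width 256, Adam, seeded He
initialisation, z-scored targets (restored at prediction — necessary for a
common learning rate across cm/kg/% scales), last partial minibatch trained
as-is. The engine is RcppArmadillo with single-precision GEMMs; training is
deterministic given the seed (weight init and shuffling happen in R's RNG).

`split_dataset` offers the protocol's random 75/25 split over acquisitions
*and* a subject-level split as the default for synthetic experiments: with 8
repetitions per subject, an acquisition-level split places the same subject
on both sides, and a network can look good by memorising subjects. The
package documents this rather than silently "fixing" the protocol.

`sweep_architectures` reproduces the depth x filters x FC-width accuracy
comparison on a common split. Note the memory wall: at full 227 x 227 input,
depth 2 with 128 filters and FC 1024 implies ~1.2e9 weights (plus two Adam
moment buffers), so the shipped smoke experiment runs the full 36-cell grid
at 48 x 48 inputs — the qualitative claim under test is "every cell trains
and yields finite validation error", not the clinical RMSE values.

## Agreement statistics

RMSE, MAE, squared Pearson correlation, and ICC(2,1) — two-way
random-effects, absolute agreement, single measurement — computed from the
ANOVA mean squares of the n x 2 table:

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}, \quad k = 2.$$

Absolute agreement is the right variant for method comparison (radar vs
reference): it penalises systematic offsets, which consistency variants
forgive. Sample (n-1) denominators throughout. Degenerate inputs (zero
variance, all-identical tables) raise errors instead of returning NaN.

## Problem sizes used by the test-suite experiments

Chosen as the package's own desk-scale experimental design: height recovery
uses 30 subjects (noiseless) and 10 (default noise); the weight-recovery
experiment uses 60 subjects x 8 repetitions (360 training / 120 validation
items after the subject-level split) at 20 epochs, where the validation RMSE
sits near a third of the validation SD with ICC above 0.9; the architecture
sweep smoke-test uses 16 items at 48 x 48. The empty-room calibration default
is 5 minutes (6000 frames); tests calibrate from 30-60 s, which is already
far into the regime where per-bin statistics are stable.

## Known limitations

* The generator's body-composition coupling is an assumption; only its
  self-consistency is testable.
* Four composition percentages project onto three secondary-reflection
  observables; their individual recovery leans on population correlations.
* The CFAR detector assumes a single person at nadir under the ceiling
  sensor; multi-person scenes and off-centre standing beyond the modelled
  jitter are out of scope, as are OS-CFAR variants.
* Supine posture, moving subjects, and real-hardware effects (drift,
  interference, antenna patterns) are not modelled.
* Single-precision training means float-level (not bitwise) equality for
  identical inputs placed at different batch positions.
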