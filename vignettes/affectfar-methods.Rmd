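---
title: "Facial-action features for affect annotation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial-action features for affect annotation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In the psychiatric mental status examination, a clinician annotates a
patient's *affect* — the externally observable emotional state — along
several categorical dimensions. `affectfar` works with three:

* **quality**: dysphoric, euthymic, or manic;
* **range**: full, restricted, blunt, or flat;
* **subtype**: twelve finer labels (unknown, stupid, euphoria, empathetic,
  self-contempt, anxious, suspicious, hopeless, frightened, irritable,
  vacancy, sense of guilt).

Affect annotation is notoriously inconsistent between raters. The package
implements a facial-action-recognition (FAR) analysis of this problem: given
face videos of patients and independent annotations from several raters, it
(i) quantifies inter-rater agreement, (ii) tests which video-derived
features and which facial regions carry each rater's signal, and (iii)
predicts each rater's labels with a classifier evaluated by leave-one-out
(LOO) cross-validation. Because clinical interview videos cannot be shared,
the package also contains a synthetic cohort generator that reproduces the
statistical structure the analysis assumes, so every stage is fully testable
offline.

# From video to features

## Normalization and the cell grid

Each frame is aligned by a least-squares similarity transform (rotation,
isotropic scale, translation — solved in closed form with the
complex-number formulation) that maps the frame's facial landmarks
(eye centers, nose tip, mouth corners, chin) onto fixed canonical template
positions, then resampled to a square canvas (default 96 x 96 pixels) with
bilinear interpolation; samples outside the source frame are filled with 0.
The normalized face is divided into a grid of equally sized cells (default
8 x 8; the canvas side must be divisible by the grid so no remainder pixels
exist), and the mean gray level of each cell r at frame n is recorded as the
matrix X_r[n] — the canonical per-frame descriptor. Cells are indexed
row-major with the top-left cell 0; pixel coordinates are 0-based with the
origin at the top-left, x rightward and y downward. Color input is reduced
to gray as 0.299 R + 0.587 G + 0.114 B.

Six facial parts (left/right eye, left/right cheek, mouth, nose) are defined
as rectangles in normalized [0,1]^2 face coordinates; a cell belongs to a
part iff its center falls inside the rectangle. Composite groups (eyes,
mouth-and-nose, cheeks, all-parts) are exact unions. The default rectangles
place the eyes in the upper half, cheeks laterally, nose centrally and the
mouth in the lower quarter; they are package constants because no published
coordinates exist for this partition.

## Mid-level features

Three per-video descriptors summarize X_r[n], all invariant to video length:

1. **expression** (length 7): a linear one-vs-all scorer per expression
   class (norm, anger, disgust, fear, happiness, sadness, surprise) is
   applied to each frame's cell vector and the seven scores are averaged
   arithmetically over frames. Averaging is a documented choice — the
   aggregation into a single length-7 vector is not otherwise specified for
   this kind of analysis; the mean is the simplest length-invariant option.
2. **label** (length 1): the number of transitions of the per-frame
   dominating expression (argmax of the seven scores, ties resolved to the
   lowest class index, so an all-zero scorer yields "norm").
3. **motion** (length 1): the *population* standard deviation (denominator
   N) of the per-frame mean gray level over a chosen cell set — the whole
   face or any facial part. The population form is fixed for
   reproducibility; either convention is defensible.

Two concatenations, **motion+label** (length 2) and **motion+expression**
(length 8), always place motion first. Per-part analyses use the motion
descriptor only: the other features require expression classification,
which is trained on the entire face.

## Classifiers

Multiclass prediction uses one-vs-all linear support vector machines
(LIBSVM, via the e1071 package): one binary scorer per class, a test sample
assigned to the class with the highest response, exact ties resolved to the
earlier class in the domain's fixed label order. Each scorer is stored as an
explicit linear function (w, b) on the standardized feature space, which
makes degenerate cases transparent: classes absent from a training fold get
a constant most-negative scorer, and a training set with a single observed
class yields a flagged degenerate model that always predicts that class
(both situations are unavoidable in LOO folds with n = 25 and rare labels).

Features are standardized to zero mean and unit variance using
*training-fold* statistics only (switchable). Without this, mixed-scale
concatenations — motion is on the order of 0.1–1 gray levels, label
transitions on the order of tens — are dominated by one component.

The soft-margin cost defaults to `C = 100`. On standardized mid-level
features the within-class spread is small relative to class separation, and
a near-hard margin keeps low-dimensional scorers informative; at `C = 1`
the one-dimensional motion scorers for the extreme classes are so heavily
regularized that their decision lines barely cross the constant scorers of
the middle classes. `C` is exposed in every training function.

One structural property of this classifier family is worth knowing: on a
*one-dimensional* feature with four ordered classes, the one-vs-rest
problems for the two middle classes have no linear separator, and their
hinge-loss optima collapse to the constant scorer (w = 0, b = -1). The
argmax rule then decides between the two middle classes by the fixed-order
tie rule alone, so clean-label accuracy is capped at one minus the prior of
the losing middle class. This is a property of the method, not of the
implementation; richer features (the concatenations) do not share it.

## Evaluation

Each rater and domain is evaluated separately by LOO: every patient is the
test sample once, the classifier is trained on the others, and accuracy is
the fraction of correctly predicted labels. Because label distributions are
far from uniform, accuracy is also reported as the **improvement
coefficient**: accuracy divided by the frequency of the rater's most common
label (the accuracy of always guessing that label). A rater whose labels
have no variability in a domain is skipped with an explicit
reason — predicting a constant is not informative, and such raters occur in
practice.

# Statistics

**Pairwise agreement** between two raters is the percentage of patients with
identical labels. The summary over a rater panel is the mean and *sample*
standard deviation (denominator n-1) of the n(n-1)/2 unique off-diagonal
entries, reported at full precision and rounded to integer percent. The
sample form is used because it reproduces the published panel summaries for
the range (43 +/- 16) and subtype (25 +/- 13) domains, whereas the
population form does not.

**Association tests** use multinomial logistic regression (nnet::multinom)
of a rater's labels on a feature, compared with an intercepts-only baseline
by a likelihood-ratio test: LR = 2(ll_full − ll_null), referred to a
chi-square with (K-1) x p degrees of freedom for K observed classes and p
retained predictors. The baseline log-likelihood is computed in closed form
from the label counts (sum of n_k log(n_k/n)), which we verified agrees with
an intercept-only multinom fit to numerical precision. Zero-variance
predictors are dropped with a warning (a model with no predictors left *is*
the baseline: LR = 0, p = 1); fits with fewer observations than parameters
are skipped with reason "insufficient n" rather than reported — with n = 25
this affects, e.g., 7-predictor expression features against the 12-class
subtype domain. Non-converged fits under the bounded iteration limit
(e.g. quasi-separation) are flagged, never silently accepted. The LR
statistic is clamped at 0 against optimizer round-off; p-values are reported
raw, as is conventional for this analysis (a Benjamini–Hochberg option
exists in spirit via `stats::p.adjust` but no correction is applied by
default). The 12-class subtype logit at n = 25 is deliberately *not*
class-collapsed; instability surfaces as skips or convergence flags instead
of silent changes to the class structure.

The null behavior of this test is checked by simulation in the test suite:
with n = 200, three balanced classes and an independent standard-normal
predictor, the rejection rate at alpha = 0.05 over 1000 replicates must lie
in [0.035, 0.065]. The asymptotic chi-square reference is mildly
anti-conservative at this sample size — larger replications put the true
rejection rate near 0.057 rather than 0.050 — which is expected for a
likelihood-ratio test without small-sample correction and worth remembering
when reading borderline p-values at n = 25.

# The synthetic cohort generator

The generator emulates the setting the analysis was designed for: about 25
patients, five raters, one video each. It has three layers.

**Face renderer.** A parametric grayscale face — elliptical head with six
region rectangles at known canonical coordinates — whose region intensities
oscillate sinusoidally (region-specific frequencies of 0.3–0.9 Hz at a
nominal 30 frames/s, random phases per video). The latent *range* class
multiplies the oscillation amplitudes (defaults flat 1 < blunt 4 <
restricted 8 < full 14 gray levels on the eye region), the latent *quality*
class shifts the region intensity mixture (scale 25 gray levels), and the
latent *subtype* adds a small fixed per-class template (scale 6). Noise is a
static per-pixel facial texture (SD 2 gray levels) plus independent
per-region per-frame intensity jitter (SD 1): modeling the temporal noise at
region level rather than per pixel leaves the motion statistics of interest
essentially unchanged (per-pixel temporal noise averages out in cell means
by a factor of ~1/12 per cell) while keeping large simulation studies
tractable on a desktop. A per-patient similarity pose jitter (up to ~5%
translation, 8% scale, 7 degrees rotation) is applied so that the
landmark-based normalization stage does real work; the generator emits the
true landmark coordinates, standing in for the face detector that real
videos would require.

**Latent affect states** are drawn from configurable priors whose defaults
follow the label distributions reported for schizophrenia inpatients:
quality mostly euthymic (0.20/0.65/0.15), range dominated by blunt
(0.12/0.28/0.38/0.22 for full/restricted/blunt/flat), subtype dominated by
"unknown" and "stupid".

**Rater model.** Each rater annotates each patient and domain independently
by drawing from a row-stochastic confusion matrix applied to the latent
label. The default matrices are `reliability * I + (1 - reliability)/K`;
with a shared matrix C and latent prior pi, the expected pairwise agreement
is `sum_j pi_j sum_k C[j,k]^2` — an analytically controllable target, which
the test suite verifies at n = 500 within three Monte-Carlo standard errors.

Default `rater_reliability` is 0.9. This value was fixed by the
package's recovery requirement: at the default cohort size (n = 25) the
planted range effect must be recoverable from the motion feature well above
the most-common-label baseline, and reliabilities of 0.5–0.8 leave too
little signal in 24 noisy training labels for a stable margin (the
structural middle-class ceiling described above compounds with label noise).
Reliability around 0.5 reproduces the *agreement* regime actually reported
for expert affect annotation (about 44% pairwise agreement for range under
the default priors) and is the setting to use when emulating realistic rater
behavior rather than testing recovery.

**What the generator does not emulate.** Photorealistic appearance, head
pose changes within a video, illumination drift, facial occlusion,
expression dynamics richer than stationary sinusoids, rater biases that are
systematic rather than independent noise, and any correlation between the
three affect domains. Passing the recovery tests therefore demonstrates
that the pipeline is *correct* — it finds exactly the structure the
generator plants, localized where it is planted — not that the features
suffice for real interview footage.

## Expression training set

The seven-class expression scorer is trained on synthetic faces with
class-specific region-intensity templates (scale 30 gray levels) plus
per-pixel noise, because the original expression corpus behind this kind of
system is not redistributable; the model is pluggable for users with real
labeled frames. The seven template points are constructed to be affinely
independent (mild left/right asymmetry; the "norm" template displaced off
the centroid of the others) so each class is a vertex of their convex hull
and every one-vs-rest problem is linearly separable — with left/right
symmetric templates the difference vectors drop rank and the interior class
becomes unlearnable for a linear scorer. The test suite requires a held-out
accuracy of at least 95% at 50 frames per class.

# Numerical choices

* Similarity fit: closed-form complex least squares; degenerate when all
  source landmarks coincide or the fitted scale is ~0 (error). Two
  non-coincident landmarks suffice; collinear landmarks are fine for a
  similarity (unlike an affine fit).
* Bilinear resampling with zero fill; when landmarks are constant across
  frames the sampling plan is computed once per video.
* Motion SD uses denominator N; agreement-summary SD uses denominator n-1
  (see above for why the two differ).
* Expression-score ties and OVA prediction ties resolve to the lowest class
  index of the fixed orders; most-common-label ties resolve to the
  vocabulary order.
* Confusion-matrix rows must sum to 1 within 1e-9; cell-mean conservation
  and grid-refinement identities hold to 1e-9; LR scale-invariance to 1e-6
  (optimizer tolerance, `reltol = 1e-12`, `maxit = 500`).
* All randomness flows through explicit integer seeds; per-patient and
  per-stage sub-seeds are derived by seeded `sample.int`, so any cohort,
  video or report is bitwise reproducible.

# Problem sizes

The shipped simulations are desk-scale by design: default videos are 300
frames of 96 x 96 pixels (a few seconds of footage rather than a full
interview — every feature is length-invariant, so video length only sets
Monte-Carlo precision); the recovery study uses 10 cohorts of 25 patients;
the localization study 50 cohorts; the rater-model calibration 500 patients
without rendering; the LRT null calibration 1000 replicates at n = 200.
Unit tests use 48-pixel frames and 20–60 frame videos.

# Known limitations

* The frequency-histogram temporal encoding that inspired the cell
  descriptor is not implemented; X_r[n] is exposed directly and the encoding
  is an extension point.
* The one-vs-all linear SVM's middle-class ceiling on one-dimensional
  features (above) limits what motion alone can achieve on the 4-class
  range domain; this is reported, not patched (e.g. no class weights, no
  kernels — both out of scope).
* The multinomial logit at n = 25 with many classes is fragile; skips and
  convergence flags make this visible.
* Percent agreement is not chance-corrected (no kappa); that matches the
  analysis this package reproduces.
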