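---
title: "Balanced comparison of object invariances: models and methods"
author: "InvarianceDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced comparison of object invariances: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Neurons in high-level visual cortex keep responding to the same object when
the object's image changes size, position, in-plane rotation or
three-dimensional viewpoint. Asking which of these invariances is stronger,
or develops earlier in the neural response, is only meaningful when the
transformations are *balanced*: if a position shift changes fewer pixels
than a size change, position invariance will look stronger for that reason
alone. The balancing currency used here is the **net pixel change** between
two images,

$$\Delta(A, B) \;=\; \sum_{x,y} \lvert A_{xy} - B_{xy} \rvert ,$$

the summed absolute difference of 8-bit intensities. For each object, the
in-depth view change at two levels defines two targets $\Delta_1 < \Delta_2$;
the magnitudes of the size, position and rotation changes are then *solved*
so that each produces the same net change at each level. On 10 objects this
yields 90 stimuli: one reference plus four transformations at two levels per
object.

This package implements that design, a spiking-population simulator with
*configurable* ground-truth invariance, and the three analysis levels used
on such data: per-neuron tuning correlations, population cross-condition
decoding, and representational-dissimilarity model comparison. Because no
physiological recordings ship with the package, every analysis is validated
as *parameter recovery* on synthetic populations whose ground truth is
known.

# Stimulus model

Objects are filled radial-frequency silhouettes: the contour radius is a
truncated Fourier series over polar angle,
$r(\theta) = r_0\,(1 + \sum_k a_k \cos k\theta + b_k \sin k\theta)$,
clamped to $[0.15, 1.55]\, r_0$. This stands in for rendered 3-D objects:
it is fully parametric, asymmetric enough that in-plane rotation produces a
large image change, and cheap to rasterize. The **view** transformation
interpolates linearly between the reference coefficients and a second,
per-object coefficient set, producing a smooth non-affine image change --
the analogue of rotating an object in depth -- while size, position and
rotation act affinely on the rendered image.

Default design choices (each made once, before any analysis):

* **Canvas 128 x 128 px, foreground intensity 255, background exactly 0.**
  The base radius defaults to about a fifth of the canvas so that shifted
  and rotated silhouettes never touch the border (touching the border is an
  error naming the offending parameter).
* **Area-sampled rasterization (4 x 4 subpixels).** Each pixel stores its
  8-bit area coverage. A hard-edged (binary) rendering makes the net pixel
  change a step function with steps of one full pixel intensity, which is
  coarser than the 0.1% matching tolerance on a 128-px canvas; area
  sampling refines the accounting quantum 16-fold while keeping the
  background exactly zero and identity parameters bit-exact.
* **Per-object view calibration.** The second coefficient set is scaled,
  by bisection, so that the extreme view changes 36% of the object's
  intensity mass. This keeps the view-defined targets commensurate across
  objects and inside the reach of the other transformations (rotation is
  the binding constraint: its net change saturates near half the mass).
  Contours are rejection-sampled until a 170-degree rotation changes at
  least half the mass, discarding near rotationally symmetric draws.
* **Search ranges.** Size rescales about the object centre over
  [0.25, 1]; position shifts horizontally (one fixed direction, the
  analogue of a contralateral shift) up to 20 px; rotation spans up to 170
  degrees; view spans [0, 1]. Default view levels are 0.45 and 0.95.
* **Solver.** Bracketed bisection on the scalar parameter with relative
  tolerance $10^{-3}$ and at most 60 iterations, keeping the best iterate;
  if the target is not met (net change can plateau under rotation), a
  512-point grid scan brackets the best region and bisection resumes
  there. A target beyond the range maximum is an error reporting that
  maximum. With these defaults the realized net changes within an (object,
  level) cell agree to well under 0.5% relative spread.

Coordinates are row-major, 0-based, origin top-left; positive shifts move
rightward. Pixel differences are computed on the stored 8-bit values
directly (no gamma model).

# Population simulator

Each neuron $i$ draws an object-tuning vector $z_i \sim \mathcal N(0, I)$
over objects, mapped through a softplus and normalized to unit mean drive.
Firing is inhomogeneous Poisson with rate

$$\lambda_i(t, s) = \text{baseline} + g_i \, \kappa(t)\, d_i(s, t),$$

where $g_i \sim U(30, 70)$ sp/s is a per-neuron gain and $\kappa(t)$ is a
normalized response kernel: zero before the 60-ms onset, a gamma-shaped
transient peaking at 100 ms, settling to a 30% sustained level by the end
of the 200-ms presentation, then decaying exponentially (tau = 50 ms). The
drive $d_i$ for a transformed stimulus mixes the neuron's reference tuning
with an independent "retuned" vector: with invariance strength $s \in
[0,1]$, the mixed drive is $s\,d^{\text{ref}} + (1-s)\,d^{\text{alt}}$,
and the mix is gated on only after onset + per-transformation latency (a
hard gate by default; a linear ramp is available via `rampMs`). Before the
gate the response follows the retuned vector alone, so the transformed
responses are vigorous but carry no reference tuning -- invariance, not
responsiveness, is what develops late.

The simulator is deterministic given its master seed, with per-neuron
substreams derived by fixed offsets: enlarging the population leaves
existing neurons' spike trains unchanged. Trials are treated as
independent presentations (no adaptation, no correlated noise, no eye
movements); repetition indices across neurons are arbitrary, and analyses
apply a seeded within-neuron repetition shuffle before assembling
pseudo-population vectors.

`studyScenario()` fixes the study conditions: 10 objects, 90 balanced
stimuli (a fixed design seed, like a fixed image set shown to all
sessions), 127 neurons, 8 repetitions, strengths at the large change level
0.85 for size and position versus 0.45 for rotation and view (0.9
everywhere at level 1), and gating latencies 0, 20, 50, 50 ms for size,
position, rotation, view. These encode the ground truth the pipeline must
recover: size/position stronger and earlier than rotation/view, with
rotation and view indistinguishable.

What the simulator does *not* emulate: realistic PSTH diversity across
neurons, spike-count correlations, firing-rate nonstationarity across
trials, or any image-computable link between stimulus pixels and rates
(tuning is abstract, not feature-based). Passing recovery tests therefore
shows the *analyses* are correct and sensitive under Poisson variability
at realistic counts -- not that cortical data will behave this way.

# Analyses

**Tuning correlations.** Rates are spike counts in a 50--200 ms window
(or 20-ms bins) divided by the window length. Per neuron and condition,
invariance is the Pearson correlation across objects between
trial-averaged responses to reference and transformed images (Spearman is
available); p-values use the standard t transform, two-sided, with no
multiple-testing correction (raw p-values are the convention for this
analysis). Zero-variance neurons yield NA, are excluded pairwise, and are
counted in the summaries. Conditions are compared by paired Wilcoxon
sign-rank on the per-neuron correlations and by a two-proportion
chi-square on invariant fractions. Binned time courses report the mean
correlation per 20-ms bin, its peak latency (bin center of the maximum,
earliest bin on ties), and a per-bin rank-sum comparison of the affine
(size, position) versus non-affine (rotation, view) invariances.

**Co-occurrence.** For two transformations with invariant counts $n_A$,
$n_B$ out of $n$, the expected cell counts under independence are the
products of the marginal proportions times $n$, in the order (both,
B-only, A-only, neither). The test statistic is $\sum (O-E)^2/E$ with
*unrounded* expectations by default -- rounding the expectations first is
supported (`rounded = TRUE`) because back-of-envelope arithmetic on
printed integer counts does exactly that, and the two statistics differ
(8.71 vs 8.47 on the worked example in the test suite). The appropriate
degrees of freedom are genuinely ambiguous for this 4-cell comparison
(1 with both margins taken as given, 3 with only the total fixed), so
p-values under both conventions are reported and neither is privileged.

**Decoding.** The population readout is a multi-class linear discriminant
with a shared covariance matrix. With 127 neurons and 80 training trials
the pooled covariance is singular, so its off-diagonal is shrunk toward
the diagonal, $S(\lambda) = (1-\lambda)S + \lambda\,\mathrm{diag}(S)$,
with $\lambda$ chosen analytically (Schafer-Strimmer variance-minimizing
estimator for the diagonal target; fixed values, including the classical
$\lambda = 0$, are configurable). This replaces the textbook unregularized
discriminant, which cannot be fit in the trials < features regime at all.
Generalization trains on reference trials and tests on transformed trials
and vice versa; both directions are reported along with their mean, and
test trials are never part of training (a leakage assertion guards every
path). Chance is 1/number of objects. Binned decoding repeats this per
20-ms bin; peak latency uses the earliest-maximal-bin rule. Bootstrap
latency statistics resample neurons with replacement (default 100
resamples, roughly matching the population size), recompute the binned
time course and its peak per condition, and report pairwise order
fractions and sign-rank p-values; degenerate flat time courses are kept
under the earliest-bin rule and their frequency is reported. Because
repetition counts are carried by a single tensor, mismatched repetition
counts between conditions are structurally impossible rather than a
runtime error. Neuron subsets (e.g. the top-k most invariant cells) and
object subsets (with chance recomputed) reuse the identical machinery.

**Model comparison.** Representations enter as units x stimuli activation
matrices: pixels (stored intensities), a V1 stage (zero-mean Gabor bank,
4 frequencies x 8 orientations x 2 phases on a stride-4 grid, half-wave
rectified and divisively normalized by pooled energy across orientation
and phase per frequency -- a deliberately scaled-down bank; all parameters
configurable), and externally computed features loaded from file (the
adapter validates the stimulus mapping; no network is bundled or run).
Unit invariance is computed exactly as for neurons. Dissimilarity matrices
are 1 minus the Pearson correlation between activation columns over units;
matches between matrices correlate strict lower triangles, excluding NA
pairs. Split-half reliability averages, over random disjoint halves of the
neurons (first half larger by one when odd), the correlation between
half-RDMs, and applies the Spearman-Brown correction
$r_c = 2r/(1+r)$. Layer selection is the generic "rank candidate
activation matrices by RDM match to a target".

# Numerical and design notes

* Problem sizes: unit tests run on 4-object, 64-px designs and populations
  of tens of neurons; the full study design (10 objects, 128 px, 127
  neurons, 8 repeats) is used for the end-to-end recovery checks, with 20
  population seeds for the ordering-recovery test and 100 bootstrap
  resamples per seed.
* All randomness descends from explicit seeds through fixed-offset
  substreams; identical configuration and seed reproduce byte-identical
  CSV outputs, and every numeric output file carries the seed and a
  configuration hash in a comment header.
* Ties in any argmax-latency rule break to the earliest bin; ties in the
  readout's argmax break to the lowest class index.
* The pipeline (`runPipeline()`) runs stages stimuli, simulate,
  invariance, decode, models from one master seed; a stage can be re-run
  against existing artifacts, and a missing upstream artifact aborts with
  the responsible stage named. `reportSummary()` is idempotent.
* Known limitations: the silhouette generator cannot represent texture,
  shading or occlusion, so "view" changes are purely contour-based; the
  V1 model's normalization constants follow common practice rather than a
  fitted physiological model; decoding accuracies on the synthetic
  scenario saturate near 1 for strongly invariant conditions, which is
  higher than typical cortical data.
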