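---
title: "Methods: decoding a heading-direction ring network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding a heading-direction ring network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ringcompass)
```

## The system and the model

A ring attractor represents a circular variable — here the heading direction
of a larval zebrafish — as the position of a localized bump of activity on a
ring of neurons. In the anterior hindbrain (rhombomere 1) the ring is
anatomical as well as functional: neurons are arranged on a rough circle in
the horizontal plane, each with sinusoidal tuning to the network phase and
an anticorrelated partner at the opposite (pi) angle. Directional swims move
the bump — left swims rotate it clockwise (viewed from above), right swims
anticlockwise — and between swims the bump stays put, so the bump angle
integrates motor commands into a heading estimate. `ringcompass` implements
the analysis chain that extracts this description from a recording, and a
generator that produces synthetic sessions with known ground truth under the
same assumptions.

## Conventions

All angles are radians, all times seconds. The ring angle `alpha` and the
network phase `phi` live in `(-pi, pi]` with caudal = 0, left = +pi/2,
right = -pi/2, increasing clockwise viewed from above. The anatomical angle
of an ROI at left-right coordinate `lr` (positive = left) and rostro-caudal
coordinate `rc` (positive = rostral) is `atan2(lr, -rc)`. A positive
laterality index is a rightward swim; integrated heading is the cumulative
sum of lateralities, so heading rises with right swims while the phase
falls — the phase-heading coupling is an *anti*correlation by construction.
We adopt the caudal-zero phase convention throughout; the alternative
rostral-zero statement that sometimes accompanies descriptions of this
system is inconsistent with a caudal-zero `alpha` and is not used.

## The synthetic session generator

`sessionParams()` fixes the reference study conditions; the defaults are the
conditions under which every quantitative claim in the test suite is made.

| parameter | default | meaning |
|---|---|---|
| `nNeurons` | 80 | ring neurons (real sessions: 50-100, median 74) |
| `durationS`, `imagingRateHz` | 600 s, 5 Hz | volumetric imaging session |
| `behaviorRateHz` | 400 Hz | tail tracking rate |
| `tuningShape`, `amplitude` | raised cosine, 1 | `g(theta) = 0.5 (1 + cos theta)` |
| `noiseSd` | 0.15 | additive i.i.d. Gaussian noise, activity units |
| `calciumTauS` | 1.8 s | single-exponential indicator decay (GCaMP6s-like) |
| `swimRateHz` | 0.1 Hz | Poisson bout rate (~60 bouts per session) |
| laterality mixture | sd 0.1 / mean 0.6, sd 0.15 / weight 0.3 central | symmetric trimodal |
| `phaseGain` | 1 | rad of bump rotation per rad of laterality |
| `distractorFraction` | 0.3 | non-ring ROIs (half motor-locked, half noise) |

Design choices worth stating explicitly:

* **The bump is imposed kinematically.** The true phase is piecewise
  constant, stepping by `-phaseGain * laterality` at each swim onset. There
  is no connectivity-based attractor dynamics, no drift and no diffusion;
  passing tests therefore validate the *analysis*, not any claim that real
  networks behave this ideally.
* **Calcium kernel.** Drives are filtered by a causal exponential with a
  1.8 s decay, normalized to preserve steady states. The kernel is the main
  source of decoding error at the default conditions: after each swim the
  measured bump takes ~2 time constants to catch up with the true phase.
* **Bout kinematics are invented** (25 Hz carrier, 100 ms envelope,
  150-300 ms duration, 0.5 s refractory), constrained only to be invertible
  under the vigor/laterality definitions: the bias term of each bout is set
  so the mean tail angle over the first 70 ms equals the drawn laterality
  exactly.
* **Raw fluorescence** is `baselineF * (1 + signal)` with a 5% linear
  bleaching trend, so the dF/F stage is exercised; the clean signal traces
  are kept in the session (`sessionSignal()`) for decoder round trips.
* **Gaze** is piecewise constant with Poisson step saccades (disabled by
  default); no attempt is made to model smooth pursuit or eye-position
  nystagmus.

What the generator does *not* emulate: correlated (shared) noise across
ROIs, slow representational drift, non-sinusoidal or heterogeneous tuning
widths, bout-to-bout kinematic variability beyond the laterality mixture,
and visual-stimulus-driven activity. Gain conditions are metadata only.

## Preprocessing

dF/F uses a centered rolling-mean baseline (900 s window, truncated at the
edges; centered avoids onset bias since the window exceeds many recordings'
length). A rolling-percentile baseline is available behind a flag. Traces
are then median-filtered (default kernel 3 frames — the smallest kernel that
removes single-frame impulses) and z-scored. Zero-variance ROIs are dropped
with a warning; an all-constant matrix is an error. The pipeline is
invariant to per-ROI multiplicative gain by construction.

## Behavior

Vigor is the right-aligned 50 ms rolling standard deviation of the tail
angle, zero-padded at the start. Swims are maximal vigor > 0.1 episodes,
merged when closer than 100 ms (both the right-aligned window and the merge
gap are stabilizing choices; onset error against synthetic ground truth is
under 10 ms). The laterality window (70 ms) starts at the detected
threshold crossing. The trimodal classification fits the *histogram* (61
symmetric bins) of lateralities by least squares with the central mean
pinned at 0 and mirror-symmetric side components; the classification
threshold is the positive intersection of the central and side component
densities, with 0.239 rad packaged as the fixed fallback operating point.
One caveat the analysis honors: the laterality-to-turn-angle slope is not
necessarily one, so all heading statistics are correlations or
within-session slope comparisons, never absolute angles.

A note on an invariant: episode *counts* are not monotone in the vigor
threshold — an oscillatory vigor profile can split one bout into two
episodes at a higher threshold. The property that does hold, and that the
suite tests, is nesting: every episode found at a higher threshold lies
inside an episode found at a lower one.

## Ring detection

An ROI is a ring candidate when its minimum pairwise Pearson correlation is
at or below a threshold (default -0.6; an optional scan over [-0.75, -0.5]
maximizes a ring-quality score, 1 minus the coefficient of variation of the
PC-projection radii). This replaces per-fish manual tuning with a
reproducible rule. The manual exclusion of traces that disrupt the
angle-sorted correlation matrix is formalized as a cosine-template test:
an ROI is excluded when its row of the sorted correlation matrix correlates
below 0.5 with the ideal `cos(alpha_i - alpha_j)` template. This is a
surrogate for curation, not a reconstruction of anyone's judgment.
Anatomically gated selection is deliberately avoided (it would make the
anatomy-function correlation circular).

## Embedding and anatomy

Neuron-space PCA (ROIs as observations over time) maps each ROI to the
plane of the first two components; a hyperaccurate algebraic circle fit
(checked in the tests against an iterative geometric fit) normalizes the
cloud to a unit circle. Two anatomy-weighted anchor vectors — coordinates
weighted by the mean-centered rostro-caudal and right-left positions, the
simplest linear estimator pointing at the rostral-most and right-most ROIs
— are rotated onto their targets (pi and -pi/2) by exhaustive search on a
0.1 degree grid over rotations and both chiralities, minimizing
|theta1| + |theta2|. The objective is a sum of absolute angles, hence
non-smooth, which is why a grid beats gradient methods here; ties break
toward the smaller rotation. The Fisher-Lee T-linear circular correlation
between `alpha` and the anatomical angle is computed by the O(n) resultant
identity and pinned against a brute-force double loop in the tests.

## Phase, bump profile, tuning

Percentile clipping (2nd/98th) is applied per ROI over the whole recording;
the per-frame variant across ROIs is implemented behind `clipMode = "frame"`
but not default, because ~80 ROIs give unstable frame-wise percentiles.
After clipping, the across-ROI mean is removed at every frame and the
population vector is averaged with the unit-circle coordinates. Unwrapping
is the standard cumulative removal of 2 pi discontinuities.

One property of this decoder deserves emphasis: any per-ROI *time*-mean
removal (z-scoring, dF/F) leaves a constant bias vector proportional to the
resultant of the phase occupancy, which smoothly warps the absolute decoded
phase when the session lingers in some headings. The warp cancels in every
Delta-based statistic (triggered averages, window correlations, slope
regressions). Accordingly, the absolute-accuracy round trips in the tests
decode the rendered signal against the ground-truth embedding (circular
RMSE ~0.14 rad at default noise, dominated by the kernel lag; ~0.001 rad
noiseless and kernel-free), while all comparative statistics run on the
full estimated pipeline.

The bump profile interpolates activity over `alpha` (periodic linear
interpolation) onto 100 bins, circularly shifts each frame by the decoded
phase, and averages; a non-interpolated variant (alpha-sorted rows shifted
by the nearest ROI) is kept as a consistency check, and the interpolated
matrix is used only for this profile, never for raster displays. FWHM uses
the profile minimum as baseline (profiles need not decay to zero), half
level halfway to the peak, and linear interpolation of the two crossings on
the circle; a flat profile is an error, not a zero. Tuning curves bin each
ROI's activity by the wrapped phase (36 bins); empty bins are interpolated
circularly before the FWHM step and curves with more than half their bins
missing return NA.

## Heading and coupling

Heading steps by the laterality at each swim onset (first frame at or after
the onset — the same convention as the phase integrator, which matters: a
half-frame disagreement between the two integrators turns into a visible
slope bias). Heading is resampled to the imaging clock by zero-order hold,
which is exact for a piecewise-constant signal. The rolling 300-s window
correlation steps by window/10 (the natural reading of "ten overlaps");
the shuffle pairs each phase window with a uniformly drawn non-overlapping
heading epoch, and the two correlation populations are compared by a
two-sided rank-sum test. In a 600-s session only the complementary epoch
qualifies as non-overlapping, so the shuffle population is small and the
attainable p-value floors at ~0.026; longer sessions behave normally.
Because overlapping windows are not independent, the rank-sum test is
anticonservative under the null; for null-calibration checks the package's
non-overlapping variant (`windowStepS = windowS`) is used, under which
~95% of independent random-walk pairs are correctly non-significant.

Post-swim delta regression measures, for each swim, the change of phase and
of heading from just before the onset to the mean over a 15-20 s post-event
window, and regresses one on the other; with the kernel present the recovered
slope magnitude is attenuated by a few percent because swims inside the
window contribute fully to heading but only a partially decayed kernel
response to phase — gain-recovery accuracy is therefore stated under
kernel-free conditions. Condition comparisons use Wilcoxon signed-rank
(paired) or Mann-Whitney U (unpaired) with exact small-sample p-values;
all-zero paired differences return p = 1 by convention, flagged. Motor and
gaze regressors convolve onset indicators (and gaze angle/velocity) with
`exp(-t/tau)`, tau = 3 s; the phase derivative for cross-validated
regression uses central differences after a 3-frame running median. Train
and test epochs (5 min each) are drawn disjointly, 500 times by default.

## Skeletons and neuropil autocorrelation

SWC files are parsed and validated as single-rooted connected trees;
compartments come from the SWC type codes or a sidecar table. A branch
point is a node with out-degree of at least two; compartment centroids are
unweighted means over branch points (an all-node fallback exists behind a
flag), midline distances are |x - midline| with the midline a configured
constant plane per dataset. The synthetic skeleton population places each
axon contralaterally at the complementary lateral offset of its dendrite
(lateral dendrite, medial axon), which makes the two midline-distance
columns exactly anticorrelated — the geometry that a plain reflection
(which preserves distance to the midline) would not produce. The neuropil
autocorrelation averages pixel traces in 3.5 um bins, z-scores per bin,
correlates every bin pair and averages by signed per-axis offset;
zero-variance bins are excluded with bookkeeping. Mirrored traveling-bump
planes (`makeMirroredBumpFrames()`) validate that paired sources at lateral
offset D produce correlation side lobes at |Delta frontal| = D within one
bin.

## Problem sizes and budgets

The test suite and the acceptance script use five 600-s sessions of 80 ring
neurons plus 34 distractors at 5 Hz (3,000 frames) with tails at 400 Hz
(240,000 samples); null calibrations use 100 repetitions of 1,800-sample
series; cross-validation examples use 30-50 draws. These sizes keep the
whole suite under a minute of compute on a single core while leaving every
statistical margin comfortably away from its threshold.

## Known limitations

* The session bundle is a CSV/JSON directory; no HDF5 dialect is provided.
* The generator's bump has no drift, diffusion or attractor dynamics, so
  persistence statistics are trivially clean.
* Absolute decoded phase inherits the occupancy warp discussed above; users
  comparing absolute phase across sessions should prefer Delta-based
  statistics, as the analyses here do.
* No quantitative detectability criterion is offered for whether a
  recording contains a ring network at all (detection rates in real data
  depend on behavior richness in ways the generator does not model).
* Cross-fish pooling into an atlas space is out of scope; alignment is
  per-fish only.
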