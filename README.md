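# ringcompass

Analysis of heading-direction ring attractor networks in larval zebrafish
calcium imaging.

Head-restrained zebrafish larvae carry a population of GABAergic neurons in
the anterior hindbrain (rhombomere 1) whose activity forms a localized bump
on an anatomical ring. The bump rotates with directional swims — clockwise
after left swims, anticlockwise after right swims — and persists for tens of
seconds at rest, so its angular position acts as a compass: an integrated
estimate of the animal's heading built from motor efference copies.
`ringcompass` implements the full analysis that takes a raw recording to
that conclusion, plus a synthetic session generator with ground truth so
every stage can be validated quantitatively.

## The core computation

Given z-scored dF/F traces `f_i(t)` for ring neurons embedded at unit-circle
rotated-PC coordinates `rPC_i` (ring angle `alpha_i`, with caudal = 0,
left = +pi/2, right = -pi/2), the network phase is the angle of the
population vector

    v(t) = (1/n) * sum_i f_i(t) * rPC_i,   phi(t) = atan2(v_y, v_x)

where each trace is clipped to its 2nd/98th percentiles and the across-ROI
mean is subtracted at every frame (`sum_i f_i(t) = 0`). Around this decoder
the package provides:

* **traceprep** — rolling-baseline (900 s) dF/F, median filtering, z-scoring;
* **behavior** — swim vigor (50 ms rolling s.d. of the tail angle), bout
  detection at vigor > 0.1, the laterality index (mean tail angle over the
  first 70 ms of a bout), and left/forward/right classification from a
  symmetric trimodal Gaussian mixture fit;
* **ringdetect** — ring-neuron selection by pairwise anticorrelation
  (threshold in [-0.75, -0.5]) with a cosine-template exclusion rule on the
  angle-sorted correlation matrix;
* **rpcspace** — neuron-space PCA, hyperaccurate circle fit, rotation /
  reflection alignment to anatomical anchor directions, and the Fisher-Lee
  circular correlation between ring angle and anatomy;
* **phasedyn** — phase decoding, the phase-zeroed 100-bin bump profile and
  its FWHM, and single-neuron tuning curves;
* **headnav** — heading integration from swim lateralities, rolling-window
  phase-heading coupling with an epoch shuffle, swim-triggered phase
  averages, post-swim delta regression (gain conditions), exponential motor
  and gaze regressors (tau = 3 s), and cross-validated phase regression;
* **ipnmap** — SWC skeleton morphometry of the interpeduncular projection
  (branch-point centroids, midline distances) and the 3.5 um pixel-bin
  spatial autocorrelation of neuropil activity;
* **synthio / pipeline_io** — the synthetic generator, a CSV/JSON session
  bundle format, the `runPipeline()` orchestrator and report writer.

## Worked example

```r
library(ringcompass)

session <- simulateSession(sessionParams(seed = 1))
session
#> SyntheticSession: 80 ring + 34 distractor ROIs, 600 s @ 5 Hz, 59 swims (seed 1)

results <- runPipeline(session)
results$summary[c("n_ring_rois", "variance_fraction_pc12", "bump_fwhm_rad")]
```

On this session the pipeline prints:

```
ring ROIs selected:        80
variance in first 2 PCs:   0.897
bump FWHM:                 3.15 rad
median tuning FWHM:        3.25 rad
phase-heading correlation: -0.976 (median, 300-s windows)
phase-heading slope:       -0.79
alpha vs anatomy rho_t:    0.992
```

Reading these numbers: all 80 ring neurons (and none of the 34 distractors)
were recovered by the anticorrelation rule; the network trajectory is
essentially two-dimensional (89.7% of variance in two components); the
activity bump spans half the ring (FWHM close to pi radians), as do the
single-neuron tuning curves; the decoded phase is strongly anticorrelated
with the integrated heading, with a negative regression slope, because left
swims rotate the bump toward positive phase while decreasing the heading;
and the ring angle recovers the programmed anatomical layout almost exactly
(Fisher-Lee rho_t = 0.992). `writeReport(results, "out/")` saves the
summary JSON, phase/profile tables and diagnostic figures.

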