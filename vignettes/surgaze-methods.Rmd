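---
title: "Methods: gaze and capsulorhexis analytics for heads-up display cataract surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze and capsulorhexis analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgaze)
```

## The problem

During simulated cataract surgery on a 3-D heads-up display (HUD), a
head-mounted eye tracker records where the surgeon looks at 200 Hz while
they perform a continuous curvilinear capsulorhexis (CCC) on a model eye.
Expertise shows up in the gaze signal — shorter fixations, smaller
saccades, more attention on the HUD — and in the geometry of the tear the
surgeon produces: experts tear tangentially (small angle between the tear
vector and the forceps axis), start the tear near the forceps insertion
wound, and produce longer, more circular tears. `surgaze` implements the
full measurement chain for these quantities, plus the group-level
inference used to compare training levels (PGY2, PGY3, PGY4, fellow,
attending; five surgeons per group), and a synthetic-data generator that
emulates each training level so that every stage of the chain can be
validated without access to recordings.

## Event detection

Fixations are detected with the classical dispersion-threshold algorithm
(I-DT): a window of consecutive samples is a fixation when its angular
dispersion stays within **1.50 degrees** and its time span lies in
**80–420 ms**. Dispersion is the *maximum pairwise* angular separation of
the window's samples — rotation-invariant, order-free, and matching the
dispersion notion of the deployed tracker (not the bounding-box sum of
some I-DT variants). Angular separation is computed on the flat degree
plane; at the amplitudes involved (under a degree) the small-angle
approximation is exact to well below measurement noise.

Windows grow greedily left to right, so earliest-start windows win ties.
Dwells longer than 420 ms split into consecutive capped fixations, with a
remainder kept when it still reaches 80 ms; splitting preserves total
dwell accounting. Two further rules matter in practice:

* **Confidence filtering.** Samples below a confidence threshold
  (default 0.6, configurable) are removed before detection. Pupil
  detection degrades during fast eye motion and eyelid closure, so
  saccadic and blink samples carry low confidence.
* **Gap breaking.** A temporal gap longer than twice the nominal sample
  interval (10 ms at 200 Hz) always terminates a window. This is what
  actually separates consecutive fixations: reported saccade amplitudes
  (0.12–0.29 degrees) are an order of magnitude *below* the 1.5-degree
  dispersion threshold, so dispersion alone could never split two
  neighboring dwells. The gaps left by confidence filtering do.

Saccades are taken centroid-to-centroid between consecutive fixations.
A pair only counts as a measured saccade when the temporal gap between
the fixations is at most `max_gap` (default 25 ms, the saccadic duration
scale for sub-degree shifts at 200 Hz). Longer gaps — blinks, tracking
loss, large reorienting shifts between scene regions — are excluded from
amplitude statistics; `max_gap = Inf` restores unconditional pairing.
Whether the study measured saccade length centroid-to-centroid or as
sample-path length is not stated in its methods; centroid-to-centroid is
the deterministic choice and is used throughout. Blinks are maximal runs
of confidence below 0.1 lasting at least 50 ms.

## Areas of interest

Three labeled polygons partition the scene: the HUD, the instrument
field (the area of the model eye), and the peripheral view. Fixations
are assigned by the surface containing their *centroid* (point-in-polygon
with boundaries counted inside); centroids outside every polygon fall
back to `peripheral`, and overlaps resolve by the priority
HUD > instrument field > peripheral. The gaze distribution is
count-based — each fixation weighs equally, matching a "proportion of
total fixations" reading rather than duration weighting. Marker-based
surface tracking (homography estimation from video) is out of scope:
surfaces arrive already in scene coordinates.

## Coverage maps

The coverage algorithm quantifies how much of the model the surgeon
visually sampled. The baseline image carries an exact blue label
(0, 0, 255) on the model region. A circular marker of 5 degrees angular
size is painted at each fixation centroid; coverage is the count of
pixels that are blue in the baseline and non-blue in the painted image,
divided by the total pixel count of the baseline image (a
`blue_region` denominator is available, which reads coverage as a
fraction of the model itself). Two readings of "5-degree circular
marker" are possible; the package defaults to 5 degrees *diameter*
(radius 2.5 degrees) and exposes `size_is = "radius"` for the
alternative. Markers are placed at fixation centroids rather than every
raw sample — this makes coverage invariant to sampling rate — and
degrees map to pixels through the single linear scale
`diagonal_fov / diagonal pixel length` (0.068 deg/px for a 1280 x 720
frame with a 100-degree diagonal field of view).

## Tear geometry

A tear annotation records the forceps axis, the tear vector, the circle
traced by the forceps travel, the tear path polyline, the initiation
point, and the wound (insertion) point. Metrics:

* **Tear angle** — angle between the tear vector and the forceps axis.
  The default treats both as *directed vectors*, giving angles in
  [0, 180] degrees. This choice is forced by the published group
  statistics: a novice group mean of 88.4 degrees with a between-subject
  SD of 14.3 is arithmetically impossible if every measurement were
  folded to [0, 90] (the maximum attainable SD for an n = 5 group with
  mean 88.4 under a 90-degree cap is about 3.6), so the measured angles
  must have exceeded 90 degrees. An undirected `mode = "line"` fold to
  [0, 90] remains available.
* **Diameter fraction** — tear-path arc length over the reference length
  of the full capsulorhexis model. The reference is an explicit
  annotation field (by convention the model-circle circumference), so
  either convention for "length of the full model" can be supplied.
* **Initiation distance** — distance from initiation point to wound,
  in units of the travel-circle radius.
* **Circularity** — the isoperimetric quotient 4πA/P² of the closed tear
  path (shoelace area, segment-sum perimeter): 1 for a circle, π/4 for a
  square. Paths are auto-closed when the endpoint gap is below 10% of
  the path length; wider gaps are rejected, so partial tears report no
  circularity rather than a misleading one.

## Group inference from summary statistics

Published results tables give per-group (n, mean, SD). The package
computes the one-way fixed-effects ANOVA directly from those moments
(SS_between from group means, MS_within as the pooled variance), which
is algebraically identical to a raw-data ANOVA on any sample matching
the moments — a property the test suite verifies against `lm`/`anova` on
moment-matched samples. Tukey HSD follows with
q = |m_i − m_j| / sqrt(MS_within / n) on the studentized range
distribution (k groups, Σ(n_i − 1) df), requiring equal n as in the
study design (Tukey–Kramer is deliberately out of scope). The
studentized range tail uses R's `ptukey`; the classical k = 2 identity
(Tukey p equals the pooled two-sample t-test p) and published critical
values (q₀.₀₅ = 3.877 at k = 3, df = 10) serve as independent checks.
Because printed means and SDs are rounded, reproduced p-values are
compared as bounds (p < 0.0001), not as equalities. Pearson correlation
uses the t transform on n − 2 df.

```{r}
tear_angles <- group_summary(
  c("pgy2", "pgy3", "pgy4", "fellow", "attending"),
  n = 5, mean = c(88.4, 70.4, 48.4, 18.4, 6.0),
  sd = c(14.3, 7.30, 4.03, 2.7, 1.58))
anova_oneway_from_summary(tear_angles)
head(tukey_hsd_from_summary(tear_angles), 4)
```

## The synthetic-data generator

Sessions are built as alternating dwells and transitions:

* **Dwell durations** follow a log-normal truncated to the detectable
  80–420 ms range, right-skewed as empirical fixation durations are. The
  log-sd is fixed at 0.45; the location parameter is solved per session
  (by root finding on the truncated mean) so the truncated mean equals
  the subject-level target exactly. Durations are quantized to the
  200 Hz sample grid by rounding, which keeps the session mean unbiased.
* **Between-subject variation.** Each session first draws its own mean
  fixation duration, mean saccade amplitude and HUD share from
  Normal(group mean, group SD) — the published SDs are between-subject
  SDs, and without this layer "within 3 standard errors over 30
  replicates" checks would be degenerate.
* **Transitions** between dwells are 2–3 samples at low confidence
  (0.35), linearly interpolated. Low confidence during saccades is a
  physical property of pupil tracking, and it is load-bearing: after
  filtering, the 15–20 ms gaps delimit fixation windows, which is the
  only way consecutive dwells 0.1–0.3 degrees apart can be separated
  under a 1.5-degree dispersion threshold. Within-dwell jitter is
  Gaussian truncated at ±2 sd (default sd 0.15 degrees): tracker noise
  inside a fixation has no Gaussian tails — fast excursions *are*
  saccades and are modeled as such. With the default jitter the maximum
  pairwise spread of a dwell is bounded by ~0.85 degrees, so detection
  closure (detected events = generated events) is exact; at 0.3 degrees
  jitter, counts still agree within 2%.
* **Area-of-interest runs.** Dwell labels come in runs (mean length 8
  dwells for feed-forward experts, who rapidly alternate focus; 18 for
  reactive novices); each run's label is drawn independently from the
  profile's AOI proportions, which makes per-label fixation fractions
  unbiased regardless of run length. Relocations between regions follow
  the saccadic main sequence (21 ms + 2.2 ms/degree) and are excluded
  from saccade-amplitude statistics by the `max_gap` rule, as in the
  detector. Within a region, dwell centers random-walk with
  gamma-distributed step lengths (shape 4) whose mean is the
  subject-level saccade amplitude. Reactive profiles concentrate
  instrument-field dwells in a Gaussian cluster at the tear site at the
  edge of the model; feed-forward profiles spread uniformly over the
  model — reproducing the observation that novices stare at the tear
  area while experts distribute attention over the whole field, and
  giving experts larger coverage fractions.
* **Blinks** drop confidence to 0.02 for 100–300 ms at dwell boundaries,
  at a per-boundary probability calibrated to the profile's blink rate
  (no blink model was published; 10 per minute is a mid-range resting
  value).
* **Tear annotations** draw the true angle from Normal(group mean,
  group SD) truncated to [0, 180] degrees, build the tear path as an arc
  of the travel circle spanning the drawn diameter fraction, and place
  the initiation point near the wound for feed-forward profiles and far
  for reactive ones.

Determinism: identical (profile, seed) pairs give byte-identical
sessions; cohort seeds derive from a base seed plus a stable string hash
of the group label and replicate index, so manifests are reproducible
across platforms.

### Profile parameters

The five built-in profiles carry the published group values: fixation
durations (attending 0.118 ± 0.016 s, PGY2 0.286 ± 0.152 s), saccade
amplitudes (PGY2 0.294 ± 0.053°, fellow 0.122 ± 0.022°, attending
0.126 ± 0.018°), HUD/instrument-field shares (attending 77.2 ± 4.09% /
16.6 ± 5.5%, PGY2 43.4 ± 8.32% / 36.4 ± 12.1%), tear angles (88.4 ± 14.3
down to 6.0 ± 1.58 degrees) and diameter fractions (14.6 ± 3.5% up to
57.6 ± 16.4%). Values never published — the intermediate groups' AOI
shares, saccade lengths, diameter fractions and most fixation
durations — are filled with monotone interpolations consistent with the
published ordering; they affect only the intermediate synthetic groups,
not any validated quantity.

One known interaction: PGY2's published fixation duration
(0.286 ± 0.152 s) collides with the detectable range — subject-level
draws truncated to (0.08, 0.42) have mean ≈ 0.26, not 0.286. This is a
property of the published numbers (a mean that close to the window edge
with that SD cannot survive truncation), affects no validated target,
and is left as-is rather than silently re-weighted.

### What the generator does *not* emulate

Synthetic streams have piecewise-stationary dwells, ideal confidence
separation between fixation and saccade samples, and exactly polygonal
AOIs. Real recordings add smooth pursuit, head-motion artifacts,
calibration drift, and confidence that degrades gradually rather than
discretely. Passing recovery tests therefore shows that the measurement
chain is unbiased under the study's statistical structure — not that the
detector is robust to every artifact of real hardware.

## Numerical choices

* Dispersion comparisons use an absolute tolerance of 1e-9 to keep
  grid-exact dwells (e.g. spans of exactly 0.420 s) inside closed
  bounds under floating-point arithmetic.
* The truncated log-normal mean is evaluated through whichever normal
  tail keeps precision, and the location solver brackets ±12 log-sd, so
  subject means across the admissible range (0.085–0.405 s) solve to
  1e-12.
* The absorption property of I-DT (raising the dispersion threshold
  never sheds absorbed samples) holds for the uncapped algorithm and is
  tested with `max_duration = Inf`. With a duration cap it can fail at
  the margin: a merged window may orphan a sub-80 ms remainder that a
  smaller threshold kept as its own fixation.
* Heatmap kernels are truncated at 4 sd; each kernel integrates to its
  fixation's weight, so the unnormalized grid total equals total weight
  up to edge clipping.

## Problem sizes

Validation runs use 30 replicate sessions of 300 s at 200 Hz per group
(the study's sessions are of comparable order: ~1400–2800 fixations) for
parameter recovery, 200 synthetic annotations per group for tear-angle
recovery, and 100–1000 random cases for each oracle-equivalence
property. Recovery checks compare the grand mean across replicates to
the group parameter within three standard errors of the replicate
means.

## Limitations

* The pipeline analyzes gaze and tear geometry; it does not rate
  surgical competency (human rubric scoring is out of scope), detect
  surfaces from video, or reconstruct 3-D gaze.
* Summary-statistic inference can only reproduce results whose group
  summaries were published in full; the five-group tear-angle table is
  complete, while e.g. the fixation-duration table is not (three of five
  group summaries unpublished), so its pairwise contrast is not
  reproducible and is not claimed.
* Velocity-based (I-VT) saccade detection and smooth-pursuit
  classification are non-goals; the saccade inventory is exactly the
  complement of the fixation inventory under the gap rules above.
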