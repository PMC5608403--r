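---
title: "Methods: single-cell CDK2 tracking and protein dynamics maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell CDK2 tracking and protein dynamics maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdk2map)
```

## The measurement problem

Cultured populations of non-transformed cells are mixtures: most cells
proliferate, but a fraction spontaneously exits to quiescence (G0), and a
further fraction re-enters the cycle after a variable dwell. A live-cell
CDK2 activity sensor separates these behaviors at the single-cell level:
the sensor is nuclear when CDK2 is inactive and translocates to the
cytoplasm as activity builds, so the cytoplasmic-to-nuclear ratio of its
fluorescence reads out CDK2 activity. Filming an asynchronous population
(one frame every 12 minutes for 24 hours), fixing the cells, and staining
them for a protein of interest lets each cell's endpoint immunofluorescence
(IF) value be placed on a per-cell time axis — time since that cell's last
anaphase, or since its CDK2 activity buildup (the restriction point) —
without any chemical synchronization. `cdk2map` implements the full
computational chain this requires, plus a ground-truthed synthetic data
generator used to validate every stage.

## Pipeline stages

### Nuclear segmentation (`segment_nuclei`, `bridge_deflections`)

Frames are log-transformed (after adding a positive offset, default 1) and
convolved with a rotationally symmetric Laplacian-of-Gaussian (LoG) filter;
objects are contiguous pixels above a response threshold, 8-connected.
Defaults that the underlying method leaves open were fixed as follows:

* **Blob scale.** `log_sigma = nucleus_radius / sqrt(2)` pixels, the
  standard matched scale for disk-like blobs.
* **Response threshold.** `"auto"` uses median + 5 MAD of the response
  (estimated on a pixel subsample for large frames). Background dominates
  the histogram, so this sits just above the noise floor while the LoG
  response inside nuclei stays far above it.
* **Mask refinement.** The LoG support bleeds 1–2 px past a sharp nuclear
  boundary. Because the activity ratio is exquisitely sensitive to nuclear
  masks annexing perinuclear cytoplasm (and vice versa), the blob mask is
  gated at the Otsu split of the log-intensity histogram, which lands the
  mask on the intensity edge. This refinement can be disabled
  (`refine = FALSE`) for data without sharp nuclear boundaries.
* **Area bounds.** Objects outside `[0.25, 4]` times the expected nucleus
  area are discarded.

Touching nuclei form a single object with concave "waist" points on its
perimeter. The deflection-bridging step extracts the ordered boundary,
smooths it (circular moving average over 5 vertices), computes signed
turning angles over a 3-vertex lag, and marks vertices whose concave turn
exceeds `concavity_angle_threshold` (default 15 degrees). Among admissible
concave pairs (bridge no longer than `max_bridge_length`, interior inside
the object, not adjacent along the contour) the shortest bridge wins, ties
broken by deeper summed concavity. The cut removes pixels within 0.75 px
of the bridge segment — the narrowest straight cut that disconnects an
8-connected region — and recursion continues on the parts until no
admissible pair remains. Bridging runs on every object of the first frame
and afterwards only on putative merged objects flagged by the tracker
(`adaptive_resegment`), mirroring the adaptive design of the original
method.

### Intensity quantification (`quantify_frame` and per-cell operations)

* **Local background** (nuclear signals): the nuclear mask is expanded by
  25 µm and the median of non-masked pixels inside the expansion is
  subtracted from the nuclear mean; negative results clip to 0. The
  exported `local_background_subtract()` implements this definition
  exactly. The per-frame driver uses an equivalent pooled estimator for
  throughput — mean of pure-background pixels (farther from any nucleus
  than the perinuclear band) in coarse tiles spanning the same window —
  which agrees with the median definition on smooth backgrounds.
* **Global background** (cytoplasmic signals): all nuclear masks are
  dilated by 50 µm and the mode (integer-binned histogram) of the
  remaining pixels is used.
* **CDK2 activity**: the cytoplasmic statistic is the mean of the top 50%
  brightest pixels of a perinuclear ring — the nuclear mask dilated by
  `ring_inner_offset + ring_width` (defaults 1 + 4 px) minus the mask
  dilated by `ring_inner_offset`, excluding pixels of (or immediately
  next to) other nuclei. Activity is this ring statistic divided by the
  background-subtracted nuclear mean; when the nuclear mean falls below a
  floor (default 20 intensity units) the ratio is marked missing instead
  of exploding. The per-frame driver computes ring membership from a
  chamfer distance transform with each cell's ring restricted to its own
  neighborhood disk; on disk-like nuclei this agrees with the exported
  per-cell operation, and on noiseless renders both recover the generator's
  activity exactly.

### Tracking and anaphase detection (`link_frames`, `call_anaphase`)

Linking is greedy nearest-future-neighbor screened by conservation of
mass: candidate pairs within `max_displacement` (default 3 nucleus radii
per frame) are processed in order of increasing distance (ties by smaller
mass difference) and accepted only if the total H2B fluorescence matches
within `h2b_tolerance` (default 20%). Unmatched cells open or close
tracks; a track end may re-link across a single missing frame. Mass
conservation also drives event detection: an unmatched target whose mass
matches the sum of its two nearest vanished sources is a putative merge
(sent back to adaptive re-segmentation); an unmatched source whose mass
splits over its two nearest targets is a division candidate. The anaphase
call itself requires both candidate daughters to carry between 45% and
55% of the mother's total H2B fluorescence, endpoints inclusive.

### Fate classification (`classify_trace`)

Thresholds follow the published rules: dividing cells are `CDK2inc` if
activity is at or above 0.5 at every post-anaphase frame, `CDK2low` if
below 0.5 at every post-anaphase frame, and `CDK2emerge` if below 0.5 for
at least 3 h post-anaphase followed by a confirmed rise (3 consecutive
frames at or above threshold). Cells that divide but fit no rule are
reported `unclassified`, never forced. The method description also
mentions scoring from 2 h after mitosis; the all-frames rule is the one
stated with complete thresholds, so it is the default, and a
`grace_period` option reproduces the 2-hour variant. Nondividing cells
use the separate 0.6 threshold: `prolonged_quiescent` if activity stays
below 0.6 for the whole movie, `nondividing_emerge` if a confirmed rise
above 0.6 occurs. Anchoring the nondividing rise test at 0.6 (not 0.5)
keeps the three nondividing outcomes a clean partition. Predicates are
evaluated over observed frames only, so isolated missing frames do not
change a trace's class. Population fractions are reported per starting
cell: each first-frame cell contributes one label, read from the trace
after its last anaphase (following the first daughter at each division).

### Restriction point (`detect_rpoint`)

The R-point is the time CDK2 activity first begins to rise. Slopes are
fitted over forward-looking windows of 6–10 time points; the per-point
slope is the maximum across windows; and the linear score
`w_time * t − w_activity * activity + w_slope * slope` is maximized
(long time since mitosis, low activity, high slope). The score
coefficients are not published; the defaults (`w_time = 0.02` per hour,
`w_activity = 1`, `w_slope = 1` hour) were tuned once, on simulated
emerging traces independent of the test cases, to well below one hour of
median error, and are fully configurable. A large slope weight makes the
score ride the slope-estimation noise, so the tuning favors the activity
term for localization and uses the slope term mainly to reject flat
regions. Flat traces (no slope above `noise_floor`, default
0.05/h) return no R-point.

### IF registration (`estimate_jitter`, `match_if_to_traces`)

The stage jitters slightly between the last live frame and the fixed-cell
images. The shift is found by exhaustive integer search over
`[-radius, radius]^2` (default 20 px), scoring each candidate by the mean
absolute difference between the nuclear channels over the overlapping
region; normalizing by overlap area (a mean, not a sum) keeps large
shifts from being favored by smaller overlaps. Sub-pixel registration is
deliberately out of scope. IF values are then measured through the same
quantification path (nuclear mean, or the ring statistic for cytoplasmic
markers such as cytoplasmic Cyclin B1) on the back-shifted images; cells
whose centroid leaves the field are flagged missing, not scored zero.

### Snapshot phase gating (`fit_gates`, `call_phase`)

For fixed-only experiments, cells are placed in 7 phases from DNA
content, EdU, phospho-Rb and phospho-histone H3. Exact cutoffs are fitted
from the data: DNA content is rescaled so the first major density mode
(2N) sits at 1; near-2N and near-4N windows default to `[0.8, 1.25]` and
`[1.6, 2.5]`; EdU negative/intermediate/high thresholds come from the
valleys of the trimodal log-EdU density; phospho-Rb and pHH3 thresholds
from the valley between their two modes. The decision tree: EdU-negative
2N cells split into G0/G1 by phospho-Rb; EdU-intermediate cells are early
or late S by DNA content; EdU-high cells are S; EdU-negative 4N cells
split into G2/M by pHH3. Cells outside every box stay `unassigned` —
conservative gates commit only where the markers are unambiguous, and the
unassigned fraction is always reported. Accuracy of the gating is
therefore judged on the cells the gates commit to; with the generator's
default lognormal measurement noise a noise-displaced boundary cell is
left unassigned rather than guessed.

### Dynamics maps (`reconstruct_dynamics`, `moving_average`,
`normalize_pair`, `assign_group`)

Each cell contributes one point at `x = fixation time − anchor time`;
prolonged-quiescent cells (no anaphase) are plotted at the movie length.
The summary curve is a sliding-window mean ± SD (window 2 h, step 0.5 h,
bins with fewer than 10 points suppressed; these values are not stated in
the source method and are configurable). For cross-protein maps, the
proliferating and quiescent curves of a protein are rescaled together so
the shared minimum is 0 and the shared maximum is 1. A protein is
"Group 1" (off in quiescence) when its normalized quiescent curve is flat
(range < 0.2) and low (below 0.25); otherwise it is "Group 2" (changing
dynamically in quiescence). The S-phase annotation is the interval where
the EdU moving average of proliferating cells exceeds its half-maximum.

## The synthetic data generator

No raw microscopy accompanies the study, so validation rests on a
generator that emulates the statistical structure the analysis assumes
and carries complete ground truth.

* **Population composition.** Default fate fractions are 79.0%
  CDK2-increasing, 8.8% CDK2-low, 7.8% CDK2-emerging, 2.3% prolonged
  quiescent and 2.1% nondividing-emerging — the study's reported
  population structure; 95.6% of cells divide once during the movie.
  Fates are drawn i.i.d. from these fractions.
* **Traces.** Activity laws are piecewise linear with Gaussian
  frame-to-frame fluctuation (SD 0.02), the simplest family reproducing
  the published trace morphology: increasing cells are born at 0.60–0.80
  and rise 0.05–0.09/h; low cells sit at 0.20–0.35; emerging cells dwell
  3.5 h or more before rising at 0.20–0.35/h; mothers ramp to a
  pre-mitotic peak of 1.6–2.2. Event times are drawn so each fate's
  defining behavior is observable within the 24-hour movie.
* **Division.** At anaphase the mother disk is replaced by two daughters
  at ±1 nucleus radius along a random axis, with H2B mass split 48–52%
  (sister chromatid segregation is near-exact; the 45–55% detection band
  then tolerates measurement error).
* **Rendering.** Nuclei are uniform disks whose integrated H2B intensity
  equals the cell's mass; the sensor splits a fixed per-cell total
  between nucleus and a 7-px cytoplasmic annulus so that the annulus:
  nucleus mean ratio equals the true activity. Cytoplasm is territorial:
  a contested pixel belongs to the cell with the nearest nucleus edge,
  as in a monolayer, so neighboring cells' signals do not add. Nuclei
  are impenetrable — a hard-core exclusion keeps nucleus edges at least
  `contact_gap` (3 px) apart while cells random-walk (SD 0.3 px/frame).
  Gaussian pixel noise (SD 5 on a background of 100) is added per frame
  from a seed derived deterministically from the configuration.
* **Endpoint IF.** Per-cell intensities come from parametric profiles of
  (fate, time-since-anaphase) encoding the published shapes: Cyclin A2
  linear through S/G2 and off in quiescence; Cyclin B1 supra-linear from
  late S; Geminin rising then plateauing; c-Myc and phospho-Rb climbing
  and off in quiescence; Cyclin D1 U-shaped in cyclers but high and
  rising in quiescence; Cyclin E peaking at G1/S in cyclers and rising
  in quiescence; p21 low in cyclers, accumulating in quiescence; Cdt1
  high in G1, degraded in S, recovering in G2, decaying slowly in
  quiescence; EdU marking the S window (default 5–13 h post-anaphase);
  p27 flat. Staining noise is lognormal (sdlog 0.1), and the whole IF
  set is rigidly translated by the stage jitter (returned for testing).
* **What is not emulated.** No optical PSF, photobleaching, uneven
  illumination, apoptosis, directional migration, or segmentation-hostile
  texture. Passing end-to-end tests therefore demonstrates the internal
  consistency and correctness of the pipeline's logic under the assumed
  noise structure — not robustness to every artifact of real microscopy.

## Numerical choices and determinism

Identical configuration and seed give bit-identical cohorts, movies, IF
sets and result tables; per-frame noise seeds are derived from the
configuration seed so frames can be rendered in any order. The distance
transform in the per-frame quantifier is a chamfer (3,4)/3 approximation
(within ~6% of Euclidean), which only gates ring membership and
background purity; the exported per-cell operations use exact distances.
Thresholds estimated from large frames use pixel subsamples (at most
2×10^5 pixels), which changes estimates by far less than their sampling
error. Anaphase band endpoints are inclusive. Negative
background-subtracted means clip to zero.

## Problem sizes

The test suite exercises full movies at 121 frames with cohorts of 25
(noiseless, exact-recovery checks) and 150 cells (noisy end-to-end
recovery); `scripts/acceptance.R` reproduces the population-composition
results on 10 cohorts of 600 cells each (6,000 starting cells, roughly
11,500 tracked cells after divisions), sizes chosen so the whole analysis
runs on a laptop-class single core while keeping binomial sampling error
well inside the tolerances of the reported percentages.

## Known limitations

* The greedy mass-screened tracker reproduces the original design and is
  not a global (Hungarian/ILP) tracker; it relies on subconfluent
  densities, as the source experiments did.
* The ring statistic measures perinuclear cytoplasm; in very crowded
  fields neighboring cytoplasm can contaminate rings even with other
  nuclei excluded, a limitation shared with the original measurement.
* Fate rules are strict threshold predicates; a single-frame excursion
  reclassifies a trace (the optional `grace_period` and the generator's
  noise margins quantify this sensitivity).
* The gating module fits thresholds from marker densities and will
  refuse rather than guess when a distribution is not bimodal/trimodal;
  manual overrides are provided for such data.
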