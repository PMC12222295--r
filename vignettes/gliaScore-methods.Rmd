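---
title: "Scoring neuroglial cells with gliaScore: models, parameters and design choices"
author: "gliaScore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring neuroglial cells with gliaScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaScore)
```

# The measurement problem

Glial activation changes cell morphology: resting ("ramified") microglia
carry many long thin processes, activated cells retract them and grow a
broad cytoplasm, ending in the "amoeboid" state. Scoring these states by
eye is slow and observer-dependent. gliaScore implements an automated
scoring chain over multi-channel immunofluorescence images — DAPI for
nuclei, Iba1 for microglia, GFAP for astrocytes, neurofilament for
neuronal processes — that reduces each image to a small set of
morphometric numbers: per-channel area fractions, microglia counts,
per-cell process counts, and an activity-state label per cell derived
from the relative area of its nucleus.

Because no public image set accompanies the protocol, the package ships
a synthetic-scene generator with planted per-cell ground truth; every
stage of the chain is validated end-to-end against it.

# Projection

Input stacks hold up to 30 planes spaced 0.24 µm along Z (both
configurable; acquisition protocols in this setting vary between 28 and
30 planes, so the cap is a parameter rather than a constant). The stack
is collapsed by maximum-intensity projection, `P(x,y) = max_z I(x,y,z)`.
All downstream measurements are two-dimensional and expressed in pixels;
the lateral pixel size is carried as metadata only. Channels are stored
as named intensity rasters — display colours are presentation, not data —
and absent channels are tolerated, so single-stain and double-stain
images both load.

# Trainable segmentation

Object/background separation is a scribble-trained per-pixel
classification, mirroring the interactive workflow of commercial
trainable-segmentation tools. The feature bank is deliberately small and
versioned (`v1`): raw intensity, Gaussian-smoothed intensity at σ = 1
and 2 px, Sobel gradient magnitude, and local variance in a 5×5 window.
The classifier is a shallow random-forest ensemble (50 trees) seeded
explicitly: identical features, scribbles and seed reproduce the
identical mask bit-exactly, which the test suite asserts. Training
accuracy on the scribbled pixels is reported alongside the out-of-bag
accuracy; the latter is the honest generalisation estimate (training
accuracy of a forest on overlapping classes is near 1 by construction).

Two post-processing rules apply before any measurement:

- **Small-object suppression.** Connected components with fewer than 24
  pixels are reassigned to background. Connectivity is 8-neighbourhood —
  diagonally touching fluorescent pixels belong to one structure — and
  the threshold is *strictly below*: a 24-px component survives at the
  default. The threshold is a configuration knob (`minSize`); 24 px is
  the default used throughout.
- **Area fraction.** `100 · object pixels / image pixels`, bounded in
  [0, 100] and monotone under mask union.

# Microglia detection

A microglial nucleus is a nucleus-channel blob wrapped in Iba1 signal.
Candidates are 8-connected components of the (filtered) nucleus mask;
components below the 24-px rule are discarded for consistency with the
global background rule. Touching candidates are split by a watershed on
the Euclidean distance transform and flagged (`split`), since clumped
nuclei are the main failure mode of blob counting. The border criterion
is operationalised as: at least 50 % of the candidate's 1-px outward
dilation shell must lie on microglia-channel object pixels. The source
protocol states the criterion qualitatively only — a dark nucleus rimmed
in green — so the 0.5 threshold is an explicit, documented
configuration value (`borderFractionMin`); the accepted count is monotone
non-increasing in it, which the tests assert. Whether a full or partial
ring was originally required is unknowable from the protocol — 0.5 makes
the choice visible rather than burying it.

# The zone of influence

Processes are counted in an annular ring around each nucleus: a 9-px
open gap followed by a 14-px radial band. Two choices deserve comment.

**Distance metric.** Distances are Euclidean (isotropic), measured from
the nucleus *pixel set* (i.e. its boundary), not its centroid: the gap
is specified between the ring and the object itself, and centroid-based
rings would deform with nucleus size. A Manhattan variant is selectable
through the `metric` argument.

**Pixel-count semantics.** The ring is the set of pixels whose distance
d to the nucleus set satisfies `gap + 1 ≤ d < gap + width + 1`. On the
pixel grid this is the reading under which the stated numbers are true
by count: exactly `gap` background pixel shells separate nucleus and
ring, and the ring spans the next `width` shells. The half-open
alternative `gap < d ≤ gap + width` looks equivalent but is not: the
smallest attainable inter-pixel distance above 9 is √82 ≈ 9.06 (an off-
axis offset), so that variant yields a measured open gap of 8 pixels,
not 9. The package's definition makes a distance-transform measurement
of the planted ring reproduce 9 and 14 exactly, and the acceptance
script performs exactly that measurement.

The process count is the number of 8-connected components of
(microglia mask ∩ ring), computed within the ring subgraph: green runs
separated by background are separate processes, and a branch that forks
outside the ring and re-enters counts once per crossing. Rings clipped
at the image border are flagged (`border_clipped`), as are rings that
overlap a neighbouring cell's ring or nucleus (`overlap_flag`);
processes from neighbouring cells are counted — nothing in the 2-D
projection distinguishes them — and the flag lets users filter instead.

# Activity-state classification

For each activity state, the per-cell relative nucleus areas (percent of
total image area) are summarised by their mean and a two-sided t-based
95 % CI, `mean ± t₀.₉₇₅,ₙ₋₁ · s/√n` — the protocol specifies a
parametric analysis without naming the interval, and the t-interval is
the standard parametric choice at these group sizes. States whose
intervals overlap are merged by transitive closure. The shipped
calibration table (197 visually categorised cells: 14 ramified, 102
hyper-ramified, 68 bushy, 13 amoeboid) merges ramified
([0.15, 0.25]) with hyper-ramified ([0.15, 0.18]) and leaves bushy
([0.39, 0.44]) and amoeboid ([0.59, 0.81]) separate — three groups:

```{r}
mergeOverlapping(referenceNucleusAreaStates())
```

Classification is a total monotone step function: decision boundaries
sit at the midpoints of the gaps between adjacent merged intervals
(0.32 and 0.515 for the calibration table); a value exactly on a
boundary goes to the lower group, and values beyond the extreme
intervals clamp to the end groups. The protocol gives "upper and lower
limits" without an out-of-range rule, so midpoint assignment plus
clamping is the package's choice — it is the unique rule that is total,
monotone and symmetric around each gap. Separation of the states can be
checked nonparametrically (`validateSeparation`: Kruskal–Wallis plus all
pairwise rank-sum tests, unadjusted and Holm-adjusted). Rod-shaped
cells are outside the label set; `isRodCandidate` flags them as
metadata via pixel-set eccentricity > 0.95.

# Study statistics

The unit of analysis is the mouse: per-image values are averaged within
(mouse, line, day, region, metric) before any test. Group comparisons
pass a Shapiro–Wilk gate on within-group-centred residuals; at p < 0.05
the values are natural-log transformed and re-tested, and the analysis
proceeds on the log scale (the transform flag is reported; the log
branch refuses non-positive values rather than silently shifting them).
The two-sample test is Welch's t-test — the protocol names no specific
test, and unequal variances between a wild-type and a transgenic line
are plausible. Time-course comparisons apply the same gate pairwise
between days and report both unadjusted and Holm-adjusted p-values;
the unadjusted values are kept because the reference analysis reported
raw p-values. The type-I error of the whole gate + test procedure is
calibrated by simulation in the test suite: within [0.03, 0.07] at
nominal 0.05 with 8 mice per group over 1,000 null replicates.

# Synthetic scenes and what they do (not) show

`generateScene` renders, per channel: disks for nuclei; a bright soma
annulus (3 px) around each nucleus — guaranteeing the green border that
detection requires — plus straight radial arms at jittered angles with
an enforced minimum angular separation, so the number of ring crossings
equals the planted arm count analytically; persistent random-walk
filaments for astrocytes; and parallel tracts with an orientation
dispersion parameter for neurofilament (dispersion 0 emulates the
strictly parallel arrangement of healthy tissue, larger values the
disordered one). Defaults: background 0.05 and Gaussian noise sd 0.05
of the dynamic range (a 10-sigma contrast to the 0.85–0.9 object
intensities, at which the default segmentation reaches the ≥ 0.95
pixel-agreement the tests require), optional Poisson shot noise,
non-overlapping placement by dart throwing with pair-specific minimum
separations derived from the soma radii. Class-conditional nucleus
areas are normal with the calibration table's means and standard
deviations back-computed from the printed CIs,
`s = √n · (ci_high − mean) / t₀.₉₇₅,ₙ₋₁` (0.087, 0.102, 0.124, 0.182
for ramified, hyper-ramified, bushy, amoeboid), truncated below at
0.02 % so every nucleus stays rasterisable; draws sit far from the
truncation point for all classes, so the induced bias is negligible.
Ground truth (pixel rasters, per-cell areas, arm counts, labels) is
recorded before noise. Identical spec and seed give bit-identical
scenes.

`renderZstack` distributes structures over planes with a Gaussian axial
profile whose peak lies exactly on an integer plane, so the
maximum-intensity projection of the stack reproduces the noise-free
scene exactly — the round-trip is asserted to within one 16-bit
quantisation step. Plane-level noise is deliberately not simulated:
it would break the round-trip identity that makes the projection stage
testable; scene noise is applied in 2-D after projection instead.

`generateStudy` emulates the reference design (two lines × days 3/7/14 ×
up to 9 mice × images) with lognormal per-mouse random effects
(sd 0.1) and multiplicative planted line effects on arm counts, cell
counts and nucleus areas. Truth tables are always produced; full scene
rendering is optional (`render = TRUE`), since the statistics layer is
validated on truth-propagated metrics.

What passing on synthetic scenes does *not* show: real tissue has
anti-aliased and uneven staining, curved and tapering processes,
overlapping cells in dense fields, and out-of-focus haze. The generator
plants sharp-edged, well-separated structures precisely so that ground
truth is unambiguous; results on real images will degrade with staining
quality, and the classifier must be retrained per staining batch.

# Numerical choices and degenerate inputs

- Raster convention: matrices indexed (row, column); intensities
  non-negative, 8-bit TIFF input up-scaled ×257 to the 16-bit range.
- Gaussian features use a separable kernel clipped to the raster, so
  small images remain featurisable; boundary handling is replication.
- Zero-variance states give degenerate CIs `[c, c]`; they merge only
  with intervals containing c.
- Empty masks: zero area fraction, zero detections, zero process
  counts — never errors. Zero-area images, empty nucleus sets,
  single-class scribbles, rings entirely outside the image, and all-tied
  data in the rank tests are errors.
- Problem sizes used in validation: property suites run on scenes
  between 256² and 420² pixels (100 seeds for arm recovery, 50 for
  count recovery); parameter-recovery experiments use 512² scenes with
  13 cells (amoeboid) and 1024² scenes with 68 cells (bushy), replicated
  so the class-mean estimate's sampling error (SE ≈ 0.013 and 0.007
  percentage points) is well inside the ±0.05 acceptance band. These
  sizes were chosen to keep a full validation run on a single CPU in
  minutes while leaving the statistical conclusions unchanged at larger
  scale.

# Known limitations

- Astrocytes are measured only as an area fraction; their dense network
  is not separated into single cells (single-astrocyte morphometry is an
  open problem in this protocol family).
- Process length and width in µm, curvature, and 3-D tracing are out of
  scope; everything is measured on the 2-D projection, so processes
  missed by every Z plane are invisible.
- The ring attributes any crossing process to the ring's cell; in dense
  fields, use `overlap_flag` to exclude ambiguous cells.
- The chessboard distance variant for the ring is not offered
  (Euclidean and Manhattan are); the per-image activity summary averages
  over cells and can mask a mixed population — classify per cell.
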