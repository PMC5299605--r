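---
title: "Choroid segmentation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choroid segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(choroidseg)
```

## The problem

Enhanced-depth OCT volumes image the choroid — the vascular layer between
Bruch's membrane (BM) and the sclera — as a stack of noisy cross-sectional
B-scans. Its thickness is a candidate biomarker in several retinal and
systemic conditions, but the posterior boundary, the choroid–sclera
interface (CSI), is a weak, broken edge: often only the posterior walls of
individual choroidal vessels are visible, where the dark vessel lumen gives
way to the brighter sclera. `choroidseg` implements a fully automatic
pipeline that turns such a volume into 2-D thickness maps and 3-D shape
descriptors, and ships a synthetic phantom so the whole chain can be
validated end to end with exact ground truth.

## Pipeline model, stage by stage

**Anterior boundaries.** On each Gaussian-presmoothed B-scan the two
strongest local maxima of the axial intensity gradient mark the
retina–vitreous interface (anterior of the two) and the anterior edge of the
RPE band; the first negative gradient minimum below the latter gives a first
posterior-RPE estimate. Each raw trace is cleaned by a single-pass
polynomial rejection: one degree-5 fit, points farther than 5 median
absolute residuals discarded and refilled by linear interpolation. We chose
a single pass over iterated rejection for determinism; with a spike fraction
well under half, one pass already pins the fit to the consensus trace.

The RPE center is then re-traced as the minimum-cost left-to-right path
through the band between the two interfaces, with node cost `255 − I` (the
brightest ridge), per-column steps capped at `step_cap_px` (2 px) and ties
broken toward the smaller step. Whether the original formulation minimized
or maximized accumulated intensity is not decidable from its description;
the brightest-ridge convention is our reading and is recorded here rather
than asserted. The posterior RPE is placed at a constant per-B-scan shift
behind the center: a second band path weighted by `1/(|∂I/∂z| + ε)` follows
the strongest slope, its per-column offset is refined to sub-pixel by
quadratic peak interpolation, and the median offset becomes the shift. A
per-B-scan (rather than per-volume) shift tolerates tilted stacks.

**BM as a convex hull.** The BM is the posterior-side chain of the 2-D
convex hull of the posterior-RPE points, evaluated at every column along the
hull edges. Drusen push the RPE anteriorly but leave the BM in place, so the
hull bridges them with straight chords. Before the hull we damp the trace's
±1 px search wiggle with a small Gaussian along x; without it the posterior
chain systematically rides the local maxima of the noise (a ~1 px posterior
bias on the noisy phantom).

**Flattening and transverse smoothing.** Eye motion shifts whole B-scans
axially, so neighboring scans cannot be averaged directly. Each column is
shifted by the integer `round(d − BM(x))` so every BM lands on the common
depth `d` (default: half the image height), then each B-scan is replaced by
a Gaussian-weighted average of its flattened neighbors: scale
`sigma_y_um` (default 200 µm, i.e. roughly ±1 scan at 150 µm spacing),
half-window `N = ⌈3σ/Δy⌉`, weights renormalized over the part of the window
inside the stack so they always sum to one — no reflection, no invented
data. Integer shifts avoid resampling blur; the residual ±0.5 px BM
placement is negligible against the CSI uncertainty. The smoothing scale is
named for the across-scan axis (y) here; descriptions of this scheme
sometimes label the same parameter as an x-direction scale.

**CSI by graph search.** On the smoothed, flattened B-scan (after an
in-plane Gaussian low-pass, σ = 6 px in x and 2 px in z — anisotropic
because the boundary is locally horizontal, so averaging along x suppresses
speckle without biasing the axial inflexion position) candidate nodes are the
axial inflexion points below the BM: axial derivative above
`grad_thresh` (1.0 intensity/px) with `|∂²I/∂z²|` below
`curv_thresh` (0.05 intensity/px²); contiguous qualifying runs collapse to
the run's curvature minimum. The defaults were chosen on the phantom's
smooth sigmoidal edges; very abrupt profiles may need a larger
`curv_thresh`, which is a config key.

Edges connect nodes left-to-right within 5·`T_x` columns and 5·`T_z` rows,
with weight

```
w = c1·√(Δx²+Δz²) + c2·A_z·H(|Δz|−T_z)(|Δz|/T_z)^α
  + c3·A_x·H(|Δx|−T_x)(|Δx|/T_x)^α + c4 / max(A, ε)
```

where `A` sums the Gabor edge probability `P` over the discrete line between
the nodes. The combined form and the Heaviside-gated power-law penalties
realize the named ingredients (Euclidean attraction, gated jump penalties,
affinity toward high-probability corridors); every coefficient lives in the
`[csi]` config section so alternative functional forms are one-line changes.
`P` is the pixelwise maximum over an odd (sine) Gabor bank — 5 angles evenly
spaced in [−20°, 20°] about the +z axis, 3 scales in [10, 20] µm — oriented
so dark-to-bright axial transitions respond positively, clipped at zero and
normalized per B-scan (counts of 5 and 3 are our sampling of the stated
ranges; normalizing per volume instead would couple unrelated B-scans).
Kernels are built on physical (µm) coordinates, so the anisotropic pixel
pitch is handled naturally; a scale below one axial pixel is rejected. With
a 7.5 mm/512 transverse pitch the 10–20 µm scales are inherently sub-pixel
in x, so the one-pixel check applies to the axial direction, where the
filter does its work.

Dijkstra runs between two virtual endpoint nodes wired with zero weight to
the first and last occupied columns. Ties are broken toward the
lexicographically smallest node sequence, making the search deterministic.
If no spanning path exists the graph is split into weakly connected
fragments (weak connectivity is the right notion: edges are directed by
construction and never form cycles), each fragment gets fresh virtual
endpoints so its sub-search terminates, and overlapping fragment paths are
resolved greedily by segment score
`A_s·W_sum + A_m·W_mean + A_h·W_height` (coefficients 0.4/0.3/0.3, summing
to one; `W_height` is one over the mean node depth). A B-scan counts as
successfully segmented when a kept segment has at least 4 nodes.

**Maps and descriptors.** Choroidal thickness is measured only at CSI
nodes, as `(z_CSI − z_BM)·Δz`, weighted by the node's edge probability, and
positioned in fundus coordinates. Sibson natural-neighbor interpolation
builds the display lattice (default cell 50 µm — display only); every
quantitative descriptor is computed from the scattered weighted points,
never from the lattice, so interpolation artifacts cannot leak into
numbers. The macula is the global minimum of the lightly smoothed
(σ = 2 cells, NA-aware normalized convolution) retinal thickness map, ties
broken toward the scan center; the ROI is the largest circle around it
inside the scan square. Descriptors: weighted mean thickness
`ΣW·Δz / ΣW`; a W-weighted least-squares plane `t = ax + by + c`
(thickness in µm, fundus coordinates in mm) summarized by the spherical
angles of the upward normal `(−a·10⁻³, −b·10⁻³, 1)` — θ off +z, φ pointing
toward the thin side; and diagonal quadrant contrasts
`(m₁−m₂)/(m₁+m₂)` (a normalized difference; the contrast notion is not
otherwise pinned down). Weighting the plane fit keeps it consistent with
the weighted mean. The anatomical frame is +x temporal→nasal (OS volumes
mirrored in x about the ROI center) and +y inferior→superior; this frame is
declared, not inferred, and is printed in the map legends.

**Natural-neighbor implementation.** No installed backend provides Sibson
interpolation, so it is built here over a `deldir` Delaunay triangulation:
for each query the triangles whose circumcircles contain it form the
Bowyer–Watson cavity, and each cavity vertex's weight is the Voronoi area it
would cede to the inserted query (circumcenter polygons, shoelace areas).
This is exact at data sites and has linear precision. Robustness measures,
all deterministic: sub-resolution hash-based jitter (≈10⁻⁶ of the point-set
diameter) breaks the cocircular degeneracies of gridded sites; queries are
nudged by ≈10⁻⁸ of the diameter off Voronoi-vertex degeneracies; computed
weights must reproduce the query position (Sibson coordinates are local
coordinates) to 10⁻⁶·diameter, and any failing cavity falls back to
barycentric interpolation in the containing Delaunay triangle, which
preserves exactness and linear precision. Collinear site sets are rejected
up front.

## The phantom: what it emulates, and what it does not

`phantom_spec()` renders a 7.5 × 7.5 mm macular cube of 50 B-scans
(512 × 496 px, Δz = 3.87 µm, Δy = 7500/49 ≈ 153 µm — a common acquisition
geometry) with: a bright retina–vitreous band over a foveal pit (pit depth
150 µm, σ = 900 µm, so the fovea is the global retinal-thickness minimum,
as in a real macular scan); a bright RPE band whose posterior edge — the
ground-truth BM — is concave toward the posterior per B-scan, so the
convex-hull estimate is exact; optional drusen that lift the band but not
the BM; a darker stroma with dark vessel ellipses whose smooth sigmoid
posterior rims rest exactly on the CSI (so the rims contain genuine
inflexion points); a brighter sclera; multiplicative gamma speckle of mean
one (strength = coefficient of variation, clipped to [0, 255] — a noise
regime, not a physical speckle model); and whole-pixel axial jitter per
B-scan, kept integer so the ground truth stays exact. The choroid thickness
surface is a tilted plane (12, −8) µm/mm plus a gentle 40 µm sinusoidal
undulation around a 260 µm base.

Presets: `clean` (no noise), `noisy` (speckle CV 0.30, jitter ≤ 8 px),
`drusen` (4 drusen, mild noise), `low_contrast` (vessel dip halved). What
passing on the phantom does *not* show: real OCT speckle is correlated and
depth-dependent, real vessels are tortuous tubes with shadowing, real RPE
pathology is harsher than smooth drusen caps, and intra-B-scan motion is
absent. Phantom results bound algorithmic correctness, not clinical
performance.

## Numerical choices and degenerate inputs

* ε = 10⁻⁶ guards `1/A` and `1/height`; intensity rescale maps a constant
  image to 0; a constant image yields `P ≡ 0`, no nodes, and a
  "B-scan unsegmented" outcome rather than an error.
* Gradient peaks need two positive maxima and a posterior negative minimum
  per column; columns failing that are invalid and refilled by the outlier
  stage, and an all-invalid B-scan raises a stage failure that the pipeline
  records in its MANIFEST.
* The band searches restart cleanly if outlier bands leave a column
  unreachable; empty bands take the band midpoint.
* Flattening rejects a target depth outside the image; a flat posterior
  band falls back to a configured default shift with a warning.
* All randomness lives in the phantom generator (single seed); segmentation
  itself is deterministic, so reruns are byte-identical.

## Problem sizes used in the shipped checks

Unit tests run on a handful of B-scans; the end-to-end property checks run
the three presets at the full 50-scan, 512 × 496 study geometry, and the
acceptance script re-runs the complete pipeline (maps on a 150 µm lattice)
on the noisy preset plus boundary recovery on clean and drusen. These sizes
are the package's validation conditions; larger volumes simply scale
linearly in the number of B-scans.

## Known limitations

* The CSI edge model assumes dark-above/bright-below transitions; inverted
  or isoreflective scleral boundaries (e.g. heavy shadowing) will starve the
  node detector.
* The convex-hull BM is exact only where the true BM is posterior-convex
  per B-scan; strong posterior staphylomas violate that locally.
* Success bookkeeping (≥4 nodes in a kept segment) is a proxy, not a
  guarantee of map quality.
* The Heidelberg/Zeiss/Topcon proprietary containers are out of scope:
  volumes enter as exported image files plus a plain-text metadata file.
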