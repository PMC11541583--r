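---
title: "Methods behind the cytomorph measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the cytomorph measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomorph)
```

`cytomorph` turns four microscopy-based tumour-biology assays — stellate
spheroid invasion, organoid-field live/dead cytometry, endothelial tube
formation, and cell migration on scaffolds — into scripted, seeded,
testable measurements, together with two closed-form scalar scores.
This vignette explains the models behind each measurement, the tunable
parameters and their defaults, what the synthetic phantoms do and do not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## Image model and conventions

All pipelines operate on calibrated frames: a matrix of intensities in
`[0, 2^bit_depth - 1]` plus the pixel size in µm. Coordinates are
0-based with `x` along columns and `y` along rows, origin top-left;
areas are pixel counts times `pixel_size^2`, lengths are in µm.
Calibration is always supplied by the user rather than parsed from TIFF
tags, because tag dialects are unreliable across instruments; a wrong
calibration rescales areas quadratically, so this is the one parameter
worth double-checking. All randomness flows from one explicit integer
seed (default 0, never wall-clock), which makes batch runs byte-for-byte
reproducible.

## Stellate spheroid invasion

The assay grows a single spheroid per well in basement-membrane matrix;
invasive lines send strands of cells radiating into the matrix. The
pipeline quantifies that phenotype in five stages.

1. **Grey conversion** — unweighted channel mean, rounded half-up.
2. **Inversion for brightfield** — spheroids are darker than the
   background in brightfield; frames labelled `brightfield` are
   inverted so "positive objects" are bright in every assay.
3. **Local background reduction** — a morphological white top-hat: the
   greyscale opening with a disc of radius `ball_radius` is subtracted.
   A flat or planar illumination field is removed exactly in the
   interior (edges use replicate padding). The generic default is
   50 µm, but `analyze_stellate()` defaults to **250 µm**: the ball
   must be larger than the structure that has to survive subtraction,
   and here that structure is the spheroid core itself, typically
   300 µm across. A 50 µm ball would roll over the core and subtract it
   as "background"; 250 µm passes under it while still tracking
   millimetre-scale illumination gradients.
4. **Foreground and density** — Otsu thresholding (lowest-threshold tie
   break, favouring dim invading cells) or a fixed threshold, then a
   density image: the 0/1 foreground smoothed by a Gaussian of scale
   `sigma` (default 15 µm, about one cell diameter — small enough to
   resolve the core boundary, large enough that scattered cells score
   low density). The density image is computed from the binary mask,
   not the grey intensities, making the zone split invariant to
   illumination and exposure.
5. **Zone split** — inner core: largest connected component of
   `{density >= d_hi}` within the foreground, hole-filled; outer core:
   hole-filled largest component of `{density >= d_lo}` minus the
   inner core; periphery: the remaining foreground. Defaults
   `d_hi = 0.75`, `d_lo = 0.35` are calibration choices on the
   density scale (no published numeric cut-offs exist for the
   proprietary pipeline this mirrors); because the density image is
   mask-based, they transfer across instruments. Hole-filled pixels
   are absorbed into the reported foreground so the three zones
   partition it exactly — a filled hole inside a core is spheroid
   interior, not matrix. The largest-component rule encodes the
   one-spheroid-per-well design of the assay.

Read-outs: inner-core circularity `4*pi*A/P^2` clamped to `[0, 1]`
(1 = circular, least invasive), inner and outer core areas, and
peripheral area of invading cells (µm²).

**Circularity estimator.** Chain-code perimeters overestimate curved
boundaries by up to ~8 %, which would depress the circularity of a
genuinely round core to ~0.90. We instead trace the boundary chain,
smooth it with a circular Gaussian (sigma = 1.5 contour points), and
evaluate *both* perimeter and area on the resulting polygon. Using one
polygon for both quantities makes the quotient exact for axis-aligned
rectangles and discs up to the smoother's slight corner rounding; the
tests pin a rasterised disc at ≥ 0.98 and a square at `pi/4 ± 0.02`.

## Organoid-field live/dead cytometry

Patient-derived organoid cells form many small round spheroids; live
cells stain green (calcein-AM) and dead cells appear as bright orange
puncta (ethidium homodimer) with a bright centre and radially decaying
intensity.

- **Dead cells** are found by two engines whose masks are merged: a
  dot detector — maxima of a Laplacian-of-Gaussian response at the cell
  scale (`sigma = diameter / (2*sqrt(2))`), kept only if the intensity
  drops by at least `centre_drop` (default 0.3) within one radius — and
  a plain intensity threshold. Final points are engine-1 maxima plus
  centroids of threshold components no engine-1 point claimed. The
  `centre_drop` default is a calibration choice: the dot profile is
  specified qualitatively (bright centre, radial gradient), and 0.3
  accepts a Gaussian punctum sampled anywhere past ~0.85 radii while
  rejecting flat stained patches.
- **Live cells** use the threshold engine alone. Both detectors enforce
  a minimum point separation of half a cell diameter — without it,
  noise can split one punctum's supra-threshold footprint into
  satellite components that would double-count the cell.
- **Spheroids** are detected by a double threshold: intensity (relative
  thresholds make the count invariant to exposure rescaling), then
  area. The default `min_area` is the area of a disc three cell
  diameters across — an object smaller than a few cells is not a
  spheroid. Per-spheroid statistics count the live/dead points whose
  coordinates fall inside the spheroid footprint (boundary pixels count
  as inside, a deterministic tie-break) and average channel intensity
  over the member dots' footprints.

Thresholds default to fractions of the channel maximum (live 0.6,
dead 0.5, spheroid body 0.15), chosen for the fluorescence geometry the
assay assumes: puncta are several-fold brighter than spheroid bodies,
which are in turn brighter than background.

## Tube-network quantification

Endothelial cells on basement-membrane matrix organise into a
honeycomb-like network whose connectivity measures angiogenic
potential. The binarised image is thinned to a one-pixel skeleton by
Zhang–Suen parallel thinning followed by a sequential pass that deletes
simple non-endpoint pixels (Yokoi connectivity number = 1). The second
pass matters: parallel thinning leaves staircase pixels and two-pixel
"braids" on diagonal tubes, which would turn line interiors into
spurious junctions.

Skeleton pixels with a neighbour count other than two become nodes
(8-adjacent node pixels merge); segments are traced between nodes with
8-connected geodesic length (1 per axial step, `sqrt(2)` per diagonal).
Two cleanups follow:

- **Spur pruning** — branch segments ending at an extremity shorter
  than `prune_len` (default 10 µm, about one tube width) are removed
  iteratively.
- **Junction fusion** — thinning splits a thick X-junction into two
  nearby Y-junctions joined by a tube-width-long segment; junction
  pairs closer than `fuse_len` (default = `prune_len`) are fused. This
  plays the role of the unpublished junction-merging heuristics in
  macro-based network analysers, but with one transparent parameter.

Classification: extremity = degree 1; junction = degree ≥ 3; master
segment = segment with junctions at both ends; master junction =
junction touching a master segment. Meshes are interior faces fully
enclosed by the skeleton (background components not touching the image
border), with pixel-count areas; on pruned planar networks the face
count satisfies the Euler identity
`meshes = segments - nodes + components`, which the tests check against
planted lattices. Segment lengths use geodesic stepping rather than
Euclidean endpoint distance because real tubes curve.

The **angiogenesis index** is the arithmetic mean of the six parameters
each expressed relative to the control condition. "Relative to control"
is ambiguous between averaging per-image ratios and ratioing group
means; the two coincide for a single image pair. We take mean-of-ratios
as canonical for single comparisons and use group-mean parameters
before ratio formation in the batch CLI (`angio_index.csv`), where
images arrive in labelled groups. Any zero control parameter makes its
ratio undefined and raises an error naming the parameter rather than
propagating an infinity.

## Spot tracking and 3D morphometry

Cell spots are detected per frame as LoG maxima at the expected cell
scale, filtered to an intensity window in native units, and refined to
sub-pixel positions by an intensity-weighted centroid — without the
refinement, half-pixel quantisation biases speed upward by several
percent at slow speeds. Defaults mirror the published migration
analysis on bone-matrix scaffolds: diameter 18 µm, intensity window
30–230, maximum jump 20 µm, maximum gap 5 frames, 20 min frame
interval. The only spot filter implemented is the intensity window; the
proprietary "automatic quality" filter of the commercial tracker is
undocumented, and we prefer a reproducible criterion.

Linking is globally optimal per frame pair: among candidate pairs
within `max_dist`, the assignment minimising total squared displacement
(maximum-cardinality, minimum-cost bipartite matching) — not greedy
nearest-neighbour, so crossings resolve deterministically. Gap closing
then joins a track ending at frame `f` to one starting at frame
`f + g + 1` for `g = 1..max_gap` in ascending order, gated at
`max_dist * (g + 1)`, using the same optimal assignment within each gap
length: when two particles blink out on the same frame, greedy pairing
can strand one of them, while the assignment bridges both. Mean track
speed is the average over consecutive detections of displacement over
elapsed time, so a bridged two-frame gap contributes its displacement
over two frame intervals.

**Surface morphometry.** Volume is the exact voxel count times voxel
volume. Surface area is measured on an isosurface: the binary mask is
smoothed with a 3D Gaussian and triangulated at the 0.5 level by
marching tetrahedra (six tetrahedra per cube cell, no case table
ambiguities). Naive voxel-face counting overestimates a sphere's area
by a factor ~1.5; meshing the raw binary mask still overestimates
curved surfaces by ~8 % (staircase facets), while heavy smoothing
rounds the edges of polyhedral objects and underestimates them. The
default `smooth_sigma = 0.65` voxels balances the two regimes: residual
bias is under ~3 % for both a 20-voxel-radius ball and a 40-voxel cube,
within the tolerances the tests assert (`psi` of a cube
`= (pi/6)^(1/3) ± 0.03`, of a ball ≥ 0.95). Sphericity
`psi = pi^(1/3) (6V)^(2/3) / A` is clamped to `[0, 1]`; objects only a
few voxels across are below the resolution this estimator is designed
for.

## Scalar scores

Caliper tumour volume is `V = pi/6 * (d1 * d2)^(3/2)` with both
dimensions in mm; the product in mm² raised to the 3/2 gives mm³, the
dimensionally consistent reading of the ellipse-volume formula. The
composite IHC score sums a percent-positive bin and an intensity grade
(0–3). The printed bin table ("1–25", "26–50", "51–75", "> 76") is
stated in integers and leaves 75–76 % formally unassigned; we implement
the continuous right-closed partition `(0,25] (25,50] (50,75]
(75,100]`, which is exhaustive, order-preserving and agrees with the
printed bins at every integer except inside that gap, where `> 75` is
taken as bin 4. Boundary percentages (25, 50, 75) are covered by unit
tests.

## Synthetic phantoms: what they emulate, and what not

Each generator plants objects with the statistical structure its assay
assumes and records the exact truth (masks, point lists, generating
graph, trajectories):

- `make_stellate()` — one dark core disc (default radius 150 µm) with
  radial strands of dark 6 µm-radius cells on a bright background
  (512², 2 µm/pixel), under a multiplicative planar illumination field
  (±10 %) and Gaussian read noise (default 2 % of full scale, object
  contrast ~40 %, i.e. contrast-to-noise ~20); Poisson shot noise is
  available but off by default. Strands take off 15 µm outside the
  core, as migrating cells detach from the aggregate.
- `make_organoid_field()` — 12 spheroid discs (radii 20–40 µm) placed
  with ≥ 30 µm edge separation; live puncta ride on the green spheroid
  bodies, dead puncta on a dark orange channel, both as isotropic
  Gaussians with sigma = diameter/4 (the bright-centre, radial-gradient
  profile the dot detector targets).
- `make_tube_lattice()` — a rectangular lattice of bright tubes with
  known node degrees, edge lengths and face areas. The truth also
  stores master-segment totals of the *degree-2-contracted* generating
  graph: lattice corners have degree 2, and a skeleton tracer cannot
  see degree-2 points as nodes — it merges their two edges into one
  junction-to-junction path — so the contracted graph is the honest
  oracle for what the measurement should return.
- `make_track_movie()` — straight constant-speed trajectories rendered
  as Gaussian spots (8-bit, peak 150, inside the default intensity
  window), with per-particle dropout frames and optional positional
  jitter. Trajectories are planted with a minimum pairwise separation
  (default one spot diameter): the phantom emulates distinguishable
  cells, because no tracker can keep identities for spots that sit
  inside one another's point-spread for many frames.

The phantoms deliberately omit matrix texture, optical PSF blur, 3D
rendering, photobleaching and cell shape change. Passing the recovery
tests therefore demonstrates that the measurement chain is correct and
unbiased on images that satisfy each assay's stated assumptions — not
that the pipelines are robust to every real-world artefact; on real
data the thresholds and scales above are the knobs to revisit, and the
run log records every effective value.

## Numerical choices and limitations

- Otsu ties (plateaued histograms) resolve to the lowest optimal
  threshold, favouring inclusion of dim invading cells.
- Degenerate inputs fail loudly with typed errors: constant images have
  no Otsu threshold, an empty inner core has no circularity, an empty
  3D mask no morphometry, single-detection tracks no speed, zero
  control parameters no ratio.
- Problem sizes in the test-suite and acceptance script (512² stellate
  fields, 10–20 phantom replicates per assay, twenty 25-frame movies)
  were chosen so the full suite completes in a few minutes on one CPU
  while keeping every tolerance meaningfully tight.
- The tube-graph master-length measurement loses the length of fused
  junction connectors (one tube width per thick junction); on the test
  lattices this keeps totals within ~2 % of truth, and it is the price
  of topology-faithful junction counts.
- Mesh areas are measured on skeleton-enclosed faces, not on the
  binarised tube mask's background holes: the skeleton face extends to
  the tube midlines and matches the generating graph's face area
  independent of tube width, whereas mask holes shrink by a
  tube-width-dependent margin.
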