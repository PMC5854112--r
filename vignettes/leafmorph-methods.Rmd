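---
title: "Measuring leaf-margin dissection and boundary-reporter signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leaf-margin dissection and boundary-reporter signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafmorph)
```

`leafmorph` quantifies how dissected a leaf margin is, where its teeth and
sinuses sit, how these features evolve over development, and how much
boundary-reporter fluorescence accumulates in the sinus regions that
pattern them. This vignette explains the models and procedures behind each
stage, the parameters that matter, and the design choices that were
genuinely open.

## The dissection index and its alpha-hull normalization

For a closed contour with perimeter $P$ and area $A$ the isoperimetric
quotient

$$\mathrm{DI}_{\mathrm{raw}} = \frac{P^2}{4\pi A}$$

equals 1 for a circle and grows with any departure from circularity. Used
alone it confounds two very different things: global blade shape
(elongation, the petiole) and marginal dissection (teeth). The package
therefore computes the same quotient for the contour's *alpha-hull* — a
radius-$\alpha$ generalization of the convex hull that bridges the sinuses
between teeth while still following the blade outline and the petiole —
and reports the ratio

$$\mathrm{DI} = \frac{\mathrm{DI}_{\mathrm{leaf}}}{\mathrm{DI}_{\mathrm{hull}}}.$$

Only this final ratio is compared across genotypes; it is invariant to
uniform scaling and rigid motion, ≈ 1 for smooth-margined leaves, and
increases monotonically with tooth depth.

**Computable realization.** The arc-bounded alpha-hull is realized as the
*alpha-shape*: the contour is resampled to `n_points` vertices (default
1024, decoupling hull resolution from pixel size), the vertices are
Delaunay-triangulated (Bowyer–Watson, compiled), and triangles whose
circumradius exceeds $\alpha$ are dropped. Hull area is the total kept
area; the boundary is the set of edges used by exactly one kept triangle;
the perimeter is its length. In the dense-sampling regime the pipeline
operates in, the segment-bounded alpha-shape and the arc-bounded alpha-hull
agree in area and perimeter to within the sampling resolution. Degenerate,
near-collinear triangles are treated as having infinite circumradius and
dropped unless $\alpha = \infty$ is requested.

**Choosing alpha.** The default is $\alpha = 0.2\times$ the bounding-box
diagonal (`select_alpha()`), always overridable. Two failure modes bound
the sensible range. If $\alpha$ is smaller than the maximal *inscribed*
radius of the blade, interior triangles of the Delaunay mesh — whose empty
circumcircles approximate medial balls — get dropped and the hull erodes or
tears. If $\alpha$ is too large, the hull approaches the convex hull,
over-bridging the petiole-blade notches and re-introducing exactly the
global-shape sensitivity the normalization removes. For leaf-like aspect
ratios, 20% of the diagonal sits comfortably between the two: above the
half-width of the blade, below the notch scale of the petiole. A
consequence worth knowing: for a *circular* contour every triangle of
cocircular vertices has circumradius equal to the circle's radius, so the
default alpha (≈ 0.57 r) keeps nothing and `alpha_shape()` raises an
"alpha below feature scale" error; pass an explicit larger alpha for
near-circular shapes.

Because no published alpha or sampling density exists for the original DI
analyses, absolute DI magnitudes are tied to these defaults; orderings,
ratios and trajectories of DI are the reproducible signal, and all
comparative outputs in the package are built from those.

## Contours, curvature, and the raster bridge

All shape statistics consume a single currency: a closed, simple,
counter-clockwise polyline in micrometres (`as_leaf_contour()` enforces
orientation via the shoelace sign). Binary silhouettes enter through
`extract_contour()`, which traces the iso-level 0.5 between foreground and
background pixel centres (marching squares on the binary image) rather
than pixel edges — halving the perimeter-overestimation bias of staircase
boundaries — fills interior holes first, and applies a light Gaussian
smoothing of 0.5 px of arclength to suppress the residual zigzag between
iso-crossings. With the default settings, a rasterized leaf at a pixel
size of blade_length/200 round-trips to within 2% in both area and
perimeter; rasterization itself (`rasterize_contour()`) marks a pixel
foreground when its centre lies inside the polygon.

Signed curvature is computed on uniformly resampled contours as the
arclength derivative of the periodically smoothed tangent angle (positive
on convex arcs of a counter-clockwise contour). The winding ramp is removed
before smoothing and restored after, so the discrete curvature integrates
to exactly one turn. The tangent-angle route is used instead of three-point
circumcircles because it degrades gracefully on residual raster noise; the
smoothing scale is a parameter, default perimeter/200 for general use and
perimeter/400 inside tooth detection, where landmark positions shift with
the smoothing scale and tooth supports are narrow.

## Margin landmarks

The **base** is the petiole–lamina junction. The contour is oriented by its
principal axis; a petiole is declared when one end shows an *extended*
terminal run of cross-sections narrower than 25% of the maximal width (a
tapering blade tip is narrow too, but only briefly). The junction is then
localized by fitting the half-width profile around the run's blade-side end
with a hinge model — constant petiole width plus a one-sided quadratic
flare — whose hinge position is the neck. The fit pools hundreds of margin
vertices, which matters: a realistically decurrent leaf base has a neck
depth of only a few percent of the width, smaller than plausible boundary
noise, so any pointwise minimum (of width or of curvature) wanders; the
fitted hinge stays put to about 1% of blade length. The base landmark is
the midpoint of the two margin points flanking the neck. Without a petiole
the base is the extreme vertex at the low end of the principal axis; a
near-circular contour (principal-axis eigenvalue ratio > 0.9) is rejected
as unorientable. The **apex** is the margin vertex farthest along the axis,
and **blade length** — the base-to-apex Euclidean distance — is the
developmental-stage proxy used on every trajectory axis.

**Teeth** are local maxima of signed curvature on each margin side between
base and apex, excluding the leaf apex itself and the petiole margin; each
apex's flanking **sinuses** are the nearest curvature minima on either
side, and **tooth height** is the perpendicular distance from the apex to
the chord through its two sinuses. Two filters discard spurious candidates:
curvature prominence below `min_prominence` (default 5× the median absolute
curvature — noise bumps are prominent only at the noise scale) and height
below `min_height` (default 1% of blade length). Both thresholds are
deliberate free parameters; nothing in the source analyses pins them.
Candidate positions found on the smoothed profile are refined on a
minimally smoothed one (σ = 3 vertex spacings), because smoothing biases
extremum positions inward by roughly its σ, which otherwise depresses
measured heights by ~5%. Teeth are ranked from the base on each side; the
"first tooth" reported by `measure_cohort()` is the most basal one (the
choice between most-basal and first-formed is exposed by the rank column).

## Trajectories, tests, and mean silhouettes

`loess_fit()` implements tricube-weighted local polynomial regression
directly: at each grid point the span-fraction nearest neighbours are
weighted by $(1-(d/h)^3)^3$ and a degree-1 (default) or degree-2 polynomial
is fitted and evaluated there. Defaults follow common local-regression
convention (span 0.75, degree 1). Implementing the fit directly — rather
than delegating to `stats::loess`, which serves as an independent
cross-check in the test suite — buys two contract details: grid points
whose window holds fewer than degree+1 usable points are flagged missing
instead of extrapolated, and every grid point reports its local support
count, which downstream comparisons use to restrict "curve A below curve
B" claims to well-supported regions.

`bin_and_test()` assigns measurements to half-open blade-length classes
(default 200–400, 400–600, 600–800 µm — the early window where reporter
trajectories are compared) and runs an equal-variance Student's t-test per
class; Welch is available behind `var_equal = FALSE`. Classes with fewer
than two points in either genotype are reported untestable rather than
dropped. No multiple-testing correction is applied across the three
classes by default, mirroring per-class significance marks; a `p_adjust`
argument exists and is off (`"none"`).

`mean_silhouette()` averages contours vertex-by-vertex after resampling
each to `n_points` starting exactly at the foot of its base landmark and
rigidly aligning base to the origin and the base–apex axis to +y. The
alignment never rescales: genotype size differences are biological signal
in mean-shape overlays. Starting the resampling at the projected base point
(not the nearest vertex) makes the construction exactly equivariant under
mirror images, so the mean of a leaf and its reflection is bilaterally
symmetric to floating-point accuracy.

## Reporter-fluorescence quantification

The zone procedure is seeded and otherwise automatic. `local_background()`
takes the median intensity in an annulus centred on the seed (defaults 1.5×
and 3× the expected zone radius) and a robust spread, 1.4826 × MAD — the
median tolerates a minority of signal- or saturation-contaminated annulus
pixels. `segment_zone()` thresholds at background + k·spread (k = 3 by
default) and keeps the 8-connected component containing the seed; if the
seed pixel itself is below threshold the zone is empty by contract. The
`quantify_zone()` wrapper additionally snaps the flood seed to the
brightest pixel within a 2 px click radius, the usual affordance of
semi-automatic tools, so that clicking a noise dip inside a real zone does
not return an empty mask. `accumulated_intensity()` sums
background-subtracted intensities over the zone, clipping negatives at
zero (zone pixels are above threshold by construction; clipping only
guards numerical edge cases). Background subtraction before accumulation is
the default reading; `raw_sum = TRUE` provides the alternative. The
procedure is deterministic: identical image, seed and parameters give
bit-identical masks, and accumulated intensity responds linearly to true
zone amplitude (R² > 0.99 in the acceptance sweep) — the property that
makes genotype comparisons of accumulated signal meaningful.

`detect_nuclei()` band-passes the image with a difference of Gaussians at
σ and 2σ, takes local maxima above a robust threshold (with a floor of 2%
of the dynamic range, so numerically flat regions spawn nothing), enforces
a minimal separation greedily by response, and measures each detection as
the mean raw intensity in a disk of radius 2σ. `top_k_mean()` then averages
the k = 12 most intense nuclei, flagging (not failing) when fewer than k
are available. The caller supplies the 2-D plane; no z-handling is
attempted.

## The synthetic-data generator

Every stage above is validated against `generate_leaf()` /
`generate_cohort()` / `generate_fluor_image()`, which export exact ground
truth alongside each object.

**What it emulates.** An ovate blade (half-width profile
$\propto u^{2.2}(1-u)^{3}$, widest at ~40% of the blade, acuminate tip)
tapering decurrently into a straight petiole with a rounded tip; defaults:
blade width 0.42 L, petiole 0.28 L long and 0.09 L wide for blade length L.
Teeth are raised-cosine bumps displaced along the outward normal of the
smooth margin, centred on equal slots of the 0.25–0.80 arclength band of
each side; tooth height is `tooth_height_frac` (default 0.22) of the local
half-width, so distal teeth are genuinely smaller — as in real leaves — and
sit near the 1%-of-blade-length detectability floor. Boundary noise is a
smooth, band-limited normal displacement (Fourier modes 3–15 of arclength,
never i.i.d. vertex jitter), attenuated where the local half-width
approaches the noise amplitude so the two margins can never be pushed
across each other at the tip. Cohorts draw blade lengths uniformly and
scale all linear dimensions isometrically; `genotype_tooth_scale`
multiplies tooth height to emulate a serration-deficient genotype at every
stage. Fluorescence images are a smooth background (flat, gradient, or
broad Gaussian) plus a hard-edged disk zone and truncated-Gaussian nuclei,
with optional additive Gaussian noise.

**Truth definitions are measurement definitions.** The true tooth apex is
the displaced bump centre; the true flanking sinuses are the bump's
*support edges* on the undisplaced outline — the points where the
displacement vanishes and the margin curvature genuinely attains its
minima — and the true height is the apex-to-sinus-chord distance. Defining
the sinus at the support edge (rather than, say, midway between adjacent
supports) keeps truth and measurement like-for-like: with a mid-gap
definition the two chords differ by the base-outline sagitta and the
comparison inherits a systematic 15–30% offset that has nothing to do with
detection quality. The proportions themselves were fixed once, jointly
satisfying realism and well-posedness: the decurrent base keeps margin
concavities mild, and the blade half-width stays below the default alpha so
the smooth-blade alpha-shape neither erodes nor tears (a convex leaf's DI
is 1.009 under the defaults).

**What it does not emulate.** No venation, no lamina texture, no hierarchy
of secondary teeth, no allometric shape change with size (growth is
isometric), no optical blur or detector artefacts in the fluorescence
images, and no 3-D structure anywhere. Passing recovery tests therefore
demonstrates the correctness and calibration of the measurement chain on
margin-type signals — not robustness to segmentation errors, overlapping
organs, or imaging pathologies of real micrographs.

## Numerical choices and degenerate inputs

- Contours reject fewer than 3 vertices, NA coordinates, and zero shoelace
  area; generated outlines are checked for self-intersection by exact
  segment tests and rejected with a diagnostic naming the offending
  parameters.
- The Delaunay stage applies a deterministic, index-hashed jitter of
  1e-10 × the point-set diagonal before triangulating (cocircular inputs,
  e.g. regular polygons, would otherwise break the incremental
  construction); all downstream geometry — circumradii, areas, boundary
  lengths — is computed from the *original* coordinates, so the jitter
  never reaches reported numbers. Insertion order is a deterministic
  shuffle (sequential boundary points create degenerate insertion
  cavities).
- Equality-sensitive steps (uniform-spacing check before curvature, the
  1%-tolerance) trust the resampler's certificate rather than re-deriving
  it from chord lengths, which corner-cutting would spuriously fail.
- Ties: the leaf apex is excluded from tooth candidacy within 2% of the
  perimeter; nucleus suppression is greedy by band-pass response;
  `top_k_mean` sorts descending and averages exactly `min(k, n)` values.

## Problem sizes

The test suite and the acceptance script run on cohorts of 50 leaves per
genotype (blade lengths 210–790 µm, 0.4% boundary noise), 100-leaf landmark
recovery panels (300–3000 µm, 0.5% noise), 2000-replicate permutation
calibrations, and 120–160 px fluorescence images — sizes chosen so the
whole suite completes in a few minutes on one core while keeping every
class of the blade-length analysis populated with ~16 leaves, comparable to
real per-class sample sizes.

## Known limitations

- Absolute DI values depend on the alpha default and contour sampling;
  only comparisons share-calibrated within one analysis are meaningful.
- The base landmark on strongly decurrent, noisy leaves is localized to
  ~1% of blade length on average but can err by ~4% in the tail; blade
  length inherits this.
- The alpha-shape needs `alpha` above the blade's inscribed radius;
  near-circular contours need an explicit alpha and cannot be oriented for
  landmark analysis at all.
- The permutation calibration of the class tests assumes exchangeability
  within a blade-length class; strong within-class developmental trends
  would violate it (the generator's DI is stage-stable by construction,
  real data may not be).
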