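---
title: "Shape-adjusted ellipse morphometry: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-adjusted ellipse morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saemorph)
```

## The tilt problem

Morphometry of nerve fibers in transverse sections usually treats each
fiber as a circle: the diameter is derived from the measured
cross-sectional area ($d = 2\sqrt{A/\pi}$), from the perimeter
($d = p/\pi$), or taken as the minimum Feret (caliper) diameter. But
individual fibers are not parallel to the bundle axis. Modeling a fiber as
a cylinder of base radius $r$, a section cut at dispersion (tilt) angle
$\theta$ is an ellipse with semi-minor radius $r$ and semi-major radius
$R = r/\cos\theta$. Its area is inflated by
$\rho = A_e/A_c = 1/\cos\theta$ relative to the base circle
$A_c = \pi r^2$ — a strictly increasing, strictly convex function of
$\theta$ (at $45^\circ$ the area is already $\sqrt2$ times too large, at
$60^\circ$ twice). Circle-based diameters therefore overestimate fiber
size, increasingly so at high tilt. The one quantity oblique sectioning
does *not* change is the minor axis of the ellipse: it equals the base
diameter $2r$ at every tilt.

## The shape-adjusted ellipse (SAE) solve

A pair (area, perimeter) determines an ellipse uniquely. The package
therefore inverts the measured pair to the matching ellipse and reports
its minor diameter as the tilt-corrected fiber diameter.

The ellipse perimeter is the Gauss–Kummer series
$$p = \pi (r + R) \sum_{n\ge0} \binom{0.5}{n}^2 h^n, \qquad
  h = \frac{(R - r)^2}{(R + r)^2},$$
implemented in `ellipse_perimeter_series()` (non-decreasing in the number
of terms, converging to the complete-elliptic-integral value provided by
`ellipse_perimeter_exact()`). Substituting $R = A_e/(\pi r)$ and keeping
four terms gives the fixed-area forward map used for inversion
(`sae_perimeter()`):
$$p(r; A_e) = \pi\Big(\frac{A_e}{\pi r} + r\Big)
  \Big(1 + \frac{h}{4} + \frac{h^2}{64} + \frac{h^3}{256}\Big), \qquad
  h = \Big(\frac{A_e - \pi r^2}{A_e + \pi r^2}\Big)^{\!2}.$$
Note the square on $h$: with $R = A_e/(\pi r)$ the series variable is
$\big((R-r)/(R+r)\big)^2 = \big((A_e - \pi r^2)/(A_e + \pi r^2)\big)^2$,
and the forward/inverse consistency tests in the suite pin this form down
(the unsquared ratio is not consistent with the series and can be
negative). The four-term truncation errs by only $\sim 3\times10^{-5}$
relative even at $\theta = 75^\circ$; the solver's round-trip diameter
error on exact inputs stays below 0.01%.

### Newton details

`solve_sae()` solves $p(r; A_e) = p_{meas}$ for $r$:

* initialisation at $r_0 = \sqrt{A_e/\pi}$, the circle-equivalent radius.
  $r_0$ is an upper bound for the root, and $p(r; A_e)$ is strictly
  decreasing on $(0, r_0]$, so the root is unique;
* relative tolerance $10^{-10}$ on $r$, at most 100 iterations (typical
  convergence: 3–8 iterations);
* a bracket is maintained as a safeguard, and any Newton step leaving
  $(0, r_0]$ is replaced by bisection of the bracket;
* degenerate inputs: a measured perimeter below the isoperimetric bound
  $2\sqrt{\pi A_e}$ cannot arise from any ellipse. Such records — typically
  smoothing artifacts of upstream segmenters — are clamped to the
  circle-equivalent diameter with tilt 0 and flagged `feasible = FALSE`
  rather than rejected, so they remain visible and countable downstream.

The recovered ellipse also yields the tilt estimate
$\theta = \arccos(r/R)$ and $\rho = R/r$; this inversion follows from the
cylinder model above. Angles are degrees at every interface (radians only
internally).

## Contour measurement

`measure_contour()` works on raw polygon vertices in µm: shoelace area
(absolute value — vertex orientation is never assumed), summed edge
lengths for the perimeter, the area-weighted polygon centroid, and Feret
diameters by rotating calipers over the convex hull (`feret_diameters()`),
which is exact for polygons — the minimum width is always attained
perpendicular to a hull edge, the maximum distance between hull vertices.
No smoothing is applied or exposed: the package measures what the
segmenter produced, and the perimeter sensitivity this implies is
quantified below. Pixel-space contours must be rescaled explicitly
(`scale_contour()`, `--um-per-pixel`); the package refuses to guess a
magnification.

## Shape descriptors

`shape_metrics()` implements five standard circularity descriptors:
shape factor $p/\sqrt A$, form factor $4\pi A/p^2$, aspect ratio
$F_{min}/F_{max}$, compactness $\sqrt{4A/\pi}/F_{max}$, and roundness
$4A/(\pi F_{max}^2)$. For an ideal circle the shape factor is
$2\sqrt\pi \approx 3.54$ and the other four equal 1; for exact ellipse
measurements, roundness $=$ compactness$^2$ $=$ aspect ratio — identities
the suite asserts. Descriptors needing Feret values are reported `NA` when
those are missing, never imputed, so the module also serves tabulated
upstream data without vertices.

## Axon–fiber pairing

Segmentation tools label inner (axon) and outer (fiber) contours but do
not link them. `pair_and_score()` builds the Euclidean centroid distance
matrix (`distance_matrix()`) and solves the rectangular assignment problem
with a Jonker–Volgenant shortest-augmenting-path implementation of the
Hungarian method (`optimal_assignment()`), exact against a brute-force
permutation oracle in the tests. Design choices:

* **Ties.** Among equal-cost optima the lexicographically smallest
  (row, column) sequence is selected by a refinement pass, applied up to
  64 rows; beyond that the solver's deterministic scan order decides.
  Exact cost ties have measure zero for continuous centroids — the
  refinement exists so that degenerate, hand-built inputs are
  deterministic too.
* **Unequal counts.** The matching covers the smaller side; uncovered ids
  are returned in the `unmatched` attribute, never silently dropped.
* **Sanity filter.** A correctly paired axon centroid lies inside its
  fiber, so the default drop threshold on centroid distance is the fiber's
  own SAE radius; an optional point-in-polygon containment check is off by
  default (it needs the fiber polygons). Dropped pairs are logged with
  reasons.
* Retained pairs with `g_ratio >= 1` are flagged `valid = FALSE` and kept,
  making any later exclusion explicit and reversible.

Per pair, the G-ratio is axon diameter / fiber diameter and myelin
thickness is (fiber − axon)/2, both from SAE diameters.

## The synthetic generator

`sample_population()` draws ground-truth fibers from a
`population_spec()`: a normal mixture of base diameters, a tilt
distribution, a diameter-dependent G-ratio model, and a boundary-noise
amplitude; `render_ellipse_contour()` renders each section. The defaults
describe a ventral-root-like population:

* size components at 2.5 µm (sd 0.4, weight 0.30), 4.5 µm (sd 0.8, 0.35)
  and 11 µm (sd 1.8, 0.35) — the small preganglionic autonomic, γ-motor
  and α-motor classes; the two motor peaks give the characteristic bimodal
  distribution, the autonomic component the additional small-fiber peak.
  The exact means are free parameters of the generator, chosen as
  plausible centres of the conventional 0–4 / >4–10 / >10 µm bands;
* tilt uniform on [0°, 45°] by default (validation experiments below use
  [0°, 60°] to stress the correction harder);
* mean G-ratio $0.55 + 0.01\,d$ (per µm), sd 0.04, clipped to
  (0.05, 0.95) — a weak positive correlation of G-ratio with fiber size;
* boundary noise: each vertex radius multiplied by $1 + \epsilon u$,
  $u \sim U(-1,1)$, default $\epsilon = 2\%$. Multiplicative radial noise
  preserves star-convexity, so polygons stay simple at any amplitude
  below 1;
* 100 vertices per contour, a realistic polygon density for segmented
  fibers after the vertex reduction tracing tools apply (precision
  experiments in the tests use exact 3600-vertex polygons instead).

The inner contour is the outer polygon scaled by the drawn G-ratio about
the shared centre, so the SAE-diameter ratio recovers the drawn G-ratio
essentially exactly; pairing accuracy, not diameter recovery, is what the
concentric-bundle experiments test. What the generator does **not**
emulate: non-elliptical (crenated, infolded) myelin profiles, spatially
correlated boundary error, pixel-grid rasterisation, touching or
overlapping fibers, and Remak bundles. Passing tests therefore demonstrate
correctness of the geometry and of the inverse solve under the stated
noise model — not robustness to every artifact of real micrographs.

## Noise sensitivity and the validation design

The SAE solve consumes the perimeter, and a raw polygon perimeter is the
quantity most inflated by uncorrelated vertex noise: at 2% amplitude on
100-vertex contours the measured perimeter exceeds the true ellipse
perimeter by a few percent, which the inverse solve can only explain as
extra eccentricity, biasing the recovered minor diameter low (about −14%
at the median under tilts uniform on [0°, 60°]). The bias grows with
vertex density at fixed amplitude — adjacent-vertex jitter adds length in
proportion to its ratio to the edge length. This is a genuine property of
the method and the reason upstream pipelines smooth contours before
measuring perimeters.

The population validation is therefore split into two runs of the same
bimodal spec (3 and 10 µm, sd 0.5 and 1.0, tilt uniform on [0°, 60°],
n = 2000, one seed):

* a **calibration** run with exact contours, which must place both kernel
  density modes of the SAE diameters within 5% of the true component
  means (observed: within ~1%);
* a **robustness** run at 2% boundary noise, on which the traditional
  methods must show their characteristic right shift — median
  overestimation above 5% for the area-circle and above 10% for the
  perimeter-circle diameter, with the minimum-Feret median between the
  SAE and area-circle medians, and the full ordering
  SAE < min-Feret < area-circle < perimeter-circle.

Geometry alone bounds what the noiseless run can show: under tilts uniform
on [0°, 60°] the median tilt is 30°, where the perimeter-circle excess is
only 7.9%, so the >10% right shift is a joint effect of tilt and boundary
roughness — which is exactly the regime segmented micrographs live in.

Problem sizes throughout (2000-fiber populations, 40-fiber bundles,
200 random assignment matrices up to 7×7, 3600-vertex precision polygons)
were chosen so each experiment estimates its quantity stably; the full
suite runs in about a minute.

## Units, formats, conventions

Canonical unit: µm (areas µm²). Measurement tables are comma-separated
UTF-8 with `.` decimals; common upstream column spellings (`Perim.`,
`MinFeret`, `Feret`, `XM`, `YM`, ...) are mapped through an extensible
alias dictionary. Contours are JSON-lines records with explicit vertex
arrays — human-inspectable and streaming-friendly. Coordinates follow the
image convention (y down), which no computed quantity depends on. Every
CLI run writes its resolved configuration next to its output, so results
are reproducible from inputs, config and seed alone.

## Known limitations

* The correction assumes an elliptical section of a circular cylinder;
  genuinely non-circular fibers (crenation, compression) violate this, and
  the shape descriptors exist to quantify how far a profile departs from
  the model.
* Raw-polygon perimeters make the solve sensitive to high-frequency
  boundary noise (see above); heavily rasterised or unsmoothed dense
  contours should be simplified before measurement.
* Sub-isoperimetric records are clamped, not corrected; a large
  `n_infeasible` from `compare_methods()` signals an upstream smoothing
  problem.
* Pairing assumes one axon per sheath; Remak-style multi-axon bundles are
  out of scope.
* No inferential statistics are run; the tabular outputs are designed to
  feed any statistics tool.
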