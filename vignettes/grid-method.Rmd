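---
title: "Equal-area grid grading of retinal perfusion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equal-area grid grading of retinal perfusion: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridfa)
```

## The problem

Retinal hypoperfusion on ultra-widefield fluorescein angiography (UWF FA) is
a key risk factor for progression of diabetic retinopathy, but quantifying it
is notoriously subjective: the common "ischemic index" asks a grader to
outline nonperfused retina freehand, which depends on the grader's memory of
what healthy retina looks like. The grid approach implemented here replaces
freehand outlining with a standardized, cell-by-cell ordinal judgment: the
angiogram is registered to a fixed grid, every grid cell is presented next to
the corresponding cell of a healthy-control image, and the grader assigns
each cell one of six perfusion bands (or marks it ungradable). Because every
cell covers the same retinal area, cell counts and score averages translate
directly into area fractions, and the spatial address of every judgment is
preserved.

`gridfa` implements this pipeline end to end — grid geometry, landmark
normalization, grading data model, agreement statistics — plus a synthetic
phantom generator so the whole pipeline can be validated without patient
data.

## The equal-area concentric grid

The grid is a disc partition: one central circular cell of radius $r_0$
surrounded by $n$ annular rings of radial width $2 r_0$, ring $j$ being split
into $8j$ equal sectors. Every cell then has area exactly $\pi r_0^2$:

$$\frac{\pi\left[(2j+1)^2 - (2j-1)^2\right] r_0^2}{8j} = \pi r_0^2 .$$

With the default $n = 8$ this yields $1 + 4n(n+1) = 289$ cells and a grid
radius of $17 r_0$. The $8j$ sector count is the unique per-ring subdivision
of equal-width rings that reproduces both published region sizes at once:
289 cells overall and 121 cells (central cell plus rings 1–5) in the central
region used as an ETDRS seven-standard-fields equivalent. Rings 6–8 (168
cells) form the peripheral region.

Conventions that the geometry needs but that no published description pins
down, fixed here once:

* **Half-open cell bounds** $[r_\text{in}, r_\text{out}) \times
  [\theta_0, \theta_1)$, so every point belongs to at most one cell and the
  cells tile the open disc — the partition property is testable.
* **Angular origin** at the fovea-to-disc direction, sectors counted
  counterclockwise (with image y negated, so "counterclockwise" matches the
  displayed image).
* **Grid units**: $r_0 = 1$ internally; physical units attach only through
  the landmark transform and millimetre calibration, keeping the geometry
  exact.

## Landmark normalization

Each image is standardized by two user-supplied landmarks, the fovea and the
optic-disc center. The similarity transform (translation, rotation,
isotropic scale — never a reflection) sends the fovea to the grid origin and
rotates the disc onto the positive horizontal axis at $0.095 \cdot D$ grid
units from the origin, where $D$ is the grid diameter — i.e. the fovea–disc
distance spans 9.5% of the grid diameter. Assuming a fixed anatomical
fovea–disc distance of 4.76 mm (population SD 0.34 mm), every cell covers
the same retinal area in every eye, about
$\pi (4.76 / 0.095 / 2)^2 / 289 \approx 6.8\ \text{mm}^2$, and the grid
spans $4.76 / 0.095 \approx 50.1$ mm.

Left-eye images are *not* mirrored; laterality is carried as metadata. This
means sector-level topographies of OD and OS eyes are not directly
superimposable — a deliberate choice, since silent mirroring would change
sector identities.

Two numerical rules matter downstream:

* **Quantitative statistics never use resampled pixels.** Cell membership is
  computed by mapping pixel centers *into* grid coordinates
  (`grid_label_raster()`); the image-warping function (bilinear, or nearest
  for label images) exists for display only. This avoids interpolation bias
  in per-cell means.
* Pixel coordinates are (x right, y down) with centers on integers; the
  transform negates y so grid angles are mathematically conventional.

## Grades, scores, and regions

The six gradable bands carry fixed scores
$\{1, 0.875, 0.625, 0.375, 0.125, 0\}$ (fully perfused, 76–99%, 51–75%,
26–50%, 1–25%, nonperfused) and collapse into three ordinal categories:
perfused (score 1), hypoperfused (51–99%), nonperfused (0–50%). A cell with
no visible vessel or an image artifact is UNGRADABLE: it appears in category
counts but never in score averages. Region perfusion is the mean score of
gradable cells, reported as percent hypoperfusion
$100\,(1 - \text{mean score})$; an all-ungradable region yields a flagged
undefined value rather than a silent zero. Because published study-level
summaries are ambiguous about pooling, per-image summaries are the primitive
here and any pooled value is computed explicitly by the caller.

Per-image graded-cell domains are session-defined (via `excluded` cells)
rather than hard-coded: reported studies grade fewer than 289 cells per
image (e.g. off-image cells), and the exclusion rule belongs to the session
metadata, not the geometry.

## Agreement statistics

The inter-rater protocol follows standard practice for ordinal grading:

* **Descriptives** — mean, SD, and Tukey's five-number summary (hinges are
  medians of halves including the overall median; `stats::fivenum`).
* **Bland–Altman** — differences are grader 1 − grader 2 (so a grader-2
  excess of nonperfusion appears as negative bias); limits of agreement are
  bias ± 1.96 SD.
* **Kendall's tau-b** on per-image percent nonperfusion. The tie-corrected
  variant is essential: healthy eyes produce many exact zeros.
* **Cohen's kappa** on the cell-level category cross-tabulation, in the
  disagreement-weight form $\kappa_w = 1 - \sum w_{ij} p_{ij} / \sum w_{ij}
  p_{i\cdot} p_{\cdot j}$. The default is **linear weights over the three
  ordinal categories, restricted to cells gradable by both graders**; a
  four-category variant including UNGRADABLE is available (conventionally
  unweighted, since "ungradable" is not on the ordinal scale). Linear is the
  conventional default for a three-level ordinal scale; quadratic is a
  config option. Degenerate tables (a single nonempty category) raise typed
  errors instead of returning NaN — silent NaNs would corrupt bootstrap
  distributions.
* **Image-level bootstrap** — confidence intervals resample *images* with
  replacement (all cells of an image move together), percentile method,
  default B = 2000, seed mandatory. Cells within an image are strongly
  dependent, so cell-level resampling would be anticonservative.

## The synthetic phantom and simulated graders

The phantom emulates what matters for validating the pipeline, not
photorealism: a bright branching vessel tree rooted at the disc on a dark
noisy background, circular nonperfusion blobs (placed in grid units) that
erase vessels and darken the background, peripheral lash-like occlusion
wedges, and landmark jitter. Ground truth per cell is the fraction of cell
area outside all blobs, integrated by stratified area-uniform sampling
(16×16 points per cell; the tests cross-check against 64×64). Every output
is a pure function of (spec, seed).

A simulated grader perceives $\text{clamp}(\text{truth} +
\mathcal N(0, \sigma), 0, 1)$, bands the latent value, shifts the band by an
integer bias, and marks cells ungradable with a configurable probability
wherever an artifact overlaps the cell or no vessel crosses it — the two
triggers of the ungradable rule. Truth-to-band boundaries are half-open
upward on the percent labels ($\{1\}$, $[0.76, 1)$, $[0.51, 0.76)$,
$[0.26, 0.51)$, $(0, 0.26)$, $\{\le 0\}$): the printed bands are integer
percentages, so a convention is required for continuous truth, and this one
makes the zero-noise grader reproduce banded truth exactly.

What the phantom does **not** model: fluorescein transit dynamics,
peripheral projection distortion (deliberately, matching the method's stated
limitation), vessel-scale texture, or correlated grader behavior beyond
bias/noise/ungradable propensity. Passing tests therefore validate the
geometry, bookkeeping and statistics — not clinical grading performance on
real angiograms.

Default phantom conditions: 768² images with the fovea–disc distance at 9%
of the image side (so the full 50-mm-equivalent grid fits the frame), 6
vessel branches per quadrant, 3 blobs of 1.5–3 grid-unit radius, 2
peripheral wedges, 2 px landmark jitter — values chosen once as a plausible
miniature of a UWF FA scene. Tests use smaller sizes of the same model.

## Marginal-matched paired datasets

`marginal_matched_dataset()` builds a paired categorical dataset with exact
per-grader category counts, filling the joint table diagonal-first
(agreement-maximal subject to the marginals). Between-grader count
differences depend only on the marginals; the survivor count after dropping
cells either grader called ungradable additionally depends on the
ungradable *overlap*, which is therefore an explicit argument rather than a
greedy choice.

`reference_marginals()` ships the category counts of the published
two-grader UWF FA inter-rater study (50 images; 11,900 cells entire retina,
4,900 central, 7,000 peripheral). The study prints whole-percent tables
*plus* exact count differences and exact survivor counts; the rounded
percentages alone are mutually inconsistent with the survivor counts (they
would require more both-ungradable cells than one grader has in total). The
shipped counts are the unique integer reconciliation consistent with every
printed count difference and every survivor count, which forces one
grader's ungradable set to nest inside the other's and assigns the small
rounding remainders (38 cells entire, 17 central, per grader) to the
perfused category; entire- and central-region counts still round to the
printed percentages. Peripheral counts are the entire-minus-central
difference, where two of the six derived percentages land one point off the
printed peripheral column — the published peripheral column is itself not
the rounded difference of the other two.

```{r reference}
rm_ <- reference_marginals()
ds <- marginal_matched_dataset(rm_$ENTIRE$grader1, rm_$ENTIRE$grader2,
                               rm_$ENTIRE$both_ungradable, seed = 1)
tab <- tabulate_categories(ds)
tab$diff          # grader 2 minus grader 1, per category
sum(ds$category1 != "ungradable" & ds$category2 != "ungradable")
```

## Validation strategy and problem sizes

The test suite checks each layer against an independent oracle: closed-form
cell counts against brute-force enumeration; analytic cell areas against
pixel counts of a 4000² rasterization (unit tests use 900²); the landmark
postcondition over 1000 random landmark pairs at $10^{-9}$ relative
tolerance; weighted kappa against a literal two-loop implementation on 500
random tables at $10^{-12}$; tau-b against $O(n^2)$ pair counting (and
`stats::cor`) exactly; Bland–Altman against its closed form. Bootstrap
coverage is estimated with 200 replications of a 50-image, noise-0.15
two-grader study (B = 300 per interval) against a simulation truth computed
by brute force on ~10⁶ cells, accepting coverage within 91–99%. Monotone
degradation of kappa/tau with grader noise is averaged over 50 seeds of
6-image studies on a noise grid up to 0.6. These sizes keep the full suite
under a couple of minutes on one CPU while leaving the Monte-Carlo margins
comfortably wider than the observed noise.

## Known limitations

* No correction of peripheral projection distortion: peripheral cells cover
  equal *image* area after normalization, not equal anatomical area at high
  eccentricity.
* No automatic landmark detection and no automated ungradable detection —
  both are grader inputs by design.
* OD/OS sector topographies are not comparable without an explicit mirroring
  step, which this package intentionally does not apply.
* The phantom validates bookkeeping and statistics, not human grading
  behavior; agreement values measured on phantoms say nothing about
  agreement on clinical images.
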