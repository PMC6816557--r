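---
title: "A two-layer nematic flocking model of fibroblast-driven matrix patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer nematic flocking model of fibroblast-driven matrix patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrixflock)
```

## The model

`matrixflock` simulates how migrating fibroblasts build, remodel and are in
turn guided by the extracellular matrix (ECM). It couples two layers:

* **Cells.** Each of the $n$ cells is a self-propelled agent with heading
  $\theta_i(t) \in [0, 2\pi)$, a constant speed $s_i$ drawn once from a
  truncated Gaussian, and a four-bead body (head $r$, two body beads $2r$,
  tail $r$, tangent along the axis) giving the 3:1 elongated fibroblast
  morphology. The bead radius is set from the projected cell area (default
  500 µm², so $r \approx 4$ µm and 800 cells cover about 40% of a 1 mm²
  domain).
* **Matrix.** A lattice of grid points, each holding fiber counts in
  `n_bins` (default 8) apolar orientation bins of width $\pi/8$ over
  $[0, \pi)$. Every step the grid point under a cell's head receives
  `deposition_rate` fibers in the bin of the cell's heading, loses
  `degradation_rate` fibers from every bin (floored at zero), and has up to
  `rearrangement_rate` fibers pulled from each of the two cyclic neighbour
  bins into the heading bin (conserving the total).

The heading update combines three unit vectors with weights
$w_p = 1 - w_c - w_m$, $w_c$ and $w_m$:

* *Individual migratory noise*: $(\cos(\theta_i + \eta), \sin(\theta_i +
  \eta))$ with $\eta \sim \mathcal N(0, \mathrm{Var}(\eta))$ — a persistent
  random walk;
* *Cell-cell guidance*: the mean direction of all contacting cells'
  headings, each replaced by its **nematic representative** (the element of
  $\{\theta_j, \theta_j + \pi\}$ within a quarter turn of $\theta_i$), so an
  antiparallel neighbour reinforces rather than cancels alignment; contact
  means any bead of one cell lies within the summed radii of any bead of
  the other, and the weight does not grow with the number of contacts;
* *Matrix guidance*: a bin under the head is chosen by a Gillespie draw with
  probability proportional to its fiber count, and the cell flocks with the
  nematic representative of the bin's left bound.

Terms that are undefined — no contacts, or no fibers under the head — have
their weight set to zero; the remaining weights are renormalised by their
own sum, so the combination stays convex. The new heading is the angle of
the combined vector (`atan2`, wrapped to $[0, 2\pi)$); if the vector is
numerically zero the previous heading is kept. Positions then advance by
$s_i (\cos\theta_i, \sin\theta_i) \cdot v_e$, where $v_e = 0.25$ while the
head bead overlaps another cell within 75% of the combined radii (a proxy
for volume exclusion) and 1 otherwise. Each step executes (1) all heading
updates synchronously from the time-$t$ state, (2) the matrix updates using
the new headings, (3) the position updates.

With `density_feedback = TRUE` the matrix weight is scaled by the
piecewise-linear density response $f(d)$ with $f(5) = 0$ and $f(10) = 1$
([density_feedback_scale()]), where $d$ is the fiber count of the selected
bin: sparse, freshly deposited matrix exerts no guidance, established
matrix exerts the full $w_m$.

## Choices where the design was open

Several quantities are not fixed by the model statement; the package's
choices, all configurable through [sim_params()], are:

* **Time step** `dt = 15` min. The density way-points behind $f(d)$ (a mean
  selected-bin density of ≈5 after four days and ≈10 after seven at
  deposition rate 1) require grid points to accumulate tens, not hundreds,
  of head visits over a week; at 15 min (96 steps/day) a confluent run
  reaches exactly that regime, while minute-scale steps would bury the
  way-points two orders of magnitude deep.
* **Speed** `speed_mean = 10` µm/step (≈0.67 µm/min, a typical fibroblast
  crawl) with `speed_sd = 2`. One step moves a cell about one grid spacing
  (10 µm), so deposited head tracks are contiguous lines rather than dotted
  trails.
* **Noise values** quoted with figures (0, 0.07, 0.14, 0.21) are read as the
  per-step variance $\mathrm{Var}(\eta)$ in rad²; the persistence-calibrated
  value 0.13 falls inside that range, which is the consistency check behind
  the reading.
* **Boundary**: periodic by default (standard for flocking models; avoids
  edge artifacts), reflecting available.
* **Domain defaults**: 1×1 mm with a 100×100 fiber grid (10 µm spacing).
  Tissue presets ([tissue_preset()]) carry the published noise/guidance/
  feedback triples for dermis, liver, spleen and stomach with 200 cells
  (≈10% confluence); a twice-as-fine grid with halved speed is available via
  `fine_grid = TRUE` for higher-precision fiber placement.
* **Zero-vector tie-break**: if the weighted direction sum vanishes the cell
  keeps its previous heading.
* **Rearrangement rate** is interpreted per neighbour bin (up to `rate`
  fibers from each of the two neighbours), chosen for symmetry.
* **Matrix updates use the new heading** $\theta(t+1)$, since headings are
  computed before matrix updates in the step sequence.

## The five matrix metrics

[compute_metric_set()] reports, per matrix:

* **LRA / SRA** (long/short-range alignment): per fiber, the weighted median
  acute deviation ($\in [0, \pi/2]$) to every other fiber within 200 µm
  (LRA) or 20 µm (SRA); the matrix value is the weight-averaged per-fiber
  median $\bar D$, reported as the score $1 - \bar D / (\pi/2)$ so 1 means
  perfectly aligned and 0.5 is the analytic expectation for isotropic
  orientations (the median acute deviation of uniform apolar angles is
  $\pi/4$). For simulated grids each non-empty (grid point, bin) pair is one
  fiber bundle of weight equal to its count, and the computation runs
  directly on the lattice via disk-summed bin channels; the brute-force
  pairwise path used for point fields is kept as an independent cross-check
  and the two agree to machine precision in the tests. For images, fibers
  and orientations are estimated with a structure tensor
  ([field_from_image()]).
* **HDM**: the percentage of image pixels above a threshold.
* **Curv**: the image is blurred with a large Gaussian (σ = 8 px),
  thresholded, thinned to a one-pixel skeleton (Zhang–Suen) and traced;
  sampling every 10 px of arc length, the curvature is the mean absolute
  turning angle between consecutive chords, in degrees. On a circle of
  radius $R$ a chord of length $w$ turns by $2\arcsin(w/2R)$, the closed
  form the implementation is tested against.
* **Frac**: box-counting dimension of a small-Gaussian (σ = 2 px) mask,
  counting occupied boxes at dyadic sizes from the padded image size down to
  2 px and fitting $-\mathrm{slope}$ of $\log N$ vs $\log s$.

Simulated grids are rendered ([render_matrix()]) at 5 px per grid point as a
segment along the most recently selected (else densest) bin with intensity
$\min(d/25, 1)$ — a density at the cut-off 25 draws at full intensity. HDM
on rendered matrices uses the fixed threshold 0.4, i.e. the upper feedback
way-point (density 10) over the cut-off: a per-image Otsu threshold would
adapt away exactly the density contrast between corralled and diffuse
conditions that the metric is meant to expose. External grayscale images
default to Otsu for HDM and the masks.

[starplot_normalize()] min-max normalises each metric over a compared
collection (constant axes map to 0.5) for starplot display.

## What the synthetic patterns do and do not show

[generate_fixture()] builds deterministic grounds truths: aligned stripes
(alignment exactly 1, curvature ≈ 0), a seeded isotropic field (alignment
0.5 ± 0.03 by the Monte-Carlo argument above), swirls and orientation
checkerboards (short-range order without long-range order), a circle (the
chord formula), a Hilbert-curve raster (plane-filling, dimension → 2), and
blank/filled extremes. Passing these validates the metric implementations
on patterns with known answers; it does not validate them on second-harmonic
micrographs, whose noise, illumination gradients and out-of-plane structure
the fixtures deliberately do not emulate.

## In-silico experiments

* [persistence()] implements the directionality ratio: net displacement over
  a sliding window divided by the path length within it, median over
  windows, mean over cells ([mean_persistence()]). The printed-form
  variant that sums net displacements at every lag is kept behind
  `literal = TRUE` for comparison; it is not a path length, and the default
  is the standard ratio. Calibration tracks are first smoothed with a loess
  spline (span 0.5) to suppress intracellular jitter.
* [calibrate_noise()] and [calibrate_feedback()] recover
  $\mathrm{Var}(\eta)$ and $w_m$ by least squares against observed
  persistences at 1 h and 2 h windows, simulating candidate values with
  common random numbers; the tests validate them by parameter recovery on
  synthetic data (generating observations from known values with a
  different seed and recovering them to within one grid step).
* [run_sweep()] runs seeded replicates over a parameter grid and
  [pca_summary()] z-scores the five metrics and reports variance fractions.
  The sweep behind the variance-explained figures varies noise, cell-cell
  guidance and matrix feedback together: the full
  $4 \times 4 \times 4$ factorial of $\eta \in \{0, .07, .14, .21\}$,
  $w_c \in \{0, .03, .06, .1\}$, $w_m \in \{0, .04, .12, .2\}$ (all valid,
  $w_c + w_m \le 0.3$).
* [remodeling_experiment()] grows a phase-1 matrix (dermis preset by
  default), then re-seeds fresh zero-noise cells on the retained grid with
  altered feedback and remodeling rates and follows LRA over ten days,
  ending in a two-tailed Welch t-test between the remodeling-on and
  remodeling-off arms at $w_m = 0.2$ (deposition 10, degradation and
  rearrangement 5 vs 0, N = 25 per arm, each arm with independent phase-1
  matrices so the two-sample test is correctly specified).

## Problem sizes, tolerances and limitations

The acceptance suite and `scripts/acceptance.R` run at desk scale: sweeps
use 200 cells in a 0.25 mm² domain with a 50×50 grid — the same 40%
confluence as 800 cells in 1 mm² — over 7 simulated days with 3 replicates
per point; the sub-confluent sweep uses 50 cells in the full 1 mm² domain;
the remodeling experiment runs the dermis preset at its native 200-cell
scale. Fixture tolerances are stated with each fixture (alignment ± 0.03,
fractal dimension ± 0.1 for the Hilbert raster and ± 0.05 for analytic
masks, curvature within 10%).

Known limitations:

* At sub-confluence the five metrics co-vary along a single
  order/coverage axis (HDM is near zero in almost every run, and the 8-bin
  discrete median pins isotropic alignment scores at exactly 0.5), so the
  first two principal components capture ~95% of the variance there —
  more concentrated than for image-estimated metrics with continuous
  per-run scatter.
* The day-10 remodeling contrast is directionally robust but small
  (≈0.02–0.04 LRA), so its significance at N = 25 sits close to the 0.05
  boundary and varies with the random seed.
* No cell division or death, chemotaxis, matrix cross-linking, fiber
  mechanics, or third dimension; fibers do not diffuse between grid points.
* Bin boundaries use an $10^{-9}$ tolerance so exact multiples of
  $\pi/8$ land in the bin they open despite floating-point $\pi$
  arithmetic.

## A minimal session

```{r example, eval = FALSE}
p <- sim_params(n_cells = 200, domain_size = c(500, 500),
                grid_shape = c(50, 50), noise_variance = 0, w_c = 0.03,
                w_m = 0.2, duration = 7)
st <- run_simulation(p, seed = 1)
compute_metric_set(st)
write_gray_png(render_matrix(st$grid, st$last_selected), "matrix.png")
```
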