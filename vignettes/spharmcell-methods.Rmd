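---
title: "Static and dynamic SPHARM classification of migrating cell shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic SPHARM classification of migrating cell shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spharmcell)
```

## The problem

A migrating cell changes shape continuously. Two cell populations can look
identical in any single snapshot and still move in recognisably different
ways — for instance when every cell cycles through the same sequence of
shapes but different populations cycle at different speeds. Distinguishing
such populations requires *dynamic* shape descriptors that encode how the
shape evolves, not just what it looks like at one moment.

`spharmcell` implements a complete workflow for this question in 3D:

1. a lattice Monte-Carlo **cell-migration simulator** as a controllable
   synthetic data source,
2. **surface extraction** from voxel occupancies (or external OBJ/VRML97
   meshes) and projection onto a regular spherical grid,
3. a **spherical-harmonic (SPHARM) transform** with rotation-invariant
   power spectra, stacked over time into dynamic descriptors,
4. a **linear-SVM cross-validation harness** with naive-classifier
   controls and Mann-Whitney significance tests.

## The cell-migration simulator

A synthetic cell is a set of occupied integer lattice sites ("spatial
units", SU). At initialisation the cell is a lattice ball (default radius
6.2 lattice units, 1021 SU) and a migration direction $\vec v_D$ is drawn
uniformly on the unit sphere; it stays fixed. Every SU has a relative
position $P = \hat v_P \cdot \vec v_D \in [-1, 1]$, where $\vec v_P$
points from the cell's centre of mass to the SU. Sites with $P \le FR$
form the rear; free lattice sites adjacent to the cell with $P > FR$ are
front candidates.

Each iteration moves exactly one SU from the rear surface to a free front
site. Candidates are drawn by acceptance–rejection sampling on the scores

$$S_r = |P|^{PW}\,(6 - N)^{NW}\,D^{DW}, \qquad S_f = |P|^{PW}\,N^{NW},$$

with $N$ the number of occupied 6-neighbours and $D$ the distance to the
centre of mass. The four exponents have interpretable effects: `pw`
elongates the cell along the migration axis, `nw` smooths or roughens the
surface, `dw` controls protrusion size, and `fr` sets the volume fraction
treated as the front.

Choices the score formulas do not determine, fixed as package policy:

* **Sampling normalisation.** A uniform candidate is accepted with
  probability $S/\max(S)$ over the current candidate set; rear SU and
  front site are drawn independently. If every score is zero the draw
  degenerates to uniform.
* **Neighbourhood** is 6-connectivity, forced by the $(6-N)$ factor.
* **$D$ is raw Euclidean distance** in lattice units; normalising it
  would silently change the meaning of the `dw` exponent.
* **Connectivity is not enforced**; volume conservation is (one SU out,
  one in, every iteration).
* **$P$ at the centre of mass** is defined as 0, so such a site belongs
  to the rear whenever $FR \ge 0$.
* **Frame schedule.** Snapshots are saved at every iteration divisible by
  `save_interval`; the analysis window is
  `(start_iteration, n_iterations]`. With the defaults (100 000
  iterations, interval 500, window start 60 000) a track has 80 frames —
  the window skips the early, still-spherical transient.
* **Candidate sets are recomputed every iteration** from the current
  state; the compiled kernel keeps occupancy in a re-centred dense grid
  so a full-scale cell simulates in seconds.

```{r simulate}
p <- cms_params(radius_su = 4, n_iterations = 2000, save_interval = 500,
                start_iteration = 0, seed = 1)
tr <- cms_simulate(p)
tr
```

## Surface extraction

Lattice frames become binary masks (`occupancy_to_mask()`, padded so the
surface can close around the volume) and are iso-surfaced at level 0.5 by
**body-centred marching tetrahedra**: every lattice cube is split into 24
tetrahedra spanned by its centre, a face centre and a face edge, with
centre values set to corner averages. Unlike table-driven marching cubes,
this decomposition has no ambiguous cases on binary data, so the meshes
are always closed (every edge shared by exactly two faces) — a property
the test suite asserts on balls, random blobs and single voxels.

Binary staircase surfaces over-estimate area. Before meshing, the mask is
therefore blended with its 6-neighbour mean,
$0.6\,m + 0.4\,\overline{m}_6$. Because an occupied voxel keeps a value
$\ge 0.6$ and an empty one $\le 0.4$, the blend provably never changes
which voxels are above the iso-level: topology and foreground count are
those of the raw mask, only the sub-voxel vertex placement improves. A
digitised ball of radius 10 then meshes to within 7% of the true sphere
area (the raw staircase would be 28% high).

`to_spherical_grid()` re-centres a mesh at its unweighted vertex centroid
and interpolates the scattered vertex radii onto an $N \times N$
equiangular grid, $\theta_i = \pi(i + 0.5)/N$ (offset off the poles),
$\varphi_j = 2\pi j/N$, default $N = 120$. Interpolation is local
weighted linear least squares in the tangent plane of each grid direction
(gnomonic chart) over the nearest vertex directions, found through
spherical binning in which the polar bin rows are searched as whole caps
— near-polar azimuths are numerically meaningless and must not influence
neighbour lookup. The scheme is exact for constant radii, second-order
accurate for smooth radial functions (< 0.1% RMS for a degree-4 shape on
a subdivision-5 icosphere), translation-invariant to machine precision
and exactly homogeneous under scaling.

Shapes whose centroid falls outside the body (or that are not
star-shaped) have no single-valued radial function; the interpolant of
all vertex samples is kept as-is and the grid is flagged
(`center_outside`), mirroring how such cells are tolerated, not repaired,
in practice.

## The SPHARM descriptors

The radial function is expanded in complex spherical harmonics under the
orthonormal (unit-power) convention with Condon–Shortley phase. The
azimuthal direction is handled by FFT. In colatitude the grid nodes
$\cos\theta_i$ are exactly the Fejér first-rule Chebyshev points, whose
quadrature weights integrate polynomials up to degree $N - 1$ exactly —
so analysis and synthesis are *exact* for fields band-limited to degree
$N/2 - 1$, a Driscoll–Healy-type sampling theorem on the pole-offset
grid. The test suite verifies round-trip identity to $10^{-8}$ and
checks the coefficients of analytic test shapes against an independent
nested adaptive-quadrature oracle to $10^{-6}$ relative.

The shape descriptor is the rotation-invariant power spectrum

$$F(l) = \sum_{m=-l}^{l} |A(l, m)|^2,$$

truncated to the first `l_max` degrees. Degree 0 is retained, so the
descriptor is size-sensitive; no per-cell normalisation is applied. Three
feature vectors are built per cell:

* **static** — $F(l)$ of the *first* frame only (`l_max` values); the
  remaining frames are discarded so that static and dynamic classifiers
  see the same number of independent observations (cells, never
  time points),
* **dynamic time** — the time map $F(l, t)$ over the first $T$ frames,
  flattened time-major (`l_max * T` values),
* **dynamic frequency** — magnitudes of an unpadded, unwindowed DFT of
  length exactly $T$ along time for each degree. Magnitudes (rather than
  complex values or power) give real-valued, time-shift-invariant
  features; with the unnormalised DFT, $\sum_f F(l,f)^2 = T \sum_t
  F(l,t)^2$ holds exactly.

Cells with fewer than $T$ frames are dropped from the dynamic tables
only; the static table keeps them, and the extraction records the
exclusions. Defaults `l_max = 10`, `T = 20` are exposed in every entry
point, and `tune_feature_params()` scans candidate grids for the pair
maximising mean CV accuracy, breaking ties toward the smaller feature
vector. An opt-in `static_all_timepoints` mode treats every frame as an
observation — useful only to demonstrate how pseudo-replicated static
features overfit; the default contract is one observation per cell.

Because $F$ is *quadratic* in the deformation, a symmetric shape
oscillation at frequency $f$ appears predominantly at $2f$ in the
frequency map — a property the fixture tests assert explicitly.

## Classification and controls

Classification is always pairwise, with a linear-kernel SVM
(C-classification, cost fixed at 1 and deliberately untuned — controls
and comparisons must hold the classifier constant; features are not
standardised by default, with a flag for scale-sensitive uses). Two
cross-validation schemes:

* **stratified shuffle** (ungrouped data): per round, 50 random training
  and 20 random test cells per class (defaults), disjoint by
  construction, 150 rounds;
* **group shuffle** (grouped data, e.g. imaging time series): per round
  one whole series per class is held out for testing, so a series never
  straddles train and test.

A dataset is *balanced* when no class holds strictly more than 60% of the
cells (exactly 60% is balanced). Balanced comparisons use a
**random-classifier control**: class labels are shuffled and
cross-validation re-run — 5 shuffles × 10 rounds per pair under the
shuffle scheme (50 values per pair; the three pairs of a 3-class design
pool to one 150-value control set), 15 × 10 under the group scheme (150
values per pair). Under the group scheme, labels are permuted at the
*group* level, so each series keeps a single (random) label and the
held-out-group machinery remains well-defined. Unbalanced comparisons use
the **majority classifier**: one series per class is drawn at random (150
draws), all drawn cells are assigned to the overall majority class, and
the accuracy equals the majority fraction of the draw.

Accuracy distributions are compared with a one-sided Mann–Whitney test
(`wilcox.test`: exact for small untied samples, mid-ranks with normal
approximation and tie correction otherwise), annotated at the 0.05 / 0.01
/ 0.001 tiers. Seeding is hierarchical: one master seed derives per-round
seeds, so any single round is reproducible in isolation.

One caveat worth stating plainly: CV rounds drawn from one fixed cell
sample are statistically dependent, so treating 150 of them as
independent observations — as the control procedure does — is
anti-conservative with respect to dataset-level sampling noise. At small
cohort sizes a null comparison can occasionally reach nominal
significance for this reason; conclusions should rest on effect sizes
(accuracy vs. control) as much as on the p-values.

## The oscillating-cell demonstration

The built-in fixture generator realises the motivating scenario as
volume-preserving ellipsoid oscillation: at frame $t$ the x-axis is
stretched by $\lambda_t = 1 + a\,\sin(2\pi f t/T + \varphi)$ and the
transverse axes shrunk by $\lambda_t^{-1/2}$, plus seeded radial vertex
noise. Classes differ only in $f$. Every class receives the *same*
jittered stratified set of starting phases (permuted within class), so
the classes' single-frame shape multisets are matched by construction:
the cells are unsynchronised, a snapshot carries no class information,
and only the pace of the oscillation separates the classes. (Independent
uniform phases were measured to be a weaker design: with 30 cells per
class, the chance imbalance between two independent 30-draw phase samples
is large enough for the anti-conservative control comparison above to
flag the static classifier in a noticeable fraction of seeds.)

```{r oscillation, eval = FALSE}
cells <- make_oscillating_dataset(frequencies = c(2, 5), n_per_class = 30,
                                  n_frames = 20, seed = 505)
feats <- extract_features(cells, l_max = 10, n_time = 20, grid_size = 120)
cfg <- cv_config("shuffle", n_rounds = 150, n_train_per_class = 20,
                 n_test_per_class = 10, seed = 505)
mean(cv_stratified_shuffle(feats$static, cfg))     # ~ chance
mean(cv_stratified_shuffle(feats$frequency, cfg))  # ~ 1.0
```

The acceptance suite runs exactly this comparison and requires the
frequency-map classifier to beat its label-shuffle control at
$p < 0.001$ while the static classifier does not.

## Problem sizes and runtimes

The reference experiment design — 3 classes × 70 cells, 100 000
iterations per cell, 80 frames, grid 120 — is what the defaults encode.
The test and acceptance workloads are scaled down so a full run fits
comfortably on one CPU: the simulator invariants run on 5 000-iteration
tracks; one full-scale 100 000-iteration cell (about 15 s) verifies the
80-frame schedule; the oscillating demonstration uses 30 cells per class
× 20 frames; the simulator-parameter demonstration uses PW = 1 vs 4 with
20 cells per class × 10 000 iterations. The complete test suite runs in
about five minutes; `scripts/acceptance.R` in about the same.

## Known limitations

* Radial (single-valued $r(\theta,\varphi)$) shape representation:
  strongly non-star-shaped cells are flagged but not accurately
  represented; coefficient-domain alignment (SPHARM-PDM-style
  registration) is out of scope, as the rotation-invariant spectrum makes
  it unnecessary for classification.
* The simulator has no membrane mechanics, chemotaxis or cell–cell
  interactions; it is a shape-pattern generator, not a biophysical model.
* The fixtures are ground-truth instruments, not imitations of real cell
  morphology: passing the oscillation demonstration shows the dynamic
  descriptors recover pace differences under matched shape distributions,
  not that they capture everything that distinguishes real cell types.
* Linear SVM only; other classifiers are out of scope.
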