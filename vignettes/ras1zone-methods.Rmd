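---
title: "Modeling the exploratory Ras1 mating patch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the exploratory Ras1 mating patch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological problem and the model

Mating fission yeast locate a partner with an exploratory polarity
patch: a cortical zone of active, GTP-bound Ras1 that assembles at a
random position, persists for tens of seconds, disappears, and
reassembles elsewhere, until pheromone sensing stabilizes it toward the
partner. `ras1zone` implements this system as a reaction–diffusion model
on the closed membrane surface of an idealized cell (a spherocylinder),
with three dynamic surface species:

* **Ras1-GTP** (`C_RT`): the active form, produced from membrane
  Ras1-GDP by GEF-mediated activation and lost by hydrolysis and
  membrane dissociation;
* **Ras1-GDP** (`C_RD`): the inactive membrane form, supplied from the
  cytoplasm at a constant flux `jRDp` and consumed by activation;
* **Gap1** (`C_GAP`): the GTPase-activating protein, recruited
  cooperatively by Ras1-GTP (Hill coefficient `h`, half saturation
  `Csat`) and responsible for the dominant hydrolysis pathway
  (`k2n * C_GAP * C_RT`).

The positive feedback works through a finite cytoplasmic pool of GEF
(`Ectot` molecules). In the quasi-static approximation the membrane GEF
density follows the Ras1-GTP field instantaneously,

```
C_GEF = (k1p * Ec / V) * C_RT + (k2p * Ec / V) * C_RT^2
Ec    = Ectot / (1 + integral[(k1p C_RT + k2p C_RT^2)/V] dA),
```

so that `Ec + integral(C_GEF dA) = Ectot` exactly at every step. The
quadratic term concentrates the pool on the cell with the most active
Ras1 — a winner-take-all competition — while the pool's finiteness
limits how many patches can coexist. Gap1, diffusing several-fold
faster than Ras1-GTP, spreads beyond the activation zone and both
confines the patch laterally and eventually extinguishes it; release of
the GEF pool then allows noise-seeded reformation elsewhere. A small
multiplicative activation noise (`rnoise`) converts Ras1-GDP to
Ras1-GTP at a rate drawn uniformly per cell and per step
(`dN = dt * da * p * rnoise * C_RD`, `p ~ U(0,1)`), calibrated so the
whole-cell budget `rnoise * C_RD * S` is about 6 molecules per second.
Note that the mean of the per-step draw is half that budget (the
`U(0,1)` factor); both conventions circulate for this calibration and
the generator keeps the per-step draw form, documenting the factor-two
ambiguity here rather than resolving it silently.

An expanded model variant replaces the quasi-static GEF by an explicit
fourth field with recruitment constants `rho1 = k1p * r_GEF` and
`rho2 = k2p * r_GEF` and dissociation `r_GEF`; in the limit of fast
dissociation it reduces to the quasi-static form, which the test suite
verifies directly.

## Membrane surface and discrete diffusion operator

The membrane is a cylinder of radius 2 um with spherical caps
(tip-to-tip 6 um for mating cells, about 11 um for interphase cells),
discretized into Voronoi polygons. Generator rings are placed at a
uniform meridian arc spacing equal to the projected-axis pixel size
(`tip_to_tip_length / n_axial`); each ring carries a number of
generators proportional to its band area (constant `n_circ` on the
cylinder), and the two poles carry single generators. This placement
was chosen over equal-z rings with constant per-ring counts because the
latter produces highly elongated sliver cells near the poles, which
degrade both the accuracy and the stability of the discrete operator;
with area-proportional counts the 45 x 40 mating-cell mesh has 1808
cells with areas between 0.036 and 0.044 um^2 and aspect ratios near
those of the cylinder cells everywhere.

Cell areas, adjacencies and shared-boundary lengths are measured on a
fine surface-of-revolution quadrature grid (the boundary length is
accumulated separately along the two grid orientations and combined in
quadrature, which removes the staircase bias for oblique Voronoi
edges). The Laplace–Beltrami operator uses symmetric finite-volume
weights `w_ij = edge_length / generator_distance`; generator distances
rather than centroid distances keep the two-point flux orthogonal to
the Voronoi edge. The operator annihilates constants exactly and is
exactly conservative by construction. Its accuracy is verified against
two independent references: the flat-plane Gaussian heat kernel on the
(intrinsically flat) cylindrical section (L2 error about 3%), and an
exact axisymmetric one-dimensional solve in the meridian coordinate for
a pole point source (L2 error about 2%).

Tip curvature can be varied at fixed total surface area: blunter caps
via `tip_radius > radius` (cap sphere meeting the cylinder rim),
sharper tips by shrinking the cell radius itself, with
`equal_area_length()` adjusting the length — a cap sphere cannot be
narrower than the cylinder it closes, so the sharp-tip branch of the
curvature study varies the cell radius.

## Time integration

All fields advance by forward Euler at `dt = 0.01 s` (quasi-static
model), with an explicit Gershgorin stability check that names the
offending species when the diffusion bound is violated. Negative
densities arising from the stiff hydrolysis term are clipped at zero
and the clipped mass is accumulated and reported (it stays below 0.1%
of the total Ras1 content in the test conditions). The noise draw is
tied to the fixed step size by construction, so no adaptive stepping is
used.

In the expanded model the free pool `Ec` couples all cells through the
binding flux and is by far the stiffest direction of the dynamics: at
patch densities its relaxation rate reaches 1e5–1e6 per second, which
an explicit update only resolves with steps well below 1e-5 s (and on
coarser meshes not even then, since single-cell density transients are
larger). The integrator therefore treats the single scalar `Ec`
implicitly within each step — a one-line closed-form solve — while all
per-cell fields remain explicit. This removes the pool stiffness
without changing the converged dynamics (results at `dt = 2e-4` and
`1e-4` on the coarse mesh coincide) and lets the four-field model run
at steps set by the reaction and diffusion scales. The default
`dt = 1e-5 s` remains available for fully explicit-like operation on
the fine mesh.

## FRAP machinery

The FRAP module integrates two linear transport models: uniform
cytoplasmic exchange (`D`, `r`, association flux `j_plus`; pre-bleach
steady state `j_plus/r`), and Gaussian tip recruitment (total rate `A`
molecules/s, width `sigma` in arc distance to the tip; `sigma = 0.4 um`
for the mating fusion focus and `0.8 um` for vegetative tips).
Bleaching zeroes the field on the bleach region; for the recruitment
model the amplitude is simultaneously multiplied by the post-bleach
factor (0.5 when the whole recruitable pool at the focus is bleached,
0.7 for the half-tip protocol), so by linearity the long-time recovery
equals that factor — the test suite asserts 50% and 70% to within one
percentage point. Readouts are unweighted means over region cells
restricted to a confocal slab of half-width 0.6 um about the medial
plane, normalized to the pre-bleach value. Acquisition photobleaching
is corrected by dividing background-subtracted intensities by
`exp(-r_PB t)`, with `r_PB` fitted by least squares to the
background-subtracted cytosolic signal; the multiplicative form is the
only one that leaves an unbleached constant signal invariant.

Fitting `(D, r)` uses a plain grid search (default steps 0.01 um^2/s
and 0.005 1/s, matching the resolution at which such estimates are
meaningfully distinct) with joint SSR over traces from different bleach
geometries; the acceptable set collects grid points whose curves stay
inside the per-frame replicate-SD band at every frame (a pointwise
policy; a summary-statistic band would be laxer, and the policy is
exposed as a flag). An optional second stage re-ranks acceptable points
by SSR against stored spatial profiles. Parameter recovery on synthetic
noisy replicates (5 cells, 5% frame noise) lands within one grid step
of the truth in at least 90% of replicates.

The synthetic trace generator adds independent Gaussian frame noise per
replicate around the noise-free model curve. It emulates measurement
noise and cell-to-cell averaging only: it does not model pixel-level
shot noise, focus drift, cell-shape variability, or acquisition
photobleaching (which is exercised separately through constructed
decays), so passing fits demonstrate estimator correctness under the
model's own assumptions, not robustness to every imaging artifact.

## Patch analytics

Patch detection thresholds the Ras1-GTP field at
`max(abs_floor, 0.25 * max(C_RT))` and labels connected components,
merging components closer than 0.26 um (the same merging rule the
experimental counting procedure uses for spotty signals). The absolute
floor defaults to five times the noise-sustained Ras1-GTP background of
the reference parameter set (`(rnoise/2) C_RD / (k1n + r_RT)`, about
1.7 um^-2). The period estimator takes peaks of the spatial-maximum
series with topographic prominence of at least half the series range
and reports mean peak-to-peak intervals; a series whose last half has a
coefficient of variation under 5% with no qualifying peak is flagged
stable. The regime classifier is rule-based, in order: homogeneous
activation when more than 95% of the area is locally GTP-dominated
(`C_RT > C_RD`, a criterion robust to the overall membrane Ras1 budget,
which differs strongly between regimes); never-any-patch; persistent
settled patches split into stable single patch, traveling wave (center
drift beyond 1 um), or multiple patches; single-Voronoi-cell patches;
and otherwise count-based oscillatory labels. Quantification of 1D
cortical intensity profiles follows the experimental rules exactly:
runs of at least 2 pixels above the background mean qualify when their
mean exceeds background plus three background SDs, qualifying runs
closer than 0.26 um merge, and sizes are merged spans times the 0.13 um
pixel.

## Reproducibility and problem sizes

Every stochastic entry point takes a seed; scenario runs write a JSON
manifest with a configuration hash, and sweeps derive deterministic
child seeds per grid point so points are independent but reproducible.
The test suite runs the reference 45 x 40 mesh for 600-s simulations
(a few seconds each), the noise and Gap1-detachment scans at a handful
of grid points, the expanded model on a 2x-coarsened mesh at
`dt = 2e-4`, and FRAP fits on a 41 x 20 interphase mesh; these sizes
were chosen so the full suite exercises every claim at full spatial
resolution while individual checks stay at desk scale.

## Known limitations and an honest discrepancy

* The model assumes uniform, constant cytoplasmic concentrations;
  cytoplasmic gradients, the Cdc42 layer, actin-dependent delivery and
  cell-shape change (shmoo outgrowth) are out of scope.
* The on-mesh patch detector and the dynamical-regime classifier are
  operational definitions (documented above) rather than measured
  quantities; alternative policies can be supplied as configuration
  objects.
* With the documented reference rate constants, this implementation
  sits very close to the boundary between recurrent patch turnover and
  a quasi-stable one- or two-patch state: some seeds cycle with
  periods near a minute while others settle after a few events, and
  the time-averaged Ras1-GDP background sags below its nominal
  38 um^-2 whenever a patch persists (active Ras1 dissociates 20-fold
  faster than the inactive form, so a standing patch slowly drains the
  membrane pool against the slow `jRDp` resupply). Small increases in
  the Gap1 feedback product (`k2n * k3n`) or small decreases in
  `r_GAP` move the system into robust single-patch cycling — the
  Gap1-detachment sweep in the acceptance suite shows the
  oscillatory window directly, with periods lengthening as `r_GAP`
  decreases until the patch stabilizes. The integrator itself is
  verified step-for-step against an independent R implementation of
  the update equations, and the operator against analytic kernels, so
  this sensitivity is a property of the model at these constants as
  implemented here; the affected acceptance checks are left to report
  whatever the stated conditions produce.
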