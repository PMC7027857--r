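---
title: "Models and methods behind rootpore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rootpore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootpore)
```

`rootpore` re-implements, as a tested pipeline, the analysis of how wheat
roots interact with vertical macropores in loose versus compacted subsoil.
This vignette explains the models, the parameters that matter, the
numerical choices, and what the synthetic data do and do not demonstrate.

## Coordinate conventions and geometry

All coordinates are in millimetres. `z` is depth, increasing downward from
the soil surface; `x` and `y` are centred on the column axis. This makes
layer boundaries and pore extents additive from the column design: with the
default 170 mm column, 55 mm subsoil and 45 mm pores terminating at the
base, pore tops sit at depth $170 - 45 = 125$ mm, leaving the intended
10 mm soil cap below the topsoil boundary at 115 mm.

Roots are ordered 3D polylines (proximal to distal) with a constant radius;
pores are vertical cylinders. Two geometric primitives carry the analysis:

* **Surface separation.** The distance between a root and a pore is
  surface-to-surface: the distance from a centerline point to the solid
  cylinder (with end-cap handling), minus the root radius, floored at zero.
  The published definition of an interaction ("maximum separation one
  voxel") does not state whether the distance was surface- or
  centerline-based; we chose surface-to-surface because a voxel-level
  contact criterion in an image is intrinsically about surfaces. This is a
  flagged choice, not a silent one. `min_surface_distance()` scans the
  centerline at 0.1 mm and polishes the minimum by 1D convex minimisation
  on the bracketing sub-arcs (distance to a convex solid is convex along a
  segment), which matches a 0.01 mm brute-force scan to well under the
  0.02 mm tolerance used in the tests.

* **Growth direction.** The direction at an arc position is the principal
  axis of a total-least-squares 3D line fit to the centerline resampled at
  0.5 mm within a 20 mm arc window, oriented in the direction of growth.
  TLS on a resampled window is robust to uneven vertex spacing. When the
  window is truncated by a root end, at least 5 mm of arc must remain;
  otherwise the direction is *indeterminate* and the event is excluded from
  changed/unchanged percentages (but still counted and reported). The 5 mm
  floor avoids meaningless fits near tips; the threshold is a package
  choice, since very short roots are not covered by the published rules.

## Interaction rules

An **interaction** is a contact episode where the separation is at most one
voxel (45 μm by default, the scan resolution; configurable per volume).
Contacts of the same root–pore pair separated by less than 15 mm of arc
merge into one event, keeping the first contact. An interaction
**colonizes** when the longest contiguous in-pore run of the centerline
(within the pore radius of the axis, inside its z-extent, starting at or
after contact) exceeds 15 mm; otherwise it **crosses**. Trajectory
**change** for crossers compares the 20 mm pre-contact direction with the
20 mm direction after leaving the pore (post-window origin = contact arc +
in-pore length), declaring change above 3°. Colonization counts as change
by definition.

Both thresholds are strict (`> 15 mm`, `> 3°`), a literal reading of the
published wording ("at least >15 mm", "±3°"). The simulator deliberately
keeps truth away from both boundaries (below), so classification never
hinges on the boundary convention; the convention is nevertheless fixed and
tested. Angles are measured in 3D (the published text does not say whether
a 2D projection was used); this is recorded in the package metadata.

## The synthetic-data generator

No scans from the original experiment are deposited, so the generator *is*
the study's data source, and its defaults are the study conditions: 2
genotypes × 2 packing densities × 10 replicates = 40 columns in 6
staggering-day blocks; interactions per column drawn from a Poisson with
mean 1.78 truncated at 7 (only the mean and the 0–7 range are published);
and per-cell behaviour profiles packaging the observed outcome rates —
colonization 68.8% / 12.5% (compact / loose, genotypes combined), 80.0% /
62.5% (compact, by genotype), 7.7% / 15% (loose, by genotype), trajectory
change 76.0% / 21.0% combined, 92.9% / 78.6% and 20% / 25% by genotype.

Profiles store the *overall* change rate. Because colonization implies
change, the change probability for crossers is derived:

$$p_{\mathrm{change}\mid\mathrm{cross}} =
  \frac{p_{\mathrm{change}} - p_{\mathrm{colonize}}}{1 - p_{\mathrm{colonize}}}$$

clamped to $[0,1]$ (`derive_conditional_change()`). For the compact
combined profile this gives 0.2308, for loose 0.0971. A published
loose-soil figure of 76.7% of crossers *not* changing direction is
arithmetically inconsistent with the 21.0% overall change rate under this
decomposition (it implies 23.3% ≠ 9.7%); we keep the overall rates as
primary and derive the conditional, so that the overall percentages — the
headline results — are reproduced.

The generator is **event-driven**: the interaction count is drawn first and
geometry is constructed to realise each event. A purely geometric mode
(roots grown blind, interactions emerging from proximity) would require
root-number and root-angle parameters the original study does not report,
so it could not reproduce the printed interaction rate; event-driven
construction makes the published rates recoverable by design and leaves the
geometric pipeline to *earn* them back from raw coordinates.

Each interacting root descends from the planting position (20 mm depth,
inside the 20 mm guide column) as a persistence walk: 0.5 mm steps, 0.4°
per-step Gaussian angular jitter, and a pull toward the current waypoint
that both mimics gravitropic bias and guarantees the root arrives at its
constructed contact point. Colonizers approach the pore mouth from above at
a 3–10° tilt and follow the axis to the pore bottom (no root was ever
observed exiting a pore, so colonizers never exit; their in-pore run is the
full pore length, far above the 15 mm threshold). Crossers contact the pore
flank at an 8–20° approach tilt, then continue ≥ 20 mm deflected by an
angle drawn from disjoint bands: change events Uniform(8°, 45°), no-change
events Uniform(0°, 1.5°). The bands keep truth clear of the 3° decision
boundary so that classifier accuracy is testable (the direction-fit noise
of the walk is ≈ 0.2–0.5°); both bands are configurable, including
near-boundary settings for adversarial use. Every constructed root is
validated — inside the column, > 0.5 mm clear of every non-target pore (so
the 45 μm detector cannot fire spuriously) — and rebuilt on failure.
Non-interacting filler roots (> 1 mm clear of all pores) add realism
without touching the event counts.

What passing tests on these data show is that the *geometric pipeline*
(detection, in-pore measurement, direction fitting, classification,
statistics) faithfully recovers behaviour written into 3D coordinates, at
the study's sample sizes. What they cannot show is anything about real CT
data: real roots branch, taper, and wander; real scans have noise,
partial-volume effects and contact ambiguity where a root lies inside an
air-filled pore. The segmentation module is exercised on phantoms with
known labels precisely because that last step — separating root from pore
lumen in grayscale — is the hardest real-data step, and the synthetic
acceptance path does not depend on it (label mode is available).

## Voxelization and phantoms

The working resolution is 200 μm, not the 45 μm scan resolution: a full
column at 45 μm is ~7.6 × 10⁹ voxels, which is not desk-scale, while ROI
crops at finer resolution are supported via `bounds`. Bulk regions (soil
layers, inner wall) label a voxel by its center. The 0.8 mm pores are
comparable in size to the working voxel, where center-labelling is
alignment-pathological: with the default jig the axial pore catches four
0.5 mm voxels per slice against a true cross-section of two, inflating pore
volume by ~33%. Pores are therefore rasterized area-preservingly — per
slice, voxels are ranked by analytic cross-section coverage and labelled
until the disk area is matched — which conserves pore volume to well within
the 10% test tolerance at 500 μm and is consistent across resolutions.
Roots keep center-within-radius marking: their connectivity matters for
skeletonization, and their volume is not an analysis quantity.

Grayscale phantoms assign per-label means (air-filled pores darkest at
0.05, roots 0.25, topsoil 0.55, subsoil scaled by the density ratio
$0.55\,\rho/1.1$, PVC wall 0.85) plus seeded i.i.d. Gaussian noise. Beam
hardening, rings and scanner physics are out of scope.

## Segmentation and centerlines

`region_grow()` is a deterministic running-mean region grower: a voxel
joins the region if its intensity is within the tolerance of the mean of
the region accepted so far, through 26-connectivity, in FIFO order. The
original analysis used an interactive proprietary tool; a deterministic
grower with an explicit tolerance makes results reproducible, and the
original workflow's note that no further image processing was needed
suggests connectivity-based extraction suffices on these images.

`skeletonize()` traces a one-voxel-wide medial path per 26-connected
component: an unweighted double breadth-first sweep finds the geodesic
diameter endpoints; each endpoint is refined to the deepest voxel (maximal
chamfer distance-to-background) within its local neighbourhood, which pulls
tube-end corner voxels onto the axis; and a shortest path with step costs
divided by local clearance pins the route to the medial ridge. This is a
centerline tracer rather than iterative topological thinning — appropriate
because the structures of interest are unbranched tubes and branch topology
is explicitly out of scope. It satisfies the skeleton contract: subset of
the mask, component count preserved, acyclic on tubes, and ≤ 1 voxel RMS
off-axis on straight cylinders. `extract_centerlines()` orders each path
proximal (shallow end) to distal and smooths with a 1 mm moving average,
which removes lattice zig-zag (wavelength ≤ 2 voxels) and brings arc
lengths within 2–3% of truth on straight and helical test tubes.

The chamfer distance transform uses 26-neighbourhood weights
$(1, \sqrt2, \sqrt3)\,h$; its few-percent metric error is irrelevant here
because the transform only ranks clearances. Voxels on the array boundary
are not treated as adjacent to background, so cropped structures are not
artificially eroded at the crop faces.

## Statistics

Per-column counts (interactions, colonizations, crossings, changes) are
analysed as a randomized block design, `y ~ block + genotype * treatment`,
with all factors fixed — the classical agronomic analysis matching the
original protocol. Shapiro–Wilk normality is reported for each response,
and the ANOVA is run regardless of its outcome (count responses at n = 10
per cell often fail normality); a note is emitted when normality is
rejected, preferring fidelity to the original analysis over statistical
purity. The LSD at level $\alpha$ is
$t_{1-\alpha/2,\nu}\sqrt{2\,\mathrm{MSE}/n}$ with $\nu$ the residual
degrees of freedom and $n$ the per-mean replication. Outcome percentages
use *interactions* as the denominator (the published wording mixes "roots"
and "interactions"; interactions are what the assay counts), and
changed/unchanged percentages are computed over determinate events only,
with indeterminate counts reported alongside.

## Problem sizes and tolerances

The packaged checks use the sizes the analysis itself calls for: per-arm
recovery runs accumulate ≥ 500 interactions (≈ 280 columns at the 1.78
rate), which makes three binomial standard errors ≈ 6 percentage points for
the compact colonization rate; the interaction-rate check uses a 400-column
design (3 SE ≈ 0.2 interactions per column); classifier-vs-truth agreement
is evaluated on ≥ 1000 events; binomial calibration of the generator itself
uses 3000 events; ANOVA type-I calibration uses 200 null replicates of the
40-column design. All stochastic checks fix their seeds and test three
standard errors around the target, so they are deterministic in practice
while remaining honest about sampling noise.

## Known limitations

* Roots are unbranched polylines of constant radius; no laterals, tapering
  or diameter estimation.
* The event-driven generator reproduces *rates*, not mechanisms: it encodes
  no tropism, impedance response or water relations, so it cannot be used
  to study *why* compaction changes behaviour — only whether the
  measurement pipeline recovers behaviour correctly.
* Grayscale-mode separation of a root inside an air-filled pore is not
  attempted beyond label mode; on real scans this step would need care.
* The exact jig pattern of the nine pores is not published beyond "equally
  spaced"; the default (one axial pore plus eight on an 8 mm ring at 45°)
  keeps all pores under the guide-column footprint and is configurable, and
  the layout used is recorded in output metadata.
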