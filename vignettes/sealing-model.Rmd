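---
title: "Virtual TAVR deployment and skirt sealing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual TAVR deployment and skirt sealing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tavrseal)
```

## The problem

Paravalvular leakage (PVL) after transcatheter aortic valve replacement
(TAVR) arises where the fabric skirt of the self-expanding frame fails to
appose the surrounding aortic root. Bicuspid aortic valves (BAV) — with an
absent or underdeveloped interleaflet triangle, a raphe, heavier
calcification and an elliptical "fish-mouth" annulus — seal differently
from tricuspid valves (TAV). `tavrseal` reproduces, at desk scale and on
fully synthetic anatomy, the computational chain used to study this:
parametric root meshes, a parametric self-expanding frame, quasi-static
deployment, ray-cast skirt apposition analysis at a 1 mm threshold, frame
cross-section metrics, and the cohort statistics that compare BAV against
TAV sealing behaviour.

Everything here runs from a single master seed; every figure-level quantity
the package reports is recomputed by `scripts/acceptance.R` and the test
suite — this vignette states no number that those do not compute.

## Synthetic anatomy

`build_root()` generates the *inner* surface of the aortic root as a
structured tube (two open boundary loops), because the downstream sealing
analysis only ever needs the innermost surface the skirt can contact.
Coordinates: the annular plane is `z = 0`, `+z` is aortic, and the
cylindrical angle is measured from a fixed commissure; all lengths are mm.

The radius field composes four effects:

* an elliptical annulus (`annulus_dmax`, `annulus_dmin`), extended
  cylindrically below `z = 0` as the LVOT;
* a sinus bulge `r(θ,z) = r_ann(θ) · (1 + (f − 1)·sin(π z / z_STJ))` with
  `f = sinus_radius_factor` (default 1.25, a typical sinus-to-annulus
  ratio), vanishing at the sinotubular junction;
* leaflets as an inward-bulged band: calcified stenotic leaflets pressed
  against the sinus wall form a near-cylindrical channel slightly inside
  the annular radius (`leaflet_bulge`, default 5% of the local annular
  radius, zero at the annulus so the `z = 0` section stays a clean
  ellipse);
* for BAV1, a raphe ridge protruding inward along the fused commissure.

Region labels follow the leaflet attachment lines. The attachment height is
`h(θ) = ch · u^q` with `u` ramping from 0 at each leaflet nadir to 1 at the
commissures and `q = attachment_sharpness` (default 3). Wall points below
the curve belong to the interleaflet triangle (apex at the commissure, base
on the annulus); points above it, up to the commissure height, are leaflet;
below `z = 0` is LVOT and above the commissures ascending aorta. `q = 3`
makes the triangles slim wedges occupying roughly a quarter of the
supra-annular band, which reproduces the field's observation that the
leaflets are the dominant apposition contributor. TAV has three
commissures at 120°; BAV0 two commissures at 180°, placed on the annular
long axis (the fish-mouth configuration); BAV1 keeps the developmental
three-commissure layout with one commissure fused — its triangle is
relabeled as leaflet and carries the raphe, so both BAV types have one
triangle fewer than TAV (`region_patch_count()` checks 3/2/2).

Calcium deposits (`place_calcium()`) relabel leaflet triangles inside an
angular/height footprint as `CALCIUM` and displace them inward by
`volume / footprint_area`, capped at the deposit's `protrusion`.
Overlapping deposits take the maximum displacement rather than the sum (a
nodule has a thickness, not a stack), and the lumen keeps a stenotic floor
radius of 4.5 mm — about the orifice of a severely stenotic valve.

## Synthetic cohort

`sample_cohort()` draws per-morphology covariates from truncated normals
whose means and SDs follow the published baseline table of the study
population this package emulates (17 TAV / 11 BAV0 / 15 BAV1): annulus
diameters, calcium volume (BAV ≈ 1210 vs TAV ≈ 780 mm³), and implantation
depth. Device size is the smallest of 23/26/29/32 mm reaching a configured
sizing target (size / perimeter-derived diameter). The target is
per-morphology (TAV 1.05, BAV 0.98): a single target cannot reproduce the
clinically reported sizing indices, because operators deliberately
undersize bicuspid anatomies; with the size-grid quantisation these targets
land the expected sizing indices near the reported 1.11 (TAV) and 1.04
(BAV). TAV roots get a random annular orientation per patient; BAV
orientations are anatomically anchored to the long axis.

The generator emulates: morphology mix, annular size and ellipticity,
calcium burden and its leaflet/raphe placement, implantation depth, and the
sizing policy. It does **not** emulate: real leaflet mechanics, eccentric
deployment, annular motion, CT noise, or inter-patient shape variability
beyond these parameters — so passing cohort-level tests demonstrates the
causal chain (morphology and sizing → local gaps → region-wise
malapposition), not clinical accuracy.

## Device frame and radial force

`build_frame()` builds a generic diamond-cell lattice (40 levels × 32
sectors by default, ≈ 3000 elements — the same order as a realistic device
mesh) following a flared nominal profile: inflow at the nominal size, a
constrained waist at 55% height, moderate outflow flare. The true
commercial strut geometry is proprietary; downstream analyses depend only
on the deployed outer surface and skirt, so a parametric lattice is
sufficient. The skirt covers the cells below 40% of frame height (the
devices' fabric-covered inflow portion; the exact height is config).

The radial-force bench (`virtual_bench_test()`) uses a per-level linear
spring: each level contributes `k · max(0, (r_nom − r)/r_nom)` N, with a
multiplicative unloading factor (default 0.8) for crimp hysteresis. No
public numeric radial-force data exist for calibration, so `k` is exposed
as configuration and only curve-shape properties (zero at nominal,
monotonicity, loading ≥ unloading) are asserted.

## Deployment solver

`deploy()` replaces full frictional contact finite elements with per-node
radial equilibrium, releasing levels sequentially from the ventricular end:

* each node sees the anatomy along its own radial ray (`ray_first_hit()`),
  giving the local lumen radius, region and material;
* frame expansion pressure `p_f = P·(r_nom − r)/r_nom`
  (`expansion_pressure` P, default 0.5 MPa — the order of self-expanding
  frame radial pressures);
* tissue resistance is a linear penalty on penetration with thin-shell
  stiffness `E·t/r²` (wall 2 MPa / 2 mm, leaflet 0.6 MPa / 1.5 mm, calcium
  4 MPa / 2 mm with a 0.6 MPa perfect-plastic cap — the calibrated linear
  tissue constants standard in this simulation field);
* the piecewise-linear balance is solved in closed form (elastic branch,
  plastic plateau, or tissue bottoming out at its thickness); a damped
  iteration handles nonlinear penalty exponents;
* contacted anatomy triangles are displaced outward by
  `pressure / stiffness`, capped at the tissue thickness — first-order
  compliance without volumetric meshing.

The axial position is prescribed: the friction coefficient (0.7) is stored
and reported but slip is not simulated, mirroring the original workflow in
which the implantation depth is iterated to match post-operative imaging
(`match_depth()`, convergence within 0.1 mm). Everything is deterministic:
fixed release order, no randomness, bit-identical reruns.

Consequences worth knowing: with per-node equilibrium there is no strut
coupling, so malapposition arises where the local lumen lies more than
1 mm beyond the frame's nominal surface (bare sinus wall in the
interleaflet triangles, large roots relative to the chosen size) and in
the gap channels flanking calcium nodules — exactly the pathways the
cohort statistics probe. Stiffer tissue can only reduce local expansion
(a tested monotonicity).

## Sealing analysis

For every deployed skirt element: centroid, 3D area and outward normal are
computed, a ray is cast along the normal against the deformed anatomy, and
the first hit yields the distance and the region attribution
(`element_distance()`). If no triangle is hit within `max_ray_length`, the
nearest surface point is used and flagged; if even that is farther, the
element is `UNRESOLVED` and later absorbed into the nearest resolved
region by angular proximity (reported; < 5% on synthetic cases).

Classification is strict: apposed iff distance **< 1 mm**; exactly 1 mm is
malapposed. `summarize_sealing()` sums element areas on the deformed 3D
skirt per region (LVOT, interleaflet triangles, leaflets); the ascending
aorta is quantified but excluded from all totals and percentages, which
makes the three-region sums reproduce the published table arithmetic. The
2D unrolled map (`project_skirt_2d()`) is reporting-only — areas always
come from the 3D elements, avoiding projection distortion.

The surrogate PVL grade thresholds (10% and 25% total malapposition for
none-or-trace / mild / moderate) are calibration constants of this package
chosen to reproduce two published anchor cases (4.4% ↔ grade 0, 20.9% ↔
grade 1); they are configuration, not clinical values.

## Frame metrics

`cross_section()` interpolates each sector column at a requested height and
orders the points angularly; `measure_section()` returns the maximum
diameter (max pairwise distance), minimum diameter (minimum convex-hull
width via rotating calipers), perimeter and shoelace area. The four
standard device levels (ventricular end, nadir, central coaptation,
commissures) default to height fractions 0.02/0.15/0.45/0.70 — the exact
axial definitions are device-specific supplementary material not available
here, so the fractions are configuration. Because no post-operative imaging
exists for synthetic anatomy, "observed" frames are predicted frames plus a
systematic bias and seeded noise (`perturb_measurements()`), explicitly a
stand-in that makes the comparison stage (`compare_frames()`: mean
difference, SD, R²) testable.

## Statistics

All tests are two-sided. `pooled_t_from_summary()` implements the pooled
two-sample t directly from mean/SD/n triples so that comparisons published
only as summary tables can be checked; it reproduces a raw-data
`t.test(var.equal = TRUE)` exactly. The published analysis names a "paired"
t-test, but the compared groups have unequal sizes (26 vs 17), so pairing
is impossible; the pooled two-sample form reproduces the printed p-values
(0.195, 0.987, and 0.030 to within one unit in the last printed digit —
the residual discrepancy is the 1-decimal rounding of the published
summaries), which is the justification for this reading.

`mann_whitney()` enumerates the full permutation distribution of U when
`n1 + n2 ≤ 20` without ties (two-sided: labelings at least as extreme as
observed), otherwise a tie-corrected normal approximation with continuity
correction. `fisher_exact_2x2()` uses the minimum-likelihood two-sided
convention (sum of same-margin tables with probability ≤ observed), which
reproduces the published 0.376 and 1.000.

`group_summary()` builds the published table shape (BAV0 / BAV1 / pooled
BAV / TAV columns, BAV-vs-TAV p per row), gating the t-test on Shapiro-Wilk
normality at α = 0.05 in both groups (the source states only "depending on
the variable distribution"; this is the conventional gate) and flagging the
Mann-Whitney rows. `univariate_screen()` retains candidates at p < 0.1
(strict), and `stepwise_lm()` runs forward entry at 0.05 / backward removal
at 0.10 — conventional thresholds, since only the 0.1 screening rule is
stated — iterated to a fixed point, deterministic given column order, with
collinear candidates dropped.

## Numerical choices

* Ray casting: Möller–Trumbore vectorised over triangles with a z-window
  prune; tolerance 1e-9 on the ray parameter; the test oracle vectorises
  over rays per triangle instead, so the two routes are independent.
* Apposition threshold boundary: `distance == threshold` is malapposed.
* Mesh resolution default 96 × 60 (≈ 11.5k triangles): keeps the
  brute-force oracle comparisons and a 43-patient cohort run in the
  minutes range on one CPU (the cohort sweep in the test suite and the
  acceptance script each complete in about two to four minutes).
* Convergence: pressure-imbalance residual ≤ 1e-6 MPa; tolerated
  penetration ≤ 0.05 mm against a rigid wall.
* Degenerate inputs: zero-variance statistics error or report p = 1 by
  stated convention; empty cohort groups mark rows not-computable; skirt
  quads that collapse during crimp fall back to radial normals.
* Binary STL stores float32, so its round trip is exact only to ~1e-5 mm
  at aortic coordinates; ASCII STL and PLY round-trip to 1e-6.

## Limitations

Per-node equilibrium cannot transmit hoop forces between struts, so frame
eccentricity is driven purely by local anatomy; LVOT malapposition from
eccentric or tilted deployment is under-represented. Tissue is linear
elastic with a first-order compliance update, leaflets are wall bands
rather than free shells, and no hemodynamics or regurgitant volume is
computed — the malapposition percentage is a geometric surrogate. Cohort
findings are statements about the synthetic generator's assumptions, not
about patients.
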