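---
title: "Reconstructing trabecular microstructure from low-resolution bone density images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing trabecular microstructure from low-resolution bone density images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(trabrec)
```

## The problem

Clinical bone images resolve density at roughly 600 µm per pixel — an
order of magnitude too coarse to see individual trabeculae, whose struts
are 100–300 µm thick. Yet trabecular architecture, not just average
density, determines much of a bone's strength. `trabrec` reconstructs a
plausible 50 µm-scale microstructure from a 600 µm 2D density image by
exploiting the physiological principle that bone adapts its architecture
to its mechanical environment (Wolff's law): among all fine-scale
structures consistent with the measured coarse-scale density, the one
bone itself would build is (to first approximation) the mechanically
stiffest. That turns resolution enhancement into a topology optimization
problem.

## The model

Each low-resolution (LR) pixel is subdivided into an n × n block of
high-resolution (HR) elements (n = 12 takes 600 µm to 50 µm). On a
structured grid of square bilinear plane-stress elements, relative
density ρ maps to elastic modulus by two laws:

* **Design (micro) elements** inside the region of interest (ROI) follow
  the SIMP power law `E = ρ^γ E0` with `γ = 3` and `E0 = 15` GPa.
  Penalization makes intermediate densities inefficient, so the
  optimizer segregates material into discrete struts.
* **Non-design (continuum) elements** elsewhere follow the piecewise
  BMD–modulus regression
  `E = 0.3044 (2ρ)^1.49 E0` for `ρ ≤ 0.84` and
  `E = 0.1908 (2ρ)^2.39 E0` above, continuous at the break point and
  equal to `E0` at full density. Poisson's ratio is 0.3 throughout.

The design problem minimizes the weighted multi-load compliance

    f(ρ) = Σ_j c_j · ½ u_jᵀ K u_j

over the HR design densities, subject to a density-deviation constraint
that preserves the patient-specific information of the input image. The
deviation is measured at the continuum level: writing `m_b(ρ)` for the
mean HR density over the parent LR pixel `b` and `ρ0_b` for that pixel's
measured density,

    g(ρ) = (1/N_LR) Σ_b (m_b(ρ) − ρ0_b)² ≤ ε,   ε = 0.01.

This reading — block means rather than per-HR-element deviations — is a
deliberate modelling decision. A per-element deviation bound of the same
magnitude mathematically excludes near-binary fields altogether (a 0/1
field deviates from a mid-valued target by ≈ 0.25 mean-squared, 25× the
budget), which contradicts both the intent of preserving *continuum*
information and the observable fact that compliance-driven remodeling
produces discrete trabeculae. The block-mean form preserves exactly the
quantity the LR image measures while leaving within-pixel redistribution
free, and the penalized objective then binarizes it.

## The two reconstruction routes

**Conventional (global) mode** refines the whole image, routes material
laws as above, and evaluates compliance on the full refined global model
under the physiological loads at every design update. It is the
reference method: the ROI sees exactly the stress state transmitted by
its anatomical surroundings.

**Localized mode** first estimates the loads the surroundings exert on
the ROI, then discards the surroundings:

1. the LR global model is solved under the global loads;
2. the displacements of the single node layer on the ROI perimeter (the
   *cut boundary*) are prescribed on an LR model of the ROI alone, and
   the resulting reactions are read off. This is static condensation in
   operational form: the reactions equal
   `K'cc Dc − K'cl Kll⁻¹ K'lc Dc`, the forces the eliminated exterior
   transmits through the boundary, exactly (linear elasticity). The test
   suite verifies both the algebraic identity against an explicitly
   formed Schur complement and the resulting interior-field match to
   1e-6 after removing rigid motion;
3. the estimated nodal forces are lifted to the refined boundary and the
   small localized model alone is optimized. The lifted load set is
   self-equilibrated, so three pinned corner DOFs suffice to remove
   rigid-body modes; their reactions stay at rounding level.

Because the loads are estimated once at LR granularity, the localized
boundary sees a slightly different (coarser) load pattern than the
embedded boundary of the global run. This is an inherent feature of the
method, visible as extra microstructure along the cut boundary, and the
package's validation quantifies exactly how much it matters.

Each LR nodal force is lifted to the refined cut boundary as a linear
hat over its tributary boundary stretch — the consistent nodal loads of
a piecewise-linear traction at LR granularity. Mapping each force to the
single coincident HR node instead concentrates it into a point load
whose artificial singularity grows with n; the hat mapping preserves
per-node resultants (hence self-equilibrium) while keeping the load's LR
resolution.

## Numerical machinery

* **FE core.** Square bilinear plane-stress elements (2 × 2 Gauss),
  sparse assembly through a precomputed triplet-to-CSC map so that only
  `K@x` changes between design updates, CHOLMOD Cholesky with symbolic
  reuse, and a Jacobi-preconditioned conjugate-gradient fallback above
  5 × 10⁵ free DOFs (tolerance 1e-8).
* **Exact exterior condensation in global mode.** Only ROI moduli change
  during optimization, so the fixed exterior is condensed onto the cut
  boundary once (Schur complement via a factorized exterior block), and
  each design update solves an ROI-sized system plus a dense boundary
  coupling. This is algebraically identical to solving the full refined
  model — a test asserts equality to 1e-7 against the full-solve path —
  and cuts the per-iteration cost of a desk-scale conventional run by
  roughly an order of magnitude.
* **Optimizer.** A single-constraint Method of Moving Asymptotes with
  the standard asymptote rules (initialization 0.5 × range, adaptation
  0.7/1.2, move limit 0.2) and an exactly solved dual (bisection on the
  one multiplier). Written in-package: no MMA implementation exists in
  the installed R ecosystem.
* **Regularization.** Cone-weight density filtering (radius in HR
  element widths) sets the minimum strut scale and suppresses
  checkerboards; a smoothed Heaviside projection (η = 0.5) sharpens the
  filtered field toward 0/1. The default radius of 2.5 elements gives
  struts about 4–5 elements wide — the ≈250 µm trabecular scale at
  50 µm resolution — which also keeps thickness statistics away from
  the sub-pixel jitter that dominates them for 2-element struts.
* **Continuation, on schedules that depend only on the iteration
  count** (hence identical for both modes): the SIMP exponent ramps
  1 → 3 over the first 60 iterations — at γ = 1 the micro law has
  continuum-comparable stiffness, so the force-driven localized model
  and the displacement-embedded global ROI start from matched stress
  states — the projection steepness β doubles from 1 to 16 as the
  penalty settles, and the move limit halves periodically afterwards so
  the design-change criterion (max |Δρ| < 0.01) can engage. Convergence
  is only declared after all schedules have settled; stopping earlier
  would freeze an unpenalized design.
* **Objective scaling.** MMA subproblems see the compliance gradient
  scaled to O(1). The scale is computed from the ROI interior (one LR
  block in from the cut boundary), where the two modes' stress fields
  coincide, so both modes take the same trajectory; the scaling leaves
  the KKT point unchanged.

## The phantom

No suitable public 2D proximal-femur density image exists at this
resolution, so the package generates one. The outline is a smooth union
of four primitives (head disc, neck corridor, greater-trochanter lobe,
shaft corridor) in a 94.2 × 104.4 mm domain (or 47.1 × 52.2 mm at the
half-scale "desk" setting); densities comprise a 1.2 mm cortical shell
(ρ = 0.95), smooth regional cancellous levels (head ≈ 0.5,
intertrochanter ≈ 0.3, neck ≈ 0.1 background), densified bands along
the principal compressive (head-to-calcar, ≈ 24° from vertical),
tensile and secondary trajectories, and two noise scales: a smooth
correlated field (σ = 0.04) and independent per-pixel texture
(σ = 0.15) emulating partial-volume averaging of unresolved trabeculae
within each 600 µm pixel. The texture matters: it is what gives the
reconstructed fields many distinct trabeculae rather than a few broad
bands, and real LR images of cancellous bone are conspicuously granular
for the same reason. The seed fully determines the phantom.

What the phantom does *not* emulate: anisotropic partial-volume
correlations, cortical thinning with age, marrow heterogeneity, imaging
noise spectra, or any patient-specific anatomy. Passing the validation
suite therefore shows that the localized method agrees with the
conventional one on a realistic *class* of inputs — not that either
reproduces any particular patient's microstructure.

Three daily-activity load cases act on the phantom (one-legged stance,
abduction, adduction), each pairing a hip-contact force on the femoral
head arc (2317/1158/1548 N at 24°/−15°/56° from vertical) with an
abductor force on the trochanter arc (703/351/468 N at 28°/−8°/35°),
weighted 0.6/0.2/0.2 by daily loading cycles. Forces are distributed as
a cosine profile over a 60° surface arc, nodal forces parallel to the
load axis and normalized so the resultant is exact; the distal shaft
cut is fully fixed.

## Morphometry

Reconstructions are compared by standard 2D trabecular indices on the
field binarized at 0.5: BV/TV (area fraction), Tb.Th and Tb.Sp (mean
local thickness of the bone and marrow phase, largest-inscribed-disc
definition computed from the Euclidean distance map at quarter-pixel
radius resolution), Tb.N = (BV/TV)/Tb.Th (plate model; its internal
consistency is regression-tested against an 18-row reference table of
printed index triples), and the primary alignment angle. Alignment is
measured as the energy-weighted orientation of the dominant peak of the
local structure-tensor orientation distribution (Scharr gradients, whose
orientation bias is ≤ 0.15° vs ≈ 1.3° for plain central differences);
using the peak rather than the whole-field tensor average keeps the
measurement pinned to the primary trabecular group when secondary
groups cross it, which is exactly the situation in the intertrochanteric
region. Tb.Sp is measured directly, not derived from Tb.N; BV/TV
differences are reported in percentage points, the other indices as
relative errors.

## Validation at desk scale

The shipped validation (`scripts/acceptance.R`, mirrored by the
acceptance tests) runs both pipelines on the half-scale phantom at
n = 6, iteration cap 300, on three ROI presets — femoral head (16 × 16
LR px), intertrochanteric region (16 × 16) and femoral neck (8 × 8,
its smallest size) — and reports the maximum BV/TV deviation, the
maximum dense-ROI and sparse-ROI index errors, and the maximum
alignment-angle difference between the two methods. These problem sizes
(9 216–82 944 HR elements per run) were chosen so the whole suite
completes in minutes on a laptop while preserving every structural
feature of the method: material-law routing, condensation, LR-granular
boundary loads, and morphometric comparison.

Two desk-scale caveats follow from the geometry. The cut-boundary
artifact zone is about one LR block deep regardless of scale, so it
occupies a 2–4× larger *fraction* of a desk-scale ROI than of a
full-scale one — method-agreement numbers here are conservative
relative to full scale, and the sparse neck ROI (where a single strut
added or removed at the boundary moves every index) is expected to be
the worst case. And with struts only a few HR pixels wide, sub-pixel
width differences translate into several percent of Tb.Th.

## Known limitations

* 2D plane stress only; the formulation extends to 3D but this package
  does not.
* Loads are estimated once and held fixed; no re-estimation as the ROI
  stiffness evolves during optimization.
* Rectangular, non-overlapping ROIs.
* The constraint preserves LR block means; it does not forbid
  physiologically implausible within-block arrangements beyond what
  compliance minimization itself disfavors.
* Alignment is undefined (returned as NA with a warning) for fields
  whose averaged structure tensor has an eigenvalue ratio below 1.05.

## A worked example

```{r example, eval = FALSE}
ph <- femur_phantom(width_mm = 47.1, height_mm = 52.2, seed = 7)
roi <- roi_preset(ph, "head", 16)
ctrl <- recon_control(max_iters = 300)

conv <- reconstruct(ph, roi, mode = "global", n = 6, control = ctrl)
loc <- reconstruct(ph, roi, mode = "localized", n = 6, control = ctrl)

compare_morphometry(morphometry(conv), morphometry(loc))
```
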