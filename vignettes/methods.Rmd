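---
title: "Multiscale finite-element analysis of cerebrovascular loading: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale finite-element analysis of cerebrovascular loading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific question

`vascufem` studies how mechanical loading of brain tissue during a
controlled cortical impact (CCI) translates into axial forces in the
embedded cerebral vasculature, and how the *anatomy* of that vasculature —
specifically the angle between a vessel and the local principal direction
of stress or strain in the parenchyma — shapes the distribution of those
forces. The package provides the full desk-scale chain: a calibrated
synthetic angioarchitecture generator, voxel-based hexahedral meshing with
embedded vessel beams, an explicit dynamic solver with a hyper-viscoelastic
tissue law, a refined-submodel (microscale) stage, vessel-stress mapping
with exceedance-area quantification, and the direction/correlation/ROC
statistics that constitute the headline analysis.

Everything runs from code: no imaging data is required, and the
`analysis/` scripts walk the complete pipeline on a demonstration block.

## Synthetic angioarchitecture

The generator emulates the statistical structure of a reconstructed rodent
angioarchitecture: vessel diameters between 10 and 100 µm with mean
17.85 µm, and a vascular volume fraction of 5.4%.

* **Diameter law.** Diameters follow a lognormal distribution truncated to
  [10, 100] µm. Only the range and the mean are emulated constraints, so
  the log-scale spread (`diameter_sdlog = 0.45`) is a package choice and
  the location parameter is solved numerically so that the *truncated*
  mean equals 17.85 µm exactly. Sampling uses the inverse-CDF on the
  truncated probability band, so the bounds are hard for every seed.
* **Topology.** A forest of tortuous, bifurcating trees is grown from
  random roots (segment length ~ N(60, 15) µm, bifurcation probability
  0.25 per step, branch angles ~ N(35°, 10°)), plus ~2% capillary
  cross-links between nearby nodes. Growth stops when the cumulative
  conical-frustum volume reaches the target fraction of the domain; the
  stop is applied mid-iteration so the overshoot is at most one segment.
* **Radii.** Nodal diameters are drawn iid from the calibrated truncated
  lognormal. A Murray-type radius decay (`murray_taper = TRUE`, exponent
  3) is available for morphological studies, but it cannot simultaneously
  honour the printed marginal diameter statistics, so it is off by
  default and documented as uncalibrated.
* **What it does not emulate.** Artery/vein identity, anatomical layering
  (pial vs penetrating vs capillary bed), spatially varying density, and
  vessel–vessel avoidance. Passing calibration tests therefore shows that
  the *marginal* diameter and volume statistics are right, not that the
  spatial organisation matches a real brain.

`network_stats()` treats each segment as a conical frustum between its two
nodal radii; the per-segment diameter is the mean of its two nodal
diameters. One printed statistic, the "mean vascular volume" of 6118 µm³,
does not state its averaging unit; the generator reports the per-segment
mean volume but deliberately does not calibrate against it.

## Tissue and vessel constitutive models

**Tissue.** Ogden hyperelasticity in principal stretches,
$\Psi = \sum_p \frac{\mu_p}{\alpha_p}(\lambda_1^{\alpha_p} +
\lambda_2^{\alpha_p} + \lambda_3^{\alpha_p} - 3)$, applied to the
*isochoric* stretches $\bar\lambda_i = J^{-1/3}\lambda_i$, with a
volumetric penalty $K(J-1)$. Rate dependence is a Prony series
$G(t) = \sum_i G_i e^{-t/\tau_i}$ convolved with the *deviatoric*
Green–Lagrange strain rate,
$S(t) = S^\infty + \int_0^t G(t-T)\,\partial_T E^{dev}(T)\,dT$,
integrated with the standard recursive exponential update (exact for
strain varying linearly within a step). Restricting the convolution to the
deviatoric part is the usual practice for nearly incompressible tissue;
the volumetric response is treated as elastic.

The sourced description defers the brain constants to supplementary
material that is not available here, so the shipped defaults are
*representative rodent-brain values at impact rates*, exposed through
`ogden_prony_material()` and documented as package assumptions:
one-term Ogden µ = 1.2 kPa, α = 4.5 (ground-state shear modulus
µ₀ = Σµα/2 = 2.7 kPa), Prony G = {2.4, 1.2} kPa with τ = {0.1, 1.0} ms,
density 1040 kg/m³.

**Bulk modulus.** Brain tissue is nearly incompressible (true K is of
order 2 GPa). The default penalty modulus is K = 10⁵ kPa (100 MPa,
effective Poisson ratio ≈ 0.49999). The value is chosen so that the
volumetric stiffness exceeds the *vessel* modulus by more than two orders
of magnitude — the separation that produces the paper-level mechanism
dissociation (hydrostatic pressure produces almost no vessel stress, shear
does) — while keeping the dilatational wave speed, and hence the explicit
stable time step, practical. A softer choice (effective ν ≈ 0.4999,
K ≈ 12 MPa) would leave the tissue only ~9× stiffer in bulk than the
vessels and blur that dissociation.

**Vessels.** Linear elastic, axial only: σ = E ε with tension positive.
Defaults transcribe the printed constants: E = 1.4 MPa, ν = 0.38,
ρ = 104 kg/m³. The density is suspiciously low for soft tissue (plausibly
a slip for 1040) but is kept as printed and flagged in the constructor
documentation; vessel inertia is negligible at these volume fractions
either way. 200 kPa of axial stress corresponds to 14% axial strain under
this law — the threshold-strain equivalence used when mapping stress
exceedance areas.

## Meshing

* `voxelize()` turns a thresholded voxel mask into 8-node hexahedra, one
  per coarse cell of `coarsen`³ voxels; a cell becomes an element when at
  least half of its voxels are foreground (majority vote, unbiased in
  volume). Nodes are merged exactly through integer lattice keys. The
  sourced description of the coarsening ("a single solid element
  represents 4 voxels", elements of 48 µm from a 5.92 µm stack) is not
  internally consistent, so the coarsening factor is an explicit free
  parameter.
* `smooth_outer_surface()` applies Laplacian smoothing restricted to the
  exterior surface, rescaling the boundary about the centroid each sweep
  to hold the total volume; it aborts if a Jacobian turns non-positive or
  volume drifts beyond 5%.
* `discretize_network()` splits each centreline segment into
  ⌈L/max_len⌉ beams with linearly interpolated nodal radii; summed length
  and frustum volume are conserved to round-off.
* `extract_submodel()` refines the parent elements inside an axis-aligned
  box `refinement`³-fold, clips beams to the box with radius-interpolated
  cut nodes, and stores for every refined node its parent element and
  trilinear natural coordinates. Refined elements below the 20 µm floor
  trigger a warning unless explicitly allowed.

## Explicit dynamic solver

Central-difference time integration with lumped mass, in SI units
internally (µm/ms/kPa at every interface). Hexahedra use one-point
integration with two layers of hourglass control — viscous (coefficient
0.05, resisting modal velocity) and stiffness (coefficient 0.05, giving
the four zero-energy modes a restoring force; the hourglass vectors are
orthogonalized against all affine fields, so rigid motions and
homogeneous deformations are never penalized). A shock bulk viscosity
(linear 0.06, quadratic 1.5, compression only) regularizes crushing under
the impactor; its volumetric strain rate is evaluated from the velocity
gradient tr(Ḟ F⁻¹), which is smooth, rather than from per-step
differences of J, which would amplify integration ringing as 1/dt.

**Time step.** `stable_timestep()` returns the classical estimate
0.9 · min(h)/c with c the dilatational wave speed. Two refinements govern
the actual integration: (i) the worst discrete mode of the one-point hex
lattice oscillates at √6·c/h, so the base step is scaled by √(2/3);
(ii) compression stiffens the volumetric push-back K(J−1)J C⁻¹ like
1/λ²min in the squashed direction, so the step is adapted on the fly
proportionally to the running minimum eigenvalue of C (floored at 2% of
the base step). Steps always land exactly on the output sampling times
(0.01 ms by default).

**Embedded vasculature.** Beam nodes carry no independent degrees of
freedom: their motion is slaved to the host hexahedron through trilinear
shape functions (inverse isoparametric mapping solved by Newton iteration
to a 10⁻⁹ µm round-trip residual, ties at element faces broken to the
lower element id), and beam internal forces are distributed back to the
host nodes with the transposed weights — action and reaction balance by
construction. Beams are axial (truss) members: the injury metric is axial
stress, and the bending stiffness of 5–50 µm vessels is negligible at
tissue scale. Because the beams are slaved, their stability contribution
is the frequency they add to host nodes (EA/L against the host mass), not
the bare beam wave speed — short capillary beams do not collapse the time
step.

**Contact.** The impactor is a rigid flat-tipped cylinder driven at
constant velocity to the set depth, with dwell and optional retraction.
Contact is a nodal penalty (stiffness 0.05 K·h by default) with viscous
damping at 20% of critical and a no-adhesion clamp; the tip rim carries a
quarter-torus fillet one element wide, which both reflects real flat-tip
geometry and spreads the edge shear that a perfectly sharp rim would
concentrate into a single element column. The 2 mm impact depth is the
emulated experimental setting; the impactor radius (2.5 mm), velocity
(4 m/s) and dwell are configuration values documented as assumptions.

**Boundary conditions.** The desk-scale model is a tissue block with a
fixed bottom face and free lateral faces (configurable:
`fixed_sides = TRUE` gives skull-like lateral confinement). This is a
deliberate, documented divergence from a whole-head model with skull and
CSF: it preserves the loading physics the vessel analyses need at a size
that runs on a desk.

**Energy ledger.** The solver tracks kinetic energy, internal work and
external work (contact + constraint reactions); the balance drifts by
less than 2% on impact runs and is asserted in the tests. Momentum is
conserved to round-off for free blocks, beams included.

## Submodelling

`run_submodel()` prescribes the box-boundary node displacements
interpolated from the parent history — trilinear in space through the
stored natural coordinates, linear in time between output frames — and
integrates the interior without contact. The patch property holds: with a
homogeneously deforming parent, the interior reproduces the parent field
to < 10⁻⁶ µm at refinement 1 and 2. Two practical notes from the
verification: the test uses the hyperelastic material (per-element
viscoelastic overstress from the transient otherwise keeps forcing the
interior until the slowest Prony term has relaxed), and the settle uses
light mass damping (≈1.5 ms⁻¹) with a hold phase — heavy damping is
counterproductive because the softest modes then relax at ω²/c rather
than ω.

## Vessel-stress mapping and exceedance areas

`map_vessel_stress()` assigns each tissue element the maximum over
neighbourhood beams of the maximum-over-time axial stress. The
neighbourhood is a sphere of one element edge length around the element
centroid (the smallest radius guaranteed to capture in-element beams) in
the *undeformed* configuration, which keeps the assignment stable and
reproducible. Only tensile peaks enter the injury map by default, because
the downstream comparison is against blood–brain-barrier damage, which
tensile stress predicts; a signed mode is available. Elements with no
neighbourhood beam are marked explicitly rather than zeroed.
`threshold_area()` intersects the map with the element layer nearest a
coronal coordinate (mid-plane by default) and reports exceedance areas for
150/200/250/300 kPa; `regress_area_vs_observation()` provides the OLS
comparison against per-sample observations. The regression *operation* is
part of the package; reproducing the experimentally observed correlation
values would require the animals' histology and is out of scope.

## Direction and correlation statistics

`build_records()` emits one row per beam element and output frame: axial
stress, current direction (from the slaved end-node positions), and the
host element's stress and strain tensors with their first principal
values, deviatoric first principal values (the deviatoric tensor shares
eigenvectors, eigenvalues shift by the hydrostatic part), and the
sign-free angles arccos|d·p| to the first principal stress and strain
directions. "Neighbouring tissue" of a beam is its midpoint's host
element — the minimal reading consistent with the embedded coupling.
Strain is Green–Lagrange (the solver's native measure).

`correlation_suite()` reports Pearson R with a two-sided p, the
first-order partial correlation from the covariance identity, and OLS on
optionally log₁₀-transformed responses (non-positive values are dropped
with a reported count; base 10 chosen where "logarithm" was unspecified).
No multiple-testing correction is applied, matching the reporting style
it emulates; this is a deliberate, documented choice.
`tension_compression_roc()` labels records tension/compression by the
sign of the axial stress (exact zeros excluded), scores them with the
negated angle, computes the AUC by the rank statistic with ties counted
half, and bootstraps a stratified CI (2000 resamples, seeded).

## Problem sizes and numerical choices

The demonstration pipeline uses an 8 mm cube at 20³ elements (400 µm) with
a 500-segment vascular slab under the impact site, simulated for 2 ms — an
impact-depth-to-block-height ratio (25%) comparable to a 2 mm CCI on a
real rodent brain. Calibration checks use ≥10⁴ segments; unit tests use
1–6³-element blocks. These sizes were chosen so the full suite and the
pipeline complete comfortably on a single CPU while leaving the physics
(wave transit, crush, retraction ring-down) intact.

## Known limitations

* **Angle-based tension/compression discrimination is weaker at desk
  scale than in the emulated study.** On the demonstration CCI block the
  ROC AUC of the angle predictor is ≈ 0.67–0.72, whereas the emulated
  analysis reports 0.94–0.95. This is not an implementation artifact: a
  ceiling experiment that draws *ideal* fibres directly from the
  simulated strain tensors (labels sign(aᵀEa), predictor the angle to the
  first principal direction) reaches only ≈ 0.80 under this loading. The
  flat-punch compression of a free-sided block produces predominantly
  *oblate* stretch states (two tensile lateral axes, one compressed
  axis), in which the angle to the *first* principal axis is an
  ambiguous classifier — a fibre 80° from the first axis may lie near the
  second (tension) or near the third (compression). The homogeneous
  uniaxial validation run, where the state is prolate, reaches AUC ≈ 1.
  The directional *sign* structure (negative angle–stress correlation,
  stronger partial correlation, strong deviatoric vs weak total stress
  correlation) reproduces cleanly.
* One-point hexahedra with hourglass control are robust for this loading
  but not for arbitrary crush; element inversion terminates a run with
  the offending element and time.
* The synthetic network is statistically, not anatomically, calibrated;
  conclusions about specific vascular territories are outside what these
  simulations can support.
* The contact model is frictionless and nodal; it is adequate for the
  indentation kinematics studied here, not for sliding-dominated
  problems.
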