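---
title: "Wall stress and growth-rate mapping in dissected aortas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall stress and growth-rate mapping in dissected aortas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aortagrowth` is a desk-scale pipeline for studying whether acute
structural wall stress predicts where a dissected aorta will grow. It
chains five stages, each testable in isolation: synthetic dissected-aorta
geometry, a reduced-order lumen hemodynamics surrogate, forward-penalty
wall stress, registration-based growth-rate mapping, and random-slope
mixed-effects statistics. This vignette explains the models, their
assumptions, the tunable parameters, and the numerical choices, in that
order. No empirical claim is made here that the test suite does not
itself compute.

## 1. Synthetic dissected aortas

Patient imaging is not available to a desk-scale pipeline, so every
downstream stage is exercised on synthetic type B dissection geometry
with known ground truth. `make_dissected_aorta()` builds a "candy-cane"
tube: a semicircular arch (radius 35 mm by default) continued by a
straight descending limb, total centerline length 400 mm, outer radius
15 mm at the root tapering 25% distally — typical adult thoracoabdominal
dimensions. The dissection flap is a ruled chord surface spanning the
descending aorta (arclength 130–370 mm) whose edges lie on the outer
wall; a 180° chord places the flap through the lumen center, splitting
true and false lumens of equal sector area. Tears (fenestrations) are
circular holes in the flap — circular because only their connective role
matters to the flow surrogate; the defaults are a 5 mm proximal and a
4 mm distal tear, the classic entry/re-entry configuration. Optional
mural thrombus is a wedge attached to the false-lumen wall over an
angular sector and arclength span. A smooth seeded radius perturbation
(`radius_noise`) provides patient-to-patient anatomical variation.

The left-subclavian surrogate landmark is a stored arclength (97 mm by
default), chosen so that the 200-layer structured resampling puts it at
layer 49, the canonical landmark layer of the partitioning scheme. The
centerline is generated analytically with the scene; no centerline
extraction is needed because the generator controls it.

`grow_aorta()` produces follow-up geometry by scaling each cross-section
radius by a prescribed circumferential stretch (a `growth_field`), with
an optional rigid perturbation for registration tests. The generator is
a pure function of (spec, seed): identical seeds give byte-identical
meshes.

What the generator does *not* emulate: CT voxel data and segmentation
error, arch branch anatomy (branches exist only as outlet areas),
cardiac-phase effects (non-gated CTA is simply treated as systolic
geometry, the standard reading for non-gated scans), non-circular cross-section
pathology, and tear shapes beyond circles. Passing tests therefore
validate the computational chain — meshing, calibration, solvers,
registration, statistics — not robustness to real segmentation noise.

## 2. Structured surface, frames, regions

All spatial statistics live on a cylinder-topology grid of 200
circumferential layers × 50 nodes (`parameterize_surface()`). Layer *j*
lies on the cross-section plane at the *j*-th of 200 equally spaced
arclengths (cell-centered, so the end caps are never sliced); the 50
nodes sit at equal angles about the layer center, with the angular
origin fixed by projecting the global *y* axis onto the section plane —
a deterministic convention; any residual azimuthal offset between time
points is absorbed by the nonrigid registration. Cross-sections are
extracted by slicing mesh edges with the section plane; on arched tubes
a plane can also cut the far limb, so intersection points are clustered
by center distance and the near cluster kept. The layer center is
iterated to the mean of the resampled ring, matching the definition used
for diameters.

Local frames: radial = outward in-plane direction, axial = unit vector
between consecutive layer centers (the last layer copies the
penultimate), circumferential = axial × radial; the triad is
re-orthogonalized to 1e-8. The layer diameter is twice the mean
center-to-node distance — an averaging definition, deliberately not the
maximum chord, so it is rigid-motion invariant and robust to
non-circularity.

`partition_regions()` divides the 200 layers into 50 regions: 12 before
the landmark (ascending/arch), 38 from the landmark to the distal end
(descending). Boundaries come from rounding equally spaced fractional
boundaries, so region sizes within a block differ by at most one layer;
with the landmark at layer 49 every region has exactly 4 layers. Region
13 always starts at the landmark layer.

## 3. Reduced-order hemodynamics

The steady systolic flow field is a one-dimensional Poiseuille resistive
network (`solve_network()`): the true lumen is a chain of segments along
the centerline, the false lumen a parallel chain over the flap span,
tears couple the chains as short orifices (length = flap thickness,
radius = tear radius), and each outlet drains through its Windkessel
resistance to a zero venous reference. Effective lumen radii come from
sector areas, r = sqrt(A/π), with thrombus subtracting false-lumen area.
Blood viscosity defaults to 0.004 Pa·s (density 1060 kg/m³), standard
values, configurable. Wall shear stress is the Poiseuille closed form
4μQ/(πr³) per segment.

The calibration mathematics is the full clinical-imaging workflow:
total resistance = systolic pressure / systolic flow
(`total_resistance()`, mmHg·min/L); the turbulent 1/7 power-law inlet
profile fixes mean/peak velocity at 49/60 (`inlet_from_velocity()`, so
25 L/min ≈ 417 mL/s); outlet conductances are allocated proportionally
to branch cross-sectional area (`allocate_outlets()`) — conductance, not
resistance, because a literally area-proportional *resistance* would
starve large branches, contradicting the flow-splitting intent of
Murray's law; and `tune_total_resistance()` bisects a multiplicative
factor on the calculated resistance until the simulated arch pressure
(mean true-lumen pressure proximal to the landmark, the pre-landmark
block of regions) is within 2% of the measured systolic pressure. The
pressure–resistance map is monotone, so bisection terminates on every
solvable scene; the bracket is 0.1×–10× the calculated value.

This surrogate preserves pressure levels, calibration behavior, and the
true/false-lumen coupling mechanism. It does not model secondary flow,
jet impingement, or spatial WSS patterns beyond the 1-D profile — which
is one reason WSS enters the statistics only as a comparison predictor.

## 4. Forward-penalty wall stress

The wall is thin relative to the diameter, so its stress state is
approximately statically determinate: equilibrium with the lumen
pressure fixes the stress nearly independently of material behavior. The
forward-penalty method exploits this by assigning an artificially stiff
isotropic material — Young's modulus 5×10⁵ kPa for wall and flap,
2.5×10⁴ kPa for thrombus (preserving a 1:20 thrombus-to-wall ratio) — so
the image-derived geometry deforms negligibly (order 10⁻³ mm on the
cylinder fixture at 120 mmHg) and the computed stress approximates the
true stress under the unknown patient-specific constitutive law. Under
load control the linear solution scales exactly as 1/E: uniform
stiffness rescaling leaves stress unchanged to machine precision, which
the test suite asserts literally; regional ±50% perturbations
(`stiffness_sensitivity()`) change region-averaged maximum principal
stress by ≤10% on the dissected-tube fixture.

The solid mesh (`build_solid_mesh()`) extrudes the structured outer wall
along per-node radial directions: inward by 1 mm for surfaces enclosing
the true lumen and outward by 1 mm everywhere, giving a 2 mm true-lumen
wall and 1 mm false-lumen wall and flap — the acute-dissection
configuration in which flap + false-lumen wall reconstitute the intact
wall. One deliberate meshing choice: all components
share a single 0.5 mm transmural node spacing (true-lumen wall 4 hex
layers, false-lumen wall and flap 2 each) so the flap–wall junction is
node-conforming; a structured generator cannot reproduce the manual
transition meshing of interactive tools, and halving the transmural
resolution of 1 mm components is immaterial for membrane-dominated
stress. The flap sheet is extruded along the chord normal toward the
false lumen and attaches to the wall by sharing the junction surface
nodes along its chordwise edge lines. Thrombus is meshed with hexahedra
extruded inward from the false-lumen wall, sharing its surface nodes.

Elements are standard 8-node trilinear hexahedra with full 2×2×2 Gauss
integration and Poisson ratio 0.3; ν is configurable up to 0.49, where
assembly switches to selective reduced integration (volumetric term at
the element center) to avoid locking. The hybrid-incompressible element
of specialized commercial solvers is not reproducible in a generic assembler, and
static determinacy makes the stress insensitive to this choice — that is
what the sensitivity suite verifies. Boundary conditions: inlet and
outlet rim nodes fixed (end effects are excluded from region averages
within two layers of each end); the cylinder fixtures use axial end
constraints with minimal in-plane pins so the Laplace limit
(transmural-mean hoop stress = P·r/t, within 5%) is testable. Tractions
follow undeformed normals, consistent with negligible deformation;
pressures convert at 1 mmHg = 0.133322 kPa. Stress is averaged per
element over Gauss points and extrapolated to nodes by volume weighting;
`register_stress_to_structured()` then assigns each structured node the
value of the nearest solid node (lowest-index tie-breaking).

One consequence of uncapped ends worth knowing: pressure on the arch has
a net "bend thrust" resultant that bows the vessel slightly between the
clamped ends (a global mode of order 0.1 mm on the default geometry at
systolic pressure — four orders below the geometry scale, so the loaded
configuration is still effectively undeformed).

## 5. Growth-rate mapping by registration

Baseline and follow-up surfaces are first rigidly aligned by ICP
(`icp_align()`): nearest-neighbor correspondence (deterministic
lowest-index tie-breaking), SVD (Kabsch) update, and termination when
the average change of rotation angle and translation norm over the three
most recent iterations falls below 1e-4 and 5e-4. Badly misaligned scans
are handled by the manual-initialization fallback: restarts from ±30°
pre-rotations about each axis, keeping the lowest-residual result.

Nonrigid registration (`nonrigid_register()`) minimizes

  cost(μ) = D(Φ(T), S)/σ² + Σₖₗ μₖᵀ K_R(λₖ, λₗ) μₗ,

where D is the *full* squared varifold distance ⟨T,T⟩ − 2⟨T,S⟩ + ⟨S,S⟩
with Gaussian spatial kernel (width 20 mm) and squared-cosine
orientation weighting with facet-area weights, σ = 1, and Φ is a
single-step kernel displacement field u(x) = Σₖ K_R(x, λₖ)μₖ over
control points on a regular grid at the kernel width (20 mm) spacing,
pruned to within 1.5 spacings of the surface. Two choices deserve
explanation. First, control-point LDDMM costs are sometimes written with
only the cross term of the varifold metric; the full squared distance is
used here because the cross term alone is unbounded below and its
minimum is not at coincidence — a data term described as a distance must
vanish exactly at coincidence. Second, the geodesic flow integration of
control-point LDDMM is collapsed to a single step: serial aortic growth
produces modest deformations for which the one-step field preserves the
cost structure at a fraction of the compute; this is a fidelity
simplification, stated as such. The optimizer is quasi-Newton
(L-BFGS-B) with analytic gradients of both terms; non-convergence
within the iteration budget returns a flagged result with the final
cost. The data term is evaluated on a subsampled structured grid
(default every 4th layer, every 2nd node); the fitted momenta are then
applied to the full 200×50 grid, so the deformed template keeps
node-to-node correspondence with the baseline.

`growth_strain()` estimates the local surface deformation gradient at
each node from the structured 4-neighbor stencil (circumferential
neighbors wrap, axial differences are one-sided at the ends, the triad
is completed with the unit normal, i.e. no transverse stretch is
imputed). The circumferential logarithmic strain ln√(e_cᵀFᵀF e_c), with
e_c the baseline circumferential direction, divided by the elapsed years
gives the growth rate in %/year; negative values (shrinkage, e.g. under
false-lumen remodeling) are legitimate outputs. Degenerate stencils
yield NA and are excluded from region averages. The in-surface
estimator replaces the displacement-BC finite-element run sometimes used
for this step; for surface growth the two agree by construction of the
correspondence.

The clinically interpretable summary `avg_descending_growth()` is the
mean descending-layer diameter (landmark to layer 200) difference
divided by the elapsed years, in mm/year. Elapsed years are day
differences / 365.25; medians and IQRs use linear-interpolation
(type 7) quantiles — stated because IQR values depend on the
convention.

## 6. Statistics

Regional growth is modeled as
GR = β₀ + β₁x + b₀ₘ + b₁ₘx + ε, with independent per-patient random
intercepts and slopes (diagonal covariance — the reported quantities are
separate SDs with separate CIs and no correlation parameter) and the
predictor x being regional stress (kPa), WSS (Pa), pressure (mmHg) or a
0/1 thrombus indicator. `fit_lme()` estimates by maximum likelihood via
`lme4`/`lmerTest`; an SD estimated at the boundary is reported as 0 with
a singular-fit flag. Wald-t 95% CIs use Satterthwaite degrees of
freedom; profile-likelihood CIs are available for the random-effect SDs
(they are asymmetric, as variance-component CIs should be). AIC/BIC come
from the ML log-likelihood; a fixed-effects-only least-squares fit is
returned alongside for comparison. Optional variants add a quadratic
fixed term or a follow-up-time covariate.

The fixed-slope test is F = (β̂₁/SE)² with, by default, Satterthwaite
denominator degrees of freedom. The residual-df convention
(n − n_fixed − n_groups·n_random = 322 for a 9×38 design) is available
as an option but is *not* the default: with 9 patients and non-zero
random-slope variance, the slope's effective degrees of freedom are
close to the number of patients, and residual df inflate the type-I
error to roughly 8–9% at a nominal 5%. The Monte-Carlo acceptance test
(500 null replicates) checks the calibration of the default directly.

Thrombus mapping: a structured node is thrombus-covered when the
distance to the nearest thrombus node is below the node's local radius
(its distance to the layer center — the natural reading of the node's
"calculated radius"); a region is thrombus-occupied when its node
average is strictly greater than 0.5.

ML (not REML) is used throughout so that AIC/BIC comparisons across
models differing in fixed effects are valid.

## 7. The pipeline and its generative design

`run_pipeline()` chains the stages per patient: seeded scene →
calibrated network pressures → solid mesh → penalty stress → structured
stress map → generated follow-up → ICP + nonrigid registration → growth
map → region table; then cohort-level mixed-effects fits, per-patient
Pearson correlations, the paired true/false-lumen pressure comparison,
and the calibration report. Every stage is a pure function of (config,
seed): re-execution reproduces the tables bit-identically, which the
test suite asserts.

Two generative variants coexist deliberately. `make_cohort()` draws
regional growth from the full statistical model *including* the
region-level residual ε (default SD 10 %/year — no published estimate
pins the residual; this value reflects the spread of regional growth
rates around patient lines given intercept/slope SDs of 27.8 and 0.13
and typical 50–400 kPa stresses) and backs all Monte-Carlo statistical
checks. `run_pipeline()`, by contrast, grows the geometry with only the
smooth mean structure β₀ + β₁σ + b₀ₘ + b₁ₘσ evaluated on the patient's
own regional stress: a kernel-width-20 deformation model cannot
represent region-scale white noise, so injecting ε into the geometry
would make the truth unrecoverable by construction, and physical growth
fields are smooth at that scale. The residual scatter in pipeline fits
therefore reflects the measurement chain (registration, smoothing,
interpolation), which is the thing the pipeline is meant to validate.

A power note, so the statistics are not over-read: at the preset effect
sizes (β₁ = 0.095, slope SD 0.13, 9 patients) the fixed-slope test has
standard error ≈ 0.13/√9 ≈ 0.043 and therefore only moderate power
(roughly 45–55%) — a borderline-significant result is the *expected*
outcome at these effect sizes, not a deficiency of the estimator. The
sign of β̂₁ is recovered essentially always (≈99%); the unbiasedness,
CI coverage, and type-I calibration of the estimator are what the
Monte-Carlo acceptance tests assert.

## 8. Problem sizes and numerical conventions

Defaults used by the analysis scripts and tests (chosen as the package's
own desk-scale operating point): structured surface 200×50; solid meshes
24–40 circumferential × 32–60 axial columns with 4 transmural layers
(3–12k hexahedra; the Laplace fixture is 48×24×4); network of 100
centerline segments; registration data term on a subsampled grid of
~25×25 nodes with 40–150 L-BFGS-B iterations; Monte-Carlo batches of
200 replicates (500 for the null). Linear solves use sparse Cholesky
(`Matrix`); nearest-neighbor queries use blocked exhaustive search with
lowest-index tie-breaking. Indices are 1-based in all file outputs (each
file header states the convention); internal arrays are whatever R makes
natural. Pressure converts at 1 mmHg = 0.133322 kPa exactly.

## 9. Known limitations

Steady flow; no flap motion or fluid–structure coupling (the penalty
solve is one-way by design); resistive-only outlets (no compliance);
thrombus as an impermeable solid wedge; circular tears; single-step
kernel deformation rather than geodesic flow; no image-space validation.
These mirror the stated limitations of the modeling approach the
package implements, plus the substitutions (1-D network for 3-D CFD,
in-surface strain for FEA-driven strain) that make the pipeline run at
desk scale. Conclusions from synthetic cohorts validate the machinery,
not clinical effect sizes.
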