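---
title: "Methods: coupled canopy-airflow simulation and dynamic stratified porosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled canopy-airflow simulation and dynamic stratified porosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

canopyflow simulates what an air-assisted sprayer does to a cotton canopy:
a downward air jet bends leaves, opens the canopy, and changes the optical
porosity that governs how droplets penetrate to the middle and lower
foliage. The package couples a lattice-Boltzmann air solver to an explicit
thin-shell leaf solver through an immersed boundary, on a procedurally
generated plant, and measures per-layer windward area and porosity from
rendered projection images over time. This vignette records the models, the
numerical choices, and the limits of what the test suite demonstrates.

## The virtual plant

The plant generator reproduces field-measured cotton morphometry: a 130 cm
main stem divided into 20 segments, one straight fruiting branch on each of
nodes 5-20, and three leaf classes — ovate, three-lobed, five-lobed — mixed
20/55/25% with windward (planform) areas 4206.25, 7859.10 and 9823.00 mm².
The canopy is stratified by attachment height into lower (0-50 cm), middle
(50-90 cm) and upper (90-130 cm) layers; intervals are half-open `[lo, hi)`
with the top interval closed, so the layer labels always partition the leaf
set.

Only the class areas are published, not outlines, so the shapes are fixed
parametric families scaled exactly to the target area: an egg curve for the
ovate class and cosine-lobed polar curves `r = 1 + A cos(k φ)` with k = 3
or 5 for the lobed classes. Phyllotaxy is not published either; branches
follow an alternate spiral with a 137.5° azimuth increment plus seedable
jitter. Leaves per branch (default 3), petiole length (60 ± 10 mm) and
diameter (3 ± 0.3 mm) are configurable placeholders where the source data
stop. Everything is deterministic given `rng_seed`.

```{r}
library(canopyflow)
plant <- generate_plant(plant_spec(rng_seed = 1))
export_mesh(plant, "plant.stl")
```

## Air: D3Q27 lattice-Boltzmann BGK with a WALE closure

The fluid update is the single-relaxation-time BGK evolution

f_α(r + K_α δt, t + δt) − f_α(r, t) = −(f_α − f_α^eq)/τ + δt F_α

on the 27-velocity lattice, with the standard second-order equilibrium
(weights 8/27, 2/27, 1/54, 1/216; c_s² = 1/3), Guo forcing with the
half-force velocity correction, pull streaming, half-way bounce-back at
walls, a prescribed-velocity equilibrium inlet, and zero-gradient outflow.
A uniform Cartesian grid replaces octree refinement: at desk scale
(1.5 m cube, 32-64 nodes per axis) refinement buys nothing.

Air is isothermal with ρ = 1.225 kg·m⁻³ and μ = 1.7894×10⁻⁵ Pa·s (the
recorded operating temperature 289.35 K and molecular weight 28.996 g·mol⁻¹
are configuration metadata only). Gravity acts on the fluid as a body force
by default; its effect at 5-15 m·s⁻¹ over 1.5 m is a few percent on speed.

The subgrid closure is the wall-adapting local eddy viscosity (WALE) model,

ν_t = (B_w Δ)² (S^d:S^d)^{3/2} / ((S:S)^{5/2} + (S^d:S^d)^{5/4}),

with B_w = 0.325, Δ = the grid spacing, S the symmetric velocity gradient
and S^d the traceless symmetric part of g², g_ab = ∂u_a/∂x_b. The
denominator's 0/0 limit is guarded to zero, and ν_t vanishes identically in
pure shear and rigid rotation. The gradient g is taken by second-order
central differences: WALE needs the full tensor for g², which the
non-equilibrium second moment cannot supply — the moment-based strain rate
is kept as a diagnostic (`strain_from_nonequilibrium`). The effective
relaxation time is τ_eff = 1/2 + 3(ν_mol + ν_t) per node, recomputed every
step.

Unit scaling: the user picks the grid N, so dx = 1.5/N m; dt is chosen so
the inlet speed maps to 0.05 lattice units (well inside the low-Mach bound
of 0.1, which is checked at startup along with τ > 1/2).

Numerical caveat specific to this regime: molecular air viscosity at these
grids gives τ₀ ≈ 0.500005, so the flow is effectively inviscid and all
damping is the LES viscosity. An impulsive cold start of the inlet jet
excites odd-even oscillations that WALE, by design, barely sees. Coupled
runs therefore initialize the whole domain at the inlet velocity
(`init_flow = "established"`): the fan is treated as already running when
the 0-1 s deformation analysis starts, which matches how the structural
analysis window is defined. The uniform established state is an exact
steady solution of the discrete system and is verified to remain so to
within 1% in the suite. A quiescent start (`init_flow = "quiescent"`)
remains available for front-arrival studies — the jet front sweeping down
through the canopy is what makes the upper layer respond before the lower
one — and is numerically viable exactly when a canopy is present to absorb
the front.

## Leaves: explicit thin shells

Leaves are thin (sub-millimetre) so the published solid-element model is
replaced by triangle thin shells — a constant-strain-triangle
Saint-Venant-Kirchhoff membrane (plane stress) plus discrete-hinge bending —
with the published elastic constants E = 46.5 MPa, ν = 0.32,
ρ = 700 kg·m⁻³. Element and node counts of the original solid mesh are
explicitly not reproduction targets. Leaf thickness is not published; it is
the dominant stiffness sensitivity (bending rigidity ∝ t³) and defaults to
0.5 mm, exposed as a material parameter.

The hinge stiffness per interior edge e shared by triangles of total area
A₁+A₂ is k_h = k_b |e|²/(A₁+A₂) with plate rigidity
k_b = E t³ / (12(1−ν²)). This constant is calibrated analytically: for a
regular strip bent cylindrically, the rung hinges then reproduce the
continuum plate energy (k_b/2)κ² per unit area exactly (numerically 0.97
including boundary deficits); the often-quoted coefficient three times
larger triple-counts on such meshes. Two further discrete-bending facts
shape the defaults:

* boundary edges carry no hinge, so a cantilever clamped along a single
  node line is a free door hinge — clamps therefore fix two node columns
  (zero displacement and zero slope);
* on a grid whose diagonals all point the same way, the skew hinges exert a
  net twisting couple that softens bending by a factor 1.7-2; the
  benchmark strip uses a herringbone (row-alternating) split, which cancels
  the couple and converges to the Euler-Bernoulli tip deflection (3.8%
  error at 60×6 elements, the size the acceptance check runs).

Time integration is velocity-Verlet with mass-proportional damping
(default 5 s⁻¹, benchmark 25 s⁻¹) and a Courant bound
dt ≤ 0.4 h_min/√(E/ρ(1−ν²)) that `explicit_step` enforces. Rigid free fall
is integrated exactly, which the suite uses as a kinematics oracle. The
`cantilever_benchmark` compares against qL⁴/(8EI) with ν = 0 because the
closed form assumes uniaxial beam stress.

Constraints idealize attachments as rigid clamps: all stem and branch
nodes are fixed (the stem is a completely fixed boundary), petioles are
clamped at their base ring, and each leaf is clamped over a small basal
patch around its petiole junction. Leaf-leaf contact is not modelled.

## Coupling: direct-forcing immersed boundary

Each shell triangle is subdivided in barycentric space until its rest edges
are at most one lattice spacing; one Lagrangian marker sits at each
sub-triangle centroid, with barycentric coordinates and area fractions that
transfer exactly to the deformed state. Per fluid step: fluid velocity is
interpolated to the markers with the smoothed 3-point kernel (a partition
of unity on the lattice); the momentum correction that would bring the
fluid to the marker velocity is spread back as a Guo body force; minus that
momentum, converted to newtons, loads the shell nodes through the markers'
barycentric weights. Action equals reaction to round-off by construction,
which the suite audits per step. The structure then takes as many explicit
substeps as its stability bound requires (the fluid step is much larger
than the shell step). Frames are emitted every `output_interval`; the
standard cadence, 1 s in 200 intervals of 5 ms, gives exactly 200 frames.

This is loose (explicit) partitioned coupling: no sub-iteration, so
added-mass effects are controlled by damping and sub-cycling rather than
eliminated. Leaves are zero-thickness interfaces to the fluid (shell
thickness ≪ dx). The loop draws no random numbers — records are
deterministic given the configuration.

## Porosity from projection images

For each frame and canopy band the five-step procedure runs: (1) render the
band's leaves as an orthographic top-view projection (dark plant on white;
pixel-centre coverage); (2) binarize via 3×3 median filter, grayscale, Otsu
threshold (operators the source procedure names generically); (3) take the
outer contour as the convex hull of the foreground — computed over pixel
corners rather than centres, which removes the half-pixel rim bias (a
10×10 px block measures exactly 100 px²); (4) count foreground pixels times
the pixel area for the windward area A_i; (5) form the porosity.

The porosity definition is genuinely ambiguous in the source material: the
prose defines optical porosity as the void/contour ratio, while the printed
formula is P_i = A_i/S_i with A_i the leaf area. Both are implemented:
`optical` (1 − A/S, the default, matching the prose definition) and
`literal` (A/S, the printed formula); they are exact complements and every
output table carries both columns. Bands are either the three named layers
(leaves grouped by attachment) or ten canopy-relative-height slices
(triangles binned by current centroid height, so material moves between
bands as leaves deform). The t = 0 frame provides the no-wind baseline and
the dynamic variation is P(t) − P(0).

## Validation utilities

`sample_velocity` interpolates |u| trilinearly at probe points (probe
coordinates must be user-supplied; a 3-layer × 3-point smoke grid is
provided). `nmae` is mean(|s−m|)/mean(m)×100 — the normalization is not
printed in the source, so the commonest convention is the default with a
per-point alternative. `linear_fit` regresses measured on simulated (the
direction the published fit uses) via ordinary least squares. The published
validation numbers themselves (NMAE 7.5-20.7%, R² = 0.92) depend on
unpublished hot-wire measurements and are not reproducible; the module
reproduces the *method*, and the suite checks it against closed-form
oracles.

## Problem sizes and what the tests show

The suite runs scaled-down configurations chosen to finish in minutes while
still exercising every claim: Poiseuille at 64 nodes across the channel
(<1% profile error), a decaying vortex at 48³ (energy decay within 2% of
exp(−4νk²t)), mass conservation to 1e-10 over 1000 steps, the cantilever at
60×6 elements (<5% of beam theory), single-leaf coupled runs at 24³-32³,
and an end-to-end canopy run with the full 48-leaf plant at 40³ for 0.25 s
from a quiescent start. That end-to-end run reproduces two qualitative
signatures of the real system: upper-layer leaves cross a deflection
threshold before lower-layer leaves as the front arrives (the canopy opens
from the top, first crossings at 0.020/0.025/0.030 s for
upper/middle/lower), and band-mean airflow speed decays monotonically with
depth into the canopy (top band ~3.6 m/s down to ~3.0 m/s at the bottom in
that run); the monotonicity check carries a 2% slack for turbulent
fluctuation of the band means.

What passing does *not* show: the synthetic plant has simplified straight
branches, no bolls or flowers, rigid stem and branches, no leaf-leaf
contact, and placeholder petiole statistics; the fluid is a uniform-inlet
desk-scale LES without a validated wall model; porosity numbers for a
specific real plant depend on leaf placement the generator cannot know.
Absolute porosities printed for the original plant are therefore treated as
non-reproducible reference points, not targets — the package reproduces the
measurement pipeline exactly (verified on constructed masks) and the
dynamics qualitatively.
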