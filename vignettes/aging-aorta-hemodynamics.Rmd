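---
title: "Methods: reduced-order hemodynamics of the aging aorta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order hemodynamics of the aging aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aortapulse)
```

## What the package models

`aortapulse` studies how age-associated regional changes in aortic
geometry (caliber, length, tortuosity) and wall properties (thickness,
biaxial material stiffness, perivascular support) reshape the clinical
surrogates of arterial stiffening: pulse pressure (PP), cross-sectional
distensibility (D), foot-to-foot pulse wave velocity (PWV) and the cyclic
change in stored elastic energy (ΔW). The full 3D fluid–structure problem
is replaced by a distributed 1D model: this preserves the physics that
dominates the four metrics — compliant-tube wave propagation, tapering,
branching, peripheral reflection — at a cost of seconds per cardiac cycle,
while giving up 3D flow detail (secondary flow, wall shear distributions,
curvature losses), which none of the four metrics needs directly.

## The synthetic aortic tree and virtual aging

No geometry files ship with the package; the tree is built in code
(`build_baseline_tree()`). The trunk is parameterized by normalized arc
length `s` (0 at the root, 1 at the aorto-iliac bifurcation, the iliac
path continuing to about 1.27), with inner radius interpolating three
published station values (ascending, proximal descending, infrarenal
stations at s = 0.12/0.40/0.88) linearly in `s` and constantly beyond
them. Eleven branches and the two iliac chains attach at fixed
`s`-coordinates; a 1D model needs junction locations, not 3D angles.
Default take-offs, branch lengths and radii are literature-typical values
for a young adult male and are configurable; the baseline trunk length
(0.50 m root-to-bifurcation) can be overridden from a VTK centerline.

`age_geometry()` applies the virtual-aging steps: region lengths compound
geometrically per decade (ascending +3%, arch +7%, descending +5% per 10
years; geometric compounding is the unique rule consistent under
composition of aging steps), radii rescale so the three station values
match the target-age table exactly (scale factor interpolated in `s`,
branches following the nearest trunk factor), the straight-line
root-to-bifurcation distance shrinks 1% per decade (height loss) while
arc length is preserved — in 1D this only manifests as recorded
tortuosity, its hemodynamic cost being absorbed by the distal-resistance
calibration — and thickness follows the published table when wall
properties are assigned.

The inflow generator (`generate_inflow()`) emulates a measured aortic
root flow of which only the mean (5.79 L/min) and heart rate (60 bpm) are
prescribed. The shape family is a truncated-sine systolic lobe built from
two half-sines (ejection one third of the cycle, peak 30% into ejection,
i.e. ~100 ms, matching measured aortic flow acceleration), a 3%-volume
end-systolic reverse lobe, and zero diastolic flow; the sampled mean is
normalized to the target exactly. A symmetric single half-sine was
rejected: it puts peak flow at mid-ejection (~165 ms) and produces an
unphysiologically shallow initial pressure upstroke on which the
intersecting-tangent foot is ill-conditioned.

What the generator does *not* emulate: subject-specific 3D curvature and
branch angles, within-subject variability of branch anatomy, respiratory
and beat-to-beat variability, and the true measured inflow waveform.
Passing tests therefore certify the method pipeline under idealized,
population-averaged conditions — not subject-level prediction.

## Wall mechanics

The wall model has two operating modes. In the default *table* mode the
published in vivo linearized biaxial stiffness values (per age and
station) drive the simulation directly; circumferential stiffness,
thickness, MAP and external pressure interpolate linearly between
stations with constant extrapolation beyond them, through the iliacs.
Carotid and subclavian arteries receive an isotropic age-dependent
stiffness (defaults tuned to age-typical carotid wave speeds of ~6, 7.5
and 8.5 m/s; approximate and configurable); muscular and splanchnic
branches are age-invariant at the stiffness of the oldest abdominal
station, reflecting the evidence that muscular arteries do not stiffen
with age.

The *constitutive* mode serves users with four-fiber-family parameters: a
neo-Hookean matrix plus four Fung-type exponential fiber families under
incompressible membrane kinematics. `small_on_large()` linearizes the
biaxial response about the in vivo state (`K_θθ = λ_θ ∂σ_θθ/∂λ_θ` at
fixed axial stretch, and its axial counterpart), verified in the tests
against independent finite-difference linearization of the stress to
1e-5 relative error. The package deliberately does not fit fiber
parameters to experimental data; fitted parameters are inputs.

The axial stiffness `K_zz` is carried through the data model but does not
enter the tube law: the model resolves radial wall motion only, a known
limitation shared with the radial-tethering focus of the approach it
reimplements.

## Tube law and external tissue support

Wall and perivascular support act as parallel linear springs on the
radius, sharing the lumen load from a common zero-traction radius `r0`
(the wall-unloaded radius, obtained by linear extrapolation of the in
vivo state: `r0 = R − TP·R²/(K_θθ h)`). This gives

- area compliance `dA/dP = 2πr/(K_θθ h/R² + k_s)`,
- wave speed `c = √((K_θθ h/R + k_s R)/(2ρ))`,
- external pressure `EP = k_s (r̄ − r0)`, the support's share of mean
  pressure; `EP → 0` as `k_s → 0` and `EP → MAP` in the rigid-support
  limit.

Two numerical consequences are worth recording. First, the solver's tube
law is linear in *radius* (`P = P_ref + β(√A − √A_ref)`), the exact
reduction of the spring pair — not linear in area, which would double the
amplitude dependence of the wave speed. Second, because the support and
wall share a common anchor, the radius at MAP shifts by O(1%) when the
tuned `k_s` differs from the value implied by the published EP pattern;
station radii remain exact in the geometry itself.

The support is piecewise constant over three regions (ascending to
s = 0.25, thoracic to s = 0.66, abdominal beyond; arch branches inherit
the ascending values, lower branches the abdominal ones). The damping
coefficient `c_s` enters the momentum equation as a diffusion
`D_s = c_s r/(2ρ)` via mass conservation and is chosen by
`choose_damping()` as the smallest value (doubling search) for which
pressure energy above 20 Hz stays below 1% of pulsatile energy — then held
fixed so damping never masquerades as stiffness (the tests bound its PWV
effect at 2%).

## Numerical scheme

Interior nodes advance with the two-step Lax–Wendroff (MacCormack)
predictor–corrector; friction is the Poiseuille-profile resistance
`K_R = 8πμ/ρ` with flat momentum-flux profile (α = 1); blood density
1060 kg/m³ and viscosity 4.0 mPa·s. The time step is CFL-limited on the
reference wave speed with a 35% systolic-distension margin, plus the
explicit-diffusion bound when `c_s > 0`. Default node spacing is 1 cm
(short inter-branch trunk pieces get at least 4 nodes); halving it moves
root pulse pressure by < 0.5%.

Segment ends close with Riemann invariants `u ± 4c`. One detail is
essential under tapered, property-graded vessels: the invariant carried to
a boundary node is built from the adjacent interior node's *flow and
pressure*, mapped through the boundary node's own tube law. Expressed
naively in the neighbor's `(u, A)`, the invariant is biased by the
property gradient across one cell; in a trunk crossed by many junctions
the rectified bias accumulated into several mmHg of spurious mean
pressure gradient and percent-level mass leakage. With the `(Q, P)`
mapping, a spatially uniform state is exactly invariant: mean aortic
pressure matches the 0D prediction to < 0.5 mmHg and global mass balance
closes to < 0.1%.

Junctions enforce static pressure continuity (not total pressure;
junction losses are absorbed by the distal-resistance calibration, just
as tortuosity losses are) and conserve mass exactly by construction: the
parent flow is assigned as the sum of the solved child flows. Outlets are
three-element Windkessels integrated semi-implicitly and solved jointly
with the outgoing characteristic; the distal reference pressure defaults
to 0 (venous). Simulations start from a uniform diastolic estimate (root
MAP − 20 mmHg) at zero flow, run at least 6 cycles, and stop when the
maximum cycle-to-cycle nodal pressure difference falls below 0.4 mmHg
(0.05 mmHg in the verification fixtures).

## Metric conventions

All metrics are computed from the final recorded cycle as a clinician
would measure them, not from the tube law: PP is max − min pressure; MAP
uses the `P_dia + PP/3` formula (the time average is reported alongside);
distensibility uses equivalent circular diameters, reducing to
`(A_sys − A_dia)/(A_dia·PP)`; ΔW is `0.5·PP·(A_sys − A_dia)/A_dia`
(documented as a lower bound in the ascending aorta, which also stretches
axially over the cycle); PWV is centerline path over the
intersecting-tangent foot-to-foot transit time. The foot tangent is
evaluated on a 3-point-smoothed derivative with sub-sample quadratic
refinement, and the gradient search is restricted to the initial upstroke
(below half pulse amplitude): in the proximal aorta the
reflection-augmented late-systolic gradient can rival the initial one,
and without the restriction the foot hops between the two features,
making PWV erratic under small parameter changes. Segment metrics are
evaluated at the arc-length midpoints of the six anatomical segments,
with segmental PWV measured between segment end stations. Pearson
correlations use `stats::cor`; with 3 or 6 points the population- and
sample-normalization conventions coincide.

## Calibration

`tune_windkessel()` rescales every distal resistance by one common factor
so the steady 0D prediction `MAP = P_out + Q̄/Σ(R_prox,i + R_dist,i)⁻¹`
hits the age target exactly (solved, then verified by simulation to
< 2 mmHg); proximal resistances and compliances are untouched and outlet
flow splits move < 1% under aging-magnitude rescalings.

`tune_external_support()` fixes the regional support *pattern* from the
published external-pressure pattern (`k_s = EP·K_w/TP` at the ascending
and thoracic stations, zero abdominal) and bisects a single multiplier on
it until the aorto-iliac PWV matches the age-specific population
reference value (6.9/9.3/10.9 m/s) within 0.2 m/s, with at most 20
iterations; PWV is monotone in the support stiffness, so bracketing
converges. In table mode the published stiffness is held fixed; in
constitutive mode the wall is re-linearized at the updated transmural
pressure `MAP − EP` each outer iteration until assumed and computed EP
agree within 0.5 mmHg. If the target lies below the unsupported model's
PWV the support pins at zero with a warning — this occurs for the oldest
age group, whose published wall stiffness already propagates at the
target speed in this reduction.

## Problem sizes and runtime

The default tree meshes to ~210 nodes; a cardiac cycle takes ~9000 time
steps and a converged simulation 6–16 cycles, well under a second of
compute in the compiled core. The full three-age calibrated report,
including the Windkessel solve, damping search and support bisection,
completes in a few seconds; the verification suite uses the same sizes.

## Known limitations

- Peripheral Windkessel compliances are used exactly as published. Their
  sum (~3.4 mL/mmHg) implies outlet time constants of ~3 s, which damps
  diastolic decay and absorbs distal pulse energy; the model consequently
  under-predicts pulse pressure levels and, especially, distal PP
  amplification relative to the reference 3D results (whose own printed
  pressures imply a substantially smaller total compliance). The
  low printed proximal resistances at the visceral and iliac outlets
  (well below the local characteristic impedances) act in the same
  direction.
- Segmental foot-to-foot PWV in a clean 1D model tracks the local
  Moens–Korteweg speed, which rises monotonically along the trunk
  together with the prescribed stiffness; the near-zero spatial
  correlation between segmental PWV and stiffness reported for the 3D
  geometry is therefore not reproduced — that decorrelation is carried by
  3D geometric effects (curvature, branch ostia, non-circular lumens)
  outside a 1D reduction.
- ΔW omits axial stretching work (relevant in the ascending aorta);
  axial material stiffness does not enter the dynamics; no
  wave-intensity or augmentation-index analysis is provided.
- The carotid-to-iliac PWV depends on the carotid probe station and path
  convention (default: mid right common carotid, centerline path through
  the arch), which population studies do not standardize.
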