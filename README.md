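# aortapulse

Reduced-order pulse-wave hemodynamics of the aging human aorta.

Central-artery stiffening is both a driver and a marker of cardiovascular
risk, and it is routinely summarized by a handful of clinical surrogates:
carotid-to-femoral pulse wave velocity (PWV), central pulse pressure (PP),
cross-sectional distensibility (D) and, more recently, the cyclic change in
stored elastic energy (ΔW). These metrics average very different mixtures
of material stiffness and conduit geometry, and they evolve differently as
the aorta ages. `aortapulse` provides a desk-scale computational laboratory
for studying that divergence: it builds an idealized branched model of the
human aortic tree, ages it by prescribing population-averaged changes in
regional caliber, length, tortuosity, wall thickness and biaxial material
stiffness, simulates one-dimensional blood flow through the aged trees, and
computes all four stiffening metrics — with the clinical measurement
conventions, not their analytic shortcuts — together with their spatial and
temporal correlations against the prescribed circumferential stiffness.

It is intended for cardiovascular biomechanics researchers who want a
transparent, fully scriptable alternative to 3D fluid–structure interaction
for questions where wave physics, not 3D flow detail, carries the answer.

## Model core

Each vessel is a tapered elastic tube. Blood flow obeys the 1D equations

    ∂A/∂t + ∂Q/∂x = 0
    ∂Q/∂t + ∂(Q²/A)/∂x + (A/ρ) ∂P/∂x = −K_R Q/A + D_s ∂²Q/∂x²

with area `A`, flow `Q`, Poiseuille-profile friction `K_R = 8πμ/ρ` and a
viscous term from the support damping. The wall and its perivascular
support act as parallel linear springs on the radius, giving the tube law

    P = P_ref + β(√A − √A_ref),    β = (K_θθ h/R² + k_s)/√π

whose local wave speed is the Moens–Korteweg-type form
`c = √((K_θθ h/R + k_s R)/(2ρ))`. Here `K_θθ` is the in vivo linearized
circumferential material stiffness (obtained, for user-supplied four-fiber
constitutive parameters, by small-on-large linearization about the in vivo
state), `h` the wall thickness, `R` the in vivo radius and `k_s` the
external tissue-support stiffness. The tree is closed by a measured-mean
inflow waveform at the aortic root (5.79 L/min, 60 bpm) and a three-element
Windkessel (RCR) at each of the fifteen outlets. Interior nodes advance
with a two-step Lax–Wendroff scheme; junctions conserve mass exactly and
enforce static pressure continuity through Riemann invariants `u ± 4c`.

Two calibration loops mirror the study design the package reimplements:
distal Windkessel resistances are rescaled by a common factor so the steady
0D prediction of mean aortic pressure hits the age-specific target MAP, and
the thoracic external-support stiffness is bisected until the foot-to-foot
aorto-iliac PWV (intersecting-tangent transit time over centerline
distance) matches age-specific population reference values, with the
support damping held at the smallest value that suppresses high-frequency
oscillation.

## Worked example

```r
library(aortapulse)

run <- calibrate_age(40, damping = 100)   # full 40 yo calibration
print(run$support)
#> <support_state> aorto-iliac PWV 7.08 m/s (target 6.90, converged after 1 runs)
#>   k_s [Pa/m]: ATA 3.29e+05, DTA 1.38e+05, IAA 0
#>  station    s ep_computed_mmHg ep_assumed_mmHg
#>      ATA 0.12         7.065115               7
#>      DTA 0.40         1.959870               2
#>      IAA 0.88         0.000000               0

sol <- run$solution
aorto_iliac_pwv(sol)                      # 7.08 m/s
distensibility(probe(sol, s = 0.06))      # 3.56e-05 1/Pa
pa_to_mmHg(pulse_pressure(probe(sol, s = 0)))  # 47.6 mmHg root PP
```

The support state reports the converged regional support stiffness, the
achieved aorto-iliac PWV against its population target, and the external
pressure the support carries at each wall-property station (computed from
the simulated mean radial displacement) next to the value assumed in the
published wall linearization — at 40 the two agree to within 0.1 mmHg.
`age_report()` runs all three ages and collects the segment-wise metrics,
PWV summary and correlation tables in one object; `run_pipeline()` drives
the same computation from a YAML/JSON configuration and writes CSV/JSON
outputs with a provenance block.

## Layout

- `R/geometry.R` — baseline tree, virtual aging, inflow synthesis, VTK
  centerline I/O
- `R/wall.R` — four-fiber-family constitutive model, small-on-large
  linearization, tube law, wall-property field
- `R/solver.R`, `src/pw_solver.cpp` — 1D mesh assembly and the compiled
  time-stepping core
- `R/metrics.R` — PP, MAP, distensibility, intersecting-tangent foot, PWV,
  ΔW, correlation tables
- `R/calibrate.R` — Windkessel and external-support calibration loops,
  pipeline driver
- `R/io.R` — run configuration, outputs, provenance
- `vignettes/aging-aorta-hemodynamics.Rmd` — the methods vignette
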