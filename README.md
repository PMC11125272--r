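# kneerig

Forward-dynamic simulation of **patellar tracking and patellofemoral contact**
on a spring-actuated knee test rig after total knee replacement, with a
synthetic sensorized-rig data generator so that the entire pipeline is
testable without laboratory captures.

## The problem and the model

After a total knee replacement, whether the patella tracks the trochlear
groove of the femoral implant — or subluxates and dislocates — depends
sensitively on the alignment of the extensor mechanism (the Q angle). The
package simulates a bench model of this maneuver: a three-body leg (femur,
tibia–foot, patella) in which

* the femur is held at a spherical hip and the tibia hinges about the knee
  axis — these four angles (three hip, one knee) are **guided** by rheonomic
  drivers reconstructed from optical marker trajectories;
* the patella is a **free rigid body** coupled to the leg by two linear
  spring–dampers (patellar-tendon and quadriceps analogues, tension
  `T = k (l − l0) + c l̇`) and by unilateral normal contact between its
  spherical button and the femoral implant.

The equations of motion use an **augmented Lagrangian index-3 formulation in
mixed coordinates** (12 natural coordinates per body plus 4 relative driven
angles): with `M` the constant mass matrix, `Φ(q, t) = 0` the `m = 34`
holonomic constraints and `α` the penalty factors,

```
[M q̈] δm + [Φqᵀ λ* + Φqᵀ α Φ] δf = Q δf ,      λ*₍ᵢ₊₁₎ = λ*₍ᵢ₎ + α Φ ,
```

integrated by the Newmark scheme (trapezoidal rule, 1 ms step) with Newton–
Raphson corrections and mass-weighted **velocity/acceleration projections**
onto the constraint subspaces. Contact uses an analytic detector — the
implant surface is a bivariate quartic `z = P(x, y)` fitted by least squares,
the closest point found by damped Newton iteration — and the **Flores
continuous normal force model**

```
Fₙ = kₙ δᵖ [ 1 + 8(1−ε)/(5ε) · δ̇/δ̇₀ ] n ,
```

clamped at zero (no tensile contact). Static equilibrium initialization,
spring calibration, genetic-algorithm parameter refinement (±10 % bounds)
and Bland–Altman agreement reporting complete the toolchain.

## Worked example

```r
library(kneerig)

geom <- generate_rig_geometry("A")     # laterally displaced quadriceps spring
geom
#> <rig_geometry> configuration A; Q angle 4.55 deg; button at (0.054, 0.000, -0.390) m

sys <- build_leg_model(rig_config(geom))
sys
#> <mbs_system> 3 bodies, 40 coordinates, 34 constraints, 2 springs, 1 contact pair(s)
#>   bodies: femur, tibia, patella
#>   guided dofs: hip_z, hip_x, hip_y, knee_flexion

eq <- solve_static_equilibrium(sys)
tr <- simulate_guided(sys, generate_motion(),
                      settings = solver_settings(record_every = 10),
                      initial = eq)
tr
#> <mbs_trajectory> 501 recorded states over 5.000 s
#>   max |Phi|_inf = 1.5e-10, max Newton iters = 30
#>   dislocation events: 1 (first at t = 4.749 s)
```

The maneuver flexes the knee 35° → 90° → 45° → 90° → 10°; in configuration A
(femoral spring attachment displaced 20 mm laterally, a 4.55° larger
Q angle) the patella escapes the trochlear groove during the final extension
below 20° knee flexion; configuration B completes the motion without event.
`max |Phi|_inf` confirms the constraints hold to 1.5e-10 over all 5000 steps.

A complete synthetic dataset (marker CSV at 100 Hz with 0.5 mm noise, force
CSV, rig YAML) and the full pipeline — filter, reconstruct, equilibrate,
simulate, validate:

```r
td <- tempfile(); dir.create(td)
paths <- synthesize_dataset(td, configurations = "A", seed = 1)
res <- run_pipeline(list(markers = paths$A$markers, forces = paths$A$forces,
                         rig = paths$A$rig, output_dir = file.path(td, "out"),
                         configuration = "A", seed = 1))
res$report[, c("channel", "units", "bias", "loa_low", "loa_high")]
#>  channel units    bias loa_low loa_high
#>  contact     N  0.0200  -1.279    1.319
#>   tibial     N  0.0776  -0.465    0.620
#>  femoral     N  0.0312  -0.459    0.521
#>        X    mm  0.0376  -2.127    2.202
#>        Y    mm  0.2475 -14.096   14.591
#>        Z    mm -0.3039 -15.852   15.244
```

Simulated-minus-reference biases stay well inside the Bland–Altman limits of
agreement; the wide Y/Z limits for configuration A come from the dislocation
phase, where small timing differences between the reconstructed and the
reference motion displace the patella by centimeters. The same stages are
available from a shell via `exec/kneerig` (`synth`, `run-all`, `validate`,
`optimize`, `calibrate`).

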