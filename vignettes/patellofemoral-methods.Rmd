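---
title: "Methods: guided multibody simulation of patellofemoral contact on a knee test rig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guided multibody simulation of patellofemoral contact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical methods and the design
decisions behind `kneerig`, in the spirit of a methods section: what is
computed, under which assumptions, with which parameters, and what the tests
do and do not demonstrate.

## 1. The mechanical model

The leg is three rigid bodies. The femur can rotate about a fixed spherical
hip; the tibia–foot assembly hinges on the femur about the knee axis
identified by the two markers on the sides of the knee. Both are *guided*:
their four angles (three hip, one knee flexion) are rheonomic drivers that
follow splines of reconstructed (or synthesized) marker data. The patella is
a fully free six-degree-of-freedom body. It interacts with the leg through

* a tibial spring (patellar-tendon analogue) from the tibial tubercle to the
  inferior patellar attachment,
* a femoral spring (quadriceps analogue) from a proximal femoral attachment
  to the superior patellar attachment — deliberately the softer of the two,
* unilateral normal contact between the spherical patellar button and the
  trochlear surface of the femoral implant. Friction is not modeled: the
  physical bench this emulates lubricates the articulation, so only normal
  forces are considered.

Masses and inertias are design values of the synthetic rig, not claims about
any physical hardware; they enter the patellar dynamics but hardly matter
for the driven bodies.

## 2. Coordinates and constraints

Each body carries twelve *natural coordinates*: a reference point `r` and
the three columns `u, v, w` of its rotation matrix. This gives a constant
mass matrix per body (a 4x4 inertia-moment matrix Kronecker the identity)
and low-order polynomial constraints. Four *relative angle* coordinates are
appended: the Z–X–Y Euler angles of the femur about the hip and the knee
flexion angle. The constraint set (m = 34 rows for n = 40 coordinates) is:

| rows | constraint |
|---|---|
| 18 | rigid-body conditions per body (`u·u = 1`, `u·v = 0`, …) |
| 3  | femur hip point fixed at the hip center |
| 3  | femur and tibia knee points coincident |
| 3  | femur orientation equals `Rz(φ1) Rx(φ2) Ry(φ3) R⁰` (skew-part form) |
| 3  | tibia orientation equals femur ∘ rotation about the knee axis by θ |
| 4  | rheonomic drivers `φᵢ − φᵢ*(t) = 0`, `θ − θ*(t) = 0` |

The orientation-definition rows use the axial (skew) part of `BᵀR − I`,
which is exactly zero at the solution and has a well-conditioned Jacobian at
all driven configurations; single dot-product forms would lose rank near 0°.
The hinge is implied by the relative-orientation rows, so the system has no
redundant constraints, and the free degrees of freedom are exactly the
patella's six. The Z–X–Y hip sequence is a convention (the middle, X, angle
stays far from ±90° in this motion, so the gimbal singularity is never
approached); the generator and the reconstruction share it, making
angle round-trips exact by construction.

## 3. Time integration

The solver implements the augmented Lagrangian index-3 scheme with
projections: each step solves the dynamic equilibrium at `t_{n+1}` with the
Newmark kinematic relations (γ = 1/2, β = 1/4, the undamped trapezoidal
rule; the generalized-α scalars δf, δm default to 1), iterating
Newton–Raphson corrections with the nested multiplier update
`λ* ← λ* + αΦ`. The iteration matrix combines `M/(βh²)`, the penalty term
`Φqᵀ α Φq` and analytic spring/contact stiffness and damping blocks. A step
is accepted only when the increment norm falls below `newton_tol` (1e-10)
**and** `|Φ|_inf < 1e-8`; the accepted velocities and accelerations are then
projected onto the constraint subspaces by mass-weighted (minimal
kinetic-energy change) KKT solves. Defaults: h = 1 ms, α = 1e7 on every row,
at most 20 Newton plus 10 multiplier iterations per step. The penalty value
is validated by the constraint-norm invariant rather than taken from any
reference; the no-numerical-damping default is validated by the energy
invariant (drift of total mechanical energy, measured relative to the stored
kinetic plus elastic energy, stays below 0.1 % over 1 s with dissipation
disabled).

Two behaviors of this setup are worth knowing. First, the multipliers are
carried across steps and the simulation is seeded with the multipliers of
the initial equilibrium — starting them at zero injects a small spurious
impulse while the penalty terms build the reactions up. Second, the contact-normal oscillation of the
patella is only marginally resolved at 1 ms steps and shows up as a small,
bounded, deterministic ringing of the contact force; it decays under the
spring dampers, but it is the reason force-level comparisons between two
*different* runs are only meaningful above that ringing amplitude.

## 4. Static equilibrium

The initial state solves the equilibrium equations obtained by deleting
accelerations and velocity-dependent forces. Newton–Raphson on the
penalty-form residual stalls on this model: the penalty (1e7) punishes the
second-order constraint violation of any finite rotation step, and the
patella has an almost-neutral spin direction that spreads the Jacobian over
fourteen orders of magnitude. The implementation therefore iterates on the
equivalent penalty-free saddle system `Φqᵀλ = Q`, `Φ = 0`, recovering the
multipliers by least squares at each iterate, re-orthonormalizing the body
rotations after every trial step (polar decomposition) and line-searching a
combined merit. At convergence `|Φ|` is at rounding level, so the
penalty-form equations hold trivially and the converged multipliers seed the
dynamic stepper. If the guess is poor the solver first relaxes dynamically
(frozen drivers, velocities scaled by 0.9 per step) and then re-polishes.
Systems in contact can have several equilibria; the solver deliberately
returns the one reached from the initial guess.

## 5. Contact

The implant surface is the graph `z = P(x, y)` of a full bivariate quartic
in the implant frame, fitted by least squares (`R² = 1 − SS_res/SS_tot`,
defined as 1 for a zero-variance cloud that is fitted exactly). Closest
points are found by damped Newton iteration on the two-variable
stationarity conditions, seeded at the vertical projection (or at the
previous step's solution inside the integrator) with a trust-region-style
step cap. Contact exists when the center-to-surface distance drops below
the sphere radius; the normal points from the contact point toward the
sphere center. The normal force follows the Flores model with defaults
kₙ = 1e6 N/m^1.5, p = 1.5 (Hertz exponent of a sphere on a smooth surface)
and ε = 0.8; computed negative magnitudes (late restitution at small ε) are
clamped to zero, and the hysteresis term is dropped when the episode starts
with |δ̇₀| < 1e-6 m/s (quasi-static onset).

Episode bookkeeping is updated once per accepted step, never inside the
Newton loop, keeping the residual smooth: δ̇₀ is latched at episode onset
and reused until separation. Two additional rules make the unilateral
behavior robust:

* if the closest-point iterate leaves the fitted domain while contact is
  active, contact is declared inactive and a **dislocation event** is
  logged — this is precisely how the lateralized configuration renders
  patellar dislocation;
* after a dislocation (or whenever a body ends up behind the surface
  patch), contact re-engages only on a fresh approach with indentation
  below 2 mm. Without this rule the freed patella, swinging on the springs,
  can cross the extrapolated surface and would re-enter contact at
  centimeter-scale indentation.

A brute-force triangle-mesh closest-point oracle (exact point–triangle
distances over every facet) exists purely to validate the analytic detector
in the tests.

## 6. Marker processing

Captures are wide CSV (or read-only TRC) at 100 Hz. Conditioning follows
bench practice: a second-order zero-phase Butterworth low-pass at 12 Hz on
marker channels (forward–backward passes over an odd-reflection padded
copy, because a textbook two-pass filter without padding corrupts the first
and last half-second), and singular spectrum analysis with window 30 on
force channels (components kept to 99.5 % of squared-singular-value energy,
capped at 5). Body poses come from least-squares rigid registration of the
configured body-frame marker coordinates (the assembly pose defines the
frames); the three-point orthogonal-frame construction is exposed as its
own primitive. The hip center is identified from a calibration capture by
the pivot sphere fit — the fixed point keeping constant distances to all
femur markers — with a condition-number guard against insufficient
rotation. The femur anatomical frame for reporting has its origin at the
hip center, Y along the knee marker pair and Z normal to Y and the
hip–knee line; the patellar button center is expressed there, exactly as
the validation compares it.

Driver splines are natural cubics through the 100 Hz angle samples; the
1 ms integrator evaluates value, velocity and acceleration from the same
spline, so the three driver arrays are consistent by construction.

## 7. The synthetic rig

The generator emulates a sensorized bench: ≥ 3 markers per body (including
the knee-axis pair and two hip-calibration markers), two spring tension
channels and one contact pressure channel at 100 Hz, two spring-routing
configurations, and the standard maneuver 35° → 90° → 45° → 90° → 10° over
5 s (quintic smoothstep segments: monotone, with zero velocity *and*
acceleration at the waypoints, emulating smooth manual actuation — and
keeping the 12 Hz filter's passband droop negligible). Key design values:

| parameter | default | why |
|---|---|---|
| femur length | 0.40 m | adult femur scale |
| trochlear groove | `z = c₀ + c₁x + c₂x² + (a₀ + a₁x) y² − b₄ y⁴` | simplest quartic with walls that deepen distally and a lateral ridge |
| a₀, a₁ | −4.5, 767 m⁻¹·(m⁻¹) | groove nearly flat at the proximal end of the patellar track, wall curvature ≈ 30 m⁻¹ distally (sphere still fits: 2a < 1/r) |
| b₄ | 1.8e5 m⁻³ | puts the ridge crest within the patella's lateral reach only where the groove is shallow |
| sphere radius | 13 mm | commercial button scale |
| k (tibial / femoral) | 1200 / 600 N/m | femoral softer, as on the bench |
| damping c | 8 / 5 N·s/m | settles the patella within ~0.1 s |
| pretensions at 35° | 10 / 16 N | tensions in the tens-of-newtons range over the maneuver |
| quadriceps lever | 251.3 mm | frontal-plane lever; the 20 mm lateral offset of configuration A then changes the Q angle by atan(20/251.3) = 4.55° |
| marker noise σ | 0.5 mm | optical-capture scale errors |
| force noise σ | 0.1 N | load-cell scale |

The dislocation mechanism is geometric: the patella rides distally
(deep groove) in flexion and proximally (shallow groove) in extension; the
lateral pull of the displaced quadriceps spring is resisted by the groove
wall *and* by the lateral pendulum stiffness of both springs, and only
below ≈ 20° flexion does the lateral equilibrium cross the ridge crest,
after which the quartic fall-off drives the contact point out of the
fitted domain — logged as the dislocation event. These coefficients were
calibrated once, as part of the rig design, so that configuration A
dislocates on the final extension and configuration B never does; they are
design constants of the synthetic bench, not estimates of any implant.

What the generator does **not** emulate: soft-tissue artifact (the rig is
rigid), marker occlusions and gaps, camera-model distortions, tangential
(friction) contact, tibiofemoral implant contact, and collateral-ligament
springs. Passing tests therefore demonstrate internal consistency of the
pipeline and solver under realistic magnitudes — not fidelity to any
particular physical knee.

## 8. Calibration and optimization

`calibrate_springs()` fits `T = k (l − l₀)` per spring by linear least
squares from static observations (≥ 2 distinct lengths; negative fitted
stiffness is flagged). The refinement objective is the flat sum the bench
validation uses: RMSE of the three force channels (N) plus the mean
Euclidean femur-frame button-position error (mm) — no weights, with an RMS
position variant available. The optimizer is a real-coded genetic
algorithm (tournament of 3, blend crossover on [−0.5, 1.5], Gaussian
mutation at 2 % of the box width decaying by 0.88 per generation, elitism,
defaults in the initial population) over the six spring parameters within
±10 % bounds; deterministic for a fixed seed, and by construction never
worse than the defaults. Identifiability note: stiffness separates from
natural length only through the *variation* of spring length in the
reference motion, so the parameter-recovery experiment uses one wide
flexion sweep (12° → 105° in 0.8 s), which maximizes the femoral spring's
length spread.

## 9. Problem sizes and tolerances used by the tests

The suite runs the full 5 s maneuver at 1 ms (5000 steps) for constraint
fidelity and the A/B phenomenology; 1000 random sphere poses against a
100k-triangle mesh for the contact oracle; a 1.2 s bouncing-sphere drop for
restitution; 0.5 s pendulum runs at 2/1/0.1 ms for the convergence order;
and population 30 × 25 generations (≈ 750 simulations of a 0.8 s window)
for the recovery experiment. Tolerances asserted are the contracts stated
throughout the documentation (e.g. `|Φ|_inf ≤ 1e-8` per accepted step,
finite-difference Jacobian agreement to 1e-6, mg/k to 1e-9). The
end-to-end closure check runs the pipeline on a noiseless capture with the
Butterworth stage disabled: the filter's passband droop (a property of the
filter, tested separately against its transfer function) otherwise alters
the driver angles by ~6e-5 rad, which the Hertzian contact stiffness
amplifies to a few newtons even though the path agrees to 0.08 mm.

## 10. Known limitations

* The contact patch is a single quartic graph; multi-patch implants and
  conforming (non-spherical) buttons are out of scope.
* No friction, by design; adding tangential forces would change the
  dislocation threshold.
* The undamped trapezoidal rule preserves the marginally resolved
  contact-normal mode; analyses that need that mode resolved should halve
  the step.
* The genetic algorithm's recovery precision is problem-dependent; with
  short or narrow reference motions the stiffness/natural-length trade-off
  is weakly identifiable.
* Real-time execution is not a goal; the compiled core runs the 5 s
  maneuver in a few seconds on one CPU.
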