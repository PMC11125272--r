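units: m
configuration: A
gravity:
- 0.0
- 0.0
- -9.8100000000000005
bodies:
  femur:
    mass: 0.59999999999999998
    com:
    - 0.01
    - 0.0
    - -0.17999999999999999
    inertia:
    - 0.012
    - 0.012
    - 0.0015
    r_ref:
    - 0.0
    - 0.0
    - 0.0
    R_ref:
      .matrix:
      - 3
      - 3
      values:
      - 1.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
    hip_local:
    - 0.0
    - 0.0
    - 0.0
    knee_local:
    - 0.0
    - 0.0
    - -0.40000000000000002
    markers:
      fem_knee_med:
      - 0.0
      - -0.055
      - -0.40000000000000002
      fem_knee_lat:
      - 0.0
      - 0.055
      - -0.40000000000000002
      fem_shaft:
      - 0.035
      - 0.015
      - -0.22
  tibia:
    mass: 0.90000000000000002
    com:
    - 0.005
    - 0.0
    - -0.17000000000000001
    inertia:
    - 0.015
    - 0.015
    - 0.002
    r_ref:
    - 0.0
    - 0.0
    - -0.40000000000000002
    R_ref:
      .matrix:
      - 3
      - 3
      values:
      - 1.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
    knee_local:
    - 0.0
    - 0.0
    - 0.0
    markers:
      tib_ant_med:
      - 0.04
      - -0.035
      - -0.12
      tib_ant_lat:
      - 0.04
      - 0.035
      - -0.12
      tib_shaft:
      - 0.015
      - 0.0
      - -0.28000000000000003
  patella:
    mass: 0.045
    com:
    - 0.0
    - 0.0
    - 0.0
    inertia:
    - 4.00000000000000033e-05
    - 4.00000000000000033e-05
    - 3.00000000000000008e-05
    r_ref:
    - 0.05375020219706111
    - 0.0
    - -0.38995579815196479
    R_ref:
      .matrix:
      - 3
      - 3
      values:
      - 1.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
      - 0.0
      - 0.0
      - 0.0
      - 1.0
    button_local:
    - 0.0
    - 0.0
    - 0.0
    markers:
      pat_sup:
      - 0.012
      - 0.015
      - 0.014
      pat_inf:
      - 0.012
      - -0.015
      - 0.014
      pat_dist:
      - 0.012
      - 0.0
      - -0.02
joints:
  hip_center:
  - 0.0
  - 0.0
  - 0.0
  knee_axis_endpoints:
    .matrix:
    - 2
    - 3
    values:
    - 0.0
    - 0.0
    - -0.055
    - 0.055
    - -0.40000000000000002
    - -0.40000000000000002
  flexion_ref: 0.6108652381980153
springs:
  tibial:
    body_a: tibia
    point_a:
    - 0.008
    - 0.0
    - -0.08
    body_b: patella
    point_b:
    - -0.001
    - 0.0
    - -0.018
    stiffness: 1200.0
    natural_length: 0.07225356634645333
    damping: 8.0
  femoral:
    body_a: femur
    point_a:
    - -0.00622
    - 0.02
    - -0.14369999999999999
    body_b: patella
    point_b:
    - -0.005
    - 0.0
    - 0.018
    stiffness: 600.0
    natural_length: 0.21386168925005264
    damping: 5.0
contact:
  surface:
    coefficients:
      .matrix:
      - 5
      - 5
      values:
      - 0.01
      - 0.05
      - -0.80000000000000004
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - -4.5
      - 767.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
      - -180000.0
      - 0.0
      - 0.0
      - 0.0
      - 0.0
    domain:
    - -0.04
    - 0.10000000000000001
    - -0.015
    - 0.015
    frame_R:
      .matrix:
      - 3
      - 3
      values:
      - 0.0
      - 0.0
      - -1.0
      - 0.0
      - 1.0
      - 0.0
      - 1.0
      - 0.0
      - 0.0
    frame_o:
    - 0.03
    - 0.0
    - -0.36499999999999999
  sphere:
    center:
    - 0.0
    - 0.0
    - 0.0
    radius: 0.013
  params:
    kn: 1000000.0
    p: 1.5
    eps: 0.80000000000000004
solver:
  step_h: 0.001
  penalty_value: 10000000.0
  newmark_gamma: 0.5
  newmark_beta: 0.25
  delta_f: 1.0
  delta_m: 1.0
  newton_tol: 1.00000000000000004e-10
  max_newton_iters: 20
  max_lambda_iters: 10
  projection_tolerance: 1.00000000000000002e-08
  record_every: 1
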