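# dynamics_solver: Newmark/ALI3-P stepping, projections, static equilibrium

test_that("free fall over 1000 steps of 1 ms is exact", {
  sys <- free_body_system()
  tr <- simulate_guided(sys, settings = solver_settings(record_every = 1000),
                        initial = system_state(sys), duration = 1)
  expect_equal(tr$q[nrow(tr$q), 3], -0.5 * 9.81, tolerance = 1e-6)
  expect_false(tr$failed)
})

test_that("undamped oscillator conserves energy to 0.01% over 1 s", {
  sys <- spring_mass_system(mass = 1, k = 100, l0 = 0.5, anchor_z = 2, z0 = 1.5)
  eq <- solve_static_equilibrium(sys)
  st <- system_state(sys, q = {q <- eq$q; q[3] <- q[3] - 0.03; q})
  tr <- simulate_guided(sys, settings = solver_settings(record_every = 20),
                        initial = st, duration = 1)
  E <- vapply(seq_len(nrow(tr$q)), function(i)
    total_energy(sys, trajectory_state(tr, i)), numeric(1))
  scale <- 0.5 * 100 * 0.03^2   # energy of the initial displacement
  expect_lt((max(E) - min(E)) / scale, 1e-4)
})

test_that("pendulum period matches the closed form within 0.1%", {
  L <- 0.3
  sys <- pendulum_system(L = L, theta0 = 2 * pi / 180)
  st <- system_state(sys)
  tr <- simulate_guided(sys, settings = solver_settings(record_every = 1),
                        initial = st, duration = 2.5)
  x <- tr$q[, 1]   # pivot-frame swing shows in the bob x through the rotation
  x <- vapply(seq_len(nrow(tr$q)), function(i)
    kneerig:::body_point(sys, tr$q[i, ], "rod", c(0, 0, -L))[1], numeric(1))
  cross <- which(diff(sign(x)) != 0)
  tc <- tr$t[cross] - x[cross] * (tr$t[cross + 1] - tr$t[cross]) /
    (x[cross + 1] - x[cross])
  period <- 2 * mean(diff(tc))
  expect_equal(period, 2 * pi * sqrt(L / 9.81), tolerance = 1e-3)
})

test_that("projections restore constraint-consistent derivatives", {
  leg <- leg_system("B")
  sys <- leg$sys
  sys$meta$guided <- frozen_guided()
  eq <- leg$eq
  # idempotence on an already-consistent state
  st <- project_state(sys, eq)
  expect_equal(st$qdot, eq$qdot, tolerance = 1e-12)
  expect_equal(st$qddot, eq$qddot, tolerance = 1e-12)
  # a velocity violating the constraints is projected back
  set.seed(17)
  bad <- system_state(sys, q = eq$q, qdot = rnorm(40, 0, 0.2), t = 0)
  pr <- project_state(sys, bad)
  expect_lt(attr(pr, "vel_norm"), 1e-10)
  expect_lt(attr(pr, "acc_norm"), 1e-8)
  # mass-weighted least squares: match the null-space oracle
  for (rep in 1:5) {
    v <- rnorm(40, 0, 0.3)
    got <- project_state(sys, system_state(sys, q = eq$q, qdot = v, t = 0))$qdot
    want <- projected_velocity_oracle(sys, eq$q, v)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("static equilibrium solves closed forms and the full model", {
  # hanging mass: elongation mg/k = 0.1 * 9.81 / 100 = 0.00981 m
  sys <- spring_mass_system()
  eq <- solve_static_equilibrium(sys)
  len <- sqrt(sum((c(0, 0, 1) - eq$q[1:3])^2))
  expect_equal(len - 0.5, 0.1 * 9.81 / 100, tolerance = 1e-9)
  # sphere resting in a symmetric bowl: contact force equals the weight
  Cb <- matrix(0, 5, 5); Cb[3, 1] <- 10; Cb[1, 3] <- 10
  bowl <- polynomial_surface(Cb, c(-0.3, 0.3, -0.3, 0.3))
  ball <- rigid_body("ball", 0.3, 0.4 * 0.3 * 0.05^2 * diag(3))
  bsys <- multibody_system(
    list(ball = ball),
    contacts = list(contact_pair("ball", c(0, 0, 0), 0.05, bowl,
                                 kn = 1e5, restitution = 1)),
    q0 = list(ball = list(r = c(0, 0, 0.0499), R = diag(3))))
  beq <- solve_static_equilibrium(bsys)
  expect_lt(max(abs(beq$q[1:2])), 1e-9)            # stays on the axis
  cts <- kneerig:::.cpp_contact_eval(bsys$model, beq$q, numeric(12))
  expect_equal(cts[[1]]$force, 0.3 * 9.81, tolerance = 1e-6)
  # full leg model: a 2 mm perturbed guess converges back
  leg <- leg_system("B")
  q2 <- leg$eq$q
  q2[25:27] <- q2[25:27] + c(1.2e-3, -0.9e-3, 1.1e-3)
  eq2 <- solve_static_equilibrium(leg$sys, q_guess = q2)
  expect_lt(max(abs(eq2$q - leg$eq$q)), 1e-6)
})

test_that("the equilibrium is a fixed point of the guided simulation", {
  leg <- leg_system("B")
  tr <- simulate_guided(leg$sys, frozen_guided(),
                        settings = solver_settings(record_every = 10),
                        initial = leg$eq, duration = 1)
  ref <- matrix(leg$eq$q[25:27], nrow(tr$q), 3, byrow = TRUE)
  expect_lt(max(sqrt(rowSums((tr$q[, 25:27] - ref)^2))), 1e-6)
  expect_lt(max(tr$phi_norm), 1e-8)
})

test_that("identical inputs give bit-identical trajectories", {
  leg <- leg_system("B")
  g <- generate_motion(motion_profile(waypoints_deg = c(35, 70),
                                      durations_s = 0.4))
  t1 <- simulate_guided(leg$sys, g, settings = solver_settings(record_every = 10),
                        initial = leg$eq)
  t2 <- simulate_guided(leg$sys, g, settings = solver_settings(record_every = 10),
                        initial = leg$eq)
  expect_identical(t1$q, t2$q)
  expect_identical(t1$tensions, t2$tensions)
  expect_identical(t1$contact_force, t2$contact_force)
})

test_that("halving the step shows second-order convergence", {
  sys <- pendulum_system(L = 0.3, theta0 = 20 * pi / 180)
  run <- function(h) {
    tr <- simulate_guided(sys, settings = solver_settings(
      step_h = h, record_every = max(1L, as.integer(round(1e-3 / h)))),
      initial = system_state(sys), duration = 0.5)
    tr$q[nrow(tr$q), ]          # full coordinate vector (pose of the rod)
  }
  ref <- run(1e-4)
  e2 <- sqrt(sum((run(2e-3) - ref)^2))
  e1 <- sqrt(sum((run(1e-3) - ref)^2))
  expect_gt(e2 / e1, 3)
  expect_lt(e2 / e1, 5)
})

test_that("full-model energy is conserved with dissipation disabled", {
  pr <- rig_params()
  pr$c_tibial <- 0; pr$c_femoral <- 0; pr$contact_eps <- 1
  geom <- generate_rig_geometry("B", params = pr)
  sys <- build_leg_model(rig_config(geom))
  eq <- solve_static_equilibrium(sys)
  st <- eq; st$qdot[25:27] <- c(0.02, 0.03, -0.02)
  tr <- simulate_guided(sys, frozen_guided(),
                        settings = solver_settings(record_every = 20),
                        initial = st, duration = 1)
  E <- vapply(seq_len(nrow(tr$q)), function(i)
    total_energy(sys, trajectory_state(tr, i)), numeric(1))
  # relative to the stored mechanical energy (kinetic + elastic)
  ke0 <- 0.5 * sum(st$qdot * (sys$model$M %*% st$qdot))
  a0 <- assemble_system(sys, eq)
  pe0 <- 0.5 * sum((a0$tensions)^2 / c(pr$k_tibial, pr$k_femoral))
  expect_lt((max(E) - min(E)) / (ke0 + pe0), 1e-3)
})

test_that("single newmark steps accept, converge and report diagnostics", {
  leg <- leg_system("B")
  sys <- leg$sys
  sys$meta$guided <- frozen_guided()
  st1 <- newmark_step(sys, leg$eq)
  expect_lt(attr(st1, "phi_norm"), 1e-8)
  expect_gte(attr(st1, "iters"), 1L)
  expect_equal(st1$t, leg$eq$t + 1e-3)
  # without projection the velocity-level residual is generally larger
  st_raw <- newmark_step(sys, leg$eq, project = FALSE)
  pr <- project_state(sys, st_raw)
  expect_lte(attr(pr, "vel_norm"), 1e-10)
})
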