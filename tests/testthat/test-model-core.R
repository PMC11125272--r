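# model_core: bodies, springs, constraint assembly, mass matrix

test_that("spring tension follows the linear spring-damper law", {
  s <- spring_damper(NULL, c(0, 0, 0), NULL, c(1, 0, 0),
                     stiffness = 200, natural_length = 0.10, damping = 0)
  # at natural length, no tension
  expect_equal(spring_tension(s, c(0, 0, 0), c(0.10, 0, 0)), 0)
  # k (l - l0): 200 * 0.05 = 10 N
  expect_equal(spring_tension(s, c(0, 0, 0), c(0.15, 0, 0)), 10)
  # damping term alone: c * ldot = 5 * 0.2 = 1 N
  sd5 <- spring_damper(NULL, c(0, 0, 0), NULL, c(1, 0, 0),
                       stiffness = 200, natural_length = 0.10, damping = 5)
  expect_equal(spring_tension(sd5, c(0, 0, 0), c(0.10, 0, 0),
                              v_a = c(0, 0, 0), v_b = c(0.2, 0, 0)), 1)
  expect_error(spring_tension(s, c(0, 0, 0), c(0, 0, 0)), "zero-length")
})

test_that("rigid body construction validates mass, inertia and points", {
  expect_error(rigid_body("b", -1, diag(3) * 1e-4), "positive")
  expect_error(rigid_body("b", 1, matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3, 3) * 1e-4),
               "symmetric")
  expect_error(rigid_body("b", 1, diag(c(1, -1, 1)) * 1e-4), "positive definite")
  expect_error(rigid_body("b", 1, diag(3), local_points = list(p = c(1, Inf, 0))),
               "finite")
})

test_that("leg model has 4 guided dofs, a free 6-dof patella and assembles", {
  leg <- leg_system("B")
  sys <- leg$sys
  expect_equal(length(sys$driver_names), 4L)
  expect_equal(sys$n_coords, 40L)
  expect_equal(sys$n_constraints, 34L)
  # net degrees of freedom with drivers removed: exactly the free patella
  d <- kneerig:::driver_eval(sys, 0)
  cs <- kneerig:::.cpp_constraints(sys$model, sys$q_ref,
                                   numeric(40), d$pos, d$vel, d$acc)
  expect_equal(qr(cs$phiq)$rank, 34L)
  # patella columns (25:36) carry only its own rigid-body rows
  pat_rows <- which(apply(cs$phiq[, 25:36] != 0, 1, any))
  expect_length(pat_rows, 6L)
  # assembled reference pose satisfies the constraints
  expect_lt(max(abs(cs$phi)), 1e-10)
})

test_that("degenerate knee axis and missing geometry are rejected", {
  geom <- generate_rig_geometry("B")
  cfg <- rig_config(geom)
  cfg$joints$knee_axis_endpoints <- rbind(c(0, 0, -0.4), c(0, 0, -0.4))
  expect_error(build_leg_model(cfg), "degenerate knee axis")
  cfg2 <- rig_config(geom)
  cfg2$bodies$patella <- NULL
  expect_error(build_leg_model(cfg2), "patella")
  cfg3 <- rig_config(geom)
  cfg3$springs <- NULL
  expect_error(build_leg_model(cfg3), "missing")
})

test_that("free-falling body reduces to the gravity wrench", {
  sys <- free_body_system(mass = 0.2)
  out <- assemble_system(sys, system_state(sys))
  qdd <- solve(out$M, out$Q)
  expect_equal(qdd[1:3], c(0, 0, -9.81), tolerance = 1e-12)
  expect_equal(max(abs(qdd[4:12])), 0, tolerance = 1e-12)
})

test_that("constraint Jacobian matches finite differences on random states", {
  sys <- leg_system("B")$sys
  d <- kneerig:::driver_eval(sys, 0)
  n <- sys$n_coords
  set.seed(11)
  worst <- 0
  for (rep in 1:100) {
    q <- sys$q_ref + rnorm(n, 0, 0.02)
    base <- kneerig:::.cpp_assemble(sys$model, q, numeric(n), d$pos)
    h <- 1e-7
    for (j in seq_len(n)) {
      qp <- q; qp[j] <- qp[j] + h
      qm <- q; qm[j] <- qm[j] - h
      fd <- (kneerig:::.cpp_assemble(sys$model, qp, numeric(n), d$pos)$phi -
               kneerig:::.cpp_assemble(sys$model, qm, numeric(n), d$pos)$phi) / (2 * h)
      worst <- max(worst, max(abs(fd - base$phiq[, j])))
    }
  }
  # relative to the Jacobian scale (entries are O(1))
  expect_lt(worst, 1e-6)
})

test_that("mirroring a system across the sagittal plane mirrors the forces", {
  # two bodies coupled by a spring with asymmetric attachment points
  mk <- function(sgn) {
    b1 <- rigid_body("a", 0.3, c(1e-4, 2e-4, 3e-4), com = c(0.01, sgn * 0.02, 0.005))
    b2 <- rigid_body("b", 0.2, c(2e-4, 1e-4, 2e-4))
    s <- spring_damper("a", c(0.02, sgn * 0.03, 0.01), "b", c(-0.01, sgn * 0.015, 0.02),
                       stiffness = 150, natural_length = 0.1, damping = 2)
    multibody_system(list(a = b1, b = b2), springs = list(s = s),
                     q0 = list(a = list(r = c(0, sgn * 0.05, 0), R = diag(3)),
                               b = list(r = c(0.1, sgn * -0.02, 0.15), R = diag(3))))
  }
  sys <- mk(1); sysm <- mk(-1)
  Mirr <- diag(c(1, -1, 1))
  set.seed(3)
  for (rep in 1:5) {
    # random pose + velocity, mirrored consistently
    q <- sys$q_ref; qm <- q
    for (b in 0:1) {
      base <- 12 * b
      R <- euler_zxy(rnorm(3, 0, 0.3))
      r <- rnorm(3, 0, 0.05) + q[base + 1:3]
      q[base + 1:3] <- r
      q[base + 4:12] <- as.numeric(R)
      qm[base + 1:3] <- Mirr %*% r
    }
    v <- rnorm(24, 0, 0.1)
    vm <- v
    for (b in 0:1) {
      base <- 12 * b
      # mirror translational and column velocities: S r, S u, -S v, S w is the
      # action on columns of R' = Mirr R Mirr
      vm[base + 1:3] <- Mirr %*% v[base + 1:3]
      vm[base + 4:6] <- Mirr %*% v[base + 4:6]
      vm[base + 7:9] <- -(Mirr %*% v[base + 7:9])
      vm[base + 10:12] <- Mirr %*% v[base + 10:12]
    }
    # the mirrored configuration must also express columns as (Su, -Sv, Sw)
    for (b in 0:1) {
      base <- 12 * b
      qm[base + 4:6] <- Mirr %*% q[base + 4:6]
      qm[base + 7:9] <- -(Mirr %*% q[base + 7:9])
      qm[base + 10:12] <- Mirr %*% q[base + 10:12]
    }
    Q <- kneerig:::.cpp_assemble(sys$model, q, v, numeric(0))$Q
    Qm <- kneerig:::.cpp_assemble(sysm$model, qm, vm, numeric(0))$Q
    for (b in 0:1) {
      base <- 12 * b
      expect_equal(Qm[base + 1:3], as.numeric(Mirr %*% Q[base + 1:3]), tolerance = 1e-9)
      expect_equal(Qm[base + 4:6], as.numeric(Mirr %*% Q[base + 4:6]), tolerance = 1e-9)
      expect_equal(Qm[base + 7:9], as.numeric(-(Mirr %*% Q[base + 7:9])), tolerance = 1e-9)
      expect_equal(Qm[base + 10:12], as.numeric(Mirr %*% Q[base + 10:12]), tolerance = 1e-9)
    }
  }
})

test_that("spring-mass oscillation frequency matches sqrt(k/m) within 0.1%", {
  sys <- spring_mass_system(mass = 1, k = 100, l0 = 0.5, anchor_z = 2, z0 = 1.5)
  eq <- solve_static_equilibrium(sys)
  st <- system_state(sys, q = {q <- eq$q; q[3] <- q[3] - 0.02; q})
  tr <- simulate_guided(sys, settings = solver_settings(record_every = 1),
                        initial = st, duration = 3)
  z <- tr$q[, 3] - eq$q[3]
  cross <- which(diff(sign(z)) != 0)
  # refine crossings linearly, average the period
  tc <- tr$t[cross] - z[cross] * (tr$t[cross + 1] - tr$t[cross]) /
    (z[cross + 1] - z[cross])
  period <- 2 * mean(diff(tc))
  expect_equal(period, 2 * pi * sqrt(1 / 100), tolerance = 1e-3)
})

test_that("drivers are rheonomic: frozen angles make Phi time-independent", {
  sys <- leg_system("B")$sys
  sys$meta$guided <- frozen_guided()
  q <- sys$q_ref
  p1 <- kneerig:::constraint_violation(sys, q, t = 0.1)
  p2 <- kneerig:::constraint_violation(sys, q, t = 0.9)
  expect_equal(p1, p2, tolerance = 1e-12)
  d <- kneerig:::driver_eval(sys, 0.5)
  cs <- kneerig:::.cpp_constraints(sys$model, q, numeric(40), d$pos, d$vel, d$acc)
  expect_equal(max(abs(cs$phit)), 0, tolerance = 1e-12)
})

test_that("reference configurations violating constraints are rejected", {
  geom <- generate_rig_geometry("B")
  cfg <- rig_config(geom)
  cfg$bodies$tibia$r_ref <- cfg$bodies$tibia$r_ref + c(0.01, 0, 0)
  expect_error(build_leg_model(cfg), "violates constraints")
})
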