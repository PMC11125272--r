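# shared model builders and oracles for the test suite

# single free body (projectile / free-fall checks)
free_body_system <- function(mass = 0.2, r0 = c(0, 0, 0)) {
  b <- rigid_body("ball", mass = mass, inertia = c(1e-4, 1e-4, 1e-4))
  multibody_system(list(ball = b),
                   q0 = list(ball = list(r = r0, R = diag(3))))
}

# point mass hanging from a vertical spring anchored at (0, 0, anchor_z)
spring_mass_system <- function(mass = 0.1, k = 100, l0 = 0.5, damping = 0,
                               anchor_z = 1, z0 = 0.45) {
  b <- rigid_body("m", mass = mass, inertia = c(1e-6, 1e-6, 1e-6))
  s <- spring_damper(NULL, c(0, 0, anchor_z), "m", c(0, 0, 0),
                     stiffness = k, natural_length = l0, damping = damping)
  multibody_system(list(m = b), springs = list(hang = s),
                   q0 = list(m = list(r = c(0, 0, z0), R = diag(3))))
}

# rigid pendulum: slender body pinned at the origin, bob at distance L below
pendulum_system <- function(mass = 0.5, L = 0.3, theta0 = 2 * pi / 180) {
  b <- rigid_body("rod", mass = mass,
                  inertia = mass * L^2 * diag(c(1e-6, 1e-6, 1e-6)),
                  com = c(0, 0, -L))
  R0 <- rot_y(theta0)
  multibody_system(
    list(rod = b),
    constraints = list(list(type = "fixed_point", body = "rod",
                            local = c(0, 0, 0), target = c(0, 0, 0))),
    q0 = list(rod = list(r = c(0, 0, 0), R = R0)))
}

# sphere bouncing on the ground plane z = 0 (graph surface of a zero quartic)
bouncing_sphere_system <- function(mass = 0.2, radius = 0.05, kn = 5e4,
                                   eps = 1, z0 = 0.08) {
  surf <- polynomial_surface(matrix(0, 5, 5), c(-1, 1, -1, 1))
  b <- rigid_body("ball", mass = mass,
                  inertia = 0.4 * mass * radius^2 * diag(3))
  cp <- contact_pair("ball", c(0, 0, 0), radius, surf, surface_body = NULL,
                     kn = kn, p = 1.5, restitution = eps)
  multibody_system(list(ball = b), contacts = list(cp),
                   q0 = list(ball = list(r = c(0, 0, z0), R = diag(3))))
}

# guided trajectory holding all four leg angles constant
frozen_guided <- function(flexion_rad = 35 * pi / 180, duration = 1.5) {
  tt <- seq(0, duration, by = 0.01)
  guided_trajectory(tt, cbind(0 * tt, 0 * tt, 0 * tt,
                              rep(flexion_rad, length(tt))))
}

# cached default leg systems (building + equilibrating once per run)
leg_cache <- new.env(parent = emptyenv())
leg_system <- function(configuration = "B") {
  key <- paste0("cfg", configuration)
  if (is.null(leg_cache[[key]])) {
    geom <- generate_rig_geometry(configuration)
    sys <- build_leg_model(rig_config(geom))
    eq <- solve_static_equilibrium(sys)
    leg_cache[[key]] <- list(geom = geom, sys = sys, eq = eq)
  }
  leg_cache[[key]]
}

# brute-force closest-point distance oracle: dense grid sampling of the graph
dense_distance_oracle <- function(surface, center, n = 1000) {
  d <- surface$fit_domain
  xs <- seq(d[1], d[2], length.out = n)
  ys <- seq(d[3], d[4], length.out = n)
  g <- expand.grid(x = xs, y = ys)
  z <- surface_eval(surface, g$x, g$y, check_domain = FALSE)
  min(sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (z - center[3])^2))
}

# mass-weighted feasible-velocity oracle by the null-space method
projected_velocity_oracle <- function(system, q, qdot_star, t = 0) {
  d <- kneerig:::driver_eval(system, t)
  cs <- kneerig:::.cpp_constraints(system$model, q, qdot_star, d$pos, d$vel, d$acc)
  A <- cs$phiq
  b <- -cs$phit
  M <- system$model$M
  # min-norm particular solution and null-space basis via the QR of t(A)
  qrA <- qr(t(A))
  v_p <- as.numeric(t(A) %*% solve(tcrossprod(A), b))
  N <- qr.Q(qrA, complete = TRUE)[, (qrA$rank + 1):ncol(A), drop = FALSE]
  y <- solve(t(N) %*% M %*% N, t(N) %*% M %*% (qdot_star - v_p))
  as.numeric(v_p + N %*% y)
}

random_quartic_surface <- function(seed = 1, scale = 8, domain = c(-0.06, 0.06, -0.06, 0.06)) {
  set.seed(seed)
  C <- matrix(0, 5, 5)
  for (i in 0:4) for (j in 0:(4 - i)) {
    # keep curvature gentle so the graph stays smooth at the test scale
    C[i + 1, j + 1] <- rnorm(1, 0, scale * 0.1^(i + j))
  }
  C[1, 1] <- 0
  polynomial_surface(C, domain)
}
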