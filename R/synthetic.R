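# synthetic_rig: deterministic generator for a complete synthetic test-bench
# dataset (geometry, guided motion, marker clouds, force records) with ground
# truth, emulating a spring-actuated knee rig with two spring-routing
# configurations (A = femoral attachment displaced 20 mm laterally vs B).

#' Design parameters of the synthetic rig
#'
#' All lengths in m, stiffnesses in N/m, masses in kg. The trochlear groove
#' is the quartic `z = c0 + c1 x + c2 x^2 + (a0 + a1 x) y^2 - b4 y^4` in the
#' implant frame (x distal along the femur, y lateral, z anterior): the
#' `y^2` term forms the groove walls (deeper distally through `a1 > 0`), the
#' `-y^4` term caps the lateral ridge so that a laterally pulled patella can
#' escape where the groove is shallow (proximally, i.e. at low knee
#' flexion).
#'
#' @param femur_length hip-to-knee distance.
#' @param knee_half_span half distance between the knee-axis markers.
#' @param groove_c0,groove_c1,groove_c2 anterior height of the groove floor.
#' @param groove_a0,groove_a1 groove wall curvature (1/m) and its distal
#'   gradient (1/m^2).
#' @param groove_b4 quartic ridge coefficient (1/m^3).
#' @param surface_origin implant frame origin in the femur frame.
#' @param domain fit domain `c(xmin, xmax, ymin, ymax)` of the quartic.
#' @param sphere_radius patellar button radius.
#' @param quad_lever frontal-plane distance from the button to the femoral
#'   spring attachment; with the 20 mm lateral offset of configuration A
#'   this sets the Q-angle difference `atan(0.020 / quad_lever)`.
#' @param quad_posterior posterior offset of the femoral attachment
#'   direction (presses the button into the groove).
#' @param k_tibial,k_femoral spring stiffnesses (femoral lower, as on the
#'   physical bench).
#' @param c_tibial,c_femoral spring damping coefficients (N s/m).
#' @param pretension_tibial,pretension_femoral spring tensions at the
#'   reference (35 degree flexion) pose, used to set natural lengths.
#' @param contact_kn,contact_p,contact_eps Flores normal-force parameters.
#' @param masses,patella_com named masses and the patella center of mass.
#' @return list of rig parameters.
#' @export
rig_params <- function(femur_length = 0.40,
                       knee_half_span = 0.055,
                       groove_c0 = 0.010, groove_c1 = 0.05, groove_c2 = -0.8,
                       groove_a0 = -4.5, groove_a1 = 767, groove_b4 = 1.8e5,
                       surface_origin = c(0.030, 0, -0.365),
                       domain = c(-0.04, 0.10, -0.015, 0.015),
                       sphere_radius = 0.013,
                       quad_lever = 0.2513, quad_posterior = 0.060,
                       tubercle_anterior = 0.008, tubercle_distal = -0.080,
                       k_tibial = 1200, k_femoral = 600,
                       c_tibial = 8, c_femoral = 5,
                       pretension_tibial = 10, pretension_femoral = 16,
                       contact_kn = 1e6, contact_p = 1.5, contact_eps = 0.8,
                       masses = c(femur = 0.6, tibia = 0.9, patella = 0.045),
                       patella_com = c(0, 0, 0)) {
  as.list(environment())
}

# quartic coefficient matrix of the trochlear groove
trochlea_coefficients <- function(pr) {
  C <- matrix(0, 5, 5)
  C[1, 1] <- pr$groove_c0
  C[2, 1] <- pr$groove_c1
  C[3, 1] <- pr$groove_c2
  C[1, 3] <- pr$groove_a0
  C[2, 3] <- pr$groove_a1
  C[1, 5] <- -pr$groove_b4
  C
}

#' Generate the synthetic rig geometry
#'
#' Deterministic geometry for one spring-routing configuration. The femoral
#' spring attachment of configuration A equals that of configuration B
#' displaced by +20 mm along the lateral (+Y) axis, which changes the
#' frontal-plane Q angle by `atan(0.020 / quad_lever)` (4.55 degrees at the
#' default lever).
#'
#' @param configuration `"A"` (lateralized, dislocating) or `"B"` (aligned).
#' @param seed stored for provenance; the geometry itself is deterministic
#'   (randomness enters only through capture noise).
#' @param params a [rig_params()] list.
#' @return list of class `rig_geometry`.
#' @export
generate_rig_geometry <- function(configuration = c("B", "A"), seed = 1L,
                                  params = rig_params()) {
  configuration <- match.arg(configuration)
  pr <- params
  Lf <- pr$femur_length
  hip <- c(0, 0, 0)
  knee <- c(0, 0, -Lf)
  flexion_ref <- 35 * pi / 180

  # implant (surface) frame in the femur body frame: x distal, y lateral,
  # z anterior; right-handed
  Rs <- cbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))
  surface <- polynomial_surface(trochlea_coefficients(pr), pr$domain,
                                r_squared = NA_real_,
                                frame = list(R = Rs, o = pr$surface_origin))

  # provisional button reference: on the groove floor, offset by the radius
  x_seed <- 0.030
  z_seed <- surface_eval(surface, x_seed, 0, check_domain = FALSE)
  button_ref <- pr$surface_origin +
    as.numeric(Rs %*% c(x_seed, 0, z_seed + pr$sphere_radius))

  # femoral spring attachment: proximal along +Z with a posterior offset;
  # the frontal-plane lever is exactly quad_lever so that the A-vs-B Q-angle
  # difference is atan(0.020 / quad_lever)
  attach_B <- button_ref + c(-pr$quad_posterior, 0, pr$quad_lever)
  attach <- if (configuration == "A") attach_B + c(0, 0.020, 0) else attach_B

  tubercle_local <- c(pr$tubercle_anterior, 0, pr$tubercle_distal)  # tibia frame

  tubercle_ref <- knee + tubercle_local

  femur <- list(
    mass = unname(pr$masses["femur"]), com = c(0.01, 0, -0.18),
    inertia = c(0.012, 0.012, 0.0015),
    r_ref = hip, R_ref = diag(3), hip_local = c(0, 0, 0),
    knee_local = knee,
    quad_attach_local = attach,
    markers = list(fem_knee_med = c(0, -pr$knee_half_span, -Lf),
                   fem_knee_lat = c(0,  pr$knee_half_span, -Lf),
                   fem_shaft    = c(0.035, 0.015, -0.22)),
    calib_markers = list(fem_hip_1 = c(0.05, 0.02, -0.10),
                         fem_hip_2 = c(-0.04, 0.045, -0.16)))
  tibia <- list(
    mass = unname(pr$masses["tibia"]), com = c(0.005, 0, -0.17),
    inertia = c(0.015, 0.015, 0.002),
    r_ref = knee, R_ref = diag(3), knee_local = c(0, 0, 0),
    tubercle_local = tubercle_local,
    markers = list(tib_ant_med = c(0.040, -0.035, -0.12),
                   tib_ant_lat = c(0.040,  0.035, -0.12),
                   tib_shaft   = c(0.015, 0, -0.28)))
  patella <- list(
    mass = unname(pr$masses["patella"]), com = pr$patella_com,
    inertia = c(4e-5, 4e-5, 3e-5),
    r_ref = button_ref, R_ref = diag(3), button_local = c(0, 0, 0),
    quad_attach_local = c(-0.005, 0, 0.018),
    tendon_attach_local = c(-0.001, 0, -0.018),
    markers = list(pat_sup = c(0.012, 0.015, 0.014),
                   pat_inf = c(0.012, -0.015, 0.014),
                   pat_dist = c(0.012, 0, -0.020)))

  # natural lengths from the design pretensions at the reference pose
  qa_pat <- button_ref + patella$quad_attach_local
  ta_pat <- button_ref + patella$tendon_attach_local
  l_quad <- sqrt(sum((attach - qa_pat)^2))
  l_tend <- sqrt(sum((tubercle_ref - ta_pat)^2))
  springs <- list(
    tibial = list(stiffness = pr$k_tibial,
                  natural_length = l_tend - pr$pretension_tibial / pr$k_tibial,
                  damping = pr$c_tibial),
    femoral = list(stiffness = pr$k_femoral,
                   natural_length = l_quad - pr$pretension_femoral / pr$k_femoral,
                   damping = pr$c_femoral))

  geom <- list(configuration = configuration, seed = as.integer(seed),
               params = pr, hip_center = hip, knee_center = knee,
               knee_axis_endpoints = rbind(femur$markers$fem_knee_med,
                                           femur$markers$fem_knee_lat),
               flexion_ref = flexion_ref,
               femur = femur, tibia = tibia, patella = patella,
               surface = surface, sphere_radius = pr$sphere_radius,
               springs = springs,
               contact = list(kn = pr$contact_kn, p = pr$contact_p,
                              eps = pr$contact_eps),
               quad_lever = pr$quad_lever, button_ref = button_ref,
               button_q_ref = button_ref,
               tubercle_ref = tubercle_ref, quad_attach = attach)
  class(geom) <- "rig_geometry"
  # refine the patella reference onto the quasi-static groove minimum
  geom <- refine_patella_seed(geom)
  geom
}

# quasi-static scan along the groove: place the button on the surface at
# (x, 0), evaluate the potential energy of the patella, keep the minimizer
refine_patella_seed <- function(geom) {
  pr <- geom$params
  s <- geom$surface
  Rs <- s$frame$R; os <- s$frame$o
  xs <- seq(s$fit_domain[1] + 0.005, s$fit_domain[2] - 0.005, length.out = 120)
  k_t <- geom$springs$tibial$stiffness; l0_t <- geom$springs$tibial$natural_length
  k_f <- geom$springs$femoral$stiffness; l0_f <- geom$springs$femoral$natural_length
  m <- geom$patella$mass
  g <- c(0, 0, -9.81)
  best <- NULL; best_e <- Inf
  for (x in xs) {
    z <- surface_eval(s, x, 0, check_domain = FALSE)
    zx <- (surface_eval(s, x + 1e-6, 0, check_domain = FALSE) - z) / 1e-6
    nrm_s <- c(-zx, 0, 1) / sqrt(1 + zx^2)
    b <- os + as.numeric(Rs %*% (c(x, 0, z) + geom$sphere_radius * nrm_s))
    qa <- b + geom$patella$quad_attach_local
    ta <- b + geom$patella$tendon_attach_local
    lq <- sqrt(sum((geom$quad_attach - qa)^2))
    lt <- sqrt(sum((geom$tubercle_ref - ta)^2))
    e <- 0.5 * k_f * (lq - l0_f)^2 + 0.5 * k_t * (lt - l0_t)^2 - m * sum(g * b)
    if (e < best_e) { best_e <- e; best <- b }
  }
  geom$patella$r_ref <- best
  geom$button_ref <- best
  geom
}

#' Motion profile of the rig maneuver
#'
#' Knee-flexion waypoints connected by quintic smoothstep segments with zero end
#' velocities and accelerations (each segment monotone); hip angles are small constants with
#' optional low-amplitude wander mimicking manual actuation.
#'
#' @param waypoints_deg knee flexion waypoints (deg), within `[0, 120]`.
#' @param durations_s segment durations (s), positive.
#' @param hip_deg constant hip angles (deg, Z-X-Y).
#' @param hip_wander_deg wander amplitude (deg); 0 disables it.
#' @param wander_seed seed for the wander phases.
#' @return list of class `motion_profile`.
#' @export
motion_profile <- function(waypoints_deg = c(35, 90, 45, 90, 10),
                           durations_s = c(1.6, 1.1, 1.1, 1.2),
                           hip_deg = c(0, 0, 0), hip_wander_deg = 0,
                           wander_seed = 1L) {
  if (length(durations_s) != length(waypoints_deg) - 1)
    stop("need one duration per segment")
  if (any(durations_s <= 0)) stop("segment durations must be positive")
  if (any(waypoints_deg < 0 | waypoints_deg > 120))
    stop("knee flexion waypoints must lie in [0, 120] degrees")
  structure(list(waypoints_deg = waypoints_deg, durations_s = durations_s,
                 hip_deg = hip_deg, hip_wander_deg = hip_wander_deg,
                 wander_seed = as.integer(wander_seed)),
            class = "motion_profile")
}

#' Sample a motion profile into a guided trajectory
#'
#' @param profile a [motion_profile()].
#' @param fs sampling frequency (Hz).
#' @return a `guided_trajectory` with `duration * fs + 1` samples.
#' @export
generate_motion <- function(profile = motion_profile(), fs = 100) {
  total <- sum(profile$durations_s)
  times <- seq(0, total, by = 1 / fs)
  knots <- c(0, cumsum(profile$durations_s))
  wp <- profile$waypoints_deg * pi / 180
  knee <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- min(times[i], total)
    k <- max(1, min(findInterval(t, knots, rightmost.closed = TRUE),
                    length(wp) - 1))
    s <- (t - knots[k]) / (knots[k + 1] - knots[k])
    # quintic smoothstep: zero velocity and acceleration at the waypoints,
    # monotone within each segment (smooth manual actuation)
    knee[i] <- wp[k] + (wp[k + 1] - wp[k]) * (10 * s^3 - 15 * s^4 + 6 * s^5)
  }
  hip <- matrix(rep(profile$hip_deg * pi / 180, each = length(times)),
                ncol = 3)
  if (profile$hip_wander_deg > 0) {
    ph <- withr_seed(profile$wander_seed, runif(6, 0, 2 * pi))
    A <- profile$hip_wander_deg * pi / 180
    for (j in 1:3)
      hip[, j] <- hip[, j] + A * (sin(2 * pi * 0.23 * times + ph[2 * j - 1]) +
                                    0.6 * sin(2 * pi * 0.41 * times + ph[2 * j]))
  }
  guided_trajectory(times, cbind(hip, knee))
}

# evaluate an expression under a temporary RNG seed, restoring the RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Frontal-plane Q angle of a rig geometry
#'
#' Angle between the quadriceps line (button to femoral attachment) and the
#' patellar tendon line (tibial tubercle to button), both projected onto the
#' frontal (Y-Z) plane, signed about the anterior axis.
#'
#' @param geometry a `rig_geometry`.
#' @return Q angle in degrees.
#' @export
q_angle <- function(geometry) {
  bref <- if (!is.null(geometry$button_q_ref)) geometry$button_q_ref else geometry$button_ref
  quad <- geometry$quad_attach - bref
  tend <- bref - geometry$tubercle_ref
  aq <- atan2(quad[2], quad[3])
  at <- atan2(tend[2], tend[3])
  (aq - at) * 180 / pi
}

#' Rig geometry as a solver-ready configuration
#'
#' @param geometry a `rig_geometry`.
#' @param solver optional [solver_settings()] overrides.
#' @return nested configuration list (YAML-serializable) accepted by
#'   [build_leg_model()].
#' @export
rig_config <- function(geometry, solver = solver_settings()) {
  g <- geometry
  list(
    units = "m",
    configuration = g$configuration,
    gravity = c(0, 0, -9.81),
    bodies = list(
      femur = list(mass = g$femur$mass, com = g$femur$com,
                   inertia = g$femur$inertia, r_ref = g$femur$r_ref,
                   R_ref = g$femur$R_ref, hip_local = g$femur$hip_local,
                   knee_local = g$femur$knee_local,
                   markers = g$femur$markers),
      tibia = list(mass = g$tibia$mass, com = g$tibia$com,
                   inertia = g$tibia$inertia, r_ref = g$tibia$r_ref,
                   R_ref = g$tibia$R_ref, knee_local = g$tibia$knee_local,
                   markers = g$tibia$markers),
      patella = list(mass = g$patella$mass, com = g$patella$com,
                     inertia = g$patella$inertia, r_ref = g$patella$r_ref,
                     R_ref = g$patella$R_ref,
                     button_local = g$patella$button_local,
                     markers = g$patella$markers)),
    joints = list(hip_center = g$hip_center,
                  knee_axis_endpoints = g$knee_axis_endpoints,
                  flexion_ref = g$flexion_ref),
    springs = list(
      tibial = list(body_a = "tibia", point_a = g$tibia$tubercle_local,
                    body_b = "patella", point_b = g$patella$tendon_attach_local,
                    stiffness = g$springs$tibial$stiffness,
                    natural_length = g$springs$tibial$natural_length,
                    damping = g$springs$tibial$damping),
      femoral = list(body_a = "femur", point_a = g$femur$quad_attach_local,
                     body_b = "patella", point_b = g$patella$quad_attach_local,
                     stiffness = g$springs$femoral$stiffness,
                     natural_length = g$springs$femoral$natural_length,
                     damping = g$springs$femoral$damping)),
    contact = list(
      surface = list(coefficients = g$surface$coefficients,
                     domain = g$surface$fit_domain,
                     frame_R = g$surface$frame$R,
                     frame_o = g$surface$frame$o),
      sphere = list(center = g$patella$button_local,
                    radius = g$sphere_radius),
      params = g$contact),
    solver = unclass(solver))
}

#' Build the three-body leg model from a rig configuration
#'
#' Femur fixed at a spherical hip, tibia hinged to the femur about the knee
#' axis, patella fully free; four rheonomic drivers guide the hip and knee
#' angles. The reference configuration must assemble (constraints satisfied
#' at the stored poses).
#'
#' @param config configuration list as produced by [rig_config()] or read
#'   with [read_rig_config()].
#' @return an `mbs_system` with leg metadata (hip center, knee markers,
#'   button center) used for femur-frame reporting.
#' @export
build_leg_model <- function(config) {
  req <- c("bodies", "joints", "springs", "contact", "solver")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("configuration is missing entries: ",
                         paste(miss, collapse = ", "))
  bd <- config$bodies
  for (nm in c("femur", "tibia", "patella"))
    if (is.null(bd[[nm]])) stop("configuration is missing body: ", nm)

  ep <- as.matrix(config$joints$knee_axis_endpoints)
  axis <- ep[2, ] - ep[1, ]
  if (sqrt(sum(axis^2)) < 1e-9)
    stop("degenerate knee axis: endpoints coincide")
  axis <- axis / sqrt(sum(axis^2))

  mk_body <- function(nm) {
    b <- bd[[nm]]
    rigid_body(nm, b$mass, as.numeric(unlist(b$inertia)), com = b$com,
               local_points = b$markers)
  }
  bodies <- list(femur = mk_body("femur"), tibia = mk_body("tibia"),
                 patella = mk_body("patella"))

  Rf <- as_matrix3(bd$femur$R_ref); Rt <- as_matrix3(bd$tibia$R_ref)
  Rp <- as_matrix3(bd$patella$R_ref)
  flex0 <- config$joints$flexion_ref
  R0_hinge <- t(rot_axis(axis, flex0)) %*% t(Rf) %*% Rt

  constraints <- list(
    list(type = "fixed_point", body = "femur",
         local = if (is.null(bd$femur$hip_local)) c(0, 0, 0) else bd$femur$hip_local,
         target = config$joints$hip_center),
    list(type = "coincident_points", body_a = "femur",
         local_a = bd$femur$knee_local,
         body_b = "tibia", local_b = bd$tibia$knee_local),
    list(type = "orientation_euler", body = "femur",
         angles = c("hip_z", "hip_x", "hip_y"), R0 = Rf),
    list(type = "orientation_hinge", body_a = "femur", body_b = "tibia",
         angle = "knee_flexion", axis = axis, R0 = R0_hinge),
    list(type = "driver", coord = "hip_z"),
    list(type = "driver", coord = "hip_x"),
    list(type = "driver", coord = "hip_y"),
    list(type = "driver", coord = "knee_flexion"))

  sp <- config$springs
  springs <- list(
    tibial = spring_damper(sp$tibial$body_a, sp$tibial$point_a,
                           sp$tibial$body_b, sp$tibial$point_b,
                           sp$tibial$stiffness, sp$tibial$natural_length,
                           sp$tibial$damping),
    femoral = spring_damper(sp$femoral$body_a, sp$femoral$point_a,
                            sp$femoral$body_b, sp$femoral$point_b,
                            sp$femoral$stiffness, sp$femoral$natural_length,
                            sp$femoral$damping))

  ct <- config$contact
  surface <- polynomial_surface(as_matrix(ct$surface$coefficients, 5, 5),
                                as.numeric(unlist(ct$surface$domain)),
                                frame = list(R = as_matrix3(ct$surface$frame_R),
                                             o = as.numeric(unlist(ct$surface$frame_o))))
  contacts <- list(contact_pair(
    sphere_body = "patella", center = ct$sphere$center,
    radius = ct$sphere$radius, surface = surface, surface_body = "femur",
    kn = ct$params$kn, p = ct$params$p, restitution = ct$params$eps))

  sset <- config$solver
  settings <- solver_settings(
    step_h = sset$step_h, penalty_value = sset$penalty_value,
    newmark_gamma = sset$newmark_gamma, newmark_beta = sset$newmark_beta,
    delta_f = sset$delta_f, delta_m = sset$delta_m,
    newton_tol = sset$newton_tol, max_newton_iters = sset$max_newton_iters,
    max_lambda_iters = sset$max_lambda_iters,
    projection_tolerance = sset$projection_tolerance,
    record_every = sset$record_every)

  q0 <- list(femur = list(r = bd$femur$r_ref, R = Rf),
             tibia = list(r = bd$tibia$r_ref, R = Rt),
             patella = list(r = bd$patella$r_ref, R = Rp),
             hip_z = 0, hip_x = 0, hip_y = 0, knee_flexion = flex0)

  sys <- multibody_system(
    bodies = bodies,
    extra_coords = c("hip_z", "hip_x", "hip_y", "knee_flexion"),
    constraints = constraints, springs = springs, contacts = contacts,
    gravity = config$gravity, q0 = q0,
    penalty = sset$penalty_value, settings = settings)

  sys$meta$leg <- list(
    hip_center = as.numeric(config$joints$hip_center),
    knee_marker_locals = rbind(as.numeric(bd$femur$markers$fem_knee_med),
                               as.numeric(bd$femur$markers$fem_knee_lat)),
    button_local = as.numeric(bd$patella$button_local),
    knee_axis = axis, flexion_ref = flex0,
    ref_femur = Rf, ref_rel = t(Rf) %*% Rt,
    configuration = config$configuration)
  sys$meta$config <- config
  sys
}

as_matrix3 <- function(x) as_matrix(x, 3, 3)
as_matrix <- function(x, nr, nc) {
  m <- matrix(as.numeric(unlist(x)), nr, nc)
  m
}

#' Synthesize a complete capture from the rig
#'
#' Runs the forward simulation of the patella under the given geometry and
#' motion, then renders 100 Hz marker positions (isotropic Gaussian noise)
#' and force channels (spring tensions and contact normal force, Gaussian
#' noise), returning the ground-truth trajectory alongside.
#'
#' @param geometry a `rig_geometry`.
#' @param motion a `guided_trajectory` from [generate_motion()].
#' @param noise_sigma marker noise standard deviation (m; default 0.5 mm).
#' @param seed RNG seed for the noise.
#' @param force_noise_sigma force channel noise (N).
#' @param solver optional [solver_settings()]; the record interval is forced
#'   to the capture rate.
#' @return list with `capture` ([marker_capture()]), `forces`
#'   ([force_record()]), `truth` (ground-truth `mbs_trajectory`), `system`,
#'   `config` and `guided`.
#' @export
synthesize_capture <- function(geometry, motion = generate_motion(),
                               noise_sigma = 5e-4, seed = 1L,
                               force_noise_sigma = 0.1,
                               solver = solver_settings()) {
  fs <- 1 / diff(motion$times[1:2])
  solver$record_every <- as.integer(round(1 / (fs * solver$step_h)))
  config <- rig_config(geometry, solver = solver)
  system <- build_leg_model(config)
  init <- solve_static_equilibrium(system)
  traj <- simulate_guided(system, motion, settings = solver, initial = init)
  if (traj$failed) stop("forward simulation of the synthetic rig failed")

  marker_locals <- c(lapply(config$bodies$femur$markers, as.numeric),
                     lapply(config$bodies$tibia$markers, as.numeric),
                     lapply(config$bodies$patella$markers, as.numeric))
  marker_body <- c(rep("femur", length(config$bodies$femur$markers)),
                   rep("tibia", length(config$bodies$tibia$markers)),
                   rep("patella", length(config$bodies$patella$markers)))
  nrec <- nrow(traj$q)
  positions <- lapply(seq_along(marker_locals), function(k) {
    P <- matrix(0, nrec, 3)
    for (i in seq_len(nrec))
      P[i, ] <- body_point(system, traj$q[i, ], marker_body[k],
                           marker_locals[[k]])
    P
  })
  names(positions) <- names(marker_locals)
  tib <- traj$tensions[, "tibial"]
  fem <- traj$tensions[, "femoral"]
  con <- traj$contact_force[, 1]
  withr_seed(seed, {
    if (noise_sigma > 0)
      positions <- lapply(positions, function(P)
        P + matrix(rnorm(length(P), 0, noise_sigma), nrow(P), 3))
    if (force_noise_sigma > 0) {
      tib <- tib + rnorm(nrec, 0, force_noise_sigma)
      fem <- fem + rnorm(nrec, 0, force_noise_sigma)
      con <- con + rnorm(nrec, 0, force_noise_sigma)
    }
  })
  capture <- marker_capture(traj$t, positions, fs = fs)
  forces <- force_record(traj$t, tibial_spring = tib, femoral_spring = fem,
                         contact_normal = con)
  list(capture = capture, forces = forces, truth = traj, system = system,
       config = config, guided = motion)
}

#' Synthesize a hip-center calibration capture
#'
#' Kinematic femur rotations about the fixed hip center (no dynamics); the
#' femur markers plus the two dedicated hip-calibration markers are
#' rendered, for use with [hip_center_from_calibration()].
#'
#' @param geometry a `rig_geometry`.
#' @param duration capture length (s).
#' @param amplitude_deg rotation amplitude about each hip axis.
#' @param noise_sigma marker noise (m).
#' @param seed RNG seed for the noise.
#' @param fs sampling rate (Hz).
#' @return a [marker_capture()].
#' @export
synthesize_calibration_capture <- function(geometry, duration = 4,
                                           amplitude_deg = 20,
                                           noise_sigma = 0, seed = 1L,
                                           fs = 100) {
  times <- seq(0, duration, by = 1 / fs)
  A <- amplitude_deg * pi / 180
  a1 <- A * sin(2 * pi * 0.4 * times)
  a2 <- A * 0.8 * sin(2 * pi * 0.27 * times + 1)
  a3 <- A * 0.6 * sin(2 * pi * 0.53 * times + 2)
  locals <- c(geometry$femur$markers, geometry$femur$calib_markers)
  hip <- geometry$hip_center
  positions <- lapply(locals, function(a) {
    P <- matrix(0, length(times), 3)
    for (i in seq_along(times)) {
      R <- euler_zxy(c(a1[i], a2[i], a3[i])) %*% geometry$femur$R_ref
      P[i, ] <- hip + as.numeric(R %*% a)
    }
    P
  })
  names(positions) <- names(locals)
  if (noise_sigma > 0)
    positions <- withr_seed(seed, lapply(positions, function(P)
      P + matrix(rnorm(length(P), 0, noise_sigma), nrow(P), 3)))
  marker_capture(times, positions, fs = fs)
}

#' @export
print.rig_geometry <- function(x, ...) {
  cat(sprintf("<rig_geometry> configuration %s; Q angle %.2f deg; button at (%.3f, %.3f, %.3f) m\n",
              x$configuration, q_angle(x),
              x$button_ref[1], x$button_ref[2], x$button_ref[3]))
  invisible(x)
}
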