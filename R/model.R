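# model_core: rigid bodies in natural coordinates, constraint set, assembly.
#
# Each body carries 12 dependent coordinates: its reference point r followed
# by the three columns u, v, w of its rotation matrix. Relative angle
# coordinates (the four guided degrees of freedom of the leg) are appended
# after the body blocks. Rigid-body (unit/orthogonality) constraints,
# joint constraints and rheonomic drivers close the system.

#' Define a rigid body
#'
#' @param name body label.
#' @param mass mass in kg (> 0).
#' @param inertia 3x3 symmetric positive-definite inertia tensor about the
#'   center of mass, expressed in the body frame (kg m^2). A length-3 vector
#'   is taken as the diagonal.
#' @param com center of mass in body-frame coordinates (m).
#' @param local_points named list of 3-vectors in the body frame (marker
#'   sites, spring attachments, sphere center, joint points).
#' @return object of class `rigid_body`.
#' @export
rigid_body <- function(name, mass, inertia, com = c(0, 0, 0), local_points = list()) {
  if (!is.numeric(mass) || length(mass) != 1 || !is.finite(mass) || mass <= 0)
    stop("mass must be a positive finite scalar")
  if (is.numeric(inertia) && length(inertia) == 3) inertia <- diag(inertia)
  if (!is.matrix(inertia) || any(dim(inertia) != 3))
    stop("inertia must be a 3x3 matrix or length-3 diagonal")
  if (max(abs(inertia - t(inertia))) > 1e-12 * max(abs(inertia)))
    stop("inertia tensor must be symmetric")
  ev <- eigen(inertia, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("inertia tensor must be positive definite")
  pts <- lapply(local_points, as.numeric)
  if (length(pts) && !all(vapply(pts, function(p) length(p) == 3 && all(is.finite(p)), TRUE)))
    stop("local_points must be finite 3-vectors")
  structure(list(name = name, mass = mass, inertia = inertia,
                 com = as.numeric(com), local_points = pts),
            class = "rigid_body")
}

#' Define a linear spring-damper
#'
#' Tension is positive in stretch: `T = k (l - l0) + c ldot`.
#'
#' @param body_a,body_b body names, or `NULL` for a ground anchor.
#' @param point_a,point_b attachment points: body-frame coordinates for a
#'   body, global coordinates for a ground anchor (m).
#' @param stiffness spring constant k in N/m (> 0).
#' @param natural_length unloaded length l0 in m (> 0).
#' @param damping viscous coefficient c in N s/m (>= 0).
#' @return object of class `spring_damper`.
#' @export
spring_damper <- function(body_a, point_a, body_b, point_b,
                          stiffness, natural_length, damping = 0) {
  if (stiffness <= 0) stop("stiffness must be > 0")
  if (natural_length <= 0) stop("natural_length must be > 0")
  if (damping < 0) stop("damping must be >= 0")
  structure(list(body_a = body_a, point_a = as.numeric(point_a),
                 body_b = body_b, point_b = as.numeric(point_b),
                 stiffness = stiffness, natural_length = natural_length,
                 damping = damping),
            class = "spring_damper")
}

# constant 12x12 natural-coordinate mass matrix of one body
body_mass_matrix <- function(body) {
  m <- body$mass; c0 <- body$com; Ic <- body$inertia
  Io <- Ic + m * (sum(c0^2) * diag(3) - tcrossprod(c0))   # inertia about body origin
  Sig <- 0.5 * sum(diag(Io)) * diag(3) - Io               # second-moment matrix
  J <- rbind(c(m, m * c0), cbind(m * c0, Sig))
  kronecker(J, diag(3))
}

# constant gravity generalized force of one body
body_gravity_force <- function(body, gravity) {
  m <- body$mass; c0 <- body$com
  c(m * gravity, c0[1] * m * gravity, c0[2] * m * gravity, c0[3] * m * gravity)
}

#' Assemble a multibody system
#'
#' Builds the container used by the solver: constant mass matrix, constraint
#' list, springs, contact pairs and the reference (assembled) configuration.
#'
#' @param bodies named list of [rigid_body()] objects (order defines the
#'   coordinate layout).
#' @param extra_coords character vector naming relative angle coordinates
#'   appended after the body blocks.
#' @param constraints list of constraint descriptors; supported types:
#'   `fixed_point` (body, local, target), `coincident_points`
#'   (body_a, local_a, body_b, local_b), `orientation_euler`
#'   (body, angles = 3 extra-coord names, R0), `orientation_hinge`
#'   (body_a, body_b, angle = extra-coord name, axis in body_a frame, R0),
#'   and `driver` (coord = extra-coord name). Rigid-body constraints are
#'   always added for every body.
#' @param springs list of [spring_damper()] objects.
#' @param contacts list of contact pair descriptors (see [contact_pair()]).
#' @param gravity gravity vector (m/s^2).
#' @param q0 reference configuration: named list per body with elements `r`
#'   and `R`, plus one scalar per extra coordinate.
#' @param penalty scalar penalty factor of the augmented Lagrangian
#'   formulation (entries of the diagonal matrix multiplying the constraint
#'   violations).
#' @param settings solver settings, see [solver_settings()].
#' @return object of class `mbs_system`.
#' @export
multibody_system <- function(bodies, extra_coords = character(),
                             constraints = list(), springs = list(),
                             contacts = list(), gravity = c(0, 0, -9.81),
                             q0 = NULL, penalty = 1e7,
                             settings = solver_settings()) {
  stopifnot(length(bodies) >= 1)
  bnames <- names(bodies)
  if (is.null(bnames) || any(bnames == ""))
    stop("bodies must be a named list")
  nb <- length(bodies)
  nx <- length(extra_coords)
  n <- 12 * nb + nx

  bid <- function(nm) {
    if (is.null(nm)) return(0L)
    i <- match(nm, bnames)
    if (is.na(i)) stop("unknown body: ", nm)
    as.integer(i)
  }
  xid <- function(nm) {
    i <- match(nm, extra_coords)
    if (is.na(i)) stop("unknown extra coordinate: ", nm)
    as.integer(12 * nb + i)
  }

  M <- matrix(0, n, n)
  Qg <- numeric(n)
  for (i in seq_len(nb)) {
    ix <- (12 * (i - 1) + 1):(12 * i)
    M[ix, ix] <- body_mass_matrix(bodies[[i]])
    Qg[ix] <- body_gravity_force(bodies[[i]], gravity)
  }

  fixpoints <- list(); coincidences <- list(); oeuler <- list()
  orel <- list(); drivers <- list(); driver_names <- character()
  for (cn in constraints) {
    type <- cn$type
    if (type == "fixed_point") {
      fixpoints[[length(fixpoints) + 1]] <-
        list(body = bid(cn$body), local = as.numeric(cn$local),
             target = as.numeric(cn$target))
    } else if (type == "coincident_points") {
      coincidences[[length(coincidences) + 1]] <-
        list(bodyA = bid(cn$body_a), localA = as.numeric(cn$local_a),
             bodyB = bid(cn$body_b), localB = as.numeric(cn$local_b))
    } else if (type == "orientation_euler") {
      oeuler[[length(oeuler) + 1]] <-
        list(body = bid(cn$body), idx = vapply(cn$angles, xid, 1L),
             R0 = cn$R0)
    } else if (type == "orientation_hinge") {
      orel[[length(orel) + 1]] <-
        list(bodyA = bid(cn$body_a), bodyB = bid(cn$body_b),
             idx = xid(cn$angle), axis = as.numeric(cn$axis), R0 = cn$R0)
    } else if (type == "driver") {
      drivers[[length(drivers) + 1]] <- list(coord = xid(cn$coord))
      driver_names <- c(driver_names, cn$coord)
    } else stop("unknown constraint type: ", type)
  }

  cts <- lapply(contacts, function(cp) {
    list(sphere_body = bid(cp$sphere_body), center = as.numeric(cp$center),
         radius = cp$radius, surf_body = bid(cp$surface_body),
         Rs = cp$frame_R, os = as.numeric(cp$frame_o),
         coef = cp$surface$coefficients, dom = as.numeric(cp$surface$fit_domain),
         kn = cp$kn, p = cp$p, eps = cp$restitution)
  })
  sps <- lapply(springs, function(s) {
    list(bodyA = bid(s$body_a), localA = s$point_a,
         bodyB = bid(s$body_b), localB = s$point_b,
         k = s$stiffness, l0 = s$natural_length, c = s$damping)
  })

  model <- list(n_bodies = as.integer(nb), n_extra = as.integer(nx),
                M = M, Qg = Qg, rigid = seq_len(nb),
                fixpoints = fixpoints, coincidences = coincidences,
                orient_euler = oeuler, orient_rel = orel,
                drivers = drivers, springs = sps, contacts = cts,
                alpha = penalty)
  m <- 6 * nb + 3 * length(fixpoints) + 3 * length(coincidences) +
    3 * length(oeuler) + 3 * length(orel) + length(drivers)
  if (m >= n) stop("constraint count m must be < number of coordinates")

  qref <- numeric(n)
  ref_driver <- numeric(length(drivers))
  if (!is.null(q0)) {
    for (i in seq_len(nb)) {
      e <- q0[[bnames[i]]]
      qref[(12 * (i - 1) + 1):(12 * i)] <- c(e$r, as.numeric(e$R))
    }
    for (j in seq_along(extra_coords)) {
      val <- q0[[extra_coords[j]]]
      qref[12 * nb + j] <- if (is.null(val)) 0 else val
    }
    if (length(driver_names))
      ref_driver <- qref[vapply(driver_names, xid, 1L)]
  } else {
    for (i in seq_len(nb)) qref[(12 * (i - 1) + 4):(12 * i)] <- as.numeric(diag(3))
  }

  sys <- structure(list(
    bodies = bodies, body_names = bnames, extra_coords = extra_coords,
    n_coords = n, n_constraints = m, model = model,
    driver_names = driver_names, ref_driver = ref_driver,
    q_ref = qref, gravity = gravity, penalty = penalty,
    springs = springs, contacts = contacts, settings = settings,
    meta = list()), class = "mbs_system")

  phi0 <- constraint_violation(sys, qref)
  if (!is.null(q0) && phi0 > 1e-8)
    stop(sprintf("reference configuration violates constraints (|Phi|_inf = %g)", phi0))
  sys
}

#' Describe a sphere-versus-surface contact pair
#'
#' @param sphere_body body carrying the spherical primitive.
#' @param center sphere center in the body frame (m).
#' @param radius sphere radius (m, > 0).
#' @param surface a [polynomial_surface()].
#' @param surface_body body the surface is attached to (`NULL` = ground).
#' @param frame_R,frame_o pose of the surface frame in the carrying body's
#'   frame (rotation, origin). Default: the surface's own `frame`.
#' @param kn equivalent contact stiffness (N/m^p).
#' @param p Hertz exponent (1.5 for a sphere on a smooth surface).
#' @param restitution coefficient of restitution in (0, 1].
#' @return contact pair descriptor (plain list).
#' @export
contact_pair <- function(sphere_body, center, radius, surface,
                         surface_body = NULL, frame_R = NULL, frame_o = NULL,
                         kn = 1e6, p = 1.5, restitution = 0.8) {
  if (radius <= 0) stop("radius must be > 0")
  if (kn <= 0) stop("kn must be > 0")
  if (p < 1) stop("Hertz exponent must be >= 1")
  if (restitution <= 0 || restitution > 1) stop("restitution must be in (0, 1]")
  if (is.null(frame_R)) frame_R <- surface$frame$R
  if (is.null(frame_o)) frame_o <- surface$frame$o
  list(sphere_body = sphere_body, center = as.numeric(center), radius = radius,
       surface = surface, surface_body = surface_body,
       frame_R = frame_R, frame_o = as.numeric(frame_o),
       kn = kn, p = p, restitution = restitution)
}

#' Solver settings
#'
#' @param step_h time step (s).
#' @param penalty_value penalty factor alpha (per constraint row).
#' @param newmark_gamma,newmark_beta Newmark parameters (trapezoidal rule by
#'   default: no numerical damping).
#' @param delta_f,delta_m generalized-alpha scalars multiplying the force and
#'   inertia blocks (1 = undamped Newmark).
#' @param newton_tol convergence tolerance on the Newton increment (inf-norm).
#' @param max_newton_iters,max_lambda_iters iteration caps for the Newton loop
#'   and the nested multiplier updates.
#' @param projection_tolerance tolerance on constraint norms after
#'   projections (and on |Phi|_inf at acceptance).
#' @param record_every record every k-th step in trajectories.
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(step_h = 1e-3, penalty_value = 1e7,
                            newmark_gamma = 0.5, newmark_beta = 0.25,
                            delta_f = 1, delta_m = 1,
                            newton_tol = 1e-10, max_newton_iters = 20,
                            max_lambda_iters = 10,
                            projection_tolerance = 1e-8, record_every = 1L) {
  stopifnot(step_h > 0, penalty_value > 0,
            newmark_beta >= 0, newmark_beta <= 0.5,
            newton_tol > 0, projection_tolerance > 0)
  structure(list(step_h = step_h, penalty_value = penalty_value,
                 newmark_gamma = newmark_gamma, newmark_beta = newmark_beta,
                 delta_f = delta_f, delta_m = delta_m,
                 newton_tol = newton_tol,
                 max_newton_iters = as.integer(max_newton_iters),
                 max_lambda_iters = as.integer(max_lambda_iters),
                 projection_tolerance = projection_tolerance,
                 record_every = as.integer(record_every)),
            class = "solver_settings")
}

# settings list in the layout the compiled core expects
cpp_settings <- function(settings) {
  list(step_h = settings$step_h,
       newmark_gamma = settings$newmark_gamma,
       newmark_beta = settings$newmark_beta,
       delta_f = settings$delta_f, delta_m = settings$delta_m,
       newton_tol = settings$newton_tol,
       projection_tol = settings$projection_tolerance,
       max_newton_iters = settings$max_newton_iters + settings$max_lambda_iters,
       record_every = settings$record_every)
}

#' Create a system state
#'
#' @param system an `mbs_system`.
#' @param q coordinate vector (defaults to the reference configuration).
#' @param qdot,qddot first/second derivatives (default zero).
#' @param t time (s).
#' @param lambda approximate Lagrange multipliers (default zero).
#' @return object of class `system_state`.
#' @export
system_state <- function(system, q = system$q_ref, qdot = NULL, qddot = NULL,
                         t = 0, lambda = NULL) {
  n <- system$n_coords; m <- system$n_constraints
  if (length(q) != n) stop("q has wrong length")
  if (is.null(qdot)) qdot <- numeric(n)
  if (is.null(qddot)) qddot <- numeric(n)
  if (is.null(lambda)) lambda <- numeric(m)
  if (length(qdot) != n || length(qddot) != n) stop("derivative vectors have wrong length")
  if (length(lambda) != m) stop("lambda has wrong length")
  structure(list(t = t, q = as.numeric(q), qdot = as.numeric(qdot),
                 qddot = as.numeric(qddot), lambda = as.numeric(lambda)),
            class = "system_state")
}

# driver positions/velocities/accelerations at time t; systems built without
# a guided trajectory hold their drivers at the reference values
driver_eval <- function(system, t) {
  nd <- length(system$driver_names)
  if (nd == 0)
    return(list(pos = numeric(0), vel = numeric(0), acc = numeric(0)))
  if (!is.null(system$meta$guided)) {
    g <- system$meta$guided
    list(pos = guided_eval(g, t, 0), vel = guided_eval(g, t, 1),
         acc = guided_eval(g, t, 2))
  } else {
    list(pos = system$ref_driver, vel = numeric(nd), acc = numeric(nd))
  }
}

#' Evaluate mass matrix, forces and constraints at a state
#'
#' Returns the building blocks of the equations of motion: the (constant)
#' mass matrix M, the generalized force vector Q (gravity, spring-dampers and
#' contact), the constraint vector Phi and its Jacobian Phiq.
#'
#' @param system an `mbs_system`.
#' @param state a [system_state()].
#' @return list with `M`, `Q`, `phi`, `phiq`, spring `tensions` and per-pair
#'   `contacts` diagnostics.
#' @export
assemble_system <- function(system, state) {
  d <- driver_eval(system, state$t)
  out <- .cpp_assemble(system$model, state$q, state$qdot, d$pos)
  names(out$tensions) <- names(system$springs)
  out
}

# inf-norm of the constraint vector at q
constraint_violation <- function(system, q, t = 0) {
  d <- driver_eval(system, t)
  out <- .cpp_assemble(system$model, q, numeric(system$n_coords), d$pos)
  if (length(out$phi) == 0) return(0)
  max(abs(out$phi))
}

#' Scalar tension of a linear spring-damper
#'
#' `T = k (l - l0) + c ldot` with `l = |p_b - p_a|`; positive in stretch.
#'
#' @param spring a [spring_damper()].
#' @param p_a,p_b endpoint positions (global, m).
#' @param v_a,v_b endpoint velocities (global, m/s).
#' @return tension in N.
#' @export
spring_tension <- function(spring, p_a, p_b, v_a = c(0, 0, 0), v_b = c(0, 0, 0)) {
  d <- p_b - p_a
  l <- sqrt(sum(d^2))
  if (l < 1e-9) stop("zero-length spring: endpoints coincide")
  n <- d / l
  ldot <- sum(n * (v_b - v_a))
  spring$stiffness * (l - spring$natural_length) + spring$damping * ldot
}

# pose of one body extracted from a coordinate vector
body_pose <- function(system, q, body) {
  i <- match(body, system$body_names)
  if (is.na(i)) stop("unknown body: ", body)
  b <- 12 * (i - 1)
  list(origin = q[b + 1:3], rotation = matrix(q[b + 4:12], 3, 3))
}

# global position of a body-frame point
body_point <- function(system, q, body, local) {
  p <- body_pose(system, q, body)
  as.numeric(p$origin + p$rotation %*% local)
}

# write a pose into a coordinate vector
set_body_pose <- function(system, q, body, origin, rotation) {
  i <- match(body, system$body_names)
  b <- 12 * (i - 1)
  q[b + 1:3] <- origin
  q[b + 4:12] <- as.numeric(rotation)
  q
}

#' Total mechanical energy of a state
#'
#' Kinetic energy plus gravitational, elastic spring and elastic contact
#' potential (the contact potential integrates the elastic part of the normal
#' force model). Useful for conservation checks with dissipation disabled.
#'
#' @param system an `mbs_system`.
#' @param state a [system_state()].
#' @return energy in J (gravity potential referenced to the origin).
#' @export
total_energy <- function(system, state) {
  q <- state$q; qd <- state$qdot
  ke <- 0.5 * sum(qd * (system$model$M %*% qd))
  pe_g <- -sum(system$model$Qg * q)
  pe_s <- 0
  for (s in system$springs) {
    pa <- if (is.null(s$body_a)) s$point_a else body_point(system, q, s$body_a, s$point_a)
    pb <- if (is.null(s$body_b)) s$point_b else body_point(system, q, s$body_b, s$point_b)
    l <- sqrt(sum((pb - pa)^2))
    pe_s <- pe_s + 0.5 * s$stiffness * (l - s$natural_length)^2
  }
  pe_c <- 0
  cts <- .cpp_contact_eval(system$model, q, qd)
  for (i in seq_along(cts)) {
    ct <- cts[[i]]
    if (ct$penetrating && ct$in_domain) {
      cp <- system$contacts[[i]]
      pe_c <- pe_c + cp$kn * ct$delta^(cp$p + 1) / (cp$p + 1)
    }
  }
  ke + pe_g + pe_s + pe_c
}

#' @export
print.mbs_system <- function(x, ...) {
  cat("<mbs_system> ", length(x$bodies), " bodies, ",
      x$n_coords, " coordinates, ", x$n_constraints, " constraints, ",
      length(x$springs), " springs, ", length(x$contacts), " contact pair(s)\n",
      sep = "")
  cat("  bodies:", paste(x$body_names, collapse = ", "), "\n")
  if (length(x$driver_names))
    cat("  guided dofs:", paste(x$driver_names, collapse = ", "), "\n")
  invisible(x)
}
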