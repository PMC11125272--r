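# dynamics_solver: augmented-Lagrangian index-3 stepping with projections
# (compiled core), static equilibrium, and the guided simulation loop.

#' Static equilibrium of the assembled system
#'
#' Solves the equilibrium equations obtained by removing accelerations and
#' velocity-dependent forces from the equations of motion: the constraint
#' reactions (approximate multipliers plus penalty terms) balance the
#' applied forces. Newton-Raphson with nested multiplier updates; the
#' solution reached is determined by the initial guess (systems in contact
#' may have several equilibria).
#'
#' @param system an `mbs_system`.
#' @param q_guess initial coordinates (default: reference configuration);
#'   must satisfy the constraints loosely (assembled configuration).
#' @param t time at which rheonomic drivers are held (s).
#' @param settings [solver_settings()]; `newton_tol` and
#'   `projection_tolerance` control convergence.
#' @param max_iters Newton iteration cap.
#' @return a [system_state()] at equilibrium (zero velocity/acceleration)
#'   with attributes `iterations` and `residual_norm`.
#' @export
solve_static_equilibrium <- function(system, q_guess = NULL, t = 0,
                                     settings = system$settings,
                                     max_iters = 120, relax = TRUE) {
  if (is.null(q_guess)) q_guess <- system$q_ref
  if (constraint_violation(system, q_guess, t) > 0.05)
    stop("infeasible initial guess: constraints violated beyond assembly tolerance")
  d <- driver_eval(system, t)
  solve_lm <- function(q) .cpp_static_equilibrium(system$model, q, d$pos,
                                                  settings$newton_tol,
                                                  settings$projection_tolerance,
                                                  max_iters)
  res <- solve_lm(q_guess)
  if (relax && (!res$converged || res$residual_norm > 1e-7)) {
    # dynamic relaxation: march the system with frozen drivers and strong
    # algorithmic velocity damping toward the attractor, then re-polish
    q <- if (res$residual_norm < 1) res$q else q_guess
    nd <- length(system$driver_names)
    for (round in 1:3) {
      sset <- settings
      sset$record_every <- 1000L
      cs <- cpp_settings(sset)
      cs$vel_scale <- 0.9
      nst <- 1500L
      dp <- matrix(rep(d$pos, each = nst + 1), nst + 1, nd)
      dz <- matrix(0, nst + 1, nd)
      sim <- .cpp_simulate(system$model, cs, q, numeric(0), res$lambda,
                           dp, dz, dz, t)
      if (isTRUE(sim$failed)) break
      q <- sim$q[nrow(sim$q), ]
      res <- solve_lm(q)
      if (res$converged && res$residual_norm <= 1e-7) break
    }
  }
  if (!res$converged)
    stop(sprintf("static equilibrium Newton iteration diverged (residual %g after %d iterations)",
                 res$residual_norm, res$iterations))
  st <- system_state(system, q = res$q, t = t, lambda = res$lambda)
  attr(st, "iterations") <- res$iterations
  attr(st, "residual_norm") <- res$residual_norm
  st
}

#' Advance one Newmark step
#'
#' Newmark predictor followed by Newton-Raphson on the index-3 augmented
#' Lagrangian residual with nested multiplier updates; optionally applies
#' the velocity/acceleration projections to the accepted state.
#'
#' @param system an `mbs_system`.
#' @param state current [system_state()].
#' @param settings [solver_settings()].
#' @param project apply the constraint-subspace projections (default TRUE).
#' @return the next `system_state` with attributes `iters` and `phi_norm`.
#' @export
newmark_step <- function(system, state, settings = system$settings,
                         project = TRUE) {
  t1 <- state$t + settings$step_h
  d <- driver_eval(system, t1)
  res <- .cpp_newmark_step(system$model, cpp_settings(settings),
                           state$q, state$qdot, state$qddot, state$lambda,
                           d$pos, d$vel, d$acc, project)
  st <- system_state(system, q = res$q, qdot = res$qdot, qddot = res$qddot,
                     t = t1, lambda = res$lambda)
  attr(st, "iters") <- res$iters
  attr(st, "phi_norm") <- res$phi_norm
  st
}

#' Project velocities and accelerations onto the constraint subspaces
#'
#' Mass-weighted (minimal kinetic-energy change) projections: the projected
#' velocity solves the KKT system of the mass-weighted least-squares problem
#' subject to the velocity-level constraints, and likewise for the
#' accelerations.
#'
#' @param system an `mbs_system`.
#' @param state a [system_state()].
#' @return state with `qdot`, `qddot` replaced; attributes `vel_norm` and
#'   `acc_norm` report the residual constraint norms.
#' @export
project_state <- function(system, state) {
  d <- driver_eval(system, state$t)
  res <- .cpp_project(system$model, state$q, state$qdot, state$qddot,
                      d$pos, d$vel, d$acc)
  st <- system_state(system, q = state$q, qdot = res$qdot, qddot = res$qddot,
                     t = state$t, lambda = state$lambda)
  attr(st, "vel_norm") <- res$vel_norm
  attr(st, "acc_norm") <- res$acc_norm
  st
}

#' Simulate the system along a guided trajectory
#'
#' Time loop of [newmark_step()] plus projections at the solver step size,
#' with the rheonomic drivers following the guided splines. Logs spring
#' tensions, contact force, constraint norms and the patellar button center
#' in the femur anatomical frame (when the system carries the leg metadata);
#' dislocation events are recorded whenever an active contact leaves the
#' fitted surface domain.
#'
#' @param system an `mbs_system`.
#' @param guided a `guided_trajectory` covering the simulated span (ignored
#'   if the system has no drivers).
#' @param settings [solver_settings()].
#' @param initial initial [system_state()] (typically from
#'   [solve_static_equilibrium()]).
#' @param duration simulated time (s); default: the guided time span.
#' @return object of class `mbs_trajectory`.
#' @export
simulate_guided <- function(system, guided = NULL, settings = system$settings,
                            initial = NULL, duration = NULL) {
  nd <- length(system$driver_names)
  if (nd > 0 && is.null(guided) && is.null(system$meta$guided))
    stop("system has guided dofs but no guided trajectory was given")
  if (!is.null(guided)) system$meta$guided <- guided
  if (is.null(initial)) initial <- solve_static_equilibrium(system)
  t0 <- initial$t
  if (is.null(duration)) {
    duration <- if (!is.null(system$meta$guided))
      max(system$meta$guided$times) - t0 else 1
  }
  h <- settings$step_h
  nsteps <- max(1L, as.integer(round(duration / h)))
  tgrid <- t0 + h * (0:nsteps)
  if (nd > 0) {
    g <- system$meta$guided
    dpos <- guided_eval(g, tgrid, 0)
    dvel <- guided_eval(g, tgrid, 1)
    dacc <- guided_eval(g, tgrid, 2)
  } else {
    dpos <- dvel <- dacc <- matrix(0, nsteps + 1, 0)
  }
  raw <- .cpp_simulate(system$model, cpp_settings(settings), initial$q,
                       initial$qdot, initial$lambda, dpos, dvel, dacc, t0)
  build_trajectory(system, raw, settings)
}

# assemble the R-side trajectory object from the compiled-core record
build_trajectory <- function(system, raw, settings) {
  tr <- list(t = as.numeric(raw$t), q = raw$q, qdot = raw$qdot, qddot = raw$qddot,
             phi_norm = as.numeric(raw$phi_norm),
             vel_norm = as.numeric(raw$vel_norm),
             acc_norm = as.numeric(raw$acc_norm),
             newton_iters = as.integer(raw$newton_iters),
             tensions = raw$tensions, contact_force = raw$contact_force,
             contact_delta = raw$contact_delta,
             contact_active = raw$contact_active,
             contact_u = raw$contact_u, contact_v = raw$contact_v,
             events = raw$events, failed = isTRUE(raw$failed),
             fail_step = raw$fail_step, settings = settings,
             system = system)
  if (length(system$springs) == ncol(tr$tensions))
    colnames(tr$tensions) <- names(system$springs)
  leg <- system$meta$leg
  if (!is.null(leg)) {
    nrec <- nrow(raw$q)
    but <- matrix(0, nrec, 3)
    for (i in seq_len(nrec)) {
      q <- raw$q[i, ]
      pp <- body_pose(system, q, "patella")
      km1 <- body_point(system, q, "femur", leg$knee_marker_locals[1, ])
      km2 <- body_point(system, q, "femur", leg$knee_marker_locals[2, ])
      but[i, ] <- patella_in_femur_frame(pp, leg$button_local, leg$hip_center,
                                         rbind(km1, km2))
    }
    colnames(but) <- c("X", "Y", "Z")
    tr$button_femur <- but
    kf <- match("knee_flexion", system$extra_coords)
    if (!is.na(kf))
      tr$knee_flexion_deg <- raw$q[, 12 * length(system$bodies) + kf] * 180 / pi
    if (nrow(tr$events) > 0) {
      ev_flex <- approx(tr$t, tr$knee_flexion_deg, xout = tr$events[, 1],
                        rule = 2)$y
      tr$events <- cbind(tr$events, ev_flex)
      colnames(tr$events) <- c("time", "contact", "knee_flexion_deg")
    } else {
      tr$events <- matrix(numeric(0), 0, 3,
                          dimnames = list(NULL, c("time", "contact", "knee_flexion_deg")))
    }
  }
  class(tr) <- "mbs_trajectory"
  tr
}

#' Number of dislocation events in a trajectory
#' @param trajectory an `mbs_trajectory`.
#' @return integer count.
#' @export
dislocation_count <- function(trajectory) nrow(trajectory$events)

#' Extract a [system_state()] from a trajectory row
#' @param trajectory an `mbs_trajectory`.
#' @param i row index (default: last).
#' @return a `system_state`.
#' @export
trajectory_state <- function(trajectory, i = nrow(trajectory$q)) {
  system_state(trajectory$system, q = trajectory$q[i, ],
               qdot = trajectory$qdot[i, ], qddot = trajectory$qddot[i, ],
               t = trajectory$t[i])
}

#' @export
print.mbs_trajectory <- function(x, ...) {
  cat(sprintf("<mbs_trajectory> %d recorded states over %.3f s%s\n",
              nrow(x$q), diff(range(x$t)),
              if (x$failed) sprintf(" [FAILED at step %d]", x$fail_step) else ""))
  cat(sprintf("  max |Phi|_inf = %.3g, max Newton iters = %d\n",
              max(x$phi_norm), max(x$newton_iters)))
  if (!is.null(x$events) && nrow(x$events) > 0)
    cat(sprintf("  dislocation events: %d (first at t = %.3f s)\n",
                nrow(x$events), x$events[1, 1]))
  invisible(x)
}

#' Trajectory channels as a data frame
#'
#' Columns: time, patellar button center in the femur anatomical frame
#' (X/Y/Z), spring tensions, contact normal force and knee flexion.
#'
#' @param x an `mbs_trajectory` from the leg model.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.mbs_trajectory <- function(x, ...) {
  df <- data.frame(time = x$t)
  if (!is.null(x$button_femur)) {
    df$button_x <- x$button_femur[, 1]
    df$button_y <- x$button_femur[, 2]
    df$button_z <- x$button_femur[, 3]
  }
  if (ncol(x$tensions) > 0)
    for (nm in colnames(x$tensions)) df[[paste0(nm, "_N")]] <- x$tensions[, nm]
  if (ncol(x$contact_force) > 0) df$contact_N <- x$contact_force[, 1]
  if (!is.null(x$knee_flexion_deg)) df$knee_flexion_deg <- x$knee_flexion_deg
  df
}
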