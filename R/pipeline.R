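# rig_io_cli: pipeline orchestration - filter, reconstruct, equilibrate,
# simulate, optionally optimize, and report agreement.

#' Reconstruct body poses and guided angles from a capture
#'
#' Filters the marker trajectories (zero-phase Butterworth), registers the
#' configured body-frame marker coordinates to the measured positions frame
#' by frame (least-squares rigid registration), and extracts the four guided
#' angles in the model's conventions.
#'
#' @param capture a [marker_capture()].
#' @param system the leg `mbs_system` (supplies marker locals and reference
#'   orientations).
#' @param filter apply the 12 Hz zero-phase Butterworth filter first.
#' @return list: `guided` (a `guided_trajectory`), `poses` (per-body pose
#'   lists) and the filtered `capture`.
#' @export
reconstruct_kinematics <- function(capture, system, filter = TRUE) {
  if (filter) capture <- filter_capture(capture)
  cfg <- system$meta$config
  leg <- system$meta$leg
  n <- length(capture$times)
  pose_series <- function(body) {
    locs <- cfg$bodies[[body]]$markers
    labs <- names(locs)
    miss <- setdiff(labs, capture$labels)
    if (length(miss)) stop("capture is missing required markers: ",
                           paste(miss, collapse = ", "))
    L <- do.call(rbind, lapply(locs, as.numeric))
    lapply(seq_len(n), function(i) {
      G <- do.call(rbind, lapply(labs, function(lb) capture$positions[[lb]][i, ]))
      body_pose_from_markers(L, G)
    })
  }
  poses <- list(femur = pose_series("femur"), tibia = pose_series("tibia"),
                patella = pose_series("patella"))
  guided <- extract_guided_angles(capture$times, poses$femur, poses$tibia,
                                  knee_axis = leg$knee_axis,
                                  ref_femur = leg$ref_femur,
                                  ref_rel = leg$ref_rel,
                                  flexion_ref = leg$flexion_ref)
  list(guided = guided, poses = poses, capture = capture)
}

# reference button path (femur frame) from reconstructed poses
button_path_from_poses <- function(poses, system) {
  leg <- system$meta$leg
  n <- length(poses$patella)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    fp <- poses$femur[[i]]
    km1 <- fp$origin + as.numeric(fp$rotation %*% leg$knee_marker_locals[1, ])
    km2 <- fp$origin + as.numeric(fp$rotation %*% leg$knee_marker_locals[2, ])
    hip <- fp$origin  # femur body origin is the hip center in this model
    out[i, ] <- patella_in_femur_frame(poses$patella[[i]], leg$button_local,
                                       hip, rbind(km1, km2))
  }
  out
}

# initial coordinate vector from reconstructed poses at the first sample
state_guess_from_poses <- function(system, poses, guided) {
  q <- system$q_ref
  for (b in c("femur", "tibia", "patella")) {
    p <- poses[[b]][[1]]
    q <- set_body_pose(system, q, b, p$origin, p$rotation)
  }
  nb <- length(system$bodies)
  q[12 * nb + 1:4] <- guided$angles[1, ]
  q
}

#' Run the full simulation pipeline on recorded data
#'
#' Stages: read inputs, filter, reconstruct kinematics, solve the initial
#' static equilibrium, simulate, optionally optimize the spring parameters,
#' and write the trajectory CSV, the agreement report CSV and a JSON run
#' summary.
#'
#' @param run_config list (or path to a YAML file) with entries:
#'   `markers` (capture CSV/TRC), `forces` (force CSV), `rig` (rig config
#'   YAML), `output_dir`; optional `configuration` label, `optimize` flag,
#'   `seed`, `units`, `filter`.
#' @return invisible list with the artifacts (`trajectory`, `report`,
#'   `summary`) and their paths.
#' @export
run_pipeline <- function(run_config) {
  if (is.character(run_config)) run_config <- yaml::read_yaml(run_config)
  for (f in c("markers", "forces", "rig", "output_dir"))
    if (is.null(run_config[[f]])) stop("run configuration is missing: ", f)
  for (f in c("markers", "forces", "rig"))
    if (!file.exists(run_config[[f]])) stop("input file does not exist: ",
                                            run_config[[f]])
  out_dir <- run_config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(run_config$seed)) 1L else as.integer(run_config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  config <- stage("read-config", read_rig_config(run_config$rig))
  system <- stage("build-model", build_leg_model(config))
  capture <- stage("read-markers",
                   read_capture(run_config$markers, units = run_config$units))
  forces <- stage("read-forces", read_forces(run_config$forces))

  do_filter <- !isFALSE(run_config$filter)
  rec <- stage("reconstruct", reconstruct_kinematics(capture, system,
                                                     filter = do_filter))
  ref_button <- stage("reference-path", button_path_from_poses(rec$poses, system))
  reference <- list(forces = forces, button = ref_button)

  q_guess <- stage("initial-guess",
                   state_guess_from_poses(system, rec$poses, rec$guided))
  system$meta$guided <- rec$guided
  init <- stage("static-equilibrium",
                solve_static_equilibrium(system, q_guess = q_guess,
                                         t = capture$times[1]))
  traj <- stage("simulate",
                simulate_guided(system, rec$guided, initial = init,
                                settings = simulation_settings(system, capture)))
  if (traj$failed)
    warning("simulation failed mid-run; writing the partial trajectory")

  label <- if (is.null(run_config$configuration)) "B" else run_config$configuration
  report <- stage("agreement", agreement_report(traj, reference,
                                                config_label = label,
                                                parameter_set = "original"))
  opt <- NULL
  if (isTRUE(run_config$optimize)) {
    defaults <- spring_parameters(system)
    problem <- optimization_problem(defaults, seed = seed,
                                    population = run_config$population %||% 30L,
                                    generations = run_config$generations %||% 15L)
    opt <- stage("optimize", optimize_parameters(problem, system, rec$guided,
                                                 reference,
                                                 settings = simulation_settings(system, capture)))
    sys_opt <- set_spring_parameters(system, opt$par)
    init_opt <- stage("static-equilibrium-optimized",
                      solve_static_equilibrium(sys_opt, q_guess = q_guess,
                                               t = capture$times[1]))
    traj_opt <- stage("simulate-optimized",
                      simulate_guided(sys_opt, rec$guided, initial = init_opt,
                                      settings = simulation_settings(system, capture)))
    report_opt <- agreement_report(traj_opt, reference, config_label = label,
                                   parameter_set = "optimized")
    report <- rbind(report, report_opt)
  }

  traj_path <- file.path(out_dir, "trajectory.csv")
  report_path <- file.path(out_dir, "agreement.csv")
  summary_path <- file.path(out_dir, "run_summary.json")
  write_trajectory(traj, traj_path)
  write.csv(report, report_path, row.names = FALSE)
  summary <- list(
    configuration = label, seed = seed,
    settings = unclass(traj$settings),
    n_steps = nrow(traj$q) - 1L,
    max_constraint_violation = max(traj$phi_norm),
    max_newton_iters = max(traj$newton_iters),
    dislocation_events = lapply(seq_len(nrow(traj$events)), function(i)
      list(time = traj$events[i, 1], contact = traj$events[i, 2],
           knee_flexion_deg = traj$events[i, 3])),
    n_dislocations = nrow(traj$events),
    failed = traj$failed,
    optimized = if (!is.null(opt))
      list(par = as.list(opt$par), objective = opt$objective,
           default_objective = opt$default_objective) else NULL)
  write_run_summary(summary, summary_path)
  invisible(list(trajectory = traj, report = report, summary = summary,
                 optimization = opt,
                 paths = list(trajectory = traj_path, report = report_path,
                              summary = summary_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# solver settings matched to the capture rate (record at capture samples)
simulation_settings <- function(system, capture) {
  s <- system$settings
  s$record_every <- as.integer(round(1 / (capture$fs * s$step_h)))
  s
}

#' Materialize a complete synthetic dataset on disk
#'
#' Writes, for each requested configuration, the marker CSV, force CSV, rig
#' configuration YAML and the ground-truth trajectory CSV of one synthetic
#' capture.
#'
#' @param output_dir target directory.
#' @param configurations subset of `c("A", "B")`.
#' @param seed noise seed.
#' @param noise_sigma marker noise (m).
#' @param motion a `guided_trajectory` (default: the standard maneuver).
#' @return invisible named list of per-configuration file paths.
#' @export
synthesize_dataset <- function(output_dir, configurations = c("A", "B"),
                               seed = 1L, noise_sigma = 5e-4,
                               motion = generate_motion()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (cfg in configurations) {
    geom <- generate_rig_geometry(cfg, seed = seed)
    syn <- synthesize_capture(geom, motion, noise_sigma = noise_sigma,
                              seed = seed)
    base <- file.path(output_dir, paste0("config_", cfg))
    paths <- list(markers = paste0(base, "_markers.csv"),
                  forces = paste0(base, "_forces.csv"),
                  rig = paste0(base, "_rig.yaml"),
                  truth = paste0(base, "_truth.csv"))
    write_capture(syn$capture, paths$markers, units = "mm")
    write_forces(syn$forces, paths$forces)
    write_rig_config(syn$config, paths$rig)
    write_trajectory(syn$truth, paths$truth)
    out[[cfg]] <- paths
  }
  invisible(out)
}
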