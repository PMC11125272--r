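# kinematics: signal conditioning (zero-phase Butterworth, SSA), rigid-body
# pose reconstruction from markers, hip-center pivot calibration, guided
# joint angles, and femur-frame patella coordinates.

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward (zero-phase) application of a low-pass Butterworth
#' filter; the two passes square the magnitude response, giving effective
#' attenuation of twice the design order while cancelling phase distortion.
#'
#' @param signal uniformly sampled numeric vector.
#' @param cutoff_hz cutoff frequency (Hz).
#' @param order filter order of each pass.
#' @param fs_hz sampling frequency (Hz).
#' @return filtered vector, same length; DC gain 1.
#' @export
zero_phase_butterworth <- function(signal, cutoff_hz = 12, order = 2, fs_hz = 100) {
  if (length(signal) < 3 * order)
    stop("signal too short for filtering (need at least 3 x order samples)")
  if (anyNA(signal)) stop("signal contains NA")
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2)
    stop("cutoff must lie in (0, fs/2)")
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  # forward-backward pass over an odd-reflection-padded copy: the padding
  # absorbs the start-up transients of both passes (value and slope are
  # continuous at the joins), keeping the edges of the signal clean
  n <- length(signal)
  np <- min(n - 1, 60)
  left <- 2 * signal[1] - signal[(np + 1):2]
  right <- 2 * signal[n] - signal[(n - 1):(n - np)]
  x <- c(left, signal, right)
  y <- as.numeric(signal::filter(bf, x))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(np + 1):(np + n)]
}

#' Singular spectrum analysis smoothing
#'
#' Embeds the series in a Hankel trajectory matrix of the given window
#' length, keeps the leading singular components, and reconstructs by
#' diagonal averaging. By default components are kept until they explain
#' 99.5% of the singular-value energy, capped at `max_components`.
#'
#' @param signal numeric vector (length > window).
#' @param window embedding window length L.
#' @param n_components number of components to keep (overrides the energy
#'   rule when given).
#' @param energy cumulative share of squared singular values to retain.
#' @param max_components cap on the automatic component count.
#' @return smoothed vector, same length; attribute `n_components` records
#'   the number of components used.
#' @export
ssa_smooth <- function(signal, window = 30, n_components = NULL,
                       energy = 0.995, max_components = 5) {
  N <- length(signal)
  if (window >= N) stop("window must be smaller than the signal length")
  if (window < 2) stop("window must be at least 2")
  L <- window; K <- N - L + 1
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- signal[i:(i + K - 1)]
  sv <- svd(X)
  if (is.null(n_components)) {
    en <- cumsum(sv$d^2) / sum(sv$d^2)
    n_components <- min(which(en >= energy)[1], max_components)
    if (is.na(n_components)) n_components <- max_components
  }
  r <- min(n_components, length(sv$d))
  Xr <- sv$u[, seq_len(r), drop = FALSE] %*%
    (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
  # diagonal (anti-diagonal) averaging back to a series
  out <- numeric(N); cnt <- numeric(N)
  for (i in seq_len(L)) {
    idx <- i:(i + K - 1)
    out[idx] <- out[idx] + Xr[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  res <- out / cnt
  attr(res, "n_components") <- r
  res
}

#' Orthogonal segment frame from three non-collinear points
#'
#' Vaughan-style construction: origin at `p1`, x-axis toward `p2`, z-axis
#' along the triangle normal, y completing a right-handed frame.
#'
#' @param p1,p2,p3 global 3-vectors (m).
#' @return list of class `pose`: `origin` and 3x3 `rotation`.
#' @export
segment_pose_from_markers <- function(p1, p2, p3) {
  e1 <- p2 - p1
  e2 <- p3 - p1
  nz <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  area2 <- sqrt(sum(nz^2))
  if (area2 / 2 < 1e-8) stop("collinear points: cannot define a segment frame")
  x <- e1 / sqrt(sum(e1^2))
  z <- nz / area2
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
  structure(list(origin = p1, rotation = cbind(x, y, z, deparse.level = 0)),
            class = "pose")
}

#' Least-squares rigid-body pose from labelled markers
#'
#' Kabsch/Procrustes registration of known body-frame marker coordinates to
#' measured global positions; this is the "correlation equations" step of the
#' classical three-entity segment construction, generalized to any number of
#' markers (>= 3, non-collinear).
#'
#' @param locals n x 3 body-frame marker coordinates.
#' @param globals n x 3 measured global coordinates.
#' @return list of class `pose` (`origin`, `rotation`) with attribute
#'   `residual_rms`.
#' @export
body_pose_from_markers <- function(locals, globals) {
  locals <- as.matrix(locals); globals <- as.matrix(globals)
  stopifnot(nrow(locals) >= 3, all(dim(locals) == dim(globals)))
  cl <- colMeans(locals); cg <- colMeans(globals)
  H <- crossprod(sweep(locals, 2, cl), sweep(globals, 2, cg))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  origin <- cg - as.numeric(R %*% cl)
  fit <- sweep(locals %*% t(R), 2, origin, "+")
  structure(list(origin = origin, rotation = R),
            class = "pose",
            residual_rms = sqrt(mean(rowSums((fit - globals)^2))))
}

#' Hip center from a calibration capture (pivot sphere fit)
#'
#' Finds the fixed point about which the markers of a rotating segment
#' pivot: each marker keeps a constant distance to the hip center, which
#' leads to a linear least-squares system for the center (shared across
#' markers) and one squared radius per marker.
#'
#' @param capture a [marker_capture()] containing the calibration movement
#'   (markers rigidly attached to the pivoting femur).
#' @param markers marker labels to use (default: all).
#' @param cond_tol reject captures whose pivot system has a condition number
#'   above this value (insufficient rotation).
#' @return hip center 3-vector (m) with attribute `residual_rms`.
#' @export
hip_center_from_calibration <- function(capture, markers = NULL, cond_tol = 1e6) {
  if (is.null(markers)) markers <- capture$labels
  if (length(markers) < 2) stop("need at least 2 markers for the pivot fit")
  rows <- list(); rhs <- list()
  nm <- length(markers)
  for (k in seq_along(markers)) {
    P <- capture$positions[[markers[k]]]        # n x 3
    ind <- matrix(0, nrow(P), nm)
    ind[, k] <- 1
    rows[[k]] <- cbind(2 * P, ind)
    rhs[[k]] <- rowSums(P^2)
  }
  A <- do.call(rbind, rows)
  b <- unlist(rhs)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > cond_tol)
    stop("pivot unobservable: calibration capture has insufficient rotation")
  beta <- qr.coef(qr(A), b)
  center <- beta[1:3]
  res <- numeric(0)
  for (k in seq_along(markers)) {
    P <- capture$positions[[markers[k]]]
    dist <- sqrt(rowSums(sweep(P, 2, center)^2))
    res <- c(res, dist - mean(dist))
  }
  structure(as.numeric(center), residual_rms = sqrt(mean(res^2)))
}

#' Guided joint angles from femur and tibia pose series
#'
#' Hip angles are the intrinsic Z-X-Y Euler angles of the femur rotation
#' relative to `ref_femur`; knee flexion is the signed rotation of the tibia
#' relative to the femur about the knee axis, offset by `flexion_ref`.
#' Derivative channels come from natural cubic spline differentiation.
#'
#' @param times sample times (s).
#' @param femur_poses,tibia_poses lists of poses (one per sample).
#' @param knee_axis hinge axis in the femur body frame (unit 3-vector).
#' @param ref_femur femur reference rotation (hip angles measured relative
#'   to it; default identity).
#' @param ref_rel tibia-vs-femur reference relative rotation at
#'   `flexion_ref` (default identity).
#' @param flexion_ref knee flexion at the reference relative pose (rad).
#' @return a `guided_trajectory`: angle channels (rad) plus spline
#'   evaluators for derivatives. Samples within 1 degree of the Euler gimbal
#'   singularity are flagged via the `gimbal` attribute.
#' @export
extract_guided_angles <- function(times, femur_poses, tibia_poses, knee_axis,
                                  ref_femur = diag(3), ref_rel = diag(3),
                                  flexion_ref = 0) {
  n <- length(times)
  stopifnot(length(femur_poses) == n, length(tibia_poses) == n)
  ang <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    Rf <- femur_poses[[i]]$rotation
    Rt <- tibia_poses[[i]]$rotation
    E <- Rf %*% t(ref_femur)
    ang[i, 1:3] <- euler_zxy_inverse(E)
    # relative rotation vs the reference hinge pose: a rotation about the axis
    Drel <- t(Rf) %*% Rt %*% t(ref_rel)
    ang[i, 4] <- flexion_ref + axis_angle_about(Drel, knee_axis)
  }
  # unwrap each channel to avoid 2*pi jumps
  for (j in 1:4) {
    dj <- diff(ang[, j])
    jumps <- round(dj / (2 * pi))
    if (any(jumps != 0)) ang[, j] <- ang[, j] - c(0, cumsum(jumps)) * 2 * pi
  }
  gimbal <- abs(abs(ang[, 2]) - pi / 2) < pi / 180
  if (any(gimbal)) warning("hip angles close to the gimbal singularity")
  g <- guided_trajectory(times, ang)
  attr(g, "gimbal") <- gimbal
  g
}

#' Guided trajectory container
#'
#' Stores the four driven angle channels (three hip, one knee) and natural
#' cubic spline evaluators for values and first/second derivatives.
#'
#' @param times sample times (s), uniform.
#' @param angles n x 4 matrix (hip_z, hip_x, hip_y, knee_flexion), rad.
#' @return object of class `guided_trajectory`.
#' @export
guided_trajectory <- function(times, angles) {
  angles <- as.matrix(angles)
  stopifnot(nrow(angles) == length(times), ncol(angles) == 4)
  sf <- lapply(seq_len(4), function(j)
    splinefun(times, angles[, j], method = "natural"))
  structure(list(times = times, angles = angles, splines = sf),
            class = "guided_trajectory")
}

# evaluate all four channels (deriv = 0, 1, 2) at times t -> matrix
guided_eval <- function(g, t, deriv = 0) {
  out <- vapply(g$splines, function(f) f(t, deriv = deriv), numeric(length(t)))
  if (length(t) == 1) out <- matrix(out, 1, 4)
  out
}

#' @export
print.guided_trajectory <- function(x, ...) {
  cat(sprintf("<guided_trajectory> %d samples over %.3f s; knee flexion %.1f..%.1f deg\n",
              length(x$times), diff(range(x$times)),
              min(x$angles[, 4]) * 180 / pi, max(x$angles[, 4]) * 180 / pi))
  invisible(x)
}

#' Femur anatomical frame
#'
#' Origin at the hip center; Y along the knee marker pair; Z normal to Y and
#' to the hip-knee vector; X completes the right-handed triad.
#'
#' @param hip_center global hip center (m).
#' @param knee_marker_1,knee_marker_2 global positions of the two markers on
#'   each side of the knee (m).
#' @return list with `origin` and `rotation` (columns X, Y, Z).
#' @export
femur_anatomical_frame <- function(hip_center, knee_marker_1, knee_marker_2) {
  if (max(abs(knee_marker_1 - knee_marker_2)) < 1e-12)
    stop("knee markers coincide")
  y <- knee_marker_2 - knee_marker_1
  y <- y / sqrt(sum(y^2))
  km <- (knee_marker_1 + knee_marker_2) / 2
  d <- km - hip_center
  z <- c(d[2] * y[3] - d[3] * y[2], d[3] * y[1] - d[1] * y[3], d[1] * y[2] - d[2] * y[1])
  nz <- sqrt(sum(z^2))
  if (nz < 1e-10) stop("degenerate frame: hip center lies on the knee axis")
  z <- z / nz
  x <- c(y[2] * z[3] - y[3] * z[2], y[3] * z[1] - y[1] * z[3], y[1] * z[2] - y[2] * z[1])
  list(origin = hip_center, rotation = cbind(x, y, z, deparse.level = 0))
}

#' Patellar button center in the femur anatomical frame
#'
#' @param patella_pose pose of the patella body.
#' @param button_center_local button center in the patella frame (m).
#' @param hip_center global hip center (m).
#' @param knee_markers 2 x 3 matrix: global positions of the two knee
#'   markers.
#' @return 3-vector: button center coordinates in the femur anatomical
#'   frame (m).
#' @export
patella_in_femur_frame <- function(patella_pose, button_center_local,
                                   hip_center, knee_markers) {
  fr <- femur_anatomical_frame(hip_center, knee_markers[1, ], knee_markers[2, ])
  b <- patella_pose$origin + as.numeric(patella_pose$rotation %*% button_center_local)
  as.numeric(crossprod(fr$rotation, b - fr$origin))
}

#' Marker capture container
#'
#' @param times sample times (s), uniform at the capture rate.
#' @param positions named list of n x 3 matrices, one per marker (m).
#' @param fs sampling frequency (Hz).
#' @return object of class `marker_capture`.
#' @export
marker_capture <- function(times, positions, fs = 100) {
  labels <- names(positions)
  if (is.null(labels) || any(labels == "")) stop("positions must be a named list")
  n <- length(times)
  ok <- vapply(positions, function(p) is.matrix(p) && nrow(p) == n && ncol(p) == 3, TRUE)
  if (!all(ok)) stop("each marker needs an n x 3 position matrix")
  if (n >= 2) {
    dt <- diff(times)
    if (max(abs(dt - 1 / fs)) > 1e-9)
      stop("non-uniform sampling: time stamps deviate from the capture rate")
  }
  structure(list(labels = labels, times = times, positions = positions, fs = fs),
            class = "marker_capture")
}

#' Fill short marker drop-out gaps
#'
#' Linear interpolation of missing samples (NA runs) up to `max_gap`
#' samples; longer gaps are an error. Captures must be gap-free before
#' filtering or pose reconstruction.
#'
#' @param positions n x 3 marker position matrix possibly containing NA runs.
#' @param max_gap longest gap (samples) that may be interpolated.
#' @return gap-free n x 3 matrix.
#' @export
fill_marker_gaps <- function(positions, max_gap = 5) {
  P <- as.matrix(positions)
  bad <- which(rowSums(is.na(P)) > 0)
  if (!length(bad)) return(P)
  runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
  too_long <- vapply(runs, length, 1L) > max_gap
  if (any(too_long))
    stop("marker gap longer than ", max_gap, " samples")
  if (1 %in% bad || nrow(P) %in% bad)
    stop("cannot interpolate a gap at the capture boundary")
  ok <- setdiff(seq_len(nrow(P)), bad)
  for (j in 1:3)
    P[bad, j] <- approx(ok, P[ok, j], xout = bad)$y
  P
}

#' Low-pass filter every coordinate channel of a capture
#'
#' @param capture a [marker_capture()].
#' @param cutoff_hz,order filter design, see [zero_phase_butterworth()].
#' @return filtered `marker_capture`.
#' @export
filter_capture <- function(capture, cutoff_hz = 12, order = 2) {
  pos <- lapply(capture$positions, function(P)
    apply(P, 2, zero_phase_butterworth, cutoff_hz = cutoff_hz,
          order = order, fs_hz = capture$fs))
  marker_capture(capture$times, pos, capture$fs)
}

#' @export
print.marker_capture <- function(x, ...) {
  cat(sprintf("<marker_capture> %d markers x %d samples at %g Hz: %s\n",
              length(x$labels), length(x$times), x$fs,
              paste(utils::head(x$labels, 8), collapse = ", ")))
  invisible(x)
}
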