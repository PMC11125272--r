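# kinematics: filtering, SSA, pose reconstruction, guided angles, frames

test_that("zero-phase Butterworth matches its two-pass magnitude response", {
  fs <- 100; fc <- 12
  t <- seq(0, 10, by = 1 / fs)
  # DC gain 1
  expect_equal(zero_phase_butterworth(rep(3.7, 400), fc, 2, fs), rep(3.7, 400),
               tolerance = 1e-9)
  # two passes of an order-2 digital Butterworth (bilinear design): the
  # squared magnitude follows the prewarped frequency ratio
  gain2 <- function(f) 1 / (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^4)
  for (f in c(2, 30)) {
    y <- zero_phase_butterworth(sin(2 * pi * f * t), fc, 2, fs)
    amp <- max(abs(y[200:800]))   # steady-state mid section
    expect_equal(amp, gain2(f), tolerance = 0.02)
  }
  expect_gte(max(abs(zero_phase_butterworth(sin(2 * pi * 2 * t), fc, 2, fs))), 0.99)
  expect_lte(max(abs(zero_phase_butterworth(sin(2 * pi * 30 * t), fc, 2, fs)[200:800])),
             0.05)
  expect_error(zero_phase_butterworth(c(1, 2, 3), fc, 2, fs), "too short")
})

test_that("SSA reconstructs constants and low-order trends exactly", {
  expect_equal(ssa_smooth(rep(2.5, 100), window = 30), rep(2.5, 100),
               tolerance = 1e-12, ignore_attr = TRUE)
  t <- seq(0, 1, length.out = 200)
  trend <- 1 + 2 * t - 3 * t^2
  out <- ssa_smooth(trend, window = 30, n_components = 3)
  expect_lt(sqrt(mean((out - trend)^2)), 1e-6)
  expect_error(ssa_smooth(rnorm(10), window = 30), "window")
})

test_that("SSA denoises a slow sine (fixed seed)", {
  set.seed(42)
  t <- seq(0, 4, by = 0.01)
  clean <- sin(2 * pi * 0.8 * t)
  noisy <- clean + rnorm(length(t), 0, 0.5)
  sm <- ssa_smooth(noisy, window = 30)
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)))
  # mean preserved within 1% of the signal scale for this stationary input
  expect_lt(abs(mean(sm) - mean(noisy)), 0.01)
})

test_that("three-marker segment frames are orthonormal and equivariant", {
  p <- segment_pose_from_markers(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(p$rotation, diag(3), tolerance = 1e-14)
  expect_equal(p$origin, c(0, 0, 0))
  # translation equivariance
  tr <- c(0.3, -0.2, 0.9)
  p2 <- segment_pose_from_markers(c(0, 0, 0) + tr, c(1, 0, 0) + tr, c(0, 1, 0) + tr)
  expect_equal(p2$rotation, p$rotation, tolerance = 1e-14)
  expect_equal(p2$origin, tr)
  # rotation equivariance: 90 degrees about global Z
  Rz90 <- rot_z(pi / 2)
  p3 <- segment_pose_from_markers(as.numeric(Rz90 %*% c(0, 0, 0)),
                                  as.numeric(Rz90 %*% c(1, 0, 0)),
                                  as.numeric(Rz90 %*% c(0, 1, 0)))
  expect_equal(p3$rotation, Rz90, tolerance = 1e-12)
  expect_error(segment_pose_from_markers(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
  # orthonormality on random triads
  set.seed(5)
  for (i in 1:20) {
    pts <- matrix(rnorm(9), 3, 3)
    pp <- segment_pose_from_markers(pts[1, ], pts[2, ], pts[3, ])
    expect_lt(max(abs(crossprod(pp$rotation) - diag(3))), 1e-9)
    expect_gt(det(pp$rotation), 0)
  }
})

test_that("least-squares registration recovers an exact rigid pose", {
  set.seed(7)
  L <- matrix(rnorm(12, 0, 0.05), 4, 3)
  R <- euler_zxy(c(0.4, -0.2, 0.9))
  o <- c(0.1, 0.2, -0.3)
  G <- sweep(L %*% t(R), 2, o, "+")
  p <- body_pose_from_markers(L, G)
  expect_equal(p$rotation, R, tolerance = 1e-12)
  expect_equal(p$origin, o, tolerance = 1e-12)
  expect_lt(attr(p, "residual_rms"), 1e-12)
})

test_that("hip-center pivot fit recovers the rotation center", {
  geom <- generate_rig_geometry("B")
  cap0 <- synthesize_calibration_capture(geom, noise_sigma = 0)
  c0 <- hip_center_from_calibration(cap0)
  expect_lt(sqrt(sum((c0 - geom$hip_center)^2)), 1e-9)
  capn <- synthesize_calibration_capture(geom, noise_sigma = 5e-4, seed = 9)
  cn <- hip_center_from_calibration(capn)
  expect_lt(sqrt(sum((cn - geom$hip_center)^2)), 2e-3)
  # static femur: pivot unobservable
  still <- marker_capture(seq(0, 1, 0.01),
                          lapply(geom$femur$markers, function(a)
                            matrix(rep(a, each = 101), 101, 3)))
  expect_error(hip_center_from_calibration(still), "unobservable")
})

test_that("guided angles invert constructed poses and round-trip", {
  times <- seq(0, 1, by = 0.01)
  id_pose <- list(origin = c(0, 0, 0), rotation = diag(3))
  # coincident frames -> all four angles zero
  g0 <- extract_guided_angles(times, rep(list(id_pose), length(times)),
                              rep(list(id_pose), length(times)),
                              knee_axis = c(0, 1, 0))
  expect_equal(max(abs(g0$angles)), 0, tolerance = 1e-12)
  # pure 30-degree tibia rotation about the knee axis
  tib <- list(origin = c(0, 0, 0), rotation = rot_y(30 * pi / 180))
  g1 <- extract_guided_angles(times, rep(list(id_pose), length(times)),
                              rep(list(tib), length(times)),
                              knee_axis = c(0, 1, 0))
  expect_equal(g1$angles[1, 4], 30 * pi / 180, tolerance = 1e-12)
  expect_equal(max(abs(g1$angles[, 1:3])), 0, tolerance = 1e-12)
  # round trip: poses -> angles -> poses
  set.seed(13)
  hip <- cbind(0.3 * sin(times * 2), 0.2 * sin(times * 3 + 1), 0.25 * cos(times * 2))
  knee <- 0.6 + 0.5 * sin(times * 2.5)
  fp <- lapply(seq_along(times), function(i)
    list(origin = c(0, 0, 0), rotation = euler_zxy(hip[i, ])))
  tp <- lapply(seq_along(times), function(i)
    list(origin = c(0, 0, 0),
         rotation = euler_zxy(hip[i, ]) %*% rot_y(knee[i])))
  g <- extract_guided_angles(times, fp, tp, knee_axis = c(0, 1, 0))
  expect_equal(g$angles[, 1:3], hip, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(g$angles[, 4], knee, tolerance = 1e-9)
  for (i in c(1, 50, 101)) {
    Rf <- euler_zxy(g$angles[i, 1:3])
    Rt <- Rf %*% rot_y(g$angles[i, 4])
    expect_lt(max(abs(Rf - fp[[i]]$rotation)), 1e-9)
    expect_lt(max(abs(Rt - tp[[i]]$rotation)), 1e-9)
  }
})

test_that("femur-frame patella coordinates follow the anatomical frame", {
  hip <- c(0.1, 0.2, 0.3)
  km <- rbind(c(0.1, 0.14, -0.1), c(0.1, 0.26, -0.1))
  pose <- list(origin = c(0.15, 0.2, -0.05), rotation = diag(3))
  # button at the hip center -> origin
  out <- patella_in_femur_frame(list(origin = hip, rotation = diag(3)),
                                c(0, 0, 0), hip, km)
  expect_equal(out, c(0, 0, 0), tolerance = 1e-12)
  # button at the knee-axis midpoint: the axis normal to Y and the hip-knee
  # line (the anatomical Z) has zero coordinate there
  mid <- colMeans(km)
  out2 <- patella_in_femur_frame(list(origin = mid, rotation = diag(3)),
                                 c(0, 0, 0), hip, km)
  expect_equal(out2[3], 0, tolerance = 1e-12)
  # invariance under a rigid transform applied to all global inputs
  R <- euler_zxy(c(1.1, -0.4, 0.6)); tvec <- c(0.5, -1, 2)
  mv <- function(p) as.numeric(R %*% p + tvec)
  base <- patella_in_femur_frame(pose, c(0.01, 0.02, -0.01), hip, km)
  pose2 <- list(origin = mv(pose$origin), rotation = R %*% pose$rotation)
  out3 <- patella_in_femur_frame(pose2, c(0.01, 0.02, -0.01), mv(hip),
                                 rbind(mv(km[1, ]), mv(km[2, ])))
  expect_equal(out3, base, tolerance = 1e-10)
  expect_error(femur_anatomical_frame(c(0.1, 0.2, -0.1), km[1, ], km[1, ]),
               "coincide")
})

test_that("marker captures enforce uniform sampling", {
  tt <- seq(0, 1, 0.01); tt[5] <- tt[5] + 0.003
  expect_error(marker_capture(tt, list(a = matrix(0, length(tt), 3))),
               "non-uniform")
})

test_that("short marker gaps are interpolated, long ones rejected", {
  P <- cbind(seq(0, 1, length.out = 21), 2 * seq(0, 1, length.out = 21), 0)
  Pg <- P; Pg[8:10, ] <- NA
  expect_equal(fill_marker_gaps(Pg), P, tolerance = 1e-12)
  Pl <- P; Pl[5:11, ] <- NA
  expect_error(fill_marker_gaps(Pl), "longer than")
  Pb <- P; Pb[1, ] <- NA
  expect_error(fill_marker_gaps(Pb), "boundary")
})
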