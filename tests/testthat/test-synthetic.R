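# synthetic_rig: geometry, motion profile, capture synthesis

test_that("configuration A is configuration B shifted 20 mm laterally", {
  gA <- generate_rig_geometry("A")
  gB <- generate_rig_geometry("B")
  expect_equal(gA$quad_attach - gB$quad_attach, c(0, 0.020, 0), tolerance = 1e-12)
  # Q-angle difference from the frontal-plane lever: atan(20 / 251.3)
  expect_equal(abs(q_angle(gA) - q_angle(gB)), 4.55,
               tolerance = 5e-3)
  expect_equal(abs(q_angle(gA) - q_angle(gB)),
               atan2(0.020, 0.2513) * 180 / pi, tolerance = 1e-9)
  # femoral spring is the softer one, as on the bench
  expect_lt(gB$springs$femoral$stiffness, gB$springs$tibial$stiffness)
  # determinism
  expect_identical(generate_rig_geometry("A", seed = 3),
                   generate_rig_geometry("A", seed = 3))
})

test_that("the default motion profile matches the maneuver waypoints", {
  g <- generate_motion()
  deg <- g$angles[, 4] * 180 / pi
  expect_equal(deg[1], 35, tolerance = 1e-9)
  expect_equal(deg[length(deg)], 10, tolerance = 1e-9)
  expect_equal(max(deg), 90, tolerance = 1e-9)
  # sample count: duration * fs + 1
  expect_length(g$times, sum(motion_profile()$durations_s) * 100 + 1)
  # first segment (35 -> 90) is monotone non-decreasing
  i1 <- g$times <= motion_profile()$durations_s[1]
  expect_true(all(diff(deg[i1]) >= -1e-12))
  expect_error(motion_profile(durations_s = c(1, -1, 1, 1)), "positive")
  expect_error(motion_profile(waypoints_deg = c(35, 130, 45, 90, 10)),
               "\\[0, 120\\]")
})

test_that("noiseless captures invert to the exact body poses", {
  geom <- generate_rig_geometry("B")
  syn <- synthesize_capture(geom, generate_motion(motion_profile(
    waypoints_deg = c(35, 70), durations_s = 0.5)),
    noise_sigma = 0, force_noise_sigma = 0)
  cfg <- syn$config
  sys <- syn$system
  n <- length(syn$capture$times)
  for (i in c(1, round(n / 2), n)) {
    for (body in c("femur", "tibia", "patella")) {
      locs <- do.call(rbind, lapply(cfg$bodies[[body]]$markers, as.numeric))
      labs <- names(cfg$bodies[[body]]$markers)
      G <- do.call(rbind, lapply(labs, function(lb) syn$capture$positions[[lb]][i, ]))
      pose <- body_pose_from_markers(locs, G)
      truth <- kneerig:::body_pose(sys, syn$truth$q[i, ], body)
      expect_lt(max(abs(pose$origin - truth$origin)), 1e-9)
      expect_lt(max(abs(pose$rotation - truth$rotation)), 1e-9)
    }
  }
  # rigidity: inter-marker distances constant over time
  p1 <- syn$capture$positions[["pat_sup"]]
  p2 <- syn$capture$positions[["pat_inf"]]
  d12 <- sqrt(rowSums((p1 - p2)^2))
  expect_lt(diff(range(d12)), 1e-9)
})

test_that("marker noise has the requested dispersion", {
  geom <- generate_rig_geometry("B")
  motion <- generate_motion(motion_profile(waypoints_deg = c(35, 70),
                                           durations_s = 0.5))
  clean <- synthesize_capture(geom, motion, noise_sigma = 0, force_noise_sigma = 0)
  noisy <- synthesize_capture(geom, motion, noise_sigma = 5e-4, seed = 5,
                              force_noise_sigma = 0.1)
  res <- unlist(lapply(clean$capture$labels, function(lb)
    noisy$capture$positions[[lb]] - clean$capture$positions[[lb]]))
  expect_equal(sd(res), 5e-4, tolerance = 0.1)
  # reproducible bit-for-bit for a fixed seed
  noisy2 <- synthesize_capture(geom, motion, noise_sigma = 5e-4, seed = 5,
                               force_noise_sigma = 0.1)
  expect_identical(noisy$capture$positions, noisy2$capture$positions)
  expect_identical(noisy$forces, noisy2$forces)
})

test_that("synthetic force records carry the simulated channels", {
  geom <- generate_rig_geometry("B")
  syn <- synthesize_capture(geom, generate_motion(motion_profile(
    waypoints_deg = c(35, 70), durations_s = 0.5)),
    noise_sigma = 0, force_noise_sigma = 0)
  expect_equal(syn$forces$tibial_spring, unname(syn$truth$tensions[, "tibial"]))
  expect_equal(syn$forces$contact_normal, unname(syn$truth$contact_force[, 1]))
  expect_equal(syn$forces$times, syn$truth$t)
})
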