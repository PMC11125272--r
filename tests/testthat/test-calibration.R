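# calibration_validation: spring fits, objective, Bland-Altman, GA contract

test_that("spring calibration recovers exact parameters", {
  k <- 300; l0 <- 0.12
  lengths <- c(0.13, 0.15, 0.18)
  obs <- list(tibial = list(lengths = lengths, tensions = k * (lengths - l0)))
  fit <- calibrate_springs(obs)$tibial
  expect_equal(fit$stiffness, k, tolerance = 1e-9)
  expect_equal(fit$natural_length, l0, tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-9)
  # a consistent zero-tension observation at l0 leaves the fit unchanged
  obs2 <- list(s = list(lengths = c(lengths, l0),
                        tensions = c(k * (lengths - l0), 0)))
  fit2 <- calibrate_springs(obs2)$s
  expect_equal(fit2$stiffness, k, tolerance = 1e-9)
  expect_equal(fit2$natural_length, l0, tolerance = 1e-9)
  # endpoint-pair interface
  obs3 <- list(s = list(endpoints = lapply(lengths, function(l)
    list(p_a = c(0, 0, 0), p_b = c(l, 0, 0))),
    tensions = k * (lengths - l0)))
  expect_equal(calibrate_springs(obs3)$s$stiffness, k, tolerance = 1e-9)
  expect_error(calibrate_springs(list(s = list(lengths = 0.2, tensions = 5))),
               "at least 2")
  expect_error(calibrate_springs(list(s = list(lengths = c(0.2, 0.2),
                                               tensions = c(5, 6)))),
               "unidentifiable")
  expect_warning(calibrate_springs(list(s = list(lengths = c(0.1, 0.2),
                                                 tensions = c(6, 5)))),
                 "not positive")
})

make_ref_from <- function(tr) {
  list(forces = force_record(tr$t, tr$tensions[, "tibial"],
                             tr$tensions[, "femoral"], tr$contact_force[, 1]),
       button = tr$button_femur)
}

test_that("the objective is zero iff channels match and sums offsets", {
  leg <- leg_system("B")
  g <- generate_motion(motion_profile(waypoints_deg = c(35, 60),
                                      durations_s = 0.3))
  tr <- simulate_guided(leg$sys, g, settings = solver_settings(record_every = 10),
                        initial = leg$eq)
  ref <- make_ref_from(tr)
  expect_equal(simulation_objective(tr, ref), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  # +2 N on one force channel only -> objective 2
  ref2 <- ref; ref2$forces$tibial_spring <- ref2$forces$tibial_spring + 2
  expect_equal(simulation_objective(tr, ref2), 2, tolerance = 1e-9,
               ignore_attr = TRUE)
  # uniform 3 mm position offset -> objective 3
  ref3 <- ref; ref3$button <- ref3$button + 3e-3 / sqrt(3)
  expect_equal(simulation_objective(tr, ref3), 3, tolerance = 1e-6,
               ignore_attr = TRUE)
  # rms variant available
  expect_equal(simulation_objective(tr, ref3, position_metric = "rms"), 3,
               tolerance = 1e-6, ignore_attr = TRUE)
  # timeline mismatch is an error
  ref4 <- ref; ref4$forces$times <- ref4$forces$times + 10
  expect_error(simulation_objective(tr, ref4), "timeline")
})

test_that("Bland-Altman agrees with hand-computed closed forms", {
  x <- c(1, 2, 3, 4)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ba2 <- bland_altman(x + 2, x)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(2, 2))
  ba3 <- bland_altman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$sd_diff, 1)
  expect_equal(ba3$loa_low, -1.96)
  expect_equal(ba3$loa_high, 1.96)
  # antisymmetry
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
  expect_error(bland_altman(1:5, 1:4), "lengths")
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("agreement reports follow the six-channel schema", {
  leg <- leg_system("B")
  g <- generate_motion(motion_profile(waypoints_deg = c(35, 60),
                                      durations_s = 0.3))
  tr <- simulate_guided(leg$sys, g, settings = solver_settings(record_every = 10),
                        initial = leg$eq)
  ref <- make_ref_from(tr)
  rep0 <- agreement_report(tr, ref, config_label = "B")
  expect_equal(rep0$channel, c("contact", "tibial", "femoral", "X", "Y", "Z"))
  expect_equal(rep0$units, c("N", "N", "N", "mm", "mm", "mm"))
  expect_equal(max(abs(rep0$bias)), 0, tolerance = 1e-9)
  # injected offsets are reproduced (sign convention: simulated - reference)
  ref2 <- ref
  ref2$forces$contact_normal <- ref2$forces$contact_normal + 1.5
  ref2$button[, 2] <- ref2$button[, 2] - 2e-3
  rep2 <- agreement_report(tr, ref2, config_label = "B")
  expect_equal(rep2$bias[rep2$channel == "contact"], -1.5, tolerance = 1e-9)
  expect_equal(rep2$bias[rep2$channel == "Y"], 2, tolerance = 1e-9)
  expect_true(all(rep2$loa_low <= rep2$bias & rep2$bias <= rep2$loa_high))
})

test_that("the genetic algorithm honors bounds and the elitism contract", {
  leg <- leg_system("B")
  sys <- leg$sys
  g <- generate_motion(motion_profile(waypoints_deg = c(30, 75),
                                      durations_s = 0.3))
  sset <- solver_settings(record_every = 10, newton_tol = 1e-8)
  # reference from slightly perturbed parameters
  defaults <- kneerig:::spring_parameters(sys)
  truth <- defaults; truth["tibial_k"] <- truth["tibial_k"] * 1.05
  ref_tr <- simulate_guided(set_spring_parameters(sys, truth), g,
                            settings = sset,
                            initial = solve_static_equilibrium(
                              set_spring_parameters(sys, truth)))
  ref <- make_ref_from(ref_tr)
  problem <- optimization_problem(defaults, seed = 7, population = 8,
                                  generations = 3)
  res <- optimize_parameters(problem, sys, g, ref, settings = sset)
  expect_lte(res$objective, res$default_objective)
  expect_true(all(res$par >= problem$lower - 1e-12))
  expect_true(all(res$par <= problem$upper + 1e-12))
  expect_true(all(diff(res$history) <= 1e-12))   # best-so-far non-increasing
})
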