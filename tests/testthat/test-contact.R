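# contact: surface fitting, closest point, detection, Flores force, mesh oracle

test_that("quartic fitting recovers exact surfaces and reports R-squared", {
  surf0 <- random_quartic_surface(seed = 2)
  set.seed(2)
  x <- runif(120, -0.06, 0.06); y <- runif(120, -0.06, 0.06)
  z <- surface_eval(surf0, x, y, check_domain = FALSE)
  fit <- fit_polynomial_surface(cbind(x, y, z))
  expect_equal(fit$coefficients, surf0$coefficients, tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # flat plane: zero coefficients, R^2 reported as 1 by convention
  fitp <- fit_polynomial_surface(cbind(x, y, 0 * x))
  expect_equal(max(abs(fitp$coefficients)), 0, tolerance = 1e-12)
  expect_equal(fitp$r_squared, 1)
  # noisy fit: R^2 equals the SS_res/SS_tot definition computed independently
  set.seed(3)
  zn <- z + rnorm(length(z), 0, 0.002)
  fitn <- fit_polynomial_surface(cbind(x, y, zn))
  d <- kneerig:::quartic_design(x, y)
  beta <- qr.coef(qr(d$X), zn)
  r2_oracle <- 1 - sum((zn - d$X %*% beta)^2) / sum((zn - mean(zn))^2)
  expect_equal(fitn$r_squared, r2_oracle, tolerance = 1e-12)
  expect_error(fit_polynomial_surface(cbind(x[1:10], y[1:10], z[1:10])),
               "at least 15")
  expect_error(fit_polynomial_surface(cbind(rep(1, 20), y[1:20], z[1:20])),
               "degenerate|rank")
})

test_that("closest point on plane and symmetric bowl are exact", {
  plane <- polynomial_surface(matrix(0, 5, 5), c(-1, 1, -1, 1))
  res <- closest_point_on_surface(c(0, 0, 0.5), plane)
  expect_equal(res$point, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(res$distance, 0.5, tolerance = 1e-12)
  Cb <- matrix(0, 5, 5); Cb[3, 1] <- 5; Cb[1, 3] <- 5   # z = 5 (x^2 + y^2)
  bowl <- polynomial_surface(Cb, c(-0.2, 0.2, -0.2, 0.2))
  resb <- closest_point_on_surface(c(0, 0, 0.1), bowl)
  expect_equal(resb$point, c(0, 0, 0), tolerance = 1e-10)
  expect_error(closest_point_on_surface(c(5, 0, 1), plane), "outside")
})

test_that("closest-point distances match a dense-sampling oracle", {
  surf <- random_quartic_surface(seed = 8)
  set.seed(8)
  worst <- 0
  for (i in 1:50) {
    ctr <- c(runif(1, -0.03, 0.03), runif(1, -0.03, 0.03), runif(1, 0.01, 0.08))
    res <- closest_point_on_surface(ctr, surf)
    oracle <- dense_distance_oracle(surf, ctr, n = 1000)
    worst <- max(worst, abs(res$distance - oracle))
    # (center - point) parallel to the surface normal
    dvec <- ctr - res$point
    cosang <- sum(dvec * res$normal) / sqrt(sum(dvec^2))
    expect_gt(abs(cosang), 1 - 1e-8)
  }
  expect_lt(worst, 1e-5)
})

test_that("contact detection applies the radius rule and sign conventions", {
  plane <- polynomial_surface(matrix(0, 5, 5), c(-2, 2, -2, 2))
  st <- detect_contact(c(0, 0, 0.9), c(0, 0, 0), radius = 1, surface = plane)
  expect_true(st$active)
  expect_equal(st$delta, 0.1, tolerance = 1e-12)
  expect_equal(st$normal, c(0, 0, 1), tolerance = 1e-12)
  st2 <- detect_contact(c(0, 0, 1.5), c(0, 0, 0), radius = 1, surface = plane)
  expect_false(st2$active)
  expect_lte(st2$delta, 0)
  # descending at 0.2 m/s at first touch: ddot = ddot0 = 0.2
  st3 <- detect_contact(c(0, 0, 0.999), c(0, 0, -0.2), radius = 1, surface = plane)
  expect_equal(st3$ddot, 0.2, tolerance = 1e-12)
  expect_equal(st3$ddot0, 0.2, tolerance = 1e-12)
  # finite-difference cross-check of the indentation rate
  h <- 1e-7
  d1 <- 1 - detect_contact(c(0, 0, 0.999), c(0, 0, -0.2), 1, plane)$delta
  d2 <- 1 - detect_contact(c(0, 0, 0.999 - 0.2 * h), c(0, 0, -0.2), 1, plane)$delta
  expect_equal((d1 - d2) / h, st3$ddot, tolerance = 1e-4)
  # episode memory: ddot0 latched from the episode, not recomputed
  st4 <- detect_contact(c(0, 0, 0.99), c(0, 0, -0.05), 1, plane,
                        episode = list(ddot0 = 0.2))
  expect_equal(st4$ddot0, 0.2)
})

test_that("Flores normal force reproduces its closed forms", {
  plane <- polynomial_surface(matrix(0, 5, 5), c(-2, 2, -2, 2))
  st <- detect_contact(c(0, 0, 1 - 1e-3), c(0, 0, 0), 1, plane)
  # eps = 1: pure elastic kn delta^p
  f1 <- flores_normal_force(st, list(kn = 1e5, p = 1.5, eps = 1))
  expect_equal(attr(f1, "magnitude"), 1e5 * (1e-3)^1.5, tolerance = 1e-12)
  expect_equal(attr(f1, "magnitude"), 3.16227766, tolerance = 1e-6)
  # eps = 0.5 with ddot = ddot0: factor 1 + 8*0.5/(5*0.5) = 2.6
  st2 <- detect_contact(c(0, 0, 1 - 1e-3), c(0, 0, -0.3), 1, plane)
  f2 <- flores_normal_force(st2, list(kn = 1e5, p = 1.5, eps = 0.5))
  expect_equal(attr(f2, "magnitude"), 2.6 * 1e5 * (1e-3)^1.5, tolerance = 1e-10)
  # tensile clamp: fast restitution with small eps yields zero, not negative
  st3 <- st2; st3$ddot <- -1; st3$ddot0 <- 0.3
  f3 <- flores_normal_force(st3, list(kn = 1e5, p = 1.5, eps = 0.2))
  expect_equal(attr(f3, "magnitude"), 0)
  expect_error(flores_normal_force(st2, list(kn = 1e5, p = 1.5, eps = 0)), "restitution")
  # force -> 0 as delta -> 0+ (elastic term continuity)
  st4 <- detect_contact(c(0, 0, 1 - 1e-9), c(0, 0, 0), 1, plane)
  f4 <- flores_normal_force(st4, list(kn = 1e5, p = 1.5, eps = 1))
  expect_lt(attr(f4, "magnitude"), 1e-8)
})

test_that("mesh oracle agrees with the analytic detector", {
  plane <- polynomial_surface(matrix(0, 5, 5), c(-2, 2, -2, 2))
  mesh <- surface_mesh(plane, 40, 40)
  st <- mesh_contact_oracle(c(0, 0, 0.9), radius = 1, mesh = mesh)
  expect_true(st$active)
  expect_equal(st$delta, 0.1, tolerance = 1e-12)
  st2 <- mesh_contact_oracle(c(0, 0, 5), radius = 1, mesh = mesh)
  expect_false(st2$active)
  expect_error(mesh_contact_oracle(c(0, 0, 1), radius = 1,
                                   mesh = list(vertices = matrix(0, 0, 3),
                                               faces = matrix(0, 0, 3))),
               "empty mesh")
  # moderate-resolution agreement on a curved quartic (the full-scale
  # experiment runs in the acceptance suite)
  surf <- random_quartic_surface(seed = 21)
  m2 <- surface_mesh(surf, 120, 120)
  set.seed(21)
  for (i in 1:40) {
    ctr <- c(runif(1, -0.04, 0.04), runif(1, -0.04, 0.04), runif(1, 0.005, 0.05))
    a <- detect_contact(ctr, c(0, 0, 0), radius = 0.05, surface = surf)
    m <- mesh_contact_oracle(ctr, radius = 0.05, mesh = m2)
    expect_lt(abs(a$delta - m$delta), 5e-4)
  }
})

test_that("point-triangle distance handles all regions exactly", {
  A <- matrix(c(0, 0, 0), 1); B <- matrix(c(1, 0, 0), 1); C <- matrix(c(0, 1, 0), 1)
  d <- function(p) sqrt(kneerig:::point_triangle_distance(p, A, B, C)$d2)
  expect_equal(d(c(0.2, 0.2, 0.5)), 0.5, tolerance = 1e-12)        # face
  expect_equal(d(c(-1, -1, 0)), sqrt(2), tolerance = 1e-12)        # vertex A
  expect_equal(d(c(2, 0, 0)), 1, tolerance = 1e-12)                # vertex B
  expect_equal(d(c(0.5, -1, 0)), 1, tolerance = 1e-12)             # edge AB
  expect_equal(d(c(1, 1, 0)), sqrt(2) / 2, tolerance = 1e-12)      # edge BC
  expect_equal(d(c(-0.5, 0.5, 0)), 0.5, tolerance = 1e-12)         # edge AC
})
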