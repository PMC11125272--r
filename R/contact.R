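# contact: quartic surface fitting, analytic sphere-vs-surface detection,
# Flores normal force, and a brute-force triangle-mesh oracle used in tests.

#' Bivariate polynomial surface z = P(x, y)
#'
#' @param coefficients 5x5 matrix; `coefficients[i+1, j+1]` multiplies
#'   `x^i y^j`, with total degree `i + j <= 4` (higher entries must be 0).
#' @param fit_domain numeric length-4 `c(xmin, xmax, ymin, ymax)` (m).
#' @param r_squared fraction of variance explained by the fit, in `[0, 1]`.
#' @param frame pose of the surface frame relative to its carrying body:
#'   list with rotation `R` and origin `o`.
#' @return object of class `polynomial_surface`.
#' @export
polynomial_surface <- function(coefficients, fit_domain, r_squared = NA_real_,
                               frame = list(R = diag(3), o = c(0, 0, 0))) {
  stopifnot(is.matrix(coefficients), all(dim(coefficients) == c(5, 5)))
  deg <- outer(0:4, 0:4, "+")
  if (any(coefficients[deg > 4] != 0))
    stop("coefficients above total degree 4 must be zero")
  stopifnot(length(fit_domain) == 4, fit_domain[1] < fit_domain[2],
            fit_domain[3] < fit_domain[4])
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]")
  structure(list(coefficients = coefficients, fit_domain = as.numeric(fit_domain),
                 r_squared = r_squared, frame = frame),
            class = "polynomial_surface")
}

#' Evaluate a polynomial surface
#'
#' @param surface a [polynomial_surface()].
#' @param x,y evaluation coordinates (vectors, surface frame, m).
#' @param check_domain warn and flag points outside the fit domain.
#' @return numeric vector of heights z; if `check_domain`, an attribute
#'   `out_of_domain` marks extrapolated points.
#' @export
surface_eval <- function(surface, x, y, check_domain = TRUE) {
  C <- surface$coefficients
  z <- numeric(length(x))
  for (i in 0:4) for (j in 0:(4 - i)) {
    if (C[i + 1, j + 1] != 0) z <- z + C[i + 1, j + 1] * x^i * y^j
  }
  if (check_domain) {
    d <- surface$fit_domain
    out <- x < d[1] | x > d[2] | y < d[3] | y > d[4]
    if (any(out)) warning("surface evaluated outside its fit domain")
    attr(z, "out_of_domain") <- out
  }
  z
}

# design matrix of the full bivariate quartic (15 columns)
quartic_design <- function(x, y) {
  terms <- which(outer(0:4, 0:4, "+") <= 4, arr.ind = TRUE) - 1L
  terms <- terms[order(terms[, 1] + terms[, 2], terms[, 1]), , drop = FALSE]
  X <- matrix(0, length(x), nrow(terms))
  for (k in seq_len(nrow(terms)))
    X[, k] <- x^terms[k, 1] * y^terms[k, 2]
  list(X = X, terms = terms)
}

#' Fit a quartic polynomial surface to a point cloud
#'
#' Least-squares fit of the full bivariate polynomial of total degree 4 to
#' the vertex coordinates of an implant surface, reporting the fraction of
#' variance explained (R^2 = 1 - SS_res/SS_tot on the input z values; a cloud
#' with zero z-variance that is fitted exactly reports R^2 = 1).
#'
#' @param points n x 3 matrix of points in the surface frame (m).
#' @param degree polynomial total degree (only 4 supported).
#' @param frame optional surface frame pose (stored on the result).
#' @return a [polynomial_surface()] with `r_squared` and residual attributes.
#' @export
fit_polynomial_surface <- function(points, degree = 4,
                                   frame = list(R = diag(3), o = c(0, 0, 0))) {
  if (degree != 4) stop("only total degree 4 is supported")
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  if (nrow(points) < 15) stop("need at least 15 points for a quartic fit")
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  if (diff(range(x)) < 1e-12 || diff(range(y)) < 1e-12)
    stop("degenerate point cloud: no spread in x or y")
  d <- quartic_design(x, y)
  qr_fit <- qr(d$X)
  if (qr_fit$rank < ncol(d$X))
    stop("rank-deficient design: point cloud does not determine a quartic")
  beta <- qr.coef(qr_fit, z)
  zhat <- as.numeric(d$X %*% beta)
  ss_res <- sum((z - zhat)^2)
  ss_tot <- sum((z - mean(z))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, sum(z^2))) 1 else 1 - ss_res / ss_tot
  r2 <- min(max(r2, 0), 1)
  C <- matrix(0, 5, 5)
  for (k in seq_len(nrow(d$terms)))
    C[d$terms[k, 1] + 1, d$terms[k, 2] + 1] <- beta[k]
  s <- polynomial_surface(C, c(range(x), range(y)), r_squared = r2, frame = frame)
  attr(s, "residual_rms") <- sqrt(mean((z - zhat)^2))
  s
}

#' Closest point on a polynomial surface
#'
#' Minimizes the Euclidean distance from `center` to the graph z = P(x, y)
#' by damped Newton iteration on the two-variable stationarity conditions,
#' seeded at the vertical projection of `center`.
#'
#' @param center 3-vector in the surface frame (m).
#' @param surface a [polynomial_surface()].
#' @param seed optional `(u, v)` starting point (default: vertical
#'   projection).
#' @param check_domain error if the vertical projection of `center` falls
#'   outside the fit domain.
#' @return list with `point` (3-vector on the surface), `distance`,
#'   `normal` (upward surface normal at the point), `uv` and `converged`.
#' @export
closest_point_on_surface <- function(center, surface, seed = NULL,
                                     check_domain = TRUE) {
  d <- surface$fit_domain
  if (check_domain &&
      (center[1] < d[1] || center[1] > d[2] || center[2] < d[3] || center[2] > d[4]))
    stop("vertical projection of center lies outside the fit domain")
  if (is.null(seed)) seed <- center[1:2]
  res <- .cpp_poly_closest(surface$coefficients, as.numeric(center),
                           seed[1], seed[2])
  if (!res$converged)
    stop("closest-point Newton iteration did not converge")
  list(point = res$point, distance = res$distance, normal = res$normal,
       uv = c(res$u, res$v), converged = res$converged)
}

#' Contact state of a sphere against a polynomial surface
#'
#' Contact exists when the distance from the sphere center to the surface is
#' smaller than the sphere radius. The indentation rate at episode onset
#' (`ddot0`) is latched from `episode` and reused until separation.
#'
#' @param center,velocity sphere center position and velocity in the surface
#'   frame (m, m/s).
#' @param radius sphere radius (m).
#' @param surface a [polynomial_surface()].
#' @param episode optional episode memory from the previous evaluation
#'   (list with `ddot0`); `NULL` starts a fresh episode.
#' @return object of class `contact_state`: `active`, indentation `delta`,
#'   rate `ddot`, onset rate `ddot0`, `contact_point`, unit `normal`
#'   (toward the sphere) and `in_domain`.
#' @export
detect_contact <- function(center, velocity, radius, surface, episode = NULL) {
  res <- .cpp_poly_closest(surface$coefficients, as.numeric(center),
                           center[1], center[2])
  p <- res$point
  dist <- res$distance
  delta <- radius - dist
  d <- surface$fit_domain
  in_dom <- res$u >= d[1] && res$u <= d[2] && res$v >= d[3] && res$v <= d[4]
  nrm <- as.numeric(center) - p
  nn <- sqrt(sum(nrm^2))
  nrm <- if (nn > 1e-12) nrm / nn else c(0, 0, 1)
  ddot <- -sum(nrm * velocity)          # surface frame: surface at rest
  active <- delta > 0 && in_dom
  ddot0 <- if (active) {
    if (!is.null(episode) && !is.null(episode$ddot0)) episode$ddot0 else ddot
  } else NA_real_
  structure(list(active = active, delta = delta, ddot = ddot, ddot0 = ddot0,
                 contact_point = p, normal = nrm, in_domain = in_dom,
                 uv = c(res$u, res$v)),
            class = "contact_state")
}

#' Flores continuous normal contact force
#'
#' `F = kn delta^p (1 + 8(1 - eps) / (5 eps) * ddot / ddot0) n`, clamped at
#' zero (unilateral contact: no tensile force). With restitution `eps = 1`
#' the force is purely elastic. If the onset rate is (numerically) zero the
#' hysteresis term is dropped.
#'
#' @param state a [detect_contact()] result (must be active).
#' @param params list with `kn` (N/m^p), `p` (Hertz exponent) and `eps`
#'   (coefficient of restitution in (0, 1]).
#' @return force 3-vector acting on the sphere along the contact normal (N),
#'   with attribute `magnitude`.
#' @export
flores_normal_force <- function(state, params) {
  if (!isTRUE(state$active)) stop("contact state is not active")
  if (is.null(params$eps) || params$eps <= 0) stop("restitution must be > 0")
  if (params$eps > 1) stop("restitution must be <= 1")
  factor <- 1
  if (params$eps < 1 && is.finite(state$ddot0) && abs(state$ddot0) >= 1e-6)
    factor <- 1 + (8 * (1 - params$eps)) / (5 * params$eps) * state$ddot / state$ddot0
  mag <- max(params$kn * state$delta^params$p * factor, 0)
  f <- mag * state$normal
  attr(f, "magnitude") <- mag
  f
}

# ---------------------------------------------------------------------------
# triangle-mesh brute-force oracle (test-only reference implementation)
# ---------------------------------------------------------------------------

#' Triangulate a polynomial surface
#'
#' Regular-grid triangulation of the graph over the fit domain; used to feed
#' the mesh contact oracle.
#'
#' @param surface a [polynomial_surface()].
#' @param nx,ny grid resolution (nodes per axis).
#' @return list with `vertices` (m x 3) and `faces` (k x 3 vertex indices).
#' @export
surface_mesh <- function(surface, nx = 80, ny = 80) {
  d <- surface$fit_domain
  xs <- seq(d[1], d[2], length.out = nx)
  ys <- seq(d[3], d[4], length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  z <- surface_eval(surface, g$x, g$y, check_domain = FALSE)
  verts <- cbind(g$x, g$y, z)
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  f1 <- cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1))
  f2 <- cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  list(vertices = verts, faces = rbind(f1, f2))
}

# vectorized exact point-triangle distance (Eberly's region scheme)
# P: length-3 point; A, B, C: n x 3 triangle vertices
point_triangle_distance <- function(P, A, B, C) {
  E0 <- B - A; E1 <- C - A
  D <- sweep(A, 2, P)                      # A - P
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c <- rowSums(E1 * E1)
  d <- rowSums(E0 * D);  e <- rowSums(E1 * D)
  det <- pmax(a * c - b * b, 1e-300)
  s <- b * e - c * d
  t <- b * d - a * e
  inside <- (s + t <= det) & (s >= 0) & (t >= 0)
  s_in <- s / det; t_in <- t / det
  # edge/vertex regions: clamp to each edge and keep the nearest
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  # edge AB: t = 0
  s_ab <- clamp01(ifelse(a > 0, -d / a, 0))
  # edge AC: s = 0
  t_ac <- clamp01(ifelse(c > 0, -e / c, 0))
  # edge BC: param u from B to C
  u_bc <- clamp01(ifelse(a - 2 * b + c > 0, (a + d - b - e) / (a - 2 * b + c), 0))
  d2_for <- function(ss, tt)
    a * ss^2 + 2 * b * ss * tt + c * tt^2 + 2 * d * ss + 2 * e * tt + rowSums(D * D)
  d2_ab <- d2_for(s_ab, 0)
  d2_ac <- d2_for(0, t_ac)
  d2_bc <- d2_for(1 - u_bc, u_bc)
  d2_edge <- pmin(d2_ab, d2_ac, d2_bc)
  which_edge <- max.col(-cbind(d2_ab, d2_ac, d2_bc), ties.method = "first")
  s_edge <- cbind(s_ab, 0, 1 - u_bc)[cbind(seq_along(a), which_edge)]
  t_edge <- cbind(0, t_ac, u_bc)[cbind(seq_along(a), which_edge)]
  s_fin <- ifelse(inside, s_in, s_edge)
  t_fin <- ifelse(inside, t_in, t_edge)
  d2 <- ifelse(inside, d2_for(s_in, t_in), d2_edge)
  list(d2 = pmax(d2, 0), s = s_fin, t = t_fin)
}

#' Mesh-based contact oracle
#'
#' Exhaustive closest-point search over all triangles of a mesh; reference
#' implementation used to validate the analytic detector in tests.
#'
#' @param center,velocity sphere center position/velocity (mesh frame).
#' @param radius sphere radius (m).
#' @param mesh list with `vertices` and `faces` (see [surface_mesh()]), or a
#'   mesh read by [read_obj()].
#' @return a `contact_state` (as in [detect_contact()], `in_domain = TRUE`).
#' @export
mesh_contact_oracle <- function(center, velocity = c(0, 0, 0), radius, mesh) {
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0) stop("empty mesh")
  V <- mesh$vertices; Fc <- mesh$faces
  A <- V[Fc[, 1], , drop = FALSE]
  B <- V[Fc[, 2], , drop = FALSE]
  C <- V[Fc[, 3], , drop = FALSE]
  r <- point_triangle_distance(as.numeric(center), A, B, C)
  k <- which.min(r$d2)
  cp <- A[k, ] + r$s[k] * (B[k, ] - A[k, ]) + r$t[k] * (C[k, ] - A[k, ])
  dist <- sqrt(r$d2[k])
  delta <- radius - dist
  nrm <- as.numeric(center) - cp
  nn <- sqrt(sum(nrm^2))
  nrm <- if (nn > 1e-12) nrm / nn else c(0, 0, 1)
  ddot <- -sum(nrm * velocity)
  structure(list(active = delta > 0, delta = delta, ddot = ddot,
                 ddot0 = if (delta > 0) ddot else NA_real_,
                 contact_point = cp, normal = nrm, in_domain = TRUE,
                 uv = NULL),
            class = "contact_state")
}

#' @export
print.polynomial_surface <- function(x, ...) {
  cat("<polynomial_surface> degree-4 graph z = P(x, y)\n")
  cat(sprintf("  domain: x in [%.4g, %.4g], y in [%.4g, %.4g] m\n",
              x$fit_domain[1], x$fit_domain[2], x$fit_domain[3], x$fit_domain[4]))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
print.contact_state <- function(x, ...) {
  cat(sprintf("<contact_state> %s: delta = %.3g m, ddot = %.3g m/s%s\n",
              if (x$active) "active" else "inactive", x$delta, x$ddot,
              if (!x$in_domain) " (outside fit domain)" else ""))
  invisible(x)
}
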