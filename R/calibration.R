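# calibration_validation: spring calibration from static records, objective
# function, genetic-algorithm refinement within +-10% bounds, Bland-Altman
# agreement reporting.

#' Force record container
#'
#' @param times sample times (s), 100 Hz typically.
#' @param tibial_spring,femoral_spring,contact_normal force channels (N).
#' @return object of class `force_record`.
#' @export
force_record <- function(times, tibial_spring, femoral_spring, contact_normal) {
  n <- length(times)
  stopifnot(length(tibial_spring) == n, length(femoral_spring) == n,
            length(contact_normal) == n)
  if (!all(is.finite(c(tibial_spring, femoral_spring, contact_normal))))
    stop("force channels must be finite")
  structure(list(times = times, tibial_spring = as.numeric(tibial_spring),
                 femoral_spring = as.numeric(femoral_spring),
                 contact_normal = as.numeric(contact_normal)),
            class = "force_record")
}

#' @export
print.force_record <- function(x, ...) {
  cat(sprintf("<force_record> %d samples; tibial %.1f..%.1f N, femoral %.1f..%.1f N, contact %.1f..%.1f N\n",
              length(x$times), min(x$tibial_spring), max(x$tibial_spring),
              min(x$femoral_spring), max(x$femoral_spring),
              min(x$contact_normal), max(x$contact_normal)))
  invisible(x)
}

#' Calibrate spring parameters from static observations
#'
#' Linear least-squares fit of `tension = k (l - l0)` per spring from static
#' poses at distinct lengths.
#'
#' @param observations named list (one entry per spring); each entry is a
#'   list with `tensions` (N) and either `lengths` (m) or `endpoints`
#'   (list of `list(p_a, p_b)` global point pairs).
#' @return named list per spring: `stiffness`, `natural_length`,
#'   `residual_rms`, and `flagged` (TRUE when the fitted stiffness is not
#'   positive).
#' @export
calibrate_springs <- function(observations) {
  lapply(observations, function(obs) {
    l <- if (!is.null(obs$lengths)) as.numeric(obs$lengths)
    else vapply(obs$endpoints,
                function(e) sqrt(sum((e$p_b - e$p_a)^2)), numeric(1))
    T <- as.numeric(obs$tensions)
    if (length(l) < 2 || length(T) != length(l))
      stop("need at least 2 static observations per spring")
    if (diff(range(l)) < 1e-12)
      stop("unidentifiable: all observed lengths are equal")
    fit <- lm(T ~ l)
    k <- unname(coef(fit)[2])
    l0 <- -unname(coef(fit)[1]) / k
    flagged <- !is.finite(k) || k <= 0
    if (flagged) warning("fitted stiffness is not positive")
    list(stiffness = k, natural_length = l0,
         residual_rms = sqrt(mean(fit$residuals^2)), flagged = flagged)
  })
}

# linear resampling of simulated channels onto reference timestamps
resample_trajectory <- function(trajectory, times) {
  rng <- range(trajectory$t)
  if (min(times) < rng[1] - 1e-9 || max(times) > rng[2] + 1e-9)
    stop("timeline mismatch: reference times outside the simulated span")
  ch <- function(y) approx(trajectory$t, y, xout = times, rule = 2)$y
  out <- list(times = times,
              tibial = ch(trajectory$tensions[, "tibial"]),
              femoral = ch(trajectory$tensions[, "femoral"]),
              contact = ch(trajectory$contact_force[, 1]))
  if (!is.null(trajectory$button_femur))
    out$button <- cbind(ch(trajectory$button_femur[, 1]),
                        ch(trajectory$button_femur[, 2]),
                        ch(trajectory$button_femur[, 3]))
  out
}

#' Simulation-versus-reference objective
#'
#' Sum of the RMS errors of the three force channels (N) and the position
#' error of the patellar button in the femur frame (mm): flat sum, no
#' weights, with the position term either the mean (default) or the RMS of
#' the per-sample Euclidean distance.
#'
#' @param sim an `mbs_trajectory`.
#' @param ref reference: list with `forces` (a [force_record()]) and
#'   `button` (n x 3, femur frame, m) on the same timeline.
#' @param position_metric `"mean"` or `"rms"`.
#' @param weights named weights for the `force` and `position` blocks
#'   (default 1, matching the flat sum).
#' @return objective value with attribute `components`.
#' @export
simulation_objective <- function(sim, ref, position_metric = c("mean", "rms"),
                                 weights = c(force = 1, position = 1)) {
  position_metric <- match.arg(position_metric)
  rs <- resample_trajectory(sim, ref$forces$times)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  comp <- c(contact = rmse(rs$contact, ref$forces$contact_normal),
            tibial = rmse(rs$tibial, ref$forces$tibial_spring),
            femoral = rmse(rs$femoral, ref$forces$femoral_spring))
  dist_mm <- sqrt(rowSums((rs$button - ref$button)^2)) * 1000
  pos <- if (position_metric == "mean") mean(dist_mm) else sqrt(mean(dist_mm^2))
  comp <- c(comp, position_mm = pos)
  obj <- weights["force"] * sum(comp[1:3]) + weights["position"] * pos
  attr(obj, "components") <- comp
  unname(obj)
}

#' Define the spring-parameter optimization problem
#'
#' Parameter vector: stiffness, natural length and damping of both springs,
#' allowed to vary by +-10% around the defaults.
#'
#' @param defaults named numeric vector
#'   `(tibial_k, tibial_l0, tibial_c, femoral_k, femoral_l0, femoral_c)`.
#' @param spread half-width of the relative bounds (0.1 = +-10%).
#' @param seed RNG seed of the genetic algorithm.
#' @param population,generations genetic-algorithm budget.
#' @return list of class `optimization_problem`.
#' @export
optimization_problem <- function(defaults, spread = 0.1, seed = 42L,
                                 population = 50L, generations = 40L) {
  stopifnot(length(defaults) == 6, all(defaults > 0))
  nm <- c("tibial_k", "tibial_l0", "tibial_c", "femoral_k", "femoral_l0",
          "femoral_c")
  if (is.null(names(defaults))) names(defaults) <- nm
  structure(list(defaults = defaults,
                 lower = defaults * (1 - spread),
                 upper = defaults * (1 + spread),
                 seed = as.integer(seed),
                 population = as.integer(population),
                 generations = as.integer(generations)),
            class = "optimization_problem")
}

# spring parameters of a system as the 6-vector used by the optimizer
spring_parameters <- function(system) {
  s <- system$springs
  c(tibial_k = s$tibial$stiffness, tibial_l0 = s$tibial$natural_length,
    tibial_c = s$tibial$damping, femoral_k = s$femoral$stiffness,
    femoral_l0 = s$femoral$natural_length, femoral_c = s$femoral$damping)
}

#' Replace the spring parameters of a system
#'
#' @param system an `mbs_system` with `tibial` and `femoral` springs.
#' @param params named 6-vector (see [optimization_problem()]).
#' @return updated system.
#' @export
set_spring_parameters <- function(system, params) {
  system$springs$tibial$stiffness <- unname(params["tibial_k"])
  system$springs$tibial$natural_length <- unname(params["tibial_l0"])
  system$springs$tibial$damping <- unname(params["tibial_c"])
  system$springs$femoral$stiffness <- unname(params["femoral_k"])
  system$springs$femoral$natural_length <- unname(params["femoral_l0"])
  system$springs$femoral$damping <- unname(params["femoral_c"])
  for (i in seq_along(system$model$springs)) {
    nm <- names(system$springs)[i]
    system$model$springs[[i]]$k <- system$springs[[nm]]$stiffness
    system$model$springs[[i]]$l0 <- system$springs[[nm]]$natural_length
    system$model$springs[[i]]$c <- system$springs[[nm]]$damping
  }
  system
}

#' Genetic-algorithm refinement of the spring parameters
#'
#' Real-coded genetic algorithm (tournament selection, blend crossover,
#' Gaussian mutation with a decaying step, elitism) minimizing
#' [simulation_objective()] within the problem bounds. Every candidate is
#' simulated from its own static equilibrium. Deterministic for a fixed
#' seed.
#'
#' @param problem an [optimization_problem()].
#' @param system the leg `mbs_system` (defaults taken from its springs).
#' @param guided guided trajectory driving every simulation.
#' @param ref reference channels (see [simulation_objective()]).
#' @param settings solver settings for the candidate simulations.
#' @param verbose print per-generation progress.
#' @return list: `par` (best parameters), `objective`, `default_objective`,
#'   `history` (best-so-far per generation, non-increasing), `evaluations`.
#' @export
optimize_parameters <- function(problem, system, guided, ref,
                                settings = system$settings, verbose = FALSE) {
  lo <- problem$lower; hi <- problem$upper
  npar <- length(lo)
  evaluate <- function(par) {
    sys2 <- set_spring_parameters(system, setNames(par, names(problem$defaults)))
    obj <- tryCatch({
      init <- solve_static_equilibrium(sys2)
      tr <- simulate_guided(sys2, guided, settings = settings, initial = init)
      if (tr$failed) Inf else simulation_objective(tr, ref)
    }, error = function(e) Inf)
    as.numeric(obj)
  }
  default_obj <- evaluate(as.numeric(problem$defaults))
  n_eval <- 1L
  withr_seed(problem$seed, {
    pop <- matrix(runif(problem$population * npar, rep(lo, each = problem$population),
                        rep(hi, each = problem$population)),
                  problem$population, npar)
    pop[1, ] <- as.numeric(problem$defaults)   # seed the defaults
    fit <- apply(pop, 1, evaluate)
    n_eval <- n_eval + nrow(pop)
    history <- numeric(problem$generations)
    best <- min(fit)
    for (gen in seq_len(problem$generations)) {
      sigma <- 0.02 * (hi - lo) * 0.88^(gen - 1)   # decaying mutation step
      newpop <- matrix(0, problem$population, npar)
      ord <- order(fit)
      newpop[1, ] <- pop[ord[1], ]                 # elitism
      for (i in 2:problem$population) {
        pick <- function() {
          cand <- sample.int(problem$population, 3)
          cand[which.min(fit[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        w <- runif(npar, -0.5, 1.5)                # blend crossover (extrapolating)
        child <- w * p1 + (1 - w) * p2
        mut <- runif(npar) < 0.9
        child[mut] <- child[mut] + rnorm(sum(mut), 0, sigma[mut])
        newpop[i, ] <- pmin(pmax(child, lo), hi)
      }
      newfit <- c(fit[ord[1]], apply(newpop[-1, , drop = FALSE], 1, evaluate))
      n_eval <- n_eval + nrow(newpop) - 1L
      pop <- newpop; fit <- newfit
      best <- min(best, min(fit))
      history[gen] <- best
      if (verbose)
        message(sprintf("generation %d: best objective %.4f", gen, best))
    }
    ibest <- which.min(fit)
    result <- list(par = setNames(pop[ibest, ], names(problem$defaults)),
                   objective = fit[ibest],
                   default_objective = default_obj,
                   history = history, evaluations = n_eval)
  })
  if (result$default_objective < result$objective) {
    # elitism guarantee relative to the defaults (they are in the population)
    result$par <- problem$defaults
    result$objective <- result$default_objective
  }
  result
}

#' Bland-Altman agreement between two aligned channels
#'
#' Differences are `simulated - reference`; the limits of agreement are the
#' bias plus/minus 1.96 sample standard deviations of the differences.
#'
#' @param sim_channel,ref_channel equal-length numeric vectors (n >= 3).
#' @return list: `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(sim_channel, ref_channel) {
  if (length(sim_channel) != length(ref_channel))
    stop("channels have different lengths")
  if (length(sim_channel) < 3) stop("need at least 3 paired samples")
  d <- sim_channel - ref_channel
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

#' Agreement report over all validated channels
#'
#' Six rows in fixed order - contact, tibial and femoral forces (N), then
#' the X, Y, Z femur-frame coordinates of the button center (mm) - with
#' Bland-Altman bias and limits of agreement per channel.
#'
#' @param trajectory simulated `mbs_trajectory`.
#' @param reference list with `forces` ([force_record()]) and `button`
#'   (n x 3 femur-frame coordinates, m).
#' @param config_label configuration tag stored in the report.
#' @param parameter_set free-text tag (e.g. "original" or "optimized").
#' @return data.frame of class `agreement_report`.
#' @export
agreement_report <- function(trajectory, reference, config_label = "B",
                             parameter_set = "original") {
  rs <- resample_trajectory(trajectory, reference$forces$times)
  chans <- list(
    contact = list(sim = rs$contact, ref = reference$forces$contact_normal, unit = "N"),
    tibial = list(sim = rs$tibial, ref = reference$forces$tibial_spring, unit = "N"),
    femoral = list(sim = rs$femoral, ref = reference$forces$femoral_spring, unit = "N"),
    X = list(sim = rs$button[, 1] * 1000, ref = reference$button[, 1] * 1000, unit = "mm"),
    Y = list(sim = rs$button[, 2] * 1000, ref = reference$button[, 2] * 1000, unit = "mm"),
    Z = list(sim = rs$button[, 3] * 1000, ref = reference$button[, 3] * 1000, unit = "mm"))
  rows <- lapply(names(chans), function(nm) {
    ba <- bland_altman(chans[[nm]]$sim, chans[[nm]]$ref)
    data.frame(channel = nm, units = chans[[nm]]$unit, bias = ba$bias,
               sd_diff = ba$sd_diff, loa_low = ba$loa_low,
               loa_high = ba$loa_high, configuration = config_label,
               parameter_set = parameter_set)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", "data.frame")
  out
}
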