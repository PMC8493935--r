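#' Dynamic time warping distance
#'
#' Classic DTW with Euclidean local cost, the symmetric step pattern
#' (match, insert, delete) and anchored boundaries; returns the accumulated
#' cost along the optimal warping path. Sequences may be numeric vectors
#' (1-D series) or two-column matrices / data.frames of (x, y) points.
#'
#' @param a,b Sequences of length >= 1 (>= 2 for meaningful alignment).
#' @return Accumulated cost (same units as the coordinates, meters for
#'   planar paths).
#' @export
dtw_distance <- function(a, b) {
  as_mat <- function(z) {
    if (is.data.frame(z)) z <- as.matrix(z[, intersect(c("x", "y"), names(z)),
                                           drop = FALSE])
    if (is.null(dim(z))) z <- matrix(as.numeric(z), ncol = 1)
    storage.mode(z) <- "double"
    z
  }
  a <- as_mat(a); b <- as_mat(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty sequence")
  .dtw_cpp(a, b)
}

#' Differential evolution global optimizer
#'
#' A standard rand/1/bin differential-evolution search: each generation
#' mutates every population member with a random-base difference vector
#' (dithered mutation factor) and binomial crossover, keeping the trial
#' point when it improves. Deterministic given `seed`. Convergence is
#' declared when the population's cost spread falls below
#' `tol * |mean cost| + 1e-12`.
#'
#' @param fn Objective function of a numeric vector, returning a finite
#'   scalar (use large finite penalties for failures).
#' @param lower,upper Bounds (equal length, `lower <= upper`).
#' @param seed Integer seed.
#' @param pop_size Population size (default `10 * d`, minimum 6).
#' @param max_iter Maximum generations.
#' @param F_range Mutation factor dither range.
#' @param CR Crossover probability.
#' @param tol Relative convergence tolerance on population cost spread.
#' @return List with `par`, `value`, `iterations`, `n_eval`, `converged`.
#' @export
diff_evolution <- function(fn, lower, upper, seed = 1,
                           pop_size = max(6, 10 * length(lower)),
                           max_iter = 100, F_range = c(0.5, 1), CR = 0.7,
                           tol = 1e-3) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  d <- length(lower)
  with_seed(seed, {
    pop <- matrix(runif(pop_size * d, rep(lower, each = pop_size),
                        rep(upper, each = pop_size)),
                  nrow = pop_size)
    # degenerate (point) dimensions stay fixed automatically
    cost <- apply(pop, 1, fn)
    if (all(!is.finite(cost))) stop("objective non-finite over the whole initial population")
    n_eval <- pop_size
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(max_iter)) {
      Fm <- runif(1, F_range[1], F_range[2])
      for (i in seq_len(pop_size)) {
        idx <- sample(setdiff(seq_len(pop_size), i), 3)
        mutant <- pop[idx[1], ] + Fm * (pop[idx[2], ] - pop[idx[3], ])
        mutant <- pmin(pmax(mutant, lower), upper)
        cross <- runif(d) < CR
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        tc <- fn(trial)
        n_eval <- n_eval + 1
        if (is.finite(tc) && tc <= cost[i]) {
          pop[i, ] <- trial
          cost[i] <- tc
        }
      }
      if (diff(range(cost)) <= tol * abs(mean(cost)) + 1e-12) {
        converged <- TRUE
        break
      }
    }
    best <- which.min(cost)
    list(par = pop[best, ], value = cost[best], iterations = iter,
         n_eval = n_eval, converged = converged)
  })
}

default_fit_bounds <- function() {
  list(lower = c(beta = 0.1, gamma = 0.5, epsilon = 1),
       upper = c(beta = 20, gamma = 400, epsilon = 1000))
}

#' Fit the heading dynamics to an observed trajectory
#'
#' Searches over the free parameters (beta, gamma, epsilon) with
#' differential evolution, minimizing the DTW distance between the
#' observed (x, y) path and the path simulated under the candidate
#' parameters in the same scenario; the shaping constants c1-c4 stay
#' fixed. Candidate parameter sets whose simulation blows up are penalized
#' with a large finite cost so the population can move out of unstable
#' regions. The search is deterministic given `seed`.
#'
#' @param observed A `nav_trajectory` (the trajectory to fit).
#' @param scenario The [scenario()] the trajectory was produced in.
#' @param bounds List with `lower` and `upper` named vectors over
#'   (beta, gamma, epsilon); see `default_fit_bounds()` in the sources for
#'   the shipped brackets.
#' @param constants A [dpmp_constants()] (fixed during the fit).
#' @param start_phi Initial heading used for candidate simulations;
#'   defaults to the observed initial heading.
#' @param speed Forward speed for candidate simulations; `NULL` estimates
#'   it from the observed samples (median step speed).
#' @param dt Simulation step (s).
#' @param mode Simulation mode, `"continuous"` (default) or `"game"`.
#' @param seed Integer seed for the optimizer.
#' @param control List of optimizer settings (`pop_size`, `max_iter`,
#'   `tol`, `CR`, `F_range`) overriding the defaults.
#' @param trajectory_id Identifier stored on the result.
#' @return An object of class `dpmp_fit` with components `par` (named
#'   fitted vector), `dtw_error`, `constants`, `bounds`, `optimizer`
#'   (seed, iterations, n_eval, converged), `scenario`, `observed`,
#'   `start_phi`, `speed`, `dt`, `mode`, `trajectory_id`.
#' @seealso [coef.dpmp_fit()], [predict.dpmp_fit()], [residuals.dpmp_fit()]
#' @export
fit_dpmp <- function(observed, scenario, bounds = default_fit_bounds(),
                     constants = dpmp_constants(), start_phi = NULL,
                     speed = NULL, dt = 0.02,
                     mode = c("continuous", "game"), seed = 1,
                     control = list(), trajectory_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(observed, "nav_trajectory"),
            inherits(scenario, "nav_scenario"),
            all(is.finite(c(bounds$lower, bounds$upper))),
            all(bounds$lower <= bounds$upper))
  if (is.null(start_phi)) start_phi <- observed$phi[1]
  if (is.null(speed)) {
    step_d <- sqrt(diff(observed$x)^2 + diff(observed$y)^2)
    speed <- median(step_d / diff(observed$t))
  }
  obs_xy <- cbind(observed$x, observed$y)
  t_max <- max(duration(observed), 1)
  penalty <- 1e6
  objective <- function(p) {
    params <- dpmp_params(beta = p[1], gamma = p[2], epsilon = p[3],
                          constants = constants)
    sim <- tryCatch(
      dpmp_simulate(scenario, params, start_phi = start_phi, speed = speed,
                    dt = dt, t_max = t_max, mode = mode),
      error = function(e) NULL)
    if (is.null(sim)) return(penalty)
    dtw_distance(obs_xy, cbind(sim$x, sim$y))
  }
  ctl <- utils::modifyList(
    list(pop_size = 30, max_iter = 60, tol = 1e-3, CR = 0.7,
         F_range = c(0.5, 1)),
    control)
  res <- diff_evolution(objective, bounds$lower, bounds$upper, seed = seed,
                        pop_size = ctl$pop_size, max_iter = ctl$max_iter,
                        F_range = ctl$F_range, CR = ctl$CR, tol = ctl$tol)
  if (res$value >= penalty)
    stop("all candidate parameter sets failed to simulate")
  structure(list(par = setNames(res$par, c("beta", "gamma", "epsilon")),
                 dtw_error = res$value,
                 constants = constants, bounds = bounds,
                 optimizer = list(seed = seed, iterations = res$iterations,
                                  n_eval = res$n_eval,
                                  converged = res$converged),
                 scenario = scenario, observed = observed,
                 start_phi = start_phi, speed = speed, dt = dt, mode = mode,
                 trajectory_id = trajectory_id,
                 call = match.call()),
            class = "dpmp_fit")
}

#' @export
print.dpmp_fit <- function(x, ...) {
  cat("Heading-dynamics fit (differential evolution / DTW)\n")
  cat(sprintf("  beta = %.4g /s, gamma = %.4g /s^2, epsilon = %.4g /s^2\n",
              x$par["beta"], x$par["gamma"], x$par["epsilon"]))
  cat(sprintf("  DTW error: %.4g m (%d generations, %d evaluations%s)\n",
              x$dtw_error, x$optimizer$iterations, x$optimizer$n_eval,
              if (x$optimizer$converged) ", converged" else ""))
  invisible(x)
}

#' @export
coef.dpmp_fit <- function(object, ...) object$par

#' @export
summary.dpmp_fit <- function(object, ...) {
  s <- list(par = object$par, dtw_error = object$dtw_error,
            constants = unlist(object$constants),
            bounds = object$bounds, optimizer = object$optimizer,
            scenario_id = object$scenario$config_id,
            n_obs = nrow(object$observed), mode = object$mode,
            speed = object$speed)
  class(s) <- "summary.dpmp_fit"
  s
}

#' @export
print.summary.dpmp_fit <- function(x, ...) {
  cat("Heading-dynamics model fit\n")
  cat(sprintf("  scenario: %s (%d observed samples, %s mode, speed %.2f m/s)\n",
              x$scenario_id, x$n_obs, x$mode, x$speed))
  cat("  fitted parameters:\n")
  for (nm in names(x$par))
    cat(sprintf("    %-8s %10.4g   in [%g, %g]\n", nm, x$par[nm],
                x$bounds$lower[nm], x$bounds$upper[nm]))
  cat("  fixed constants: ",
      paste(sprintf("%s = %g", names(x$constants), x$constants),
            collapse = ", "), "\n")
  cat(sprintf("  DTW error %.4g m; %d generations, %d evaluations, %s\n",
              x$dtw_error, x$optimizer$iterations, x$optimizer$n_eval,
              if (x$optimizer$converged) "converged" else "not converged"))
  invisible(x)
}

#' Simulate from a fitted heading-dynamics model
#'
#' `predict()` re-simulates the fitted model, by default in the fitting
#' scenario, or in `newdata` (a scenario or list of scenarios);
#' `fitted()` returns the simulation in the fitting scenario;
#' `residuals()` returns per-sample x/y differences between the observed
#' path and the fitted path after resampling both to a common length.
#'
#' @param object A `dpmp_fit`.
#' @param newdata A `nav_scenario` or list of them (default: the fitting
#'   scenario).
#' @param ... Passed to [dpmp_simulate()] overrides.
#' @return A `nav_trajectory`, or a list of them for a list `newdata`.
#' @export
predict.dpmp_fit <- function(object, newdata = NULL, ...) {
  params <- dpmp_params(object$par["beta"], object$par["gamma"],
                        object$par["epsilon"], constants = object$constants)
  sim1 <- function(sc) dpmp_simulate(sc, params, start_phi = object$start_phi,
                                     speed = object$speed, dt = object$dt,
                                     t_max = max(duration(object$observed), 1),
                                     mode = object$mode, ...)
  if (is.null(newdata)) return(sim1(object$scenario))
  if (inherits(newdata, "nav_scenario")) return(sim1(newdata))
  lapply(newdata, sim1)
}

#' @export
fitted.dpmp_fit <- function(object, ...) predict(object)

#' @rdname predict.dpmp_fit
#' @param n Number of common resampling points for residuals.
#' @export
residuals.dpmp_fit <- function(object, n = 200, ...) {
  obs <- resample_to_n(object$observed, n)
  sim <- resample_to_n(predict(object), n)
  data.frame(t = obs$t, dx = obs$x - sim$x, dy = obs$y - sim$y)
}

#' @export
simulate.dpmp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  # the fitted dynamics are deterministic; nsim > 1 returns replicates
  args <- list(...)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    do.call(predict, c(list(object), args))))
}

#' @export
plot.dpmp_fit <- function(x, ...) {
  sim <- predict(x)
  ob <- x$scenario$obstacles
  plot(x$observed$x, x$observed$y, type = "l", col = "darkgreen",
       xlab = "x (m)", ylab = "y (m)", asp = 1,
       main = "Observed (green) vs fitted (red) path", ...)
  graphics::lines(sim$x, sim$y, col = "red")
  if (nrow(ob)) graphics::symbols(ob$x, ob$y, circles = ob$radius,
                                  inches = FALSE, add = TRUE, fg = "blue")
  graphics::points(x$scenario$target[1], x$scenario$target[2], pch = 19,
                   col = "red")
  invisible(x)
}

#' Characteristic parameters of one agent
#'
#' The arithmetic mean of the fitted (beta, gamma, epsilon) across all of
#' an agent's trajectory fits, giving each agent its own characteristic
#' parameter set.
#'
#' @param fits Non-empty list of `dpmp_fit` objects belonging to one agent.
#' @param agent_id Identifier.
#' @return An object of class `dpmp_characteristic`: list with `agent_id`,
#'   `beta`, `gamma`, `epsilon`, `n_fits`.
#' @export
characteristic_params <- function(fits, agent_id = "agent") {
  if (length(fits) == 0) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, TRUE, "dpmp_fit")))
  pars <- t(vapply(fits, coef, numeric(3)))
  structure(list(agent_id = agent_id,
                 beta = mean(pars[, "beta"]), gamma = mean(pars[, "gamma"]),
                 epsilon = mean(pars[, "epsilon"]), n_fits = length(fits)),
            class = "dpmp_characteristic")
}

#' @export
print.dpmp_characteristic <- function(x, ...) {
  cat(sprintf("<dpmp_characteristic %s> beta = %.4g, gamma = %.4g, epsilon = %.4g (over %d fits)\n",
              x$agent_id, x$beta, x$gamma, x$epsilon, x$n_fits))
  invisible(x)
}

#' Simulate an agent's characteristic trajectories
#'
#' One deterministic simulation per scenario under the agent's
#' characteristic parameters.
#'
#' @param cp A [characteristic_params()] result.
#' @param scenarios List of [scenario()] objects.
#' @param constants A [dpmp_constants()].
#' @param ... Passed to [dpmp_simulate()].
#' @return A list of `nav_trajectory`, one per scenario.
#' @export
simulate_characteristic <- function(cp, scenarios,
                                    constants = dpmp_constants(), ...) {
  stopifnot(inherits(cp, "dpmp_characteristic"))
  params <- dpmp_params(cp$beta, cp$gamma, cp$epsilon, constants = constants)
  lapply(scenarios, dpmp_simulate, params = params, ...)
}

#' Parameter-recovery study
#'
#' Validation harness for the fitting pipeline: for each row of a grid of
#' true (beta, gamma, epsilon) values, simulate a trajectory, optionally
#' perturb it with Gaussian position noise, re-fit, and record the
#' relative recovery error of every parameter and the residual DTW cost.
#'
#' @param true_grid Data.frame with columns `beta`, `gamma`, `epsilon`
#'   (all inside `bounds`).
#' @param scenario The [scenario()] used for all simulations.
#' @param noise_sd Standard deviation of iid Gaussian noise added to the
#'   observed x and y (m); 0 for noiseless recovery.
#' @param seed Master seed; row `i` uses `seed + i` for its fit (and its
#'   noise draw).
#' @param bounds,constants,control,dt,mode Passed to [fit_dpmp()].
#' @param start_phi,speed Simulation settings for the synthetic truths.
#' @return A data.frame with one row per grid point: true and recovered
#'   parameters, per-parameter relative errors, and `dtw_error`. The
#'   attribute `"summary"` holds median relative errors.
#' @export
recovery_study <- function(true_grid, scenario, noise_sd = 0, seed = 1,
                           bounds = default_fit_bounds(),
                           constants = dpmp_constants(), control = list(),
                           dt = 0.02, mode = "continuous",
                           start_phi = pi / 2, speed = 10) {
  if (nrow(true_grid) == 0)
    return(data.frame(beta_true = numeric(), gamma_true = numeric(),
                      epsilon_true = numeric()))
  rows <- vector("list", nrow(true_grid))
  for (i in seq_len(nrow(true_grid))) {
    p_true <- dpmp_params(true_grid$beta[i], true_grid$gamma[i],
                          true_grid$epsilon[i], constants = constants)
    truth <- dpmp_simulate(scenario, p_true, start_phi = start_phi,
                           speed = speed, dt = dt, mode = mode)
    obs <- truth
    if (noise_sd > 0) {
      with_seed(seed + i, {
        obs$x <- obs$x + rnorm(nrow(obs), 0, noise_sd)
        obs$y <- obs$y + rnorm(nrow(obs), 0, noise_sd)
      })
    }
    fit <- fit_dpmp(obs, scenario, bounds = bounds, constants = constants,
                    start_phi = start_phi, speed = speed, dt = dt,
                    mode = mode, seed = seed + i, control = control)
    est <- coef(fit)
    rows[[i]] <- data.frame(
      beta_true = true_grid$beta[i], gamma_true = true_grid$gamma[i],
      epsilon_true = true_grid$epsilon[i],
      beta_hat = est["beta"], gamma_hat = est["gamma"],
      epsilon_hat = est["epsilon"],
      beta_rel_err = abs(est["beta"] - true_grid$beta[i]) / true_grid$beta[i],
      gamma_rel_err = abs(est["gamma"] - true_grid$gamma[i]) / true_grid$gamma[i],
      epsilon_rel_err = abs(est["epsilon"] - true_grid$epsilon[i]) /
        true_grid$epsilon[i],
      dtw_error = fit$dtw_error, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    beta_median_rel_err = median(out$beta_rel_err),
    gamma_median_rel_err = median(out$gamma_rel_err),
    epsilon_median_rel_err = median(out$epsilon_rel_err),
    dtw_median = median(out$dtw_error))
  out
}
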