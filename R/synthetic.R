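#' Population profile for synthetic trajectory generation
#'
#' Describes a population of agents by the means of the heading-dynamics
#' parameters, the between-agent and within-agent (trial-to-trial)
#' coefficients of variation, and the control mode. Both defaults use
#' keyboard control (bang-bang discretization of the dynamics through the
#' game's discrete action space, queried every fifth frame): the human-like
#' profile with large CVs and substantial heading-rate noise, the drl-like
#' profile with small CVs and near-zero noise, emulating the tighter
#' trial-to-trial consistency of trained agents acting through the same
#' action interface. The default parameter means put the dynamics in a
#' regime that reliably completes the task at the game's speed and turning
#' caps.
#'
#' @param label `"human_like"` or `"drl_like"`.
#' @param param_means Named means of (beta, gamma, epsilon).
#' @param between_agent_cv,within_agent_cv Coefficients of variation
#'   (scalar or per-parameter length 3).
#' @param control `"keyboard"` or `"continuous"`.
#' @param heading_noise_sd Gaussian noise SD on the keyboard policy's
#'   desired turning rate (rad/s); ignored for continuous control.
#' @return A list of class `population_profile`.
#' @export
population_profile <- function(label = c("human_like", "drl_like"),
                               param_means = c(beta = 3.25, gamma = 30,
                                               epsilon = 600),
                               between_agent_cv = NULL,
                               within_agent_cv = NULL,
                               control = NULL, heading_noise_sd = NULL) {
  label <- match.arg(label)
  defaults <- if (label == "human_like")
    list(between = 0.30, within = 0.15, control = "keyboard", noise = 0.05)
  else
    list(between = 0.05, within = 0.02, control = "keyboard", noise = 0.01)
  if (is.null(between_agent_cv)) between_agent_cv <- defaults$between
  if (is.null(within_agent_cv)) within_agent_cv <- defaults$within
  if (is.null(control)) control <- defaults$control
  if (is.null(heading_noise_sd)) heading_noise_sd <- defaults$noise
  control <- match.arg(control, c("continuous", "keyboard"))
  stopifnot(all(between_agent_cv >= 0), all(within_agent_cv >= 0),
            all(param_means > 0))
  structure(list(label = label,
                 param_means = param_means,
                 between_agent_cv = rep_len(between_agent_cv, 3),
                 within_agent_cv = rep_len(within_agent_cv, 3),
                 control = control,
                 heading_noise_sd = heading_noise_sd),
            class = "population_profile")
}

# Log-normal draw with mean mu and coefficient of variation cv (cv = 0
# returns mu exactly). Strictly positive support.
rlnorm_cv <- function(n, mu, cv) {
  if (all(cv == 0)) return(rep(mu, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
}

#' Randomly place obstacles in the field
#'
#' Uniform rejection sampling inside the field, keeping an edge-to-edge
#' clearance of at least `min_clearance` from the walls, the canonical
#' start and target positions, and every other obstacle. Deterministic
#' given `seed`.
#'
#' @param n_obstacles Number of obstacles (>= 0).
#' @param field A [field_spec()].
#' @param min_clearance Minimum clearance (m).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param radius Obstacle radius (m).
#' @param keep_clear List of points to keep clear (defaults to the
#'   canonical starts and targets).
#' @param max_tries Rejection budget per obstacle.
#' @return An [obstacles()] data.frame.
#' @export
random_obstacle_config <- function(n_obstacles = 9, field = field_spec(),
                                   min_clearance = 1.5, seed = NULL,
                                   radius = 0.25,
                                   keep_clear = list(c(5, -16), c(-5, -16),
                                                     c(12, 16), c(0, 16),
                                                     c(-12, 16)),
                                   max_tries = 1000) {
  stopifnot(n_obstacles >= 0)
  if (n_obstacles == 0) return(obstacles())
  h <- field$half_extent
  lim <- h - radius - min_clearance
  with_seed(seed, {
    xs <- ys <- numeric(0)
    for (i in seq_len(n_obstacles)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        px <- runif(1, -lim, lim); py <- runif(1, -lim, lim)
        ok_pts <- all(vapply(keep_clear, function(p)
          sqrt((p[1] - px)^2 + (p[2] - py)^2) - radius >= min_clearance, TRUE))
        ok_obs <- !length(xs) ||
          all(sqrt((xs - px)^2 + (ys - py)^2) - 2 * radius >= min_clearance)
        if (ok_pts && ok_obs) {
          xs <- c(xs, px); ys <- c(ys, py)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place obstacle %d within %d tries (packing infeasible)",
                     i, max_tries))
    }
    obstacles(xs, ys, radius)
  })
}

#' Draw an agent's characteristic parameters from a profile
#'
#' Each parameter is drawn from a log-normal centered on the profile mean
#' with the profile's between-agent coefficient of variation; draws are
#' strictly positive and deterministic given `seed`.
#'
#' @param profile A [population_profile()].
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return Named numeric vector (beta, gamma, epsilon).
#' @export
sample_agent <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "population_profile"))
  with_seed(seed, setNames(
    vapply(1:3, function(i)
      rlnorm_cv(1, profile$param_means[i], profile$between_agent_cv[i]), 0),
    c("beta", "gamma", "epsilon")))
}

# One synthetic trial for an agent: jitters the characteristic parameters
# with the within-agent CV and runs the profile's control mode. Uses the
# current RNG state (callers seed once for whole datasets).
simulate_trial <- function(agent_pars, profile, scenario,
                           constants = dpmp_constants(),
                           kin = kinematics_spec(), t_max = 20,
                           start_phi = "target") {
  if (identical(start_phi, "target"))
    start_phi <- atan2(scenario$target[2] - scenario$start[2],
                       scenario$target[1] - scenario$start[1])
  p <- vapply(1:3, function(i)
    rlnorm_cv(1, agent_pars[i], profile$within_agent_cv[i]), 0)
  params <- dpmp_params(p[1], p[2], p[3], constants = constants)
  if (profile$control == "continuous") {
    dpmp_simulate(scenario, params, start_phi = start_phi,
                  speed = kin$forward_speed, dt = 1 / kin$frame_rate,
                  t_max = t_max, mode = "game", kin = kin)
  } else {
    pol <- scripted_dpmp_policy(params,
                                decision_dt = kin$decision_interval /
                                  kin$frame_rate,
                                noise_sd = profile$heading_noise_sd)
    run_episode(pol, scenario, spec = kin, max_time = t_max,
                start_phi = start_phi, observe = FALSE)$trajectory
  }
}

#' Generate a synthetic trial dataset
#'
#' For each agent of each profile, each scenario and each repetition,
#' draws trial parameters (within-agent jitter around the agent's
#' characteristic values), simulates under the profile's control mode and
#' records the outcome. Trials that do not reach the target (obstacle hit
#' or episode timeout) are re-run with fresh jitter up to `retry_cap`
#' times, emulating the game's restart rule and its requirement that every
#' recorded trial be a successful one; trials still failing are flagged
#' and excluded. Fully reproducible given `seed`.
#'
#' @param profiles List of [population_profile()] objects.
#' @param n_agents_per_profile Agents per profile.
#' @param scenarios Named list of [scenario()] objects.
#' @param reps Repetitions per agent x scenario (default 6).
#' @param seed Master seed.
#' @param retry_cap Maximum re-runs after obstacle hits.
#' @param constants,kin,t_max Simulation settings.
#' @param start_phi Initial heading: a number (rad) or `"target"` (the
#'   default), which points each trial's initial heading at its target --
#'   players could rotate in place before moving off.
#' @return A list with `trials` (data.frame: `trial_id`, `agent_id`,
#'   `profile`, `scenario_id`, `route_type`, `rep`, `outcome`,
#'   `n_retries`, `excluded`), `trajectories` (named list of
#'   `nav_trajectory` for non-excluded trials) and `agents` (data.frame of
#'   characteristic parameters).
#' @export
generate_dataset <- function(profiles, n_agents_per_profile, scenarios,
                             reps = 6, seed = 1, retry_cap = 20,
                             constants = dpmp_constants(),
                             kin = kinematics_spec(), t_max = 30,
                             start_phi = "target") {
  stopifnot(length(scenarios) > 0)
  if (is.null(names(scenarios)))
    names(scenarios) <- sprintf("scenario%02d", seq_along(scenarios))
  with_seed(seed, {
    trials <- list(); trajectories <- list(); agents <- list()
    for (prof in profiles) {
      for (a in seq_len(n_agents_per_profile)) {
        agent_id <- sprintf("%s_%02d", prof$label, a)
        pars <- setNames(vapply(1:3, function(i)
          rlnorm_cv(1, prof$param_means[i], prof$between_agent_cv[i]), 0),
          c("beta", "gamma", "epsilon"))
        agents[[length(agents) + 1]] <- data.frame(
          agent_id = agent_id, profile = prof$label,
          beta = pars[1], gamma = pars[2], epsilon = pars[3],
          row.names = NULL)
        for (sc_name in names(scenarios)) {
          sc <- scenarios[[sc_name]]
          for (r in seq_len(reps)) {
            tr <- NULL; tries <- 0L
            repeat {
              cand <- simulate_trial(pars, prof, sc, constants = constants,
                                     kin = kin, t_max = t_max,
                                     start_phi = start_phi)
              if (attr(cand, "outcome") == "reached_target") { tr <- cand; break }
              tries <- tries + 1L
              if (tries > retry_cap) break
            }
            excluded <- is.null(tr)
            trial_id <- sprintf("%s_%s_r%d", agent_id, sc_name, r)
            trials[[length(trials) + 1]] <- data.frame(
              trial_id = trial_id, agent_id = agent_id,
              profile = prof$label, scenario_id = sc_name,
              route_type = sc$route_type, rep = r,
              outcome = if (excluded) "failed" else attr(tr, "outcome"),
              n_retries = tries, excluded = excluded, row.names = NULL)
            if (!excluded) trajectories[[trial_id]] <- tr
          }
        }
      }
    }
    list(trials = do.call(rbind, trials),
         trajectories = trajectories,
         agents = do.call(rbind, agents))
  })
}
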