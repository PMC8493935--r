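#' Fixed shaping constants of the heading dynamics
#'
#' The four constants shape the distance/angle dependence of the goal and
#' obstacle terms: `c1` (1/m) sets the decay rate of goal attraction with
#' goal distance, `c2` (dimensionless) is the floor of the attraction gain
#' so attraction never vanishes at large distance, `c3` (1/rad) sets the
#' decay of obstacle repulsion with angular offset from the obstacle
#' direction, and `c4` (1/m) the decay of repulsion with obstacle distance.
#' The shipped defaults are the values of the original point-attractor
#' steering formulation of Fajen and Warren (2003); they are configuration,
#' and all downstream functions accept alternatives.
#'
#' @param c1,c2,c3,c4 Non-negative constants as described above.
#' @return A named list of class `dpmp_constants`.
#' @export
dpmp_constants <- function(c1 = 0.40, c2 = 0.40, c3 = 6.5, c4 = 0.8) {
  v <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4)
  stopifnot(all(is.finite(v)), all(v >= 0))
  structure(as.list(v), class = "dpmp_constants")
}

#' Model parameters of the heading dynamics
#'
#' The free parameters are `beta` (1/s), damping on turning rate; `gamma`
#' (1/s^2), stiffness of the attraction toward the goal direction; and
#' `epsilon` (1/s^2), strength of the repulsion away from obstacle
#' directions. Angles are radians throughout.
#'
#' @param beta,gamma,epsilon Non-negative free parameters.
#' @param constants A [dpmp_constants()] object.
#' @return A named list of class `dpmp_params` containing all seven values.
#' @export
dpmp_params <- function(beta = 3.25, gamma = 7.5, epsilon = 198,
                        constants = dpmp_constants()) {
  stopifnot(inherits(constants, "dpmp_constants"),
            beta >= 0, gamma >= 0, epsilon >= 0)
  structure(c(list(beta = beta, gamma = gamma, epsilon = epsilon),
              unclass(constants)),
            class = "dpmp_params")
}

#' @export
print.dpmp_params <- function(x, ...) {
  cat(sprintf("<dpmp_params> beta = %g /s, gamma = %g /s^2, epsilon = %g /s^2 (c1 = %g, c2 = %g, c3 = %g, c4 = %g)\n",
              x$beta, x$gamma, x$epsilon, x$c1, x$c2, x$c3, x$c4))
  invisible(x)
}

#' Agent state
#'
#' @param x,y Position in meters.
#' @param phi Heading in radians (world frame, counterclockwise from +x),
#'   wrapped to (-pi, pi].
#' @param phi_dot Turning rate in rad/s.
#' @param speed Forward speed in m/s (non-negative).
#' @return A named list of class `agent_state`.
#' @export
agent_state <- function(x, y, phi, phi_dot = 0, speed = 10) {
  stopifnot(speed >= 0)
  structure(list(x = x, y = y, phi = wrap_angle(phi),
                 phi_dot = phi_dot, speed = speed),
            class = "agent_state")
}

#' Egocentric view of goal and obstacles
#'
#' World-frame bearings and distances from the agent to the target and to
#' each obstacle; the dynamics act on the wrapped differences between the
#' heading and these bearings.
#'
#' @param state An [agent_state()].
#' @param target Length-2 target point (m).
#' @param obstacles Obstacle data.frame ([obstacles()]).
#' @return A list with `theta_g`, `d_g`, `theta_o`, `d_o`.
#' @export
egocentric_view <- function(state, target, obstacles = NULL) {
  dxg <- target[1] - state$x; dyg <- target[2] - state$y
  d_g <- sqrt(dxg^2 + dyg^2)
  if (d_g == 0) stop("agent position coincides with the target")
  theta_o <- d_o <- numeric(0)
  if (!is.null(obstacles) && nrow(obstacles)) {
    dxo <- obstacles$x - state$x; dyo <- obstacles$y - state$y
    d_o <- sqrt(dxo^2 + dyo^2)
    if (any(d_o == 0)) stop("agent position coincides with an obstacle center")
    theta_o <- atan2(dyo, dxo)
  }
  list(theta_g = atan2(dyg, dxg), d_g = d_g, theta_o = theta_o, d_o = d_o)
}

#' Heading angular acceleration
#'
#' Evaluates the steering dynamics
#' \deqn{\ddot\phi = -\beta\dot\phi
#'   - \gamma\,(\phi-\theta_g)\,(e^{-c_1 d_g} + c_2)
#'   + \sum_i \varepsilon\,(\phi-\theta_{O_i})\,
#'     e^{-c_3|\phi-\theta_{O_i}|}\, e^{-c_4 d_{O_i}}}
#' with every angular difference wrapped to (-pi, pi].
#'
#' @param phi Heading (rad).
#' @param phi_dot Turning rate (rad/s).
#' @param view An [egocentric_view()].
#' @param params A [dpmp_params()].
#' @return Angular acceleration in rad/s^2.
#' @export
heading_acceleration <- function(phi, phi_dot, view, params) {
  stopifnot(inherits(params, "dpmp_params"))
  dg <- wrap_angle(phi - view$theta_g)
  acc <- -params$beta * phi_dot -
    params$gamma * dg * (exp(-params$c1 * view$d_g) + params$c2)
  if (length(view$theta_o)) {
    da <- wrap_angle(phi - view$theta_o)
    acc <- acc + sum(params$epsilon * da * exp(-params$c3 * abs(da)) *
                       exp(-params$c4 * view$d_o))
  }
  acc
}

#' Simulate a trajectory under the heading dynamics
#'
#' Integrates the steering dynamics with a first-order (Euler) scheme at
#' fixed step `dt`: the angular acceleration is evaluated at the current
#' state, then turning rate, heading and position are updated in sequence.
#' In `mode = "game"` the turning rate and angular acceleration are clamped
#' to the kinematic caps of the navigation game; `mode = "continuous"`
#' integrates the dynamics uncapped. The episode terminates when the agent
#' disc overlaps the target disc (`reached_target`), overlaps an obstacle
#' (`hit_obstacle`), or at `t_max` (`timed_out`). The integration is fully
#' deterministic.
#'
#' @param scenario A [scenario()].
#' @param params A [dpmp_params()].
#' @param start_phi Initial heading (rad); default pi/2 (facing up-field).
#' @param speed Constant forward speed (m/s).
#' @param dt Time step (s); default 0.02 (the game's 50 Hz update).
#' @param t_max Maximum duration (s); default 20, the admissibility cutoff.
#' @param mode `"continuous"` (uncapped) or `"game"` (capped kinematics).
#' @param kin A [kinematics_spec()] supplying the caps for `mode = "game"`.
#' @param agent_radius Agent body radius (m) for capture/collision tests.
#' @param start_phi_dot Initial turning rate (rad/s).
#' @return A `nav_trajectory`: a data.frame with columns `t, x, y, phi` and
#'   attributes `dt`, `outcome`, `scenario_id`, `params`.
#' @export
dpmp_simulate <- function(scenario, params, start_phi = pi / 2, speed = 10,
                          dt = 0.02, t_max = 20,
                          mode = c("continuous", "game"),
                          kin = kinematics_spec(), agent_radius = 0.25,
                          start_phi_dot = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "nav_scenario"), inherits(params, "dpmp_params"),
            dt > 0, t_max > 0)
  caps <- if (mode == "game")
    c(kin$max_turn_rate * pi / 180, kin$turn_accel * pi / 180)
  else c(Inf, Inf)
  ob <- scenario$obstacles
  res <- .simulate_dpmp_cpp(
    scenario$start[1], scenario$start[2], start_phi, start_phi_dot, speed,
    scenario$target[1], scenario$target[2],
    ob$x, ob$y, ob$radius,
    scenario$target_radius, agent_radius,
    params$beta, params$gamma, params$epsilon,
    params$c1, params$c2, params$c3, params$c4,
    dt, as.integer(round(t_max / dt)), caps[1], caps[2])
  nav_trajectory(data.frame(t = res$t, x = res$x, y = res$y, phi = res$phi),
                 dt = dt, outcome = res$outcome,
                 scenario_id = scenario$config_id, params = params)
}

#' Trajectory container
#'
#' @param samples A data.frame with columns `t, x, y, phi` (seconds, meters,
#'   radians), times strictly increasing.
#' @param dt Sampling interval (s), or `NA` for non-uniform series.
#' @param outcome One of `"reached_target"`, `"hit_obstacle"`, `"timed_out"`.
#' @param scenario_id,params Optional provenance.
#' @return An object of classes `nav_trajectory` and `data.frame`.
#' @export
nav_trajectory <- function(samples, dt = NA_real_, outcome = "timed_out",
                           scenario_id = NA_character_, params = NULL) {
  stopifnot(all(c("t", "x", "y", "phi") %in% names(samples)),
            nrow(samples) >= 1, !is.unsorted(samples$t, strictly = TRUE))
  structure(samples, dt = dt, outcome = outcome, scenario_id = scenario_id,
            params = params, class = c("nav_trajectory", "data.frame"))
}

#' @export
print.nav_trajectory <- function(x, ...) {
  cat(sprintf("<nav_trajectory> %d samples over %.2f s, outcome %s\n",
              nrow(x), x$t[nrow(x)] - x$t[1], attr(x, "outcome")))
  invisible(x)
}

#' Trajectory summaries
#'
#' `path_length()` is the cumulative Euclidean arc length of the sampled
#' path; `duration()` is the elapsed time.
#'
#' @param traj A `nav_trajectory`.
#' @return A length-1 numeric (meters / seconds).
#' @export
path_length <- function(traj) {
  n <- nrow(traj)
  if (n < 2) return(0)
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' @rdname path_length
#' @export
duration <- function(traj) traj$t[nrow(traj)] - traj$t[1]

#' Read and write trajectory CSV
#'
#' Plain CSV with header `t,x,y,phi`, one row per sample; a JSON sidecar
#' (`<path>.json`) records dt, outcome and scenario id.
#'
#' @param traj A `nav_trajectory`.
#' @param path CSV path.
#' @return `read_trajectory_csv()` returns a `nav_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj)[, c("t", "x", "y", "phi")], path,
            row.names = FALSE)
  meta <- list(dt = attr(traj, "dt"), outcome = attr(traj, "outcome"),
               scenario_id = attr(traj, "scenario_id"))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(dt = NA_real_, outcome = "timed_out", scenario_id = NA_character_)
  nav_trajectory(df, dt = if (is.null(meta$dt)) NA_real_ else meta$dt,
                 outcome = meta$outcome,
                 scenario_id = if (is.null(meta$scenario_id)) NA_character_
                 else meta$scenario_id)
}

# Mirror a trajectory about the y axis (x -> -x, phi -> pi - phi).
mirror_trajectory <- function(traj) {
  out <- traj
  out$x <- -out$x
  out$phi <- wrap_angle(pi - out$phi)
  out
}

# Mirror a scenario about the y axis.
mirror_scenario <- function(s) {
  ob <- s$obstacles
  if (nrow(ob)) ob$x <- -ob$x
  scenario(config_id = paste0(s$config_id, "_mirror"), obstacles = ob,
           start = c(-s$start[1], s$start[2]),
           target = c(-s$target[1], s$target[2]),
           target_radius = s$target_radius, field = s$field)
}
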