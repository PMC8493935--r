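#' Kinematics of the navigation game
#'
#' The game moves the agent at a constant forward speed while arrow-key
#' style rotation commands accelerate the turning rate up to a hard cap.
#' Defaults are the game's settings: 10 m/s forward speed, 25 deg/s maximum
#' rotation speed, 62.5 deg/s^2 angular acceleration, 50 Hz updates, with
#' policy decisions every fifth frame.
#'
#' @param forward_speed Forward speed (m/s).
#' @param max_turn_rate Maximum rotation speed (deg/s).
#' @param turn_accel Angular acceleration of rotation commands (deg/s^2).
#' @param frame_rate Simulation update rate (Hz).
#' @param decision_interval Frames between policy queries (integer >= 1).
#' @return A list of class `kinematics_spec`.
#' @export
kinematics_spec <- function(forward_speed = 10, max_turn_rate = 25,
                            turn_accel = 62.5, frame_rate = 50,
                            decision_interval = 5L) {
  stopifnot(forward_speed > 0, max_turn_rate > 0, turn_accel > 0,
            frame_rate > 0, decision_interval >= 1)
  structure(list(forward_speed = forward_speed,
                 max_turn_rate = max_turn_rate,
                 turn_accel = turn_accel,
                 frame_rate = frame_rate,
                 decision_interval = as.integer(decision_interval)),
            class = "kinematics_spec")
}

#' Discrete actions of the navigation game
#'
#' An action is one "move" choice (forward or none) plus one "rotate"
#' choice (left, none or right); encoded as two one-hot groups with total
#' output dimension 5.
#'
#' @param move `"forward"` or `"none"`.
#' @param rotate `"left"`, `"none"` or `"right"`.
#' @return A list of class `nav_action`.
#' @export
nav_action <- function(move = c("forward", "none"),
                       rotate = c("none", "left", "right")) {
  move <- match.arg(move); rotate <- match.arg(rotate)
  structure(list(move = move, rotate = rotate), class = "nav_action")
}

#' @describeIn nav_action One-hot encoding: `c(move_forward, move_none,
#'   rotate_left, rotate_none, rotate_right)`, length 5.
#' @param action A `nav_action`.
#' @export
encode_action <- function(action) {
  stopifnot(inherits(action, "nav_action"))
  c(move_forward = as.numeric(action$move == "forward"),
    move_none = as.numeric(action$move == "none"),
    rotate_left = as.numeric(action$rotate == "left"),
    rotate_none = as.numeric(action$rotate == "none"),
    rotate_right = as.numeric(action$rotate == "right"))
}

# Egocentric ray angles: one ray straight ahead and five on each side spread
# equally over 45 degrees per side (spacing 9 degrees), ordered left to right.
ray_angles <- function() seq(45, -45, by = -9) * pi / 180

ray_classes <- c("target", "obstacle", "other", "nothing")

# Smallest positive t with |p + t u - c| = r, or Inf.
ray_circle_t <- function(px, py, ux, uy, cx, cy, r) {
  fx <- px - cx; fy <- py - cy
  b <- fx * ux + fy * uy
  c0 <- fx^2 + fy^2 - r^2
  disc <- b^2 - c0
  if (disc < 0) return(Inf)
  s <- sqrt(disc)
  t1 <- -b - s; t2 <- -b + s
  if (t1 > 0) t1 else if (t2 > 0) t2 else Inf
}

# Distance along direction (ux, uy) from (px, py) to the square boundary
# [-h, h]^2 (agent assumed inside).
ray_wall_t <- function(px, py, ux, uy, h) {
  ts <- c(if (ux > 0) (h - px) / ux, if (ux < 0) (-h - px) / ux,
          if (uy > 0) (h - py) / uy, if (uy < 0) (-h - py) / uy)
  ts <- ts[ts > 0]
  if (length(ts)) min(ts) else Inf
}

#' Raycast observation block
#'
#' Casts 11 rays (straight ahead and five per side spread equally over 45
#' degrees per side, 9 degree spacing) and reports, per ray, the nearest
#' intersected object class as a one-hot vector of size 4 over
#' (target, obstacle, other, nothing) — "other" fires on the boundary wall.
#'
#' @param state An [agent_state()].
#' @param scenario A [scenario()].
#' @param max_ray_length Maximum ray reach (m); default the field diagonal,
#'   so the wall is always detectable.
#' @return A named numeric vector of length 44 (11 rays x 4 classes),
#'   ordered from the leftmost ray (+45 deg) to the rightmost (-45 deg).
#' @export
cast_rays <- function(state, scenario,
                      max_ray_length = 2 * sqrt(2) * scenario$field$half_extent) {
  angs <- state$phi + ray_angles()
  ob <- scenario$obstacles
  h <- scenario$field$half_extent
  out <- matrix(0, nrow = 11, ncol = 4, dimnames = list(NULL, ray_classes))
  for (i in seq_len(11)) {
    ux <- cos(angs[i]); uy <- sin(angs[i])
    t_obs <- Inf
    if (nrow(ob))
      t_obs <- min(vapply(seq_len(nrow(ob)), function(j)
        ray_circle_t(state$x, state$y, ux, uy, ob$x[j], ob$y[j], ob$radius[j]),
        0))
    t_tgt <- ray_circle_t(state$x, state$y, ux, uy,
                          scenario$target[1], scenario$target[2],
                          scenario$target_radius)
    t_wall <- if (scenario$field$wall_present)
      ray_wall_t(state$x, state$y, ux, uy, h) else Inf
    ts <- c(target = t_tgt, obstacle = t_obs, other = t_wall)
    hit <- which.min(ts)
    cls <- if (ts[hit] <= max_ray_length) names(ts)[hit] else "nothing"
    out[i, cls] <- 1
  }
  v <- as.numeric(t(out))
  names(v) <- paste0("ray", rep(1:11, each = 4), "_", rep(ray_classes, 11))
  v
}

#' Full observation vector
#'
#' Concatenates the 44-entry raycast block with the egocentric target
#' heading (wrapped to (-pi, pi]) and the target distance, for a total
#' length of 46.
#'
#' @inheritParams cast_rays
#' @return A named numeric vector of length 46.
#' @export
encode_observation <- function(state, scenario,
                               max_ray_length = 2 * sqrt(2) * scenario$field$half_extent) {
  view <- egocentric_view(state, scenario$target)
  c(cast_rays(state, scenario, max_ray_length),
    target_heading = wrap_angle(view$theta_g - state$phi),
    target_distance = view$d_g)
}

#' One kinematic frame of the navigation game
#'
#' Rotation commands accelerate the turning rate toward the commanded sign
#' at `turn_accel`, clamped to `max_turn_rate`; with `rotate = "none"` the
#' rate decays toward zero at the same acceleration (without crossing).
#' Heading integrates the updated rate; the position advances
#' `forward_speed * dt` along the heading iff `move = "forward"`. There is
#' no backward motion.
#'
#' @param state An [agent_state()].
#' @param action A [nav_action()].
#' @param spec A [kinematics_spec()].
#' @param dt Frame duration (s); default `1 / frame_rate`.
#' @return The updated `agent_state`.
#' @export
env_step <- function(state, action, spec = kinematics_spec(),
                     dt = 1 / spec$frame_rate) {
  stopifnot(inherits(action, "nav_action"))
  acc <- spec$turn_accel * pi / 180
  cap <- spec$max_turn_rate * pi / 180
  s <- switch(action$rotate, left = 1, none = 0, right = -1)
  pd <- state$phi_dot
  if (s != 0) {
    pd <- pd + s * acc * dt
  } else if (pd != 0) {
    step <- acc * dt
    pd <- if (abs(pd) <= step) 0 else pd - sign(pd) * step
  }
  pd <- max(min(pd, cap), -cap)
  phi <- wrap_angle(state$phi + pd * dt)
  mv <- if (action$move == "forward") spec$forward_speed * dt else 0
  agent_state(x = state$x + mv * cos(phi), y = state$y + mv * sin(phi),
              phi = phi, phi_dot = pd,
              speed = if (action$move == "forward") spec$forward_speed else 0)
}

#' Run one episode of the navigation game
#'
#' Steps the environment at `frame_rate`, querying `policy` every
#' `decision_interval` frames and holding the action between queries. The
#' episode terminates on target capture (reward +1), obstacle collision
#' (reward -1) or timeout at `max_time` (reward -1), and records the full
#' frame-rate trajectory.
#'
#' @param policy A function `(observation, state, scenario) -> nav_action`.
#' @param scenario A [scenario()].
#' @param spec A [kinematics_spec()].
#' @param max_time Episode cap in seconds (default 30).
#' @param start_phi Initial heading (rad).
#' @param agent_radius Agent body radius (m).
#' @param observe If `FALSE`, pass `NULL` observations to the policy
#'   (cheaper for state-based scripted policies).
#' @return A list of class `episode_result` with elements `trajectory`
#'   (`nav_trajectory`), `reward` and `outcome`.
#' @export
run_episode <- function(policy, scenario, spec = kinematics_spec(),
                        max_time = 30, start_phi = pi / 2,
                        agent_radius = 0.25, observe = TRUE) {
  dt <- 1 / spec$frame_rate
  n_max <- as.integer(round(max_time * dt^-1))
  state <- agent_state(scenario$start[1], scenario$start[2], start_phi,
                       speed = spec$forward_speed)
  ob <- scenario$obstacles
  t <- x <- y <- phi <- numeric(n_max + 1)
  x[1] <- state$x; y[1] <- state$y; phi[1] <- state$phi
  outcome <- "timed_out"
  action <- nav_action("forward", "none")
  last <- 1L
  for (k in seq_len(n_max)) {
    if ((k - 1L) %% spec$decision_interval == 0L) {
      obs <- if (observe) encode_observation(state, scenario) else NULL
      action <- policy(obs, state, scenario)
      if (!inherits(action, "nav_action")) stop("policy returned a malformed action")
    }
    state <- env_step(state, action, spec, dt)
    last <- k + 1L
    t[last] <- k * dt; x[last] <- state$x; y[last] <- state$y
    phi[last] <- state$phi
    if (nrow(ob) &&
        any(sqrt((ob$x - state$x)^2 + (ob$y - state$y)^2) <
            ob$radius + agent_radius)) {
      outcome <- "hit_obstacle"; break
    }
    if (sqrt((scenario$target[1] - state$x)^2 +
             (scenario$target[2] - state$y)^2) <
        scenario$target_radius + agent_radius) {
      outcome <- "reached_target"; break
    }
  }
  idx <- seq_len(last)
  traj <- nav_trajectory(data.frame(t = t[idx], x = x[idx], y = y[idx],
                                    phi = phi[idx]),
                         dt = dt, outcome = outcome,
                         scenario_id = scenario$config_id)
  structure(list(trajectory = traj,
                 reward = if (outcome == "reached_target") 1 else -1,
                 outcome = outcome),
            class = "episode_result")
}

#' Scripted steering policy driven by the heading dynamics
#'
#' Discretizes the continuous heading dynamics into the game's action
#' space: at each decision the policy evaluates the model's angular
#' acceleration from the full state, integrates an internal desired turning
#' rate, and emits `rotate = left/right/none` by the thresholded sign of
#' the gap between desired and actual turning rate. `move` is forward
#' except while that gap exceeds `stop_threshold`: then the policy
#' releases forward motion and rotates in place, the stop-and-turn
#' maneuver the game's controls afford when the required heading change
#' outruns the capped turning rate. Optional Gaussian noise on the desired
#' turning rate emulates the granularity of human keyboard control.
#'
#' @param params A [dpmp_params()].
#' @param threshold Dead-band (rad/s): no rotation is commanded while the
#'   desired turning rate is within this margin of the actual rate.
#' @param decision_dt Time step used to integrate the desired rate (s);
#'   should equal `decision_interval / frame_rate`.
#' @param noise_sd Standard deviation of Gaussian noise added to the
#'   desired turning rate at each decision (rad/s); 0 for deterministic.
#' @param rate_cap Clamp on the desired turning rate (rad/s). The default
#'   is twice the game's rotation-speed cap: the margin beyond the cap is
#'   what triggers stop-and-turn when the dynamics demand more turning
#'   than forward motion allows, while still bounding integrator windup.
#' @param stop_threshold Rate gap (rad/s) above which the policy stops
#'   forward motion to rotate in place; `Inf` disables stopping.
#' @return A policy function for [run_episode()]. The policy is stateful
#'   (it carries its desired turning rate between decisions).
#' @export
scripted_dpmp_policy <- function(params, threshold = 0.05,
                                 decision_dt = 0.1, noise_sd = 0,
                                 rate_cap = 2 * 25 * pi / 180,
                                 stop_threshold = 0.25) {
  desired <- 0
  function(observation, state, scenario) {
    view <- egocentric_view(state, scenario$target, scenario$obstacles)
    acc <- heading_acceleration(state$phi, state$phi_dot, view, params)
    desired <<- desired + acc * decision_dt
    if (noise_sd > 0) desired <<- desired + rnorm(1, 0, noise_sd)
    desired <<- max(min(desired, rate_cap), -rate_cap)
    gap <- desired - state$phi_dot
    rot <- if (gap > threshold) "left"
    else if (gap < -threshold) "right"
    else "none"
    nav_action(move = if (abs(gap) > stop_threshold) "none" else "forward",
               rotate = rot)
  }
}

#' Start/target placement for curriculum phases
#'
#' Early-phase training places agent and target uniformly at random inside
#' the field; late-phase training pins them to the far sides (start x = -16,
#' target x = 16) with uniform random y.
#'
#' @param phase `"early"` or `"late"`.
#' @param field A [field_spec()].
#' @param seed Optional integer seed; placement is deterministic given it.
#' @param margin Wall margin (m) for random coordinates.
#' @return A list with `start` and `target` (length-2 points).
#' @export
curriculum_placement <- function(phase = c("early", "late"),
                                 field = field_spec(), seed = NULL,
                                 margin = 4) {
  phase <- match.arg(phase)
  h <- field$half_extent - margin
  with_seed(seed, {
    if (phase == "early") {
      list(start = runif(2, -h, h), target = runif(2, -h, h))
    } else {
      list(start = c(-16, runif(1, -h, h)), target = c(16, runif(1, -h, h)))
    }
  })
}

#' Steppable environment interface
#'
#' Wraps the navigation game in a `reset()` / `step(action)` interface
#' returning `(observation, reward, terminated, truncated, info)`, so
#' standard RL toolkits can drive it.
#'
#' @param scenario A [scenario()].
#' @param spec A [kinematics_spec()].
#' @param max_time Episode cap (s).
#' @param start_phi Initial heading (rad).
#' @param agent_radius Agent body radius (m).
#' @return An environment object (a list of closures `reset`, `step`,
#'   `state`).
#' @export
nav_env <- function(scenario, spec = kinematics_spec(), max_time = 30,
                    start_phi = pi / 2, agent_radius = 0.25) {
  state <- NULL; frame <- 0L
  n_max <- as.integer(round(max_time * spec$frame_rate))
  reset <- function() {
    state <<- agent_state(scenario$start[1], scenario$start[2], start_phi,
                          speed = spec$forward_speed)
    frame <<- 0L
    encode_observation(state, scenario)
  }
  step <- function(action) {
    if (is.null(state)) stop("call reset() before step()")
    state <<- env_step(state, action, spec)
    frame <<- frame + 1L
    ob <- scenario$obstacles
    hit <- nrow(ob) > 0 &&
      any(sqrt((ob$x - state$x)^2 + (ob$y - state$y)^2) <
            ob$radius + agent_radius)
    captured <- sqrt((scenario$target[1] - state$x)^2 +
                       (scenario$target[2] - state$y)^2) <
      scenario$target_radius + agent_radius
    terminated <- hit || captured
    truncated <- !terminated && frame >= n_max
    reward <- if (captured) 1 else if (hit || truncated) -1 else 0
    list(observation = encode_observation(state, scenario),
         reward = reward, terminated = terminated, truncated = truncated,
         info = list(frame = frame, state = state))
  }
  structure(list(reset = reset, step = step,
                 state = function() state),
            class = "nav_env")
}
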