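test_that("raycasts classify the nearest object per ray", {
  # wall-less empty field: every ray reports nothing
  sc_empty <- scenario("e", obstacles(), c(5, -16), c(0, 16),
                       field = field_spec(wall_present = FALSE))
  st <- agent_state(0, 0, -pi / 2)  # facing away from the target
  rb <- cast_rays(st, sc_empty)
  expect_length(rb, 44)
  m <- matrix(rb, ncol = 4, byrow = TRUE)
  expect_equal(colSums(m), c(0, 0, 0, 11), ignore_attr = TRUE)

  # obstacle centered on the forward ray
  sc_ob <- scenario("o", obstacles(0, -5), c(5, -16), c(0, 16),
                    field = field_spec(wall_present = FALSE))
  rb2 <- matrix(cast_rays(st, sc_ob), ncol = 4, byrow = TRUE)
  expect_equal(rb2[6, ], c(0, 1, 0, 0), ignore_attr = TRUE)  # center ray

  # walls fire the "other" class when present
  sc_wall <- scenario("w", obstacles(), c(5, -16), c(0, 16))
  rb3 <- matrix(cast_rays(agent_state(0, 0, 0), sc_wall), ncol = 4,
                byrow = TRUE)
  expect_true(all(rb3[, 3] == 1 | rb3[, 1] == 1))
})

test_that("ray classification agrees with a fine-marching oracle", {
  set.seed(41)
  for (rep in 1:5) {
    ob <- obstacles(runif(6, -12, 12), runif(6, -12, 12), 0.25)
    sc <- scenario(paste0("r", rep), ob, c(5, -16), c(0, 16))
    st <- agent_state(runif(1, -8, 8), runif(1, -8, 8),
                      runif(1, -pi, pi))
    maxlen <- 2 * sqrt(2) * 20
    got <- matrix(cast_rays(st, sc), ncol = 4, byrow = TRUE)
    angs <- st$phi + routenav:::ray_angles()
    for (i in 1:11) {
      want <- ray_march_class(st$x, st$y, angs[i], sc, maxlen)
      expect_identical(routenav:::ray_classes[which(got[i, ] == 1)], want)
    }
  }
})

test_that("observations concatenate rays with target heading and distance", {
  sc <- scenario("obs", obstacles(), c(5, -16), c(0, 16))
  obs <- encode_observation(agent_state(0, 0, pi / 2), sc)
  expect_length(obs, 46)
  expect_equal(unname(obs["target_heading"]), 0)
  expect_equal(unname(obs["target_distance"]), 16)
  # one-hot blocks each sum to exactly 1
  m <- matrix(obs[1:44], ncol = 4, byrow = TRUE)
  expect_equal(rowSums(m), rep(1, 11), ignore_attr = TRUE)
})

test_that("actions are two one-hot groups of total dimension 5", {
  a <- nav_action("forward", "left")
  enc <- encode_action(a)
  expect_length(enc, 5)
  expect_equal(sum(enc[1:2]), 1)
  expect_equal(sum(enc[3:5]), 1)
  expect_error(nav_action("sideways"), "arg")
})

test_that("one kinematic frame follows the capped turning rules", {
  spec <- kinematics_spec()
  st <- agent_state(0, 0, pi / 2, phi_dot = 0, speed = 10)
  # one frame of left rotation accelerates the rate by 62.5 deg/s^2 * 0.02 s
  st1 <- env_step(st, nav_action("none", "left"), spec)
  expect_equal(st1$phi_dot, 62.5 * 0.02 * pi / 180, tolerance = 1e-12)
  # one forward frame advances 0.2 m along the heading
  st2 <- env_step(st, nav_action("forward", "none"), spec)
  expect_equal(st2$y, 0.2, tolerance = 1e-12)
  expect_equal(st2$x, 0, tolerance = 1e-12)
  # idle action leaves the state unchanged
  st3 <- env_step(st, nav_action("none", "none"), spec)
  expect_equal(st3$x, st$x)
  expect_equal(st3$phi, st$phi)
  expect_equal(st3$phi_dot, 0)
  # rate cap is never exceeded
  stc <- st
  for (k in 1:100) stc <- env_step(stc, nav_action("none", "left"), spec)
  expect_lte(stc$phi_dot, 25 * pi / 180 + 1e-12)
})

test_that("episodes terminate by capture, collision or 1500-frame timeout", {
  sc_free <- scenario("free", obstacles(), c(0, -16), c(0, 16))
  pol_fwd <- function(obs, state, scenario) nav_action("forward", "none")
  ep <- run_episode(pol_fwd, sc_free, start_phi = pi / 2, observe = FALSE)
  expect_identical(ep$outcome, "reached_target")
  expect_identical(ep$reward, 1)

  pol_idle <- function(obs, state, scenario) nav_action("none", "none")
  ep2 <- run_episode(pol_idle, sc_free, start_phi = pi / 2, observe = FALSE)
  expect_identical(ep2$outcome, "timed_out")
  expect_identical(ep2$reward, -1)
  expect_identical(nrow(ep2$trajectory), 1501L)  # 30 s x 50 Hz + start

  sc_block <- scenario("blk", obstacles(0, 0), c(0, -16), c(0, 16))
  ep3 <- run_episode(pol_fwd, sc_block, start_phi = pi / 2, observe = FALSE)
  expect_identical(ep3$outcome, "hit_obstacle")
  expect_identical(ep3$reward, -1)

  # turning-rate cap holds at every frame of a real episode
  pol <- scripted_dpmp_policy(dpmp_params())
  ep4 <- run_episode(pol, sc_free, start_phi = pi / 2 + 0.5, observe = FALSE)
  dphi <- routenav:::wrap_angle(diff(ep4$trajectory$phi))
  expect_lte(max(abs(dphi)) / 0.02, 25 * pi / 180 + 1e-9)
})

test_that("the scripted policy steers by the sign of the dynamics", {
  sc <- scenario("pol", obstacles(), c(0, -16), c(0, 16))
  # goal dead ahead
  pol <- scripted_dpmp_policy(dpmp_params())
  a <- pol(NULL, agent_state(0, 0, pi / 2, speed = 10), sc)
  expect_identical(a$rotate, "none")
  expect_identical(a$move, "forward")
  # goal far left of heading -> rotate left
  pol2 <- scripted_dpmp_policy(dpmp_params())
  a2 <- pol2(NULL, agent_state(0, 0, pi / 2 - 1.2, speed = 10), sc)
  expect_identical(a2$rotate, "left")
  # goal far right -> rotate right
  pol3 <- scripted_dpmp_policy(dpmp_params())
  a3 <- pol3(NULL, agent_state(0, 0, pi / 2 + 1.2, speed = 10), sc)
  expect_identical(a3$rotate, "right")
})

test_that("mirrored scenarios yield mirrored action sequences", {
  ob <- obstacles(c(1.5, -2.5), c(-6, 2), 0.25)
  sc <- scenario("m", ob, c(5, -16), c(-12, 16))
  scm <- scenario("mm", obstacles(-ob$x, ob$y, 0.25), c(-5, -16), c(12, 16))
  phi0 <- atan2(32, -17)
  flip <- c(left = "right", none = "none", right = "left")
  record <- function(scen, phi) {
    acts <- character(0)
    pol <- scripted_dpmp_policy(dpmp_params())
    wrapped <- function(obs, state, scenario) {
      a <- pol(obs, state, scenario)
      acts[[length(acts) + 1]] <<- a$rotate
      a
    }
    run_episode(wrapped, scen, max_time = 10, start_phi = phi,
                observe = FALSE)
    acts
  }
  a1 <- record(sc, phi0)
  a2 <- record(scm, pi - phi0)
  expect_identical(unname(flip[a1]), a2)
})

test_that("curriculum placement pins late-phase x coordinates to the far sides", {
  p_late <- curriculum_placement("late", seed = 3)
  expect_identical(p_late$start[1], -16)
  expect_identical(p_late$target[1], 16)
  expect_identical(curriculum_placement("early", seed = 5),
                   curriculum_placement("early", seed = 5))
  expect_false(identical(curriculum_placement("early", seed = 5),
                         curriculum_placement("early", seed = 6)))
})

test_that("the steppable environment honours the reset/step contract", {
  sc <- scenario("env", obstacles(), c(0, -16), c(0, 16))
  env <- nav_env(sc, start_phi = pi / 2)
  obs <- env$reset()
  expect_length(obs, 46)
  res <- env$step(nav_action("forward", "none"))
  expect_named(res, c("observation", "reward", "terminated", "truncated",
                      "info"))
  expect_identical(res$reward, 0)
  # drive straight until capture
  for (k in 1:2000) {
    res <- env$step(nav_action("forward", "none"))
    if (res$terminated) break
  }
  expect_true(res$terminated)
  expect_identical(res$reward, 1)
})
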