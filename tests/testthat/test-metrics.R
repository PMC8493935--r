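test_that("binned distance is the mean absolute x difference", {
  a <- binned_from_x(rep(0, 160))
  expect_identical(trajectory_distance(a, a), 0)
  b <- binned_from_x(rep(0.5, 160))
  expect_equal(trajectory_distance(a, b), 0.5)
  # linear ramp from 0 to 2 across the grid: mean is 1 on bin centers
  ramp <- binned_from_x(seq(0, 2, length.out = 160))
  expect_equal(trajectory_distance(a, ramp), mean(seq(0, 2, length.out = 160)))
  expect_error(trajectory_distance(a, binned_from_x(rep(0, 80))),
               "different grids")
})

test_that("binned distance is a pseudometric", {
  set.seed(7)
  for (k in 1:20) {
    x <- binned_from_x(rnorm(160)); y <- binned_from_x(rnorm(160))
    z <- binned_from_x(rnorm(160))
    expect_gte(trajectory_distance(x, y), 0)
    expect_equal(trajectory_distance(x, y), trajectory_distance(y, x))
    expect_lte(trajectory_distance(x, z),
               trajectory_distance(x, y) + trajectory_distance(y, z) + 1e-12)
  }
})

test_that("group means average per bin", {
  g <- list(binned_from_x(rep(0, 160)), binned_from_x(rep(1, 160)),
            binned_from_x(rep(2, 160)))
  expect_true(all(group_mean(g)$x == 1))
  mir <- list(binned_from_x(seq(-1, 1, length.out = 160)),
              binned_from_x(-seq(-1, 1, length.out = 160)))
  expect_true(all(abs(group_mean(mir)$x) < 1e-15))
  one <- list(binned_from_x(rnorm(160)))
  expect_identical(group_mean(one)$x, one[[1]]$x)
  expect_error(group_mean(list()), "empty")
})

test_that("confidence bands use linear-interpolation percentiles", {
  # 101 trials with values 0..100 in every bin
  g <- lapply(0:100, function(v) binned_from_x(rep(v, 160)))
  band <- ci_band(g, level = 95)
  expect_true(all(band$lower == 2.5))
  expect_true(all(band$upper == 97.5))
  # degenerate group: lower = upper = common value
  gid <- lapply(1:5, function(i) binned_from_x(rep(3, 160)))
  bid <- ci_band(gid)
  expect_true(all(bid$lower == 3 & bid$upper == 3))
  # widening the level cannot narrow the band
  b90 <- ci_band(g, level = 90); b99 <- ci_band(g, level = 99)
  expect_true(all(b99$lower <= b90$lower))
  expect_true(all(b99$upper >= b90$upper))
  expect_error(ci_band(g[1]), "at least 2")
})

test_that("containment is the fraction of bins inside the band", {
  set.seed(13)
  g <- lapply(1:40, function(i)
    binned_from_x(sin(seq(0, 3, length.out = 160)) + rnorm(160, sd = 0.3)))
  band <- ci_band(g)
  expect_identical(ci_containment(group_mean(g), band), 1)
  # per-bin medians always sit inside the 2.5-97.5 span
  xs <- t(vapply(g, `[[`, numeric(160), "x"))
  med <- binned_from_x(apply(xs, 2, median))
  expect_identical(ci_containment(med, band), 1)
  # far-displaced reference is never contained
  expect_identical(ci_containment(binned_from_x(rep(100, 160)), band), 0)
  # constructed half-in/half-out split
  ref <- group_mean(g)
  ref$x[81:160] <- 100
  expect_equal(ci_containment(ref, band), 0.5)
})

test_that("route signatures record the passing side per obstacle", {
  sc <- scenario("sig", obstacles(1, 0), c(0, -16), c(0, 16))
  path <- line_trajectory(0, -16, 0, 16, n = 401)
  sig <- route_signature(path, sc)
  expect_identical(sig$side, "right")
  expect_equal(sig$min_distance, 1, tolerance = 1e-3)

  scm <- scenario("sigm", obstacles(-1, 0), c(0, -16), c(0, 16))
  mir <- path; mir$x <- -mir$x
  expect_identical(route_signature(mir, scm)$side, "left")

  # S-shaped weave: the first obstacle ends up on the agent's left, the
  # second on its right (closest approach at the swing extremes)
  tt <- seq(0, 1, length.out = 801)
  weave <- nav_trajectory(data.frame(
    t = tt, x = -2 * sin(2 * pi * tt), y = -16 + 32 * tt,
    phi = rep(pi / 2, 801)))
  sc2 <- scenario("s2", obstacles(c(-3.5, 3.5), c(-8, 8)), c(0, -16), c(0, 16))
  sig2 <- route_signature(weave, sc2)
  expect_identical(sig2$side, c("left", "right"))

  # a colliding path has no defined side
  sc3 <- scenario("s3", obstacles(0, 0), c(0, -16), c(0, 16))
  expect_error(route_signature(path <- line_trajectory(0, -16, 0, 16), sc3),
               "enters obstacle")
})

test_that("preferred routes are signature groups above the share threshold", {
  sc <- scenario("pr", obstacles(1, 0), c(0, -16), c(0, 16))
  left_path <- line_trajectory(2.5, -16, 2.5, 16)   # passes right of path? no:
  right_path <- line_trajectory(-0.5, -16, -0.5, 16)
  sig_a <- route_signature(right_path, sc)   # obstacle to the right
  sig_b <- route_signature(left_path, sc)    # obstacle to the left
  # all identical: one route with full share
  p1 <- preferred_routes(rep(list(sig_a), 12))
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$share, 1)
  # 9 vs 1: both survive at the 10% boundary
  p2 <- preferred_routes(c(rep(list(sig_a), 9), list(sig_b)))
  expect_identical(nrow(p2), 2L)
  expect_equal(p2$share, c(0.9, 0.1))
  # 19 vs 1: the 5% route drops out
  p3 <- preferred_routes(c(rep(list(sig_a), 19), list(sig_b)))
  expect_identical(nrow(p3), 1L)
  # obstacles beyond the relevance radius never split routes
  far <- scenario("far", obstacles(c(1, 14), c(0, 0)), c(0, -16), c(0, 16))
  s1 <- route_signature(line_trajectory(-0.5, -16, -0.5, 16), far)
  expect_identical(routenav:::signature_key(s1, relevance_radius = 3), "1:r")
})

test_that("distance aggregation pairs trials by scenario with exclusions", {
  mk <- function(x, id) binned_from_x(rep(x, 160), id)
  binned <- list(h1 = mk(0, "h1"), h2 = mk(1, "h2"),
                 d1 = mk(2, "d1"), d2 = mk(3, "d2"))
  labels <- data.frame(
    trial_id = c("h1", "h2", "d1", "d2"),
    agent_id = c("hA", "hB", "dA", "dB"),
    group = c("human", "human", "drl", "drl"),
    scenario_id = "s1", route_type = "middle")
  res <- aggregate_distances(binned, labels)
  bg <- res$records[res$records$group_pairing == "between_group", ]
  expect_identical(nrow(bg), 4L)  # 2 humans x 2 drl
  wg <- res$records[res$records$group_pairing == "within_group", ]
  expect_identical(nrow(wg), 2L)
  # identical trajectories across groups give zero distance
  res0 <- aggregate_distances(list(a = mk(0, "a"), b = mk(0, "b")),
                              data.frame(trial_id = c("a", "b"),
                                         agent_id = c("x", "y"),
                                         group = c("g1", "g2"),
                                         scenario_id = "s", route_type = "m"))
  expect_true(all(res0$records$distance == 0))
  # a lone participant has no admissible within-group pair: flagged missing
  solo <- aggregate_distances(
    list(a = mk(0, "a"), b = mk(1, "b")),
    data.frame(trial_id = c("a", "b"), agent_id = "same",
               group = "human", scenario_id = "s", route_type = "m"))
  expect_identical(nrow(solo$records), 0L)
  expect_true(all(solo$aggregates$missing[
    solo$aggregates$comparison == "within_group"]))
})
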