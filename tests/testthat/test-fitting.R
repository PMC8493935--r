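test_that("DTW satisfies identity, symmetry and the tiny-case oracle", {
  a <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_identical(dtw_distance(a, a), 0)
  b <- cbind(c(0, 2, 3), c(1, 0, 0))
  expect_identical(dtw_distance(a, b), dtw_distance(b, a))
  expect_identical(dtw_distance(c(0, 0, 0), c(0, 0, 1)), 1)
  expect_error(dtw_distance(numeric(0), c(1)), "empty")
})

test_that("DTW matches brute-force path enumeration on short sequences", {
  set.seed(11)
  for (k in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    d <- sample(1:2, 1)
    a <- matrix(rnorm(n * d), ncol = d)
    b <- matrix(rnorm(m * d), ncol = d)
    expect_equal(dtw_distance(a, b), dtw_bruteforce(a, b), tolerance = 1e-12)
  }
})

test_that("differential evolution minimizes standard test functions", {
  sphere <- function(x) sum((x - c(1, -2))^2)
  res <- diff_evolution(sphere, lower = c(-5, -5), upper = c(5, 5),
                        seed = 3, max_iter = 200, tol = 1e-10)
  expect_lt(res$value, 1e-6)
  expect_equal(res$par, c(1, -2), tolerance = 1e-2)
  # deterministic under the same seed
  res2 <- diff_evolution(sphere, lower = c(-5, -5), upper = c(5, 5),
                         seed = 3, max_iter = 200, tol = 1e-10)
  expect_identical(res$par, res2$par)
  expect_identical(res$n_eval, res2$n_eval)
  # collapsed bounds return the single admissible point
  res3 <- diff_evolution(sphere, lower = c(0, 0), upper = c(0, 0), seed = 1)
  expect_identical(res3$par, c(0, 0))
  expect_identical(res3$value, 5)
})

test_that("fitting recovers the generating parameters of a clean simulation", {
  sc <- fit_scenario()
  phi0 <- atan2(32, -17)
  p_true <- c(beta = 3.25, gamma = 30, epsilon = 600)
  truth <- dpmp_simulate(sc, dpmp_params(p_true[1], p_true[2], p_true[3]),
                         start_phi = phi0, speed = 10)
  fit <- fit_dpmp(truth, sc, start_phi = phi0, speed = 10, seed = 2,
                  control = list(pop_size = 30, max_iter = 60))
  expect_s3_class(fit, "dpmp_fit")
  expect_lt(max(abs(coef(fit) - p_true) / p_true), 0.10)
  expect_lt(fit$dtw_error, 1)
  # same seed, same answer
  fit2 <- fit_dpmp(truth, sc, start_phi = phi0, speed = 10, seed = 2,
                   control = list(pop_size = 30, max_iter = 60))
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$dtw_error, fit2$dtw_error)
})

test_that("the objective at the truth undercuts perturbed parameter sets", {
  sc <- fit_scenario()
  phi0 <- atan2(32, -17)
  p_true <- dpmp_params(3.25, 30, 600)
  truth <- dpmp_simulate(sc, p_true, start_phi = phi0, speed = 10)
  obj <- function(b, g, e) {
    sim <- dpmp_simulate(sc, dpmp_params(b, g, e), start_phi = phi0,
                         speed = 10, t_max = max(duration(truth), 1))
    dtw_distance(cbind(truth$x, truth$y), cbind(sim$x, sim$y))
  }
  at_truth <- obj(3.25, 30, 600)
  expect_lt(at_truth, 1e-9)
  for (f in c(0.5, 0.8, 1.25, 2))
    expect_gt(obj(3.25 * f, 30, 600) + obj(3.25, 30 * f, 600) +
                obj(3.25, 30, 600 * f), at_truth)
})

test_that("degenerate fit inputs behave as documented", {
  sc <- fit_scenario()
  phi0 <- atan2(32, -17)
  truth <- dpmp_simulate(sc, dpmp_params(3.25, 30, 600), start_phi = phi0,
                         speed = 10)
  pt <- list(lower = c(beta = 2, gamma = 20, epsilon = 500),
             upper = c(beta = 2, gamma = 20, epsilon = 500))
  fit <- fit_dpmp(truth, sc, bounds = pt, start_phi = phi0, speed = 10,
                  seed = 1, control = list(pop_size = 6, max_iter = 2))
  expect_identical(unname(coef(fit)), c(2, 20, 500))
  expect_gt(fit$dtw_error, 0)
})

test_that("characteristic parameters average an agent's fits", {
  sc <- fit_scenario()
  phi0 <- atan2(32, -17)
  truth <- dpmp_simulate(sc, dpmp_params(3.25, 30, 600), start_phi = phi0,
                         speed = 10)
  mk_fit <- function(b, g, e) {
    f <- fit_dpmp(truth, sc,
                  bounds = list(lower = c(beta = b, gamma = g, epsilon = e),
                                upper = c(beta = b, gamma = g, epsilon = e)),
                  start_phi = phi0, speed = 10, seed = 1,
                  control = list(pop_size = 6, max_iter = 1))
    f
  }
  f1 <- mk_fit(1, 10, 100); f2 <- mk_fit(3, 30, 300)
  cp <- characteristic_params(list(f1, f2), "agentX")
  expect_equal(cp$beta, 2)
  expect_equal(cp$gamma, 20)
  expect_equal(cp$epsilon, 200)
  expect_identical(cp$n_fits, 2L)
  cp1 <- characteristic_params(list(f1), "solo")
  expect_equal(unname(coef(f1)), c(cp1$beta, cp1$gamma, cp1$epsilon))
  expect_error(characteristic_params(list()), "no fits")

  # one deterministic simulation per scenario, mirror-consistent
  scen_list <- list(a = fit_scenario(), b = fit_scenario())
  sims <- simulate_characteristic(cp, scen_list, start_phi = phi0, speed = 10)
  expect_length(sims, 2)
  expect_identical(sims[[1]]$x, sims[[2]]$x)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  sc <- fit_scenario()
  phi0 <- atan2(32, -17)
  truth <- dpmp_simulate(sc, dpmp_params(3.25, 30, 600), start_phi = phi0,
                         speed = 10)
  fit <- fit_dpmp(truth, sc, start_phi = phi0, speed = 10, seed = 4,
                  control = list(pop_size = 15, max_iter = 15))
  expect_named(coef(fit), c("beta", "gamma", "epsilon"))
  pred <- predict(fit)
  expect_s3_class(pred, "nav_trajectory")
  res <- residuals(fit, n = 50)
  expect_identical(nrow(res), 50L)
  expect_lt(max(abs(res$dx)), 1)
  s <- summary(fit)
  expect_s3_class(s, "summary.dpmp_fit")
  expect_output(print(s), "DTW error")
  sims <- simulate(fit, nsim = 2)
  expect_length(sims, 2)
})

test_that("recovery degrades gracefully with observation noise", {
  sc <- fit_scenario()
  grid <- data.frame(beta = 3.25, gamma = 30, epsilon = 600)
  ctl <- list(pop_size = 20, max_iter = 25)
  clean <- recovery_study(grid, sc, noise_sd = 0, seed = 9, control = ctl,
                          start_phi = atan2(32, -17))
  noisy <- recovery_study(grid, sc, noise_sd = 0.25, seed = 9, control = ctl,
                          start_phi = atan2(32, -17))
  expect_lt(clean$dtw_error, noisy$dtw_error)
  expect_identical(nrow(recovery_study(data.frame(beta = numeric(),
                                                  gamma = numeric(),
                                                  epsilon = numeric()),
                                       sc)), 0L)
})
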