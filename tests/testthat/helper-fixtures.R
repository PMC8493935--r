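# Shared fixtures and independent oracles, built in code at test time.

# A trajectory running straight from (x0, y0) to (x1, y1) at constant speed.
line_trajectory <- function(x0, y0, x1, y1, n = 201, total_time = 4,
                            outcome = "reached_target") {
  tt <- seq(0, total_time, length.out = n)
  frac <- tt / total_time
  nav_trajectory(data.frame(t = tt,
                            x = x0 + frac * (x1 - x0),
                            y = y0 + frac * (y1 - y0),
                            phi = rep(atan2(y1 - y0, x1 - x0), n)),
                 dt = tt[2] - tt[1], outcome = outcome, scenario_id = "line")
}

# A binned trajectory with the given x-values on the standard grid.
binned_from_x <- function(x, id = "b") {
  structure(list(y = -16 + (seq_along(x) - 0.5) * (32 / length(x)),
                 x = x, source_id = id),
            class = "binned_trajectory")
}

# Brute-force DTW oracle: enumerate every admissible warping path
# recursively and take the minimum accumulated Euclidean cost. Exponential;
# only for tiny sequences.
dtw_bruteforce <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  n <- nrow(a); m <- nrow(b)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(n, m)
}

# Ray-march oracle: walk a ray in small steps and report the first object
# class encountered ("nothing" if none within max_len).
ray_march_class <- function(x, y, ang, scenario, max_len, step = 0.01) {
  ts <- seq(step, max_len, by = step)
  px <- x + ts * cos(ang); py <- y + ts * sin(ang)
  ob <- scenario$obstacles
  h <- scenario$field$half_extent
  hit_t <- Inf; hit_class <- "nothing"
  if (nrow(ob)) {
    for (j in seq_len(nrow(ob))) {
      inside <- which((px - ob$x[j])^2 + (py - ob$y[j])^2 <= ob$radius[j]^2)
      if (length(inside) && ts[inside[1]] < hit_t) {
        hit_t <- ts[inside[1]]; hit_class <- "obstacle"
      }
    }
  }
  tin <- which((px - scenario$target[1])^2 + (py - scenario$target[2])^2 <=
                 scenario$target_radius^2)
  if (length(tin) && ts[tin[1]] < hit_t) {
    hit_t <- ts[tin[1]]; hit_class <- "target"
  }
  if (scenario$field$wall_present) {
    win <- which(abs(px) >= h | abs(py) >= h)
    if (length(win) && ts[win[1]] < hit_t) {
      hit_t <- ts[win[1]]; hit_class <- "other"
    }
  }
  hit_class
}

# Reference scenario with obstacles flanking the far-side route; used by
# fitting tests so all three parameters are identifiable.
fit_scenario <- function() {
  scenario("fitsc", obstacles(c(1.5, -2.5, 0.5), c(-6, 2, 8), 0.25),
           start = c(5, -16), target = c(-12, 16))
}

# Pure-R explicit Euler reference integrator (independent of the C++ core).
simulate_dpmp_R <- function(scenario, params, start_phi, speed = 10,
                            dt = 0.02, n_steps = 50) {
  st <- agent_state(scenario$start[1], scenario$start[2], start_phi,
                    phi_dot = 0, speed = speed)
  out <- matrix(NA_real_, nrow = n_steps + 1, ncol = 3)
  out[1, ] <- c(st$x, st$y, st$phi)
  for (k in seq_len(n_steps)) {
    view <- egocentric_view(st, scenario$target, scenario$obstacles)
    acc <- heading_acceleration(st$phi, st$phi_dot, view, params)
    st$phi_dot <- st$phi_dot + acc * dt
    st$phi <- routenav:::wrap_angle(st$phi + st$phi_dot * dt)
    st$x <- st$x + speed * cos(st$phi) * dt
    st$y <- st$y + speed * sin(st$phi) * dt
    out[k + 1, ] <- c(st$x, st$y, st$phi)
  }
  out
}
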