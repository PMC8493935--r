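#' Resample a trajectory to a fixed number of points
#'
#' Linear interpolation of x, y and heading at `n` equally spaced time
#' points spanning the recorded interval. Heading is interpolated on the
#' unwrapped angle and re-wrapped, so interpolation never takes the long
#' way around.
#'
#' @param traj A `nav_trajectory` with at least 2 samples.
#' @param n Output length (default 1000).
#' @return A `nav_trajectory` with exactly `n` samples.
#' @export
resample_to_n <- function(traj, n = 1000) {
  if (nrow(traj) < 2) stop("cannot resample a trajectory with fewer than 2 samples")
  tt <- seq(traj$t[1], traj$t[nrow(traj)], length.out = n)
  phi_unwrapped <- traj$phi[1] + c(0, cumsum(wrap_angle(diff(traj$phi))))
  out <- data.frame(
    t = tt,
    x = approx(traj$t, traj$x, xout = tt)$y,
    y = approx(traj$t, traj$y, xout = tt)$y,
    phi = wrap_angle(approx(traj$t, phi_unwrapped, xout = tt)$y))
  nav_trajectory(out, dt = tt[2] - tt[1], outcome = attr(traj, "outcome"),
                 scenario_id = attr(traj, "scenario_id"),
                 params = attr(traj, "params"))
}

#' Discard anomalous trials
#'
#' Applies the two admissibility rules: a trial is discarded if its
#' cumulative path length exceeds `length_factor` times the mean path
#' length of all trials of its scenario (computed over the full pool,
#' before any discards), or if its duration exceeds `max_duration`.
#'
#' @param trials A list of `nav_trajectory` objects.
#' @param scenario_ids Character vector assigning each trial to a scenario;
#'   defaults to each trajectory's `scenario_id` attribute.
#' @param max_duration Duration cutoff in seconds (default 20).
#' @param length_factor Path-length ratio cutoff (default 1.2).
#' @return A list with `kept` (trial list), `discarded` (trial list) and
#'   `report`, a data.frame with one row per trial (`index`, `scenario_id`,
#'   `path_length`, `duration`, `kept`, `reason`).
#' @export
filter_trials <- function(trials, scenario_ids = NULL, max_duration = 20,
                          length_factor = 1.2) {
  if (length(trials) == 0) stop("empty trial list")
  if (is.null(scenario_ids))
    scenario_ids <- vapply(trials, function(tr)
      as.character(attr(tr, "scenario_id")), "")
  stopifnot(length(scenario_ids) == length(trials))
  lens <- vapply(trials, path_length, 0)
  durs <- vapply(trials, duration, 0)
  mean_len <- ave(lens, scenario_ids, FUN = mean)
  too_long <- lens > length_factor * mean_len
  too_slow <- durs > max_duration
  reason <- rep(NA_character_, length(trials))
  reason[too_long] <- "length"
  reason[too_slow] <- "duration"
  reason[too_long & too_slow] <- "length+duration"
  kept <- !(too_long | too_slow)
  list(kept = trials[kept], discarded = trials[!kept],
       report = data.frame(index = seq_along(trials),
                           scenario_id = scenario_ids,
                           path_length = lens, duration = durs,
                           kept = kept, reason = reason))
}

#' Bin a trajectory onto the fixed y-grid
#'
#' Reduces a path to one x-value per 20 cm bin of y over [-16, 16): bins
#' are half-open intervals `[y_min + k w, y_min + (k+1) w)`; each bin's x is
#' the mean of all samples falling in it (all visits, so backtracking is
#' averaged); empty interior bins are filled by linear interpolation
#' between the nearest non-empty neighbours, and empty boundary bins by
#' nearest-value extrapolation. The default grid yields exactly 160 points.
#'
#' @param traj A `nav_trajectory`.
#' @param y_min,y_max Grid limits (m).
#' @param bin_width Bin width (m, default 0.2).
#' @param min_span Minimum fraction of the y-range the trajectory must
#'   cover (default 0.5); narrower trajectories cannot be binned
#'   meaningfully and raise an error.
#' @param source_id Identifier carried on the result.
#' @return An object of class `binned_trajectory`: a list with `y`
#'   (bin centers), `x` (binned x-values) and `source_id`.
#' @export
bin_by_y <- function(traj, y_min = -16, y_max = 16, bin_width = 0.2,
                     min_span = 0.5, source_id = attr(traj, "scenario_id")) {
  n_bins <- as.integer(round((y_max - y_min) / bin_width))
  span <- diff(range(traj$y))
  if (span < min_span * (y_max - y_min))
    stop(sprintf("trajectory spans %.1f m of the %.1f m y-range; cannot bin",
                 span, y_max - y_min))
  idx <- floor((traj$y - y_min) / bin_width) + 1
  ok <- idx >= 1 & idx <= n_bins
  xs <- tapply(traj$x[ok], factor(idx[ok], levels = seq_len(n_bins)), mean)
  x <- as.numeric(xs)
  centers <- y_min + (seq_len(n_bins) - 0.5) * bin_width
  filled <- which(!is.na(x))
  if (length(filled) == 0) stop("no samples fall inside the binning range")
  if (length(filled) < n_bins)
    x <- approx(centers[filled], x[filled], xout = centers, rule = 2)$y
  structure(list(y = centers, x = x, source_id = source_id),
            class = "binned_trajectory")
}

#' @export
print.binned_trajectory <- function(x, ...) {
  cat(sprintf("<binned_trajectory> %d bins on [%.1f, %.1f), x range [%.2f, %.2f]\n",
              length(x$x), x$y[1] - diff(x$y[1:2]) / 2,
              x$y[length(x$y)] + diff(x$y[1:2]) / 2, min(x$x), max(x$x)))
  invisible(x)
}

#' Write a wide per-scenario table of binned trajectories
#'
#' @param binned A list of `binned_trajectory` objects on a shared grid.
#' @param path CSV output path; rows are bins (first column `y_center`),
#'   one column per trial.
#' @export
write_binned_csv <- function(binned, path) {
  stopifnot(length(binned) > 0)
  nms <- vapply(seq_along(binned), function(i) {
    nm <- binned[[i]]$source_id
    if (is.null(nm) || is.na(nm)) paste0("trial", i) else as.character(nm)
  }, "")
  df <- data.frame(y_center = binned[[1]]$y)
  df[make.unique(nms)] <- lapply(binned, `[[`, "x")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
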