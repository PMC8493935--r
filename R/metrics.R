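#' Pairwise distance between binned trajectories
#'
#' The mean over bins of the absolute difference between the x-values of
#' two trajectories on the shared 20 cm y-grid. This is a pseudometric:
#' non-negative, symmetric and triangle-inequality-satisfying.
#'
#' @param a,b `binned_trajectory` objects on identical grids.
#' @return Distance in meters.
#' @export
trajectory_distance <- function(a, b) {
  if (!isTRUE(all.equal(a$y, b$y, tolerance = 0)))
    stop("binned trajectories are on different grids")
  mean(abs(a$x - b$x))
}

#' Per-bin mean of a group of binned trajectories
#'
#' @param group Non-empty list of `binned_trajectory` on a shared grid.
#' @return A `binned_trajectory` holding the per-bin arithmetic mean.
#' @export
group_mean <- function(group) {
  if (length(group) == 0) stop("empty group")
  xs <- vapply(group, `[[`, numeric(length(group[[1]]$x)), "x")
  structure(list(y = group[[1]]$y, x = rowMeans(xs), source_id = "group_mean"),
            class = "binned_trajectory")
}

#' Percentile confidence band of a group
#'
#' Per-bin empirical percentiles at `(100 - level)/2` and
#' `100 - (100 - level)/2` (the 2.5th and 97.5th for the default 95% band),
#' using the linear-interpolation percentile definition (`quantile`
#' type 7). At the default level, 5% of the group's values fall outside the
#' band in each bin.
#'
#' @param group List of at least 2 `binned_trajectory` on a shared grid.
#' @param level Band level in percent (default 95).
#' @return An object of class `ci_band`: list with `y`, `lower`, `upper`,
#'   `level`, `group_size`.
#' @export
ci_band <- function(group, level = 95) {
  if (length(group) < 2) stop("need at least 2 trajectories for a band")
  stopifnot(level > 0, level < 100)
  xs <- t(vapply(group, `[[`, numeric(length(group[[1]]$x)), "x"))
  p <- (100 - level) / 200
  structure(list(y = group[[1]]$y,
                 lower = apply(xs, 2, quantile, probs = p, type = 7,
                               names = FALSE),
                 upper = apply(xs, 2, quantile, probs = 1 - p, type = 7,
                               names = FALSE),
                 level = level, group_size = length(group)),
            class = "ci_band")
}

#' Proportion of bins where a reference lies inside a band
#'
#' @param reference A `binned_trajectory`.
#' @param band A [ci_band()] on the same grid.
#' @return Proportion in [0, 1].
#' @export
ci_containment <- function(reference, band) {
  if (!isTRUE(all.equal(reference$y, band$y, tolerance = 0)))
    stop("reference and band are on different grids")
  mean(band$lower <= reference$x & reference$x <= band$upper)
}

#' Route signature of a trajectory
#'
#' Automates route identification: for each obstacle, the side on which
#' the path passes it is the sign of the cross product between the local
#' direction of travel and the vector to the obstacle center, evaluated at
#' the point of closest approach. Positive cross product means the
#' obstacle lies to the agent's left.
#'
#' @param traj A `nav_trajectory`.
#' @param scenario The [scenario()] the trajectory belongs to.
#' @return A data.frame of class `route_signature` with one row per
#'   obstacle: `obstacle`, `side` ("left"/"right"), `min_distance` (m,
#'   closest approach of the path to the obstacle center).
#' @export
route_signature <- function(traj, scenario) {
  ob <- scenario$obstacles
  n <- nrow(ob)
  side <- character(n); min_d <- numeric(n)
  dx <- c(diff(traj$x), NA); dy <- c(diff(traj$y), NA)
  m <- nrow(traj)
  if (m >= 2) { dx[m] <- dx[m - 1]; dy[m] <- dy[m - 1] }
  for (i in seq_len(n)) {
    vx <- ob$x[i] - traj$x; vy <- ob$y[i] - traj$y
    d <- sqrt(vx^2 + vy^2)
    k <- which.min(d)
    min_d[i] <- d[k]
    if (min_d[i] < ob$radius[i])
      stop(sprintf("path enters obstacle %d (closest approach %.3f m); no side defined",
                   i, min_d[i]))
    cross <- dx[k] * vy[k] - dy[k] * vx[k]
    side[i] <- if (cross > 0) "left" else "right"
  }
  structure(data.frame(obstacle = seq_len(n), side = side,
                       min_distance = min_d),
            class = c("route_signature", "data.frame"))
}

# Canonical grouping key: sides of obstacles approached within the
# relevance radius; far-off obstacles don't split routes spuriously.
signature_key <- function(sig, relevance_radius = 3) {
  rel <- sig$min_distance <= relevance_radius
  if (!any(rel)) return("(none)")
  paste(sprintf("%d:%s", sig$obstacle[rel], substr(sig$side[rel], 1, 1)),
        collapse = ",")
}

#' Preferred routes of a trajectory population
#'
#' Groups identical route signatures (restricted to obstacles approached
#' within `relevance_radius`) and returns those containing at least
#' `threshold` of the trajectories, sorted by share descending.
#'
#' @param signatures Non-empty list of [route_signature()] results from
#'   trajectories of one scenario.
#' @param threshold Minimum share for a route to count as preferred
#'   (default 0.10).
#' @param relevance_radius Obstacles never approached closer than this (m)
#'   are dropped from signatures before grouping (default 3).
#' @return A data.frame with columns `signature`, `count`, `share`.
#' @export
preferred_routes <- function(signatures, threshold = 0.10,
                             relevance_radius = 3) {
  if (length(signatures) == 0) stop("empty signature list")
  keys <- vapply(signatures, signature_key, "",
                 relevance_radius = relevance_radius)
  tab <- sort(table(keys), decreasing = TRUE)
  share <- as.numeric(tab) / length(keys)
  keep <- share >= threshold
  data.frame(signature = names(tab)[keep], count = as.integer(tab)[keep],
             share = share[keep], row.names = NULL)
}

#' Pairwise distance records and per-participant aggregates
#'
#' Computes all admissible pairwise binned distances per scenario and
#' averages them per participant and route type. Between-group records
#' pair every trajectory of group A with every trajectory of group B
#' within a scenario; within-group records pair trajectories of the same
#' group excluding pairs produced by the same participant/agent.
#'
#' @param binned Named list of `binned_trajectory` objects.
#' @param labels A data.frame with one row per element of `binned`:
#'   columns `trial_id` (matching `names(binned)`), `agent_id`, `group`,
#'   `scenario_id`, `route_type`.
#' @return A list with `records` (one row per pair: `scenario_id`,
#'   `trial_a`, `trial_b`, `agent_a`, `agent_b`, `group_pairing`, `groups`,
#'   `route_type`, `distance`) and `aggregates` (per `agent_id` x
#'   `route_type` x `comparison` mean distance, with empty cells flagged
#'   `missing = TRUE`).
#' @export
aggregate_distances <- function(binned, labels) {
  stopifnot(length(binned) == nrow(labels),
            all(c("trial_id", "agent_id", "group", "scenario_id",
                  "route_type") %in% names(labels)),
            identical(names(binned), as.character(labels$trial_id)))
  recs <- list()
  for (sc in unique(labels$scenario_id)) {
    sel <- which(labels$scenario_id == sc)
    if (length(sel) < 2) next
    pairs <- utils::combn(sel, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      same_group <- labels$group[i] == labels$group[j]
      if (same_group && labels$agent_id[i] == labels$agent_id[j]) next
      recs[[length(recs) + 1]] <- data.frame(
        scenario_id = sc,
        trial_a = labels$trial_id[i], trial_b = labels$trial_id[j],
        agent_a = labels$agent_id[i], agent_b = labels$agent_id[j],
        group_pairing = if (same_group) "within_group" else "between_group",
        groups = paste(sort(c(labels$group[i], labels$group[j])),
                       collapse = "|"),
        route_type = labels$route_type[i],
        distance = trajectory_distance(binned[[i]], binned[[j]]))
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(scenario_id = character(), trial_a = character(),
               trial_b = character(), agent_a = character(),
               agent_b = character(), group_pairing = character(),
               groups = character(), route_type = character(),
               distance = numeric())

  # per-participant aggregates: a record contributes to both endpoints
  agg <- list()
  all_agents <- unique(labels[, c("agent_id", "group")])
  route_types <- unique(labels$route_type)
  for (a in seq_len(nrow(all_agents))) {
    aid <- all_agents$agent_id[a]
    for (rt in route_types) for (cmp in c("within_group", "between_group")) {
      hit <- records$route_type == rt & records$group_pairing == cmp &
        (records$agent_a == aid | records$agent_b == aid)
      agg[[length(agg) + 1]] <- data.frame(
        agent_id = aid, group = all_agents$group[a], route_type = rt,
        comparison = cmp,
        n_pairs = sum(hit),
        mean_distance = if (any(hit)) mean(records$distance[hit]) else NA_real_,
        missing = !any(hit))
    }
  }
  list(records = records, aggregates = do.call(rbind, agg))
}

#' Within-group mean distances by route type
#'
#' Convenience summary over [aggregate_distances()] output: the mean of
#' per-participant within-group mean distances, per group and route type.
#'
#' @param aggregates The `aggregates` element of [aggregate_distances()].
#' @return A data.frame `group` x `route_type` with `mean_distance`.
#' @export
within_group_summary <- function(aggregates) {
  w <- aggregates[aggregates$comparison == "within_group" & !aggregates$missing, ]
  out <- aggregate(mean_distance ~ group + route_type, data = w, FUN = mean)
  out[order(out$group, out$route_type), ]
}
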