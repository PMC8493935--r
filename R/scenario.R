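#' Field geometry of the navigation task
#'
#' The task takes place on a square field centered at the origin, by default
#' 40 x 40 m (half-extent 20 m), optionally surrounded by a wall. The +y axis
#' points from the start side toward the target side.
#'
#' @param half_extent Half the side length of the square field, in meters.
#' @param wall_present Whether the field boundary is a solid wall (detected
#'   by raycasts as the "other" class).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(half_extent = 20, wall_present = TRUE) {
  stopifnot(is.numeric(half_extent), length(half_extent) == 1,
            half_extent > 0)
  structure(list(half_extent = half_extent,
                 wall_present = isTRUE(wall_present)),
            class = "field_spec")
}

#' Obstacle set constructor
#'
#' Obstacles are planar discs (cylinders seen from above, 0.5 m wide by
#' default).
#'
#' @param x,y Obstacle center coordinates in meters.
#' @param radius Disc radius in meters (default 0.25).
#' @return A data.frame with columns `x`, `y`, `radius`.
#' @export
obstacles <- function(x = numeric(), y = numeric(), radius = 0.25) {
  stopifnot(length(x) == length(y), all(radius > 0))
  data.frame(x = as.numeric(x), y = as.numeric(y),
             radius = rep_len(as.numeric(radius), length(x)))
}

#' Classify the route type of a start/target pairing
#'
#' A trial whose start and target lie on the same lateral side of the field
#' is a near-side route, opposite sides give a far-side route, and a target
#' on the midline (x = 0) gives a middle route.
#'
#' @param start,target Numeric length-2 points `c(x, y)`, start below target.
#' @return One of `"near_side"`, `"middle"`, `"far_side"`.
#' @export
classify_route_type <- function(start, target) {
  stopifnot(length(start) == 2, length(target) == 2)
  if (start[2] >= target[2])
    stop("start must lie below the target (start y < target y)")
  if (target[1] == 0) return("middle")
  if (start[1] == 0)
    stop("ambiguous route type: start on the midline with an off-center target")
  if (sign(start[1]) == sign(target[1])) "near_side" else "far_side"
}

#' Construct a scenario
#'
#' A scenario is one obstacle configuration together with a start and a
#' target position. The canonical design uses starts (+-5, -16) and targets
#' (+-12, 16), (0, 16); other placements are allowed but flagged free-form
#' (their route type is `NA`).
#'
#' @param config_id Identifier of the obstacle configuration.
#' @param obstacles A data.frame as returned by [obstacles()].
#' @param start,target Numeric length-2 points in meters.
#' @param target_radius Target disc radius in meters (default 0.25).
#' @param field A [field_spec()].
#' @return An object of class `nav_scenario`.
#' @export
scenario <- function(config_id, obstacles, start, target,
                     target_radius = 0.25, field = field_spec()) {
  stopifnot(inherits(field, "field_spec"), target_radius > 0)
  h <- field$half_extent
  pts <- rbind(start, target,
               if (nrow(obstacles)) cbind(obstacles$x, obstacles$y))
  if (any(abs(pts) >= h))
    stop("start/target/obstacle coordinates must lie strictly inside the field")
  canonical_start <- list(c(5, -16), c(-5, -16))
  canonical_target <- list(c(12, 16), c(0, 16), c(-12, 16))
  is_canon <- any(vapply(canonical_start, function(p) all(p == start), TRUE)) &&
    any(vapply(canonical_target, function(p) all(p == target), TRUE))
  route_type <- if (is_canon) classify_route_type(start, target) else NA_character_
  structure(list(config_id = as.character(config_id),
                 obstacles = obstacles,
                 start = as.numeric(start), target = as.numeric(target),
                 target_radius = target_radius,
                 route_type = route_type,
                 free_form = !is_canon,
                 field = field),
            class = "nav_scenario")
}

#' @export
print.nav_scenario <- function(x, ...) {
  cat(sprintf("<nav_scenario %s> start (%g, %g) -> target (%g, %g), %d obstacle(s), route %s%s\n",
              x$config_id, x$start[1], x$start[2], x$target[1], x$target[2],
              nrow(x$obstacles),
              ifelse(is.na(x$route_type), "free-form", x$route_type),
              if (x$free_form) " [free-form]" else ""))
  invisible(x)
}

#' Enumerate the Cartesian product of configurations, starts and targets
#'
#' The full design crosses every obstacle configuration with every start and
#' every target (18 x 2 x 3 = 108 scenarios in the canonical task), in
#' deterministic (config, start, target) lexicographic order.
#'
#' @param configs Named list of obstacle data.frames ([obstacles()]).
#' @param starts,targets Lists of length-2 points.
#' @param field A [field_spec()].
#' @param target_radius Target radius passed to [scenario()].
#' @return A list of `nav_scenario` objects of length
#'   `length(configs) * length(starts) * length(targets)`.
#' @export
enumerate_scenarios <- function(configs,
                                starts = list(c(5, -16), c(-5, -16)),
                                targets = list(c(12, 16), c(0, 16), c(-12, 16)),
                                field = field_spec(), target_radius = 0.25) {
  stopifnot(length(configs) > 0, length(starts) > 0, length(targets) > 0)
  if (is.null(names(configs)))
    names(configs) <- sprintf("config%02d", seq_along(configs))
  out <- vector("list", length(configs) * length(starts) * length(targets))
  k <- 0L
  for (ci in seq_along(configs))
    for (si in seq_along(starts))
      for (ti in seq_along(targets)) {
        k <- k + 1L
        out[[k]] <- scenario(
          config_id = names(configs)[ci], obstacles = configs[[ci]],
          start = starts[[si]], target = targets[[ti]],
          target_radius = target_radius, field = field)
      }
  names(out) <- vapply(out, function(s)
    sprintf("%s_s%+g_t%+g", s$config_id, s$start[1], s$target[1]), "")
  out
}

#' Report clearance violations in a scenario
#'
#' Checks all obstacle pairs and each obstacle against the start and target
#' for edge-to-edge separation below `min_clearance`. Report-only; an empty
#' data.frame means the scenario is valid.
#'
#' @param s A `nav_scenario`.
#' @param min_clearance Minimum allowed edge-to-edge separation in meters.
#' @param agent_radius Radius of the agent body used for start/target
#'   clearance, in meters.
#' @return A data.frame with columns `what`, `i`, `j`, `separation`.
#' @export
validate_scenario <- function(s, min_clearance = 0.5, agent_radius = 0.25) {
  stopifnot(inherits(s, "nav_scenario"))
  ob <- s$obstacles
  out <- data.frame(what = character(), i = integer(), j = integer(),
                    separation = numeric())
  n <- nrow(ob)
  if (n == 0) return(out)
  add <- function(what, i, j, sep) rbind(out, data.frame(
    what = what, i = i, j = j, separation = sep))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      sep <- sqrt((ob$x[i] - ob$x[j])^2 + (ob$y[i] - ob$y[j])^2) -
        ob$radius[i] - ob$radius[j]
      if (sep < min_clearance) out <- add("obstacle_pair", i, j, sep)
    }
  }
  for (i in seq_len(n)) {
    sep_s <- sqrt((ob$x[i] - s$start[1])^2 + (ob$y[i] - s$start[2])^2) -
      ob$radius[i] - agent_radius
    if (sep_s < min_clearance) out <- add("obstacle_start", i, NA_integer_, sep_s)
    sep_t <- sqrt((ob$x[i] - s$target[1])^2 + (ob$y[i] - s$target[2])^2) -
      ob$radius[i] - s$target_radius
    if (sep_t < min_clearance) out <- add("obstacle_target", i, NA_integer_, sep_t)
  }
  out
}

#' Read and write scenario JSON
#'
#' Scenarios serialize to JSON as
#' `{config_id, obstacles: [{x, y, radius}], start: [x, y], target: [x, y],
#' target_radius}`; numeric fields round-trip bit-exactly.
#'
#' @param s A `nav_scenario`.
#' @param path File path.
#' @return `read_scenario_json()` returns a `nav_scenario`;
#'   `write_scenario_json()` returns `path` invisibly.
#' @export
write_scenario_json <- function(s, path) {
  stopifnot(inherits(s, "nav_scenario"))
  obj <- list(config_id = s$config_id,
              obstacles = s$obstacles,
              start = s$start, target = s$target,
              target_radius = s$target_radius,
              half_extent = s$field$half_extent)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ob <- if (length(obj$obstacles))
    data.frame(x = obj$obstacles$x, y = obj$obstacles$y,
               radius = obj$obstacles$radius)
  else obstacles()
  scenario(config_id = obj$config_id, obstacles = ob,
           start = unlist(obj$start), target = unlist(obj$target),
           target_radius = obj$target_radius,
           field = field_spec(half_extent = obj$half_extent))
}
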