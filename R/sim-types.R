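#' Tank geometry
#'
#' Describes the cylindrical RAS tank the school swims in: a hollow cylinder
#' with a floor, a wall, and an invisible lid that keeps fish below the water
#' surface. `wall_margin` is the keep-out distance from the physical wall;
#' fish centroids are confined to radius `radius - wall_margin`.
#'
#' Defaults describe a 150 m\eqn{^3} semi-commercial growout cylinder
#' (radius 3.45 m, depth 4 m).
#'
#' @param radius Tank inner radius in metres.
#' @param height Water-column height in metres (the lid sits at `z = height`).
#' @param wall_margin Keep-out margin from the wall in metres
#'   (`0 <= wall_margin < radius`).
#' @return An object of class `"tank_geometry"`.
#' @examples
#' tank_geometry()          # the default 150 m^3 tank
#' tank_geometry(1.5, 1.0)  # a small experimental tank
#' @export
tank_geometry <- function(radius = 3.45, height = 4.0, wall_margin = 0.15) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop_invalid("radius must be a positive scalar (got %s)", format(radius))
  if (!is.numeric(height) || length(height) != 1 || height <= 0)
    stop_invalid("height must be a positive scalar")
  if (wall_margin < 0 || wall_margin >= radius)
    stop_invalid("wall_margin must satisfy 0 <= wall_margin < radius")
  structure(list(radius = radius, height = height, wall_margin = wall_margin),
            class = "tank_geometry")
}

#' Vortex force field
#'
#' A tangential force field about the tank axis used to induce circular
#' swimming. The acceleration at a point is horizontal, tangent to the circle
#' through the point, with magnitude
#' `strength * exp(-|z - source_height| / decay_length)`, so a vortex sourced
#' at the tank floor mostly stirs the lower water column and one sourced at
#' the lid stirs the upper column. `rotation_sign = +1` is counter-clockwise
#' viewed from above, `-1` clockwise.
#'
#' @param source_height Axial position (m) of the vortex source plane.
#' @param rotation_sign `+1` (counter-clockwise from above) or `-1` (clockwise).
#' @param strength Peak tangential acceleration (m s^-2), `>= 0`.
#' @param decay_length Axial e-folding length (m) of the field, `> 0`.
#' @return An object of class `"vortex_force"`.
#' @examples
#' bottom <- vortex_force(0, +1, strength = 0.8, decay_length = 2.5)
#' top    <- vortex_force(4, -1, strength = 0.25, decay_length = 1.2)
#' @export
vortex_force <- function(source_height, rotation_sign, strength, decay_length) {
  if (!rotation_sign %in% c(-1, 1))
    stop_invalid("rotation_sign must be -1 or +1 (got %s)", format(rotation_sign))
  if (strength < 0) stop_invalid("vortex strength must be >= 0")
  if (decay_length <= 0) stop_invalid("decay_length must be > 0")
  structure(list(source_height = source_height,
                 rotation_sign = as.integer(rotation_sign),
                 strength = strength, decay_length = decay_length),
            class = "vortex_force")
}

#' Cuboid deflection barrier
#'
#' An axis-aligned cuboid (a virtual ramp) placed upstream of the camera near
#' the tank wall. Fish within `repulsion_range` of its surface are pushed away
#' along the surface normal, which keeps the school from swimming into the
#' lens; fish never enter its volume.
#'
#' @param center 3-vector (m), cuboid centre.
#' @param half_extents 3-vector (m), half side lengths; all `> 0`.
#' @param repulsion_strength Peak repulsion acceleration (m s^-2).
#' @param repulsion_range Distance (m) from a face at which repulsion starts.
#' @param geometry Optional [tank_geometry()]; when given, all eight corners
#'   are checked to lie inside the tank.
#' @return An object of class `"barrier"`.
#' @export
barrier <- function(center, half_extents, repulsion_strength = 3.0,
                    repulsion_range = 0.4, geometry = NULL) {
  center <- as.numeric(center); half_extents <- as.numeric(half_extents)
  if (length(center) != 3 || length(half_extents) != 3)
    stop_invalid("center and half_extents must be 3-vectors")
  if (any(half_extents <= 0)) stop_invalid("half_extents must be > 0 componentwise")
  if (repulsion_strength < 0 || repulsion_range <= 0)
    stop_invalid("repulsion_strength must be >= 0 and repulsion_range > 0")
  if (!is.null(geometry)) {
    corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
    pts <- sweep(corners %*% diag(half_extents), 2, center, `+`)
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    if (any(r > geometry$radius) || any(pts[, 3] < 0) ||
        any(pts[, 3] > geometry$height))
      stop_invalid("barrier cuboid extends outside the tank")
  }
  structure(list(center = center, half_extents = half_extents,
                 repulsion_strength = repulsion_strength,
                 repulsion_range = repulsion_range),
            class = "barrier")
}

#' Boids behaviour parameters
#'
#' Weights and scales for the classic Reynolds flocking rules (separation,
#' alignment, cohesion) plus kinematic limits. Each rule produces a steering
#' acceleration; each term and their sum are clamped to `max_accel`, and the
#' integrated speed is clamped to `[min_speed, max_speed]` so fish neither
#' stall nor dart.
#'
#' Defaults are tuned for market-size rainbow trout cruising in a growout
#' tank: body length about 0.35 m, cruise speeds of roughly 1-3 body lengths
#' per second, neighbour perception a couple of body lengths.
#'
#' @param perception_radius Neighbourhood radius (m) for all three rules.
#' @param separation_weight,alignment_weight,cohesion_weight Dimensionless
#'   rule weights, `>= 0`.
#' @param min_separation Distance (m) under which separation engages;
#'   must be `< perception_radius`.
#' @param max_speed,min_speed Speed clamp (m s^-1), `0 < min_speed <= max_speed`.
#' @param max_accel Acceleration clamp (m s^-2).
#' @param dt Integration time step (s).
#' @return An object of class `"boids_params"`.
#' @export
boids_params <- function(perception_radius = 0.6,
                         separation_weight = 2.0,
                         alignment_weight = 0.5,
                         cohesion_weight = 0.15,
                         min_separation = 0.25,
                         max_speed = 1.2, min_speed = 0.3,
                         max_accel = 2.5, dt = 0.05) {
  if (!(min_speed > 0 && min_speed <= max_speed))
    stop_invalid("need 0 < min_speed <= max_speed")
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (!(perception_radius > min_separation && min_separation > 0))
    stop_invalid("need perception_radius > min_separation > 0")
  if (any(c(separation_weight, alignment_weight, cohesion_weight) < 0))
    stop_invalid("rule weights must be >= 0")
  if (max_accel <= 0) stop_invalid("max_accel must be > 0")
  structure(list(perception_radius = perception_radius,
                 separation_weight = separation_weight,
                 alignment_weight = alignment_weight,
                 cohesion_weight = cohesion_weight,
                 min_separation = min_separation,
                 max_speed = max_speed, min_speed = min_speed,
                 max_accel = max_accel, dt = dt),
            class = "boids_params")
}

#' School state
#'
#' Positions and velocities of the `N` simulated fish at one instant.
#' Constructed by [init_school()] and advanced by [school_step()]; build one
#' directly only for tests or custom initialisations.
#'
#' @param positions N x 3 matrix (m).
#' @param velocities N x 3 matrix (m s^-1).
#' @param time Simulation time (s).
#' @param rng_seed Seed the state was initialised from (bookkeeping only).
#' @return An object of class `"school_state"`.
#' @export
school_state <- function(positions, velocities, time = 0, rng_seed = NA_integer_) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  if (ncol(positions) != 3 || !identical(dim(positions), dim(velocities)))
    stop_invalid("positions and velocities must be matching N x 3 matrices")
  structure(list(positions = positions, velocities = velocities,
                 time = time, rng_seed = rng_seed),
            class = "school_state")
}

#' @export
print.school_state <- function(x, ...) {
  n <- nrow(x$positions)
  sp <- row_norms(x$velocities)
  cat(sprintf("<school_state> %d fish at t = %.2f s\n", n, x$time))
  cat(sprintf("  mean speed %.3f m/s, mean depth z %.2f m\n",
              mean(sp), mean(x$positions[, 3])))
  invisible(x)
}

# TRUE per fish when its centroid is strictly inside the cuboid
inside_barrier <- function(positions, barrier) {
  if (is.null(barrier)) return(rep(FALSE, nrow(positions)))
  d <- abs(sweep(positions, 2, barrier$center, `-`))
  d[, 1] < barrier$half_extents[1] &
    d[, 2] < barrier$half_extents[2] &
    d[, 3] < barrier$half_extents[3]
}

#' Check school-state containment invariants
#'
#' Verifies that every fish centroid lies inside the allowed cylinder
#' (`x^2 + y^2 <= (radius - wall_margin)^2`, `0 <= z <= height`), that every
#' speed lies in `[min_speed, max_speed]`, and that no centroid is inside the
#' barrier cuboid.
#'
#' @param state A [school_state()].
#' @param geometry A [tank_geometry()].
#' @param params A [boids_params()].
#' @param barrier Optional [barrier()].
#' @param tol Numerical slack (m or m/s) on the comparisons.
#' @return `TRUE` if all invariants hold, otherwise `FALSE` with a
#'   `"violations"` attribute naming the failures.
#' @export
check_school_state <- function(state, geometry, params, barrier = NULL,
                               tol = 1e-9) {
  p <- state$positions
  r2 <- p[, 1]^2 + p[, 2]^2
  rmax <- geometry$radius - geometry$wall_margin
  sp <- row_norms(state$velocities)
  bad <- character()
  if (any(r2 > rmax^2 + tol)) bad <- c(bad, "outside cylinder radius")
  if (any(p[, 3] < -tol) || any(p[, 3] > geometry$height + tol))
    bad <- c(bad, "outside z range")
  if (any(sp < params$min_speed - tol) || any(sp > params$max_speed + tol))
    bad <- c(bad, "speed outside [min_speed, max_speed]")
  if (any(inside_barrier(p, barrier))) bad <- c(bad, "inside barrier")
  if (length(bad) == 0) TRUE else structure(FALSE, violations = bad)
}
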