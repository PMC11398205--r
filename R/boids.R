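#' Initialise a school of fish
#'
#' Samples `n_fish` positions uniformly in the allowed cylinder interior
#' (excluding the barrier cuboid) and velocities with tangentially biased
#' headings and speeds uniform in `[min_speed, max_speed]`. The tangential
#' bias mimics fish already circulating with the tank flow; headings get an
#' isotropic perturbation so the school is not perfectly ordered at t = 0.
#'
#' Deterministic: the same `(n_fish, geometry, params, barrier, seed)` always
#' yields a bit-identical state. The caller's RNG state is left untouched.
#'
#' @param n_fish Number of fish, `>= 1`.
#' @param geometry A [tank_geometry()].
#' @param params A [boids_params()].
#' @param seed Integer RNG seed.
#' @param barrier Optional [barrier()]; sampled positions avoid its volume.
#' @return A [school_state()].
#' @examples
#' st <- init_school(50, tank_geometry(), boids_params(), seed = 1)
#' nrow(st$positions)
#' @export
init_school <- function(n_fish, geometry, params, seed, barrier = NULL) {
  if (!is.numeric(n_fish) || length(n_fish) != 1 || n_fish < 1)
    stop_invalid("n_fish must be a positive count (got %s)", format(n_fish))
  n_fish <- as.integer(n_fish)
  rmax <- geometry$radius - geometry$wall_margin
  with_seed(seed, {
    pos <- matrix(NA_real_, n_fish, 3)
    filled <- 0L
    tries <- 0L
    while (filled < n_fish) {
      tries <- tries + 1L
      if (tries > 200L)
        stop_infeasible("could not place %d fish outside the barrier; barrier occupies too much of the tank",
                        n_fish)
      m <- n_fish - filled
      r <- rmax * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      cand <- cbind(r * cos(th), r * sin(th),
                    stats::runif(m, 0, geometry$height))
      ok <- !inside_barrier(cand, barrier)
      k <- sum(ok)
      if (k > 0) {
        pos[(filled + 1):(filled + k), ] <- cand[ok, , drop = FALSE]
        filled <- filled + k
      }
    }
    # tangential heading (counter-clockwise) + isotropic jitter, renormalised
    r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    tang <- cbind(-pos[, 2], pos[, 1], 0) / pmax(r, 1e-9)
    jit <- matrix(stats::rnorm(3 * n_fish, sd = 0.4), n_fish, 3)
    dir <- tang + jit
    dn <- row_norms(dir)
    on_axis <- dn < 1e-9
    if (any(on_axis)) dir[on_axis, ] <- c(1, 0, 0)
    dir <- dir / pmax(row_norms(dir), 1e-12)
    speed <- stats::runif(n_fish, params$min_speed, params$max_speed)
    school_state(pos, dir * speed, time = 0, rng_seed = as.integer(seed))
  })
}

#' Tangential acceleration of a vortex field at a point
#'
#' Horizontal acceleration tangent to the circle through `position` about the
#' tank axis, with magnitude `strength * exp(-|z - source_height| /
#' decay_length)`. `rotation_sign = +1` gives counter-clockwise motion viewed
#' from above. On the axis itself no tangent direction exists and the zero
#' vector is returned.
#'
#' @param position 3-vector (m), or an N x 3 matrix for many points.
#' @param vortex A [vortex_force()].
#' @param tank_axis_origin 3-vector; the axis passes vertically through it.
#' @return Acceleration (m s^-2), same shape as `position`.
#' @examples
#' v <- vortex_force(source_height = 0, rotation_sign = +1,
#'                   strength = 2, decay_length = 1)
#' vortex_acceleration(c(1, 0, 0), v)   # (0, 2, 0)
#' @export
vortex_acceleration <- function(position, vortex, tank_axis_origin = c(0, 0, 0)) {
  vec_in <- is.null(dim(position))
  p <- if (vec_in) matrix(position, 1, 3) else as.matrix(position)
  rel <- sweep(p, 2, as.numeric(tank_axis_origin), `-`)
  r <- sqrt(rel[, 1]^2 + rel[, 2]^2)
  mag <- vortex$strength *
    exp(-abs(rel[, 3] - (vortex$source_height - tank_axis_origin[3])) /
          vortex$decay_length)
  out <- matrix(0, nrow(p), 3)
  off <- r > 1e-12
  out[off, 1] <- -rel[off, 2] / r[off] * mag[off] * vortex$rotation_sign
  out[off, 2] <-  rel[off, 1] / r[off] * mag[off] * vortex$rotation_sign
  if (vec_in) out[1, ] else out
}

#' Boids steering accelerations
#'
#' Classic Reynolds flocking rules. For each fish, neighbours are the other
#' fish within `perception_radius`. The three steering terms are:
#' \describe{
#'   \item{separation}{sum over neighbours closer than `min_separation` of the
#'     unit vector away from the neighbour, weighted by
#'     `(1 - d / min_separation)`;}
#'   \item{alignment}{mean neighbour velocity minus own velocity;}
#'   \item{cohesion}{neighbour centroid minus own position.}
#' }
#' Each term is scaled by its weight and clamped to `max_accel`, and so is the
#' sum. A fish with no neighbours gets zero steering.
#'
#' @param state A [school_state()].
#' @param params A [boids_params()].
#' @return N x 3 matrix of accelerations (m s^-2).
#' @export
boids_steering <- function(state, params) {
  p <- state$positions; v <- state$velocities
  n <- nrow(p)
  acc <- matrix(0, n, 3)
  if (n < 2) return(acc)
  dx <- outer(p[, 1], p[, 1], `-`)   # dx[i,j] = p_i - p_j
  dy <- outer(p[, 2], p[, 2], `-`)
  dz <- outer(p[, 3], p[, 3], `-`)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  neigh <- d <= params$perception_radius
  diag(neigh) <- FALSE
  nn <- rowSums(neigh)

  # separation: neighbours inside the personal-space radius
  wsep <- ifelse(neigh & d < params$min_separation & d > 0,
                 (1 - d / params$min_separation) / d, 0)
  sep <- cbind(rowSums(wsep * dx), rowSums(wsep * dy), rowSums(wsep * dz))

  has <- nn > 0
  ali <- coh <- matrix(0, n, 3)
  if (any(has)) {
    nm <- neigh * 1
    mean_v <- (nm %*% v) / pmax(nn, 1)
    mean_p <- (nm %*% p) / pmax(nn, 1)
    ali[has, ] <- mean_v[has, , drop = FALSE] - v[has, , drop = FALSE]
    coh[has, ] <- mean_p[has, , drop = FALSE] - p[has, , drop = FALSE]
  }
  acc <- clamp_norm(params$separation_weight * sep, params$max_accel) +
    clamp_norm(params$alignment_weight * ali, params$max_accel) +
    clamp_norm(params$cohesion_weight * coh, params$max_accel)
  clamp_norm(acc, params$max_accel)
}

#' Boundary and barrier avoidance accelerations
#'
#' Soft, continuous repulsion from the tank wall, floor, lid and the barrier
#' cuboid. Within an influence distance `L` of a boundary the push grows
#' quadratically from zero: magnitude `strength * (1 - d/L)^2` where `d` is
#' the distance to the boundary. The wall push points toward the axis, the
#' floor push up, the lid push down; the barrier pushes along the outward
#' normal of its nearest face within `repulsion_range` of the surface
#' (full strength inside the cuboid, which reflection normally prevents).
#'
#' The wall influence distance is `wall_margin + lookahead` so fish start
#' turning before the hard containment radius.
#'
#' @param state A [school_state()].
#' @param geometry A [tank_geometry()].
#' @param barrier Optional [barrier()].
#' @param strength Peak boundary push (m s^-2).
#' @param lookahead Extra influence distance (m) beyond `wall_margin`.
#' @return N x 3 matrix of accelerations (m s^-2).
#' @export
avoidance_acceleration <- function(state, geometry, barrier = NULL,
                                   strength = 3.0, lookahead = 0.4) {
  p <- state$positions
  n <- nrow(p)
  acc <- matrix(0, n, 3)
  L <- geometry$wall_margin + lookahead

  # cylinder wall: push toward the axis
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  d_wall <- geometry$radius - r
  s <- pmax(0, 1 - d_wall / L)
  close_w <- s > 0 & r > 1e-12
  if (any(close_w)) {
    mag <- strength * s[close_w]^2
    acc[close_w, 1] <- acc[close_w, 1] - p[close_w, 1] / r[close_w] * mag
    acc[close_w, 2] <- acc[close_w, 2] - p[close_w, 2] / r[close_w] * mag
  }
  # floor (push up) and lid (push down)
  sf <- pmax(0, 1 - p[, 3] / L)
  st <- pmax(0, 1 - (geometry$height - p[, 3]) / L)
  acc[, 3] <- acc[, 3] + strength * sf^2 - strength * st^2

  if (!is.null(barrier)) {
    rel <- sweep(p, 2, barrier$center, `-`)
    q <- abs(rel)
    out <- sweep(q, 2, barrier$half_extents, `-`)  # per-axis excess beyond faces
    outside <- pmax(out, 0)
    dist <- sqrt(rowSums(outside^2))
    inside <- dist == 0
    near <- !inside & dist < barrier$repulsion_range
    if (any(near)) {
      dirs <- outside[near, , drop = FALSE] * sign(rel[near, , drop = FALSE])
      dirs <- dirs / dist[near]
      mag <- barrier$repulsion_strength *
        (1 - dist[near] / barrier$repulsion_range)^2
      acc[near, ] <- acc[near, ] + dirs * mag
    }
    if (any(inside)) {
      # push out along the least-penetrated axis at full strength
      for (i in which(inside)) {
        ax <- which.max(out[i, ])
        dir <- numeric(3)
        dir[ax] <- if (rel[i, ax] >= 0) 1 else -1
        acc[i, ] <- acc[i, ] + dir * barrier$repulsion_strength
      }
    }
  }
  acc
}

# soft-sphere resolution: push any pair closer than min_sep apart to min_sep,
# splitting the correction equally; a couple of sweeps settle chains.
push_apart <- function(p, min_sep, sweeps = 2L) {
  for (s in seq_len(sweeps)) {
    d <- as.matrix(stats::dist(p))
    d[upper.tri(d, diag = TRUE)] <- Inf
    close <- which(d < min_sep, arr.ind = TRUE)
    if (nrow(close) == 0) break
    for (k in seq_len(nrow(close))) {
      i <- close[k, 1]; j <- close[k, 2]
      delta <- p[i, ] - p[j, ]
      dn <- sqrt(sum(delta * delta))
      dir <- if (dn < 1e-9) c(0, 0, 1) else delta / dn
      corr <- (min_sep - dn) / 2
      p[i, ] <- p[i, ] + dir * corr
      p[j, ] <- p[j, ] - dir * corr
    }
  }
  p
}

# reflect positions/velocities back into the allowed volume (in place)
reflect_containment <- function(p, v, geometry, barrier) {
  rmax <- geometry$radius - geometry$wall_margin
  h <- geometry$height
  for (pass in 1:2) {
    # floor / lid
    below <- p[, 3] < 0
    if (any(below)) {
      p[below, 3] <- -p[below, 3]
      v[below, 3] <- abs(v[below, 3])
    }
    above <- p[, 3] > h
    if (any(above)) {
      p[above, 3] <- 2 * h - p[above, 3]
      v[above, 3] <- -abs(v[above, 3])
    }
    p[, 3] <- pmin(pmax(p[, 3], 0), h)
    # cylinder wall: reflect the radial coordinate
    r <- sqrt(p[, 1]^2 + p[, 2]^2)
    out <- r > rmax
    if (any(out)) {
      rr <- r[out]
      new_r <- pmax(2 * rmax - rr, 0.05 * rmax)
      scale <- new_r / rr
      ux <- p[out, 1] / rr; uy <- p[out, 2] / rr
      p[out, 1] <- p[out, 1] * scale
      p[out, 2] <- p[out, 2] * scale
      vr <- v[out, 1] * ux + v[out, 2] * uy   # radial speed, + = outward
      flip <- vr > 0
      if (any(flip)) {
        idx <- which(out)[flip]
        v[idx, 1] <- v[idx, 1] - 2 * vr[flip] * ux[flip]
        v[idx, 2] <- v[idx, 2] - 2 * vr[flip] * uy[flip]
      }
    }
    # barrier: project to the nearest face, reflect that velocity component
    if (!is.null(barrier)) {
      ins <- inside_barrier(p, barrier)
      if (any(ins)) {
        rel <- sweep(p[ins, , drop = FALSE], 2, barrier$center, `-`)
        pen <- sweep(abs(rel), 2, barrier$half_extents, `-`)  # negative inside
        for (k in seq_len(nrow(rel))) {
          i <- which(ins)[k]
          ax <- which.max(pen[k, ])
          sgn <- if (rel[k, ax] >= 0) 1 else -1
          p[i, ax] <- barrier$center[ax] + sgn * barrier$half_extents[ax]
          if (sign(v[i, ax]) == -sgn) v[i, ax] <- -v[i, ax]
        }
      }
    }
  }
  list(positions = p, velocities = v)
}

#' Advance the school by one time step
#'
#' Explicit-Euler update: accelerations from [boids_steering()],
#' [avoidance_acceleration()] and the vortex fields are summed, the velocity
#' is updated and its magnitude clamped to `[min_speed, max_speed]`, the
#' position is advanced by `dt * v`, positions/velocities are reflected at
#' the cylinder wall, floor, lid and barrier faces, and residual fish-fish
#' overlaps (pairs closer than `min_separation`) are resolved by a soft
#' push-apart before a final containment reflection, so every containment
#' invariant holds on output. Deterministic given the input state.
#'
#' @param state A [school_state()].
#' @param geometry A [tank_geometry()].
#' @param barrier Optional [barrier()].
#' @param vortices List of [vortex_force()] objects (may be empty).
#' @param params A [boids_params()].
#' @return The next [school_state()].
#' @export
school_step <- function(state, geometry, barrier = NULL, vortices = list(),
                        params = boids_params()) {
  p <- state$positions; v <- state$velocities
  acc <- boids_steering(state, params) +
    avoidance_acceleration(state, geometry, barrier)
  for (vx in vortices) acc <- acc + vortex_acceleration(p, vx)
  if (anyNA(acc) || any(!is.finite(acc))) {
    bad <- which(rowSums(!is.finite(acc)) > 0)
    stop_numerical("non-finite force for fish %s at t = %.3f",
                   paste(bad, collapse = ", "), state$time)
  }
  v1 <- v + params$dt * acc
  if (any(!is.finite(v1))) {
    bad <- which(rowSums(!is.finite(v1)) > 0)
    stop_numerical("non-finite velocity for fish %s at t = %.3f",
                   paste(bad, collapse = ", "), state$time)
  }
  sp <- row_norms(v1)
  stalled <- sp < 1e-9
  if (any(stalled)) {          # keep the previous heading at minimum speed
    old <- v[stalled, , drop = FALSE]
    od <- pmax(row_norms(old), 1e-12)
    v1[stalled, ] <- old / od * params$min_speed
    sp[stalled] <- params$min_speed
  }
  scale <- pmin(pmax(sp, params$min_speed), params$max_speed) / sp
  v1 <- v1 * scale
  p1 <- p + params$dt * v1
  rc <- reflect_containment(p1, v1, geometry, barrier)
  if (nrow(p1) > 1) {
    # alternate overlap resolution and containment until both settle; the
    # reflection after a push can re-compress a pair near the wall, so a few
    # rounds are allowed before accepting the state
    for (round in 1:4) {
      p2 <- push_apart(rc$positions, params$min_separation)
      if (identical(p2, rc$positions)) break
      rc <- reflect_containment(p2, rc$velocities, geometry, barrier)
    }
  }
  school_state(rc$positions, rc$velocities,
               time = state$time + params$dt, rng_seed = state$rng_seed)
}

#' Default simulation configuration
#'
#' Bundles tank, behaviour, vortex and barrier settings into the config
#' consumed by [simulate_school()]. Defaults model a 150 m\eqn{^3} growout
#' cylinder with 200 trout, a dominant counter-clockwise bottom vortex with a
#' weaker clockwise top vortex (net circulation is therefore well defined),
#' and a ramp-shaped barrier on the floor just upstream of the camera wall
#' position.
#'
#' @param n_fish Number of fish.
#' @param geometry A [tank_geometry()].
#' @param params A [boids_params()].
#' @param vortices List of [vortex_force()]s.
#' @param barrier A [barrier()], `NULL` for none, or `"default"` for the
#'   shipped ramp-shaped deflector.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_fish = 200,
                       geometry = tank_geometry(),
                       params = boids_params(),
                       vortices = list(
                         vortex_force(source_height = 0, rotation_sign = +1,
                                      strength = 0.8, decay_length = 2.5),
                         vortex_force(source_height = geometry$height,
                                      rotation_sign = -1,
                                      strength = 0.25, decay_length = 1.2)),
                       barrier = "default") {
  if (identical(barrier, "default"))
    barrier <- finsim::barrier(center = c(2.55, -1.0, 1.1),
                               half_extents = c(0.45, 0.35, 1.1),
                               geometry = geometry)
  structure(list(n_fish = as.integer(n_fish), geometry = geometry,
                 params = params, vortices = vortices, barrier = barrier),
            class = "sim_config")
}

#' Simulate a school trajectory
#'
#' Initialises a school with [init_school()] and applies [school_step()]
#' `n_steps` times, keeping every `thin`-th state (the final state is always
#' kept). Reproducible: the same `(config, n_steps, seed, thin)` gives
#' bit-identical trajectories.
#'
#' @param config A [sim_config()].
#' @param n_steps Number of integration steps, `>= 1`.
#' @param seed Integer RNG seed for the initial state.
#' @param thin Keep every `thin`-th state (default 1 = all).
#' @param verbose If `TRUE`, log mean speed, mean depth and rotation rate
#'   every 1000 steps.
#' @return A list of class `"school_trajectory"` with elements `states`
#'   (list of [school_state()]), `config`, `seed`, `thin`, `n_steps`.
#' @examples
#' traj <- simulate_school(sim_config(n_fish = 20), n_steps = 50, seed = 1)
#' length(traj$states)
#' @export
simulate_school <- function(config, n_steps, seed, thin = 1L, verbose = FALSE) {
  if (n_steps < 1) stop_invalid("n_steps must be >= 1")
  n_steps <- as.integer(n_steps); thin <- max(1L, as.integer(thin))
  state <- init_school(config$n_fish, config$geometry, config$params,
                       seed = seed, barrier = config$barrier)
  keep <- union(seq(thin, n_steps, by = thin), n_steps)
  states <- vector("list", length(keep))
  ki <- 1L
  for (s in seq_len(n_steps)) {
    state <- school_step(state, config$geometry, config$barrier,
                         config$vortices, config$params)
    if (s %in% keep) { states[[ki]] <- state; ki <- ki + 1L }
    if (verbose && s %% 1000L == 0L) {
      p <- state$positions; v <- state$velocities
      r2 <- pmax(p[, 1]^2 + p[, 2]^2, 1e-12)
      omega <- mean((p[, 1] * v[, 2] - p[, 2] * v[, 1]) / r2)
      message(sprintf("step %d: mean speed %.3f m/s, mean z %.2f m, rotation %.3f rad/s",
                      s, mean(row_norms(v)), mean(p[, 3]), omega))
    }
  }
  structure(list(states = states, config = config, seed = as.integer(seed),
                 thin = thin, n_steps = n_steps),
            class = "school_trajectory")
}

#' @export
print.school_trajectory <- function(x, ...) {
  cat(sprintf("<school_trajectory> %d fish, %d steps (kept %d states), seed %d\n",
              x$config$n_fish, x$n_steps, length(x$states), x$seed))
  invisible(x)
}

#' Mean tangential (circulation) speed of a school
#'
#' Mean over fish of the tangential velocity component about the tank axis,
#' positive for counter-clockwise motion viewed from above. Used to verify
#' the rotation response to the vortex forcing.
#'
#' @param state A [school_state()].
#' @return Scalar m s^-1.
#' @export
mean_tangential_speed <- function(state) {
  p <- state$positions; v <- state$velocities
  r <- pmax(sqrt(p[, 1]^2 + p[, 2]^2), 1e-12)
  mean((p[, 1] * v[, 2] - p[, 2] * v[, 1]) / r)
}
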