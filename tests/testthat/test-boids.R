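test_that("school initialisation is seeded, contained and barrier-free", {
  geom <- tank_geometry(radius = 2, height = 1)
  pars <- boids_params()
  a <- init_school(50, geom, pars, seed = 7)
  b <- init_school(50, geom, pars, seed = 7)
  expect_identical(a, b)
  expect_true(isTRUE(check_school_state(a, geom, pars)))
  # one fish, different seed, still reproducible
  expect_identical(init_school(1, geom, pars, seed = 7),
                   init_school(1, geom, pars, seed = 7))
  # barrier volume is excluded
  barr <- barrier(center = c(1, 0, 0.5), half_extents = c(0.4, 0.4, 0.5),
                  geometry = geom)
  st <- init_school(200, geom, pars, seed = 3, barrier = barr)
  expect_true(isTRUE(check_school_state(st, geom, pars, barr)))
  expect_error(init_school(0, geom, pars, seed = 1),
               class = "finsim_invalid_argument")
})

test_that("initial depths are uniform over the water column", {
  geom <- tank_geometry(radius = 2, height = 1)
  st <- init_school(1000, geom, boids_params(), seed = 11)
  # oracle: mean of U(0, h) is h/2 with standard error h / sqrt(12 n)
  se <- geom$height / sqrt(12 * 1000)
  expect_lt(abs(mean(st$positions[, 3]) - geom$height / 2), 3 * se)
})

test_that("an all-covering barrier makes initialisation infeasible", {
  geom <- tank_geometry(radius = 1, height = 1)
  blanket <- barrier(center = c(0, 0, 0.5), half_extents = c(2, 2, 2))
  expect_error(init_school(5, geom, boids_params(), seed = 1, barrier = blanket),
               class = "finsim_infeasible")
})

test_that("vortex acceleration follows the tangential decay law", {
  vx <- vortex_force(source_height = 0, rotation_sign = +1,
                     strength = 2, decay_length = 1)
  # on the axis there is no tangent: zero vector
  expect_identical(vortex_acceleration(c(0, 0, 0.5), vx), c(0, 0, 0))
  # at radius 1 on the source plane: pure +y tangent of full strength
  expect_equal(vortex_acceleration(c(1, 0, 0), vx), c(0, 2, 0))
  # exponential axial decay: strength / e one decay length away
  a <- vortex_acceleration(c(1, 0, 1), vx)
  expect_equal(sqrt(sum(a^2)), 2 * exp(-1))
  # flipping the rotation sign negates the field exactly
  vneg <- vortex_force(0, -1, strength = 2, decay_length = 1)
  p <- c(0.3, -1.2, 0.7)
  expect_identical(vortex_acceleration(p, vneg), -vortex_acceleration(p, vx))
})

test_that("boids steering matches the documented three-rule model", {
  pars <- boids_params(perception_radius = 1, min_separation = 0.5,
                       separation_weight = 1, alignment_weight = 0,
                       cohesion_weight = 0)
  # single fish and out-of-range pairs get zero steering
  expect_equal(boids_steering(fixed_state(c(0, 0, 0)), pars),
               matrix(0, 1, 3))
  far <- fixed_state(c(0, 0, 0, 5, 0, 0))
  expect_equal(boids_steering(far, pars), matrix(0, 2, 3))
  # three fish in a line closer than min_separation, separation only:
  # the middle fish is balanced, the outer fish point outward
  line <- fixed_state(c(-0.2, 0, 0, 0, 0, 0, 0.2, 0, 0))
  acc <- boids_steering(line, pars)
  expect_equal(acc[2, ], c(0, 0, 0))
  expect_lt(acc[1, 1], 0)
  expect_gt(acc[3, 1], 0)
  # brute-force evaluation of the documented rule on a random configuration
  pars2 <- boids_params(perception_radius = 1.2, min_separation = 0.5,
                        separation_weight = 1.3, alignment_weight = 0.7,
                        cohesion_weight = 0.4, max_accel = 2)
  set.seed(42)
  p <- matrix(runif(15, -1, 1), 5, 3)
  v <- matrix(runif(15, -0.5, 0.5), 5, 3)
  st <- school_state(p, v)
  clamp1 <- function(x, m) { n <- sqrt(sum(x^2)); if (n > m) x * m / n else x }
  expected <- t(vapply(1:5, function(i) {
    sep <- ali <- coh <- c(0, 0, 0); nb <- integer(0)
    for (j in setdiff(1:5, i)) {
      d <- sqrt(sum((p[i, ] - p[j, ])^2))
      if (d <= pars2$perception_radius) {
        nb <- c(nb, j)
        if (d < pars2$min_separation)
          sep <- sep + (p[i, ] - p[j, ]) / d * (1 - d / pars2$min_separation)
      }
    }
    if (length(nb) > 0) {
      ali <- colMeans(v[nb, , drop = FALSE]) - v[i, ]
      coh <- colMeans(p[nb, , drop = FALSE]) - p[i, ]
    }
    clamp1(clamp1(pars2$separation_weight * sep, pars2$max_accel) +
             clamp1(pars2$alignment_weight * ali, pars2$max_accel) +
             clamp1(pars2$cohesion_weight * coh, pars2$max_accel),
           pars2$max_accel)
  }, numeric(3)))
  expect_equal(boids_steering(st, pars2), expected)
})

test_that("avoidance pushes away from wall, floor, lid and barrier", {
  geom <- tank_geometry(radius = 2, height = 2, wall_margin = 0.2)
  # mid-tank fish far from everything: exactly zero
  expect_equal(avoidance_acceleration(fixed_state(c(0.5, 0, 1)), geom),
               matrix(0, 1, 3))
  # half a wall margin from the wall: strictly inward radial push
  st <- fixed_state(c(geom$radius - geom$wall_margin / 2, 0, 1))
  acc <- avoidance_acceleration(st, geom)
  expect_lt(acc[1, 1], 0)
  expect_equal(acc[1, 2:3], c(0, 0))
  # just above the barrier top face: +z push of the documented magnitude
  barr <- barrier(center = c(1, 0, 0.5), half_extents = c(0.3, 0.3, 0.5),
                  repulsion_strength = 3, repulsion_range = 0.4)
  st2 <- fixed_state(c(1, 0, 1.01))
  acc2 <- avoidance_acceleration(st2, geom, barr)
  expect_gt(acc2[1, 3], 0)
  expect_equal(acc2[1, 3], 3 * (1 - 0.01 / 0.4)^2)
})

test_that("a force-free step is exactly ballistic", {
  geom <- tank_geometry(radius = 5, height = 5)
  pars <- boids_params(separation_weight = 0, alignment_weight = 0,
                       cohesion_weight = 0, dt = 0.1)
  v <- c(0.7, 0.2, -0.1)
  st <- school_state(matrix(c(1, 0, 2.5), 1), matrix(v, 1))
  nxt <- school_step(st, geom, NULL, list(), pars)
  expect_identical(nxt$positions[1, ], c(1, 0, 2.5) + 0.1 * v)
  expect_identical(nxt$velocities[1, ], v)
  expect_equal(nxt$time, 0.1)
})

test_that("stepping preserves containment from arbitrary valid states", {
  cfg <- sim_config(n_fish = 40)
  for (s in 1:5) {
    st <- init_school(cfg$n_fish, cfg$geometry, cfg$params, seed = s,
                      barrier = cfg$barrier)
    for (k in 1:20)
      st <- school_step(st, cfg$geometry, cfg$barrier, cfg$vortices, cfg$params)
    expect_true(isTRUE(check_school_state(st, cfg$geometry, cfg$params,
                                          cfg$barrier)))
  }
})

test_that("non-finite dynamics are reported with the fish index", {
  geom <- tank_geometry()
  st <- school_state(matrix(c(1, 0, 2), 1), matrix(c(Inf, 0, 0), 1))
  expect_error(school_step(st, geom, NULL, list(), boids_params()),
               "fish 1", class = "finsim_numerical_failure")
})

test_that("vortex forcing rotates a fish in the commanded direction", {
  # oracle: re-integrate the same ODE at dt/10 and compare the sign of the
  # accumulated angular displacement about the axis
  geom <- tank_geometry(radius = 3, height = 4, wall_margin = 0.1)
  run_sign <- function(sign, dt, steps) {
    vx <- vortex_force(source_height = 4, rotation_sign = sign,
                       strength = 1, decay_length = 2)
    pars <- boids_params(separation_weight = 0, alignment_weight = 0,
                         cohesion_weight = 0, dt = dt, max_speed = 1,
                         min_speed = 0.2)
    st <- school_state(matrix(c(1.5, 0, 3), 1), matrix(c(0, 0.3 * sign, 0), 1))
    ang <- 0
    prev <- atan2(st$positions[1, 2], st$positions[1, 1])
    for (k in seq_len(steps)) {
      st <- school_step(st, geom, NULL, list(vx), pars)
      cur <- atan2(st$positions[1, 2], st$positions[1, 1])
      d <- cur - prev
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      ang <- ang + d
      prev <- cur
    }
    ang
  }
  coarse_pos <- run_sign(+1, 0.05, 200)
  fine_pos <- run_sign(+1, 0.005, 2000)
  coarse_neg <- run_sign(-1, 0.05, 200)
  expect_gt(coarse_pos, 0)
  expect_identical(sign(coarse_pos), sign(fine_pos))
  expect_lt(coarse_neg, 0)
})

test_that("trajectories are reproducible and thinned correctly", {
  cfg <- sim_config(n_fish = 15)
  t1 <- simulate_school(cfg, n_steps = 30, seed = 5, thin = 7)
  t2 <- simulate_school(cfg, n_steps = 30, seed = 5, thin = 7)
  expect_identical(t1, t2)
  expect_equal(length(t1$states), length(union(seq(7, 30, 7), 30)))
  # n_steps = 1 equals a single explicit step from the initial state
  one <- simulate_school(cfg, n_steps = 1, seed = 5)
  st0 <- init_school(cfg$n_fish, cfg$geometry, cfg$params, seed = 5,
                     barrier = cfg$barrier)
  expect_identical(one$states[[1]],
                   school_step(st0, cfg$geometry, cfg$barrier, cfg$vortices,
                               cfg$params))
})

test_that("halving dt changes a single-fish endpoint at first order", {
  geom <- tank_geometry(radius = 3, height = 4, wall_margin = 0.1)
  vx <- vortex_force(0, +1, strength = 0.5, decay_length = 2)
  endpoint <- function(dt) {
    pars <- boids_params(separation_weight = 0, alignment_weight = 0,
                         cohesion_weight = 0, dt = dt, max_speed = 1.5,
                         min_speed = 0.1)
    st <- school_state(matrix(c(1.2, 0, 2), 1), matrix(c(0, 0.5, 0), 1))
    for (k in seq_len(round(10 / dt)))   # integrate to t = 10 s
      st <- school_step(st, geom, NULL, list(vx), pars)
    st$positions[1, ]
  }
  e1 <- endpoint(0.1); e2 <- endpoint(0.05); e4 <- endpoint(0.025)
  d12 <- sqrt(sum((e1 - e2)^2)); d24 <- sqrt(sum((e2 - e4)^2))
  expect_lt(d24, d12)                     # refinement shrinks the change
  expect_lt(d12, 0.5)                     # and the change is O(dt)-small
})

test_that("config YAML round-trips through the typed constructors", {
  cfg <- sim_config(n_fish = 25)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
  shipped <- system.file("extdata", "default_sim.yaml", package = "finsim")
  expect_equal(read_sim_config(shipped), sim_config())
  # trajectories round-trip too
  tr <- simulate_school(sim_config(n_fish = 5), 10, seed = 2, thin = 5)
  tp <- tempfile(fileext = ".rds")
  write_trajectory(tr, tp)
  expect_identical(read_trajectory(tp), tr)
})
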