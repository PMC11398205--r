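#' Read and write simulation configs as YAML
#'
#' A [sim_config()] serialises to a flat, documented YAML layout with
#' sections `n_fish`, `tank` (radius/height/wall_margin), `boids` (the
#' [boids_params()] fields), `vortices` (a list of
#' source_height/rotation_sign/strength/decay_length entries) and an
#' optional `barrier` (center/half_extents/repulsion_strength/
#' repulsion_range). `read_sim_config()` validates through the type
#' constructors, so malformed values fail with the same messages as direct
#' construction. A commented example ships in
#' `system.file("extdata", "default_sim.yaml", package = "finsim")`.
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  doc <- list(
    n_fish = config$n_fish,
    tank = unclass(config$geometry),
    boids = unclass(config$params),
    vortices = lapply(config$vortices, unclass),
    barrier = if (!is.null(config$barrier)) unclass(config$barrier))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_format("cannot parse config %s: %s",
                                                  path, conditionMessage(e)))
  for (key in c("n_fish", "tank", "boids"))
    if (is.null(doc[[key]]))
      stop_format("config %s missing section '%s'", path, key)
  geometry <- do.call(tank_geometry, doc$tank)
  params <- do.call(boids_params, doc$boids)
  vortices <- lapply(doc$vortices %||% list(), function(v)
    do.call(vortex_force, v))
  barr <- if (!is.null(doc$barrier)) do.call(barrier, doc$barrier)
  sim_config(n_fish = doc$n_fish, geometry = geometry, params = params,
             vortices = vortices, barrier = barr)
}

#' Save a trajectory
#'
#' Stores the thinned states of a [simulate_school()] run (plus its config
#' and seed) in a single R-native file; `read_trajectory()` restores it.
#'
#' @param trajectory A `"school_trajectory"`.
#' @param path Output path (conventionally `.rds`).
#' @return `path` invisibly / the trajectory.
#' @export
write_trajectory <- function(trajectory, path) {
  saveRDS(trajectory, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- readRDS(path)
  if (!inherits(tr, "school_trajectory"))
    stop_format("%s does not contain a school trajectory", path)
  tr
}
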