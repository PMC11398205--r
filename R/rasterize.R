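#' Layered frame
#'
#' One rendered view as three co-registered rasters: `rgb` (H x W x 3 in
#' `[0,1]`), `depth` (H x W, Euclidean camera-to-surface distance in metres,
#' `Inf` for background) and `index` (H x W integer instance map, 0 for
#' background, `k >= 1` for fish `k`). The layer-consistency invariant
#' `index > 0  <=>  is.finite(depth)` is enforced at construction.
#'
#' @param rgb H x W x 3 array in `[0,1]`.
#' @param depth H x W matrix (m), `Inf` marks background.
#' @param index H x W integer matrix, `0` marks background.
#' @return An object of class `"layered_frame"`.
#' @export
layered_frame <- function(rgb, depth, index) {
  index <- matrix(as.integer(index), nrow(depth), ncol(depth))
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop_invalid("rgb must be an H x W x 3 array")
  if (!identical(dim(rgb)[1:2], dim(depth)) ||
      !identical(dim(depth), dim(index)))
    stop_invalid("rgb, depth and index layers must share the same H x W shape")
  if (any((index > 0) != is.finite(depth)))
    stop_invalid("layer consistency violated: index > 0 must coincide with finite depth")
  structure(list(rgb = rgb, depth = depth, index = index),
            class = "layered_frame")
}

#' @export
print.layered_frame <- function(x, ...) {
  d <- dim(x$index)
  ids <- sort(unique(x$index[x$index > 0]))
  cat(sprintf("<layered_frame> %d x %d px, %d instances\n", d[1], d[2],
              length(ids)))
  invisible(x)
}

# squared distance factor from interpolated forward depth z to euclidean ray
# distance at pixel centre (u, v); shared by rasterize() and documentation.
ray_scale <- function(u, v, camera) {
  sqrt(1 + ((u - camera$cx) / camera$fx)^2 + ((v - camera$cy) / camera$fy)^2)
}

#' Rasterize a school state into a layered frame
#'
#' Z-buffered triangle rasterization. Each fish is posed by rotating the mesh
#' body axis onto its velocity direction (a fish with near-zero speed keeps
#' the +x heading) and translating to its position. Triangles are projected
#' through the rectilinear camera, screen-space barycentric coordinates with
#' perspective-correct inverse-depth interpolation decide coverage and depth
#' at each pixel centre, and the nearest surface wins; ties keep the earlier
#' triangle in fish-then-triangle order. Triangles with any vertex at or
#' behind the near plane are dropped.
#'
#' Shading is flat: one overhead light, pixel colour
#' `base_color * (ambient + (1 - ambient) * |n_z|)` where `n_z` is the world
#' z-component of the unit triangle normal. `depth` stores the Euclidean ray
#' distance (not the axial distance) to the winning surface.
#'
#' @param state A [school_state()] (may contain zero fish).
#' @param mesh A [fish_mesh()].
#' @param camera A [camera_spec()].
#' @param ambient Ambient shading floor in `[0,1]`.
#' @return A [layered_frame()]; fish `k` of the state renders with instance
#'   id `k`.
#' @export
rasterize <- function(state, mesh, camera, ambient = 0.35) {
  H <- camera$height; W <- camera$width
  depth <- matrix(Inf, H, W)
  index <- matrix(0L, H, W)
  r_ch <- matrix(0, H, W); g_ch <- matrix(0, H, W); b_ch <- matrix(0, H, W)
  n_fish <- nrow(state$positions)
  tri <- mesh$triangles
  for (k in seq_len(n_fish)) {
    R <- heading_rotation(state$velocities[k, ])
    vw <- mesh$vertices %*% t(R)
    vw <- sweep(vw, 2, state$positions[k, ], `+`)
    pc <- camera_coords(vw, camera)
    z <- pc[, 3]
    u <- camera$cx + camera$fx * pc[, 1] / z
    v <- camera$cy + camera$fy * pc[, 2] / z
    ok <- z > camera$near
    for (t in seq_len(nrow(tri))) {
      i1 <- tri[t, 1]; i2 <- tri[t, 2]; i3 <- tri[t, 3]
      if (!(ok[i1] && ok[i2] && ok[i3])) next
      u1 <- u[i1]; u2 <- u[i2]; u3 <- u[i3]
      v1 <- v[i1]; v2 <- v[i2]; v3 <- v[i3]
      denom <- (v2 - v3) * (u1 - u3) + (u3 - u2) * (v1 - v3)
      if (abs(denom) < 1e-12) next
      # pixel centres covered by the screen bbox: col j centre u = j - 0.5
      j_lo <- max(1L, as.integer(ceiling(min(u1, u2, u3) + 0.5)))
      j_hi <- min(W, as.integer(floor(max(u1, u2, u3) + 0.5)))
      i_lo <- max(1L, as.integer(ceiling(min(v1, v2, v3) + 0.5)))
      i_hi <- min(H, as.integer(floor(max(v1, v2, v3) + 0.5)))
      if (j_lo > j_hi || i_lo > i_hi) next
      jj <- rep(j_lo:j_hi, each = i_hi - i_lo + 1L)
      ii <- rep(i_lo:i_hi, times = j_hi - j_lo + 1L)
      up <- jj - 0.5; vp <- ii - 0.5
      w1 <- ((v2 - v3) * (up - u3) + (u3 - u2) * (vp - v3)) / denom
      w2 <- ((v3 - v1) * (up - u3) + (u1 - u3) * (vp - v3)) / denom
      w3 <- 1 - w1 - w2
      inside <- w1 >= 0 & w2 >= 0 & w3 >= 0
      if (!any(inside)) next
      jj <- jj[inside]; ii <- ii[inside]
      zpx <- 1 / (w1[inside] / z[i1] + w2[inside] / z[i2] + w3[inside] / z[i3])
      dpx <- zpx * ray_scale(jj - 0.5, ii - 0.5, camera)
      px <- cbind(ii, jj)
      win <- dpx < depth[px]
      if (!any(win)) next
      px <- px[win, , drop = FALSE]
      # flat shade from the world-space normal, two-sided overhead light
      e1 <- vw[i2, ] - vw[i1, ]; e2 <- vw[i3, ] - vw[i1, ]
      nrm <- cross3(e1, e2)
      nn <- sqrt(sum(nrm * nrm))
      shade <- if (nn < 1e-14) ambient
               else ambient + (1 - ambient) * abs(nrm[3] / nn)
      depth[px] <- dpx[win]
      index[px] <- k
      r_ch[px] <- mesh$base_color[1] * shade
      g_ch[px] <- mesh$base_color[2] * shade
      b_ch[px] <- mesh$base_color[3] * shade
    }
  }
  rgb <- array(0, c(H, W, 3))
  rgb[, , 1] <- r_ch; rgb[, , 2] <- g_ch; rgb[, , 3] <- b_ch
  layered_frame(rgb, depth, index)
}

#' Render a trajectory into layered frames
#'
#' Rasterizes (a subset of) the states of a [simulate_school()] trajectory.
#'
#' @param trajectory A `"school_trajectory"`.
#' @param camera A [camera_spec()].
#' @param mesh A [fish_mesh()]; defaults to [procedural_fish_mesh()].
#' @param which_states Integer indices into `trajectory$states`
#'   (default: all).
#' @param ambient Passed to [rasterize()].
#' @return List of [layered_frame()]s.
#' @export
render_trajectory <- function(trajectory, camera,
                              mesh = procedural_fish_mesh(),
                              which_states = seq_along(trajectory$states),
                              ambient = 0.35) {
  lapply(trajectory$states[which_states], rasterize,
         mesh = mesh, camera = camera, ambient = ambient)
}
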