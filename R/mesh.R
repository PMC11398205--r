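#' Triangle mesh for one fish
#'
#' A closed-enough triangle soup in the fish body frame: +x is forward
#' (toward the snout), +z up, units metres, origin at the body centre. The
#' renderer poses it by rotating +x onto the swimming direction.
#'
#' @param vertices V x 3 numeric matrix (m).
#' @param triangles T x 3 integer matrix of 1-based vertex indices.
#' @param base_color Length-3 RGB in `[0, 1]`.
#' @return An object of class `"fish_mesh"`.
#' @seealso [procedural_fish_mesh()] for the built-in model.
#' @export
fish_mesh <- function(vertices, triangles, base_color = c(0.55, 0.6, 0.62)) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3) stop_invalid("vertices must be V x 3")
  if (min(triangles) < 1 || max(triangles) > nrow(vertices))
    stop_invalid("triangle indices out of range [1, %d]", nrow(vertices))
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  cc <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  if (all(sqrt(nx^2 + ny^2 + nz^2) < 1e-14))
    stop_invalid("mesh has only degenerate (zero-area) triangles")
  if (any(base_color < 0) || any(base_color > 1) || length(base_color) != 3)
    stop_invalid("base_color must be RGB in [0,1]")
  structure(list(vertices = vertices, triangles = triangles,
                 base_color = as.numeric(base_color)),
            class = "fish_mesh")
}

#' @export
print.fish_mesh <- function(x, ...) {
  cat(sprintf("<fish_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Procedural fish mesh
#'
#' A self-contained stand-in for a licensed trout model: an ellipsoidal body
#' (lat-long tessellation with snout and tail poles) plus a flattened caudal
#' fin fan, about 100-200 triangles depending on the tessellation. Default
#' dimensions approximate a market-size rainbow trout (35 cm long, 10 cm
#' deep, 5 cm wide). Any [fish_mesh()] can be substituted in [rasterize()].
#'
#' @param length Body length (m), snout to caudal peduncle.
#' @param height Body depth (m).
#' @param width Body width (m).
#' @param n_segments Axial rings in the ellipsoid tessellation.
#' @param n_radial Vertices per ring.
#' @param base_color RGB in `[0,1]`.
#' @return A [fish_mesh()].
#' @examples
#' m <- procedural_fish_mesh()
#' nrow(m$triangles)
#' @export
procedural_fish_mesh <- function(length = 0.35, height = 0.10, width = 0.05,
                                 n_segments = 8, n_radial = 6,
                                 base_color = c(0.55, 0.6, 0.62)) {
  L <- length / 2; H <- height / 2; W <- width / 2
  phi <- seq(0, pi, length.out = n_segments + 2)[2:(n_segments + 1)]
  theta <- seq(0, 2 * pi, length.out = n_radial + 1)[seq_len(n_radial)]
  verts <- rbind(c(L, 0, 0))                      # 1: snout pole (+x forward)
  for (ph in phi)
    verts <- rbind(verts, cbind(L * cos(ph),
                                W * sin(ph) * cos(theta),
                                H * sin(ph) * sin(theta)))
  tail_i <- nrow(verts) + 1L
  verts <- rbind(verts, c(-L, 0, 0))              # tail pole
  ring <- function(k) 1L + (k - 1L) * n_radial + seq_len(n_radial)
  tris <- NULL
  r1 <- ring(1)
  tris <- rbind(tris, cbind(1L, r1, c(r1[-1], r1[1])))          # snout fan
  for (k in seq_len(n_segments - 1)) {
    a <- ring(k); b <- ring(k + 1)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    tris <- rbind(tris, cbind(a, b, b2), cbind(a, b2, a2))      # ring quads
  }
  rl <- ring(n_segments)
  tris <- rbind(tris, cbind(tail_i, c(rl[-1], rl[1]), rl))      # tail fan
  # caudal fin: a flattened fan in the x-z plane behind the tail pole
  fin_tip <- seq(-0.35 * pi, 0.35 * pi, length.out = 5)
  fin_len <- 0.30 * length
  fin <- cbind(-L - fin_len * cos(fin_tip), 0, fin_len * 1.2 * sin(fin_tip))
  fi <- nrow(verts) + seq_len(nrow(fin))
  verts <- rbind(verts, fin)
  for (k in seq_len(nrow(fin) - 1))
    tris <- rbind(tris, cbind(tail_i, fi[k], fi[k + 1]))
  fish_mesh(verts, tris, base_color)
}

# rotation taking the body frame (+x forward, +z up) to a world heading
heading_rotation <- function(heading) {
  f <- heading
  n <- sqrt(sum(f * f))
  f <- if (n < 1e-9) c(1, 0, 0) else f / n
  upw <- if (abs(f[3]) > 0.99) c(1, 0, 0) else c(0, 0, 1)
  l <- unit3(cross3(upw, f))           # body +y (left)
  u <- cross3(f, l)                    # body +z
  cbind(f, l, u)                       # columns = images of body axes
}
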