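#' Pinhole camera specification
#'
#' Rectilinear pinhole camera with square pixels. The default resolution and
#' horizontal field of view match the wide-angle in-tank sensor the package's
#' rendering emulates (1920 x 1080 px, HFOV 140 degrees). The focal length in
#' pixels is `fx = (width/2) / tan(hfov/2)` and the principal point sits at
#' `(width/2 - 0.5, height/2 - 0.5)` under the pixel convention that integer
#' pixel `(i, j)` (row, col, 0-based, origin top-left) has centre
#' `(j + 0.5, i + 0.5)`.
#'
#' @param position Camera centre, 3-vector (m) in world/tank coordinates.
#' @param view_direction Unit 3-vector the camera looks along.
#' @param up Approximate up direction (used to build the camera basis).
#' @param hfov Horizontal field of view in degrees, in (0, 180).
#' @param width,height Image size in pixels.
#' @param near,far Near/far clip distances (m), `0 < near < far`.
#' @return An object of class `"camera_spec"`.
#' @examples
#' cam <- camera_spec(position = c(3, 0, 1.8), view_direction = c(-1, 0, 0))
#' cam$fx   # 960 / tan(70 deg)
#' @export
camera_spec <- function(position = c(3.0, 0, 1.8),
                        view_direction = c(-1, 0, 0),
                        up = c(0, 0, 1),
                        hfov = 140, width = 1920L, height = 1080L,
                        near = 0.05, far = 30) {
  if (hfov <= 0 || hfov >= 180) stop_invalid("hfov must be in (0, 180) degrees")
  if (width < 1 || height < 1) stop_invalid("width and height must be >= 1")
  if (!(near > 0 && near < far)) stop_invalid("need 0 < near < far")
  fwd <- unit3(as.numeric(view_direction))
  upv <- unit3(as.numeric(up))
  if (abs(sum(fwd * upv)) > 1 - 1e-6)
    stop_invalid("view_direction and up are collinear")
  right <- unit3(cross3(fwd, upv))
  down <- cross3(fwd, right)          # camera +y points down in the image
  fx <- (width / 2) / tan(hfov / 2 * pi / 180)
  structure(list(position = as.numeric(position), view_direction = fwd,
                 up = upv, hfov = hfov,
                 width = as.integer(width), height = as.integer(height),
                 near = near, far = far,
                 basis = rbind(right, down, fwd),   # rows: x_cam, y_cam, z_cam
                 fx = fx, fy = fx,
                 cx = width / 2 - 0.5, cy = height / 2 - 0.5),
            class = "camera_spec")
}

# world points (N x 3) -> camera-frame coordinates (x right, y down, z forward)
camera_coords <- function(points, camera) {
  sweep(as.matrix(points), 2, camera$position, `-`) %*% t(camera$basis)
}

#' Project world points through the camera
#'
#' Rectilinear projection `u = cx + fx * x/z`, `v = cy + fy * y/z` in camera
#' coordinates (x right, y down, z forward), with `d` the Euclidean distance
#' from the camera centre to the point. Points at or behind the near plane
#' (`z <= near`) are outside the frustum and reported as `NA` rows rather
#' than raising an error.
#'
#' @param points 3-vector or N x 3 matrix of world coordinates (m).
#' @param camera A [camera_spec()].
#' @return N x 3 matrix with columns `u`, `v` (pixels) and `d` (m);
#'   rows of `NA` mark points outside the frustum.
#' @examples
#' cam <- camera_spec(position = c(0, 0, 0), view_direction = c(0, 0, 1),
#'                    up = c(0, -1, 0), width = 640, height = 480, hfov = 90)
#' project_points(c(0, 0, 2), cam)   # principal point, d = 2
#' @export
project_points <- function(points, camera) {
  vec_in <- is.null(dim(points))
  pts <- if (vec_in) matrix(points, 1, 3) else as.matrix(points)
  pc <- camera_coords(pts, camera)
  z <- pc[, 3]
  vis <- z > camera$near
  u <- v <- d <- rep(NA_real_, nrow(pc))
  u[vis] <- camera$cx + camera$fx * pc[vis, 1] / z[vis]
  v[vis] <- camera$cy + camera$fy * pc[vis, 2] / z[vis]
  d[vis] <- sqrt(rowSums(pc[vis, , drop = FALSE]^2))
  out <- cbind(u = u, v = v, d = d)
  if (vec_in) out[1, ] else out
}
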