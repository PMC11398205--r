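# Independent oracles and fixture builders shared across the suite.
# Each oracle re-derives its quantity by a different algorithmic route than
# the implementation (per-pixel scans, explicit enumeration, naive loops).

# ---- rasterizer oracle -------------------------------------------------------
# Per-pixel scan: for every pixel centre, test every triangle of every fish
# (in fish-then-triangle order) and keep the first strictly-nearest hit.
# Projection and barycentric arithmetic follow the documented formulas.
oracle_rasterize <- function(state, mesh, camera, ambient = 0.35) {
  H <- camera$height; W <- camera$width
  n_fish <- nrow(state$positions)
  tri <- mesh$triangles
  nt <- nrow(tri)
  # flatten all triangles of all fish into parallel vertex arrays
  u1 <- u2 <- u3 <- v1 <- v2 <- v3 <- z1 <- z2 <- z3 <- denom <-
    shade <- numeric(n_fish * nt)
  valid <- logical(n_fish * nt)
  fish_of <- integer(n_fish * nt)
  for (k in seq_len(n_fish)) {
    R <- finsim:::heading_rotation(state$velocities[k, ])
    vw <- mesh$vertices %*% t(R)
    vw <- sweep(vw, 2, state$positions[k, ], `+`)
    pc <- sweep(vw, 2, camera$position, `-`) %*% t(camera$basis)
    z <- pc[, 3]
    u <- camera$cx + camera$fx * pc[, 1] / z
    v <- camera$cy + camera$fy * pc[, 2] / z
    ok <- z > camera$near
    for (t in seq_len(nt)) {
      g <- (k - 1L) * nt + t
      fish_of[g] <- k
      i1 <- tri[t, 1]; i2 <- tri[t, 2]; i3 <- tri[t, 3]
      if (!(ok[i1] && ok[i2] && ok[i3])) next
      u1[g] <- u[i1]; u2[g] <- u[i2]; u3[g] <- u[i3]
      v1[g] <- v[i1]; v2[g] <- v[i2]; v3[g] <- v[i3]
      z1[g] <- z[i1]; z2[g] <- z[i2]; z3[g] <- z[i3]
      denom[g] <- (v2[g] - v3[g]) * (u1[g] - u3[g]) +
        (u3[g] - u2[g]) * (v1[g] - v3[g])
      if (abs(denom[g]) < 1e-12) next
      e1 <- vw[i2, ] - vw[i1, ]; e2 <- vw[i3, ] - vw[i1, ]
      nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
               e1[3] * e2[1] - e1[1] * e2[3],
               e1[1] * e2[2] - e1[2] * e2[1])
      nn <- sqrt(sum(nrm * nrm))
      shade[g] <- if (nn < 1e-14) ambient else ambient + (1 - ambient) * abs(nrm[3] / nn)
      valid[g] <- TRUE
    }
  }
  depth <- matrix(Inf, H, W); index <- matrix(0L, H, W)
  rgb <- array(0, c(H, W, 3))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    up <- j - 0.5; vp <- i - 0.5
    w1 <- ((v2 - v3) * (up - u3) + (u3 - u2) * (vp - v3)) / denom
    w2 <- ((v3 - v1) * (up - u3) + (u1 - u3) * (vp - v3)) / denom
    w3 <- 1 - w1 - w2
    hit <- which(valid & w1 >= 0 & w2 >= 0 & w3 >= 0)
    if (length(hit) == 0) next
    zpx <- 1 / (w1[hit] / z1[hit] + w2[hit] / z2[hit] + w3[hit] / z3[hit])
    dpx <- zpx * sqrt(1 + ((up - camera$cx) / camera$fx)^2 +
                        ((vp - camera$cy) / camera$fy)^2)
    best <- hit[which.min(dpx)]          # first minimum = earliest triangle
    depth[i, j] <- min(dpx)
    index[i, j] <- fish_of[best]
    rgb[i, j, ] <- mesh$base_color * shade[best]
  }
  list(rgb = rgb, depth = depth, index = index)
}

# ---- annotation oracle -------------------------------------------------------
# Brute-force single pass over all pixels accumulating per-id statistics,
# then the filter rules applied in documented order.
oracle_annotate <- function(frame, filter) {
  H <- nrow(frame$index); W <- ncol(frame$index)
  ids <- integer(0)
  minr <- maxr <- minc <- maxc <- cnt <- sumr <- sumc <- integer(0)
  depths <- list()
  for (i in seq_len(H)) for (j in seq_len(W)) {
    id <- frame$index[i, j]
    if (id == 0) next
    key <- match(id, ids)
    r0 <- i - 1L; c0 <- j - 1L          # 0-based pixel coords
    if (is.na(key)) {
      ids <- c(ids, id); key <- length(ids)
      minr[key] <- maxr[key] <- r0; minc[key] <- maxc[key] <- c0
      cnt[key] <- 1L; sumr[key] <- r0; sumc[key] <- c0
      depths[[key]] <- frame$depth[i, j]
    } else {
      minr[key] <- min(minr[key], r0); maxr[key] <- max(maxr[key], r0)
      minc[key] <- min(minc[key], c0); maxc[key] <- max(maxc[key], c0)
      cnt[key] <- cnt[key] + 1L
      sumr[key] <- sumr[key] + r0; sumc[key] <- sumc[key] + c0
      depths[[key]] <- c(depths[[key]], frame$depth[i, j])
    }
  }
  ord <- order(ids)
  out <- list()
  for (key in ord) {
    dd <- sort(depths[[key]]); n <- length(dd)
    med <- if (n %% 2 == 1) dd[(n + 1) / 2] else (dd[n / 2] + dd[n / 2 + 1]) / 2
    if (cnt[key] < filter$min_pixels) next
    if (med > filter$max_depth) next
    out[[length(out) + 1]] <- list(
      instance_id = ids[key],
      bbox = c(minc[key], minr[key],
               maxc[key] - minc[key] + 1, maxr[key] - minr[key] + 1),
      area_px = cnt[key],
      center = c(sumc[key] / cnt[key], sumr[key] / cnt[key]),
      depth = med)
  }
  out
}

# random layered frame: filled rectangles of distinct ids at random depths
random_layered_frame <- function(H = 64, W = 64, n_fish = 10) {
  index <- matrix(0L, H, W)
  depth <- matrix(Inf, H, W)
  n <- sample.int(n_fish, 1)
  for (id in seq_len(n)) {
    h <- sample.int(max(1, H %/% 3), 1); w <- sample.int(max(1, W %/% 3), 1)
    r <- sample.int(H - h + 1, 1); cc <- sample.int(W - w + 1, 1)
    d <- runif(1, 0.5, 6)
    index[r:(r + h - 1), cc:(cc + w - 1)] <- id
    block <- depth[r:(r + h - 1), cc:(cc + w - 1)]
    block[] <- d + runif(length(block), -0.05, 0.05)
    depth[r:(r + h - 1), cc:(cc + w - 1)] <- block
  }
  # overwritten ids may vanish; depth must be finite exactly on index > 0
  depth[index == 0] <- Inf
  rgb <- array(runif(H * W * 3), c(H, W, 3))
  layered_frame(rgb, depth, index)
}

# ---- metrics oracles ---------------------------------------------------------
# IoU by integer pixel counting (exact for integer boxes)
iou_pixel_count <- function(a, b) {
  ax <- a[1]:(a[1] + a[3] - 1); ay <- a[2]:(a[2] + a[4] - 1)
  bx <- b[1]:(b[1] + b[3] - 1); by <- b[2]:(b[2] + b[4] - 1)
  inter <- length(intersect(ax, bx)) * length(intersect(ay, by))
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# greedy matching re-derived with an explicit search at each step
oracle_match <- function(det, conf, gts, iou_thr = 0.5, iou_fun = iou_pixel_count) {
  n <- nrow(det)
  tp <- logical(n); matched <- rep(NA_integer_, n)
  gt_free <- rep(TRUE, nrow(gts))
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    i <- remaining[which.max(conf[remaining])]   # ties: lowest input index
    remaining <- setdiff(remaining, i)
    best_j <- NA_integer_; best_iou <- -1
    for (j in seq_len(nrow(gts))) {
      if (!gt_free[j]) next
      v <- iou_fun(det[i, ], gts[j, ])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (!is.na(best_j) && best_iou >= iou_thr) {
      tp[i] <- TRUE; matched[i] <- best_j; gt_free[best_j] <- FALSE
    }
  }
  list(tp = tp, matched_gt = matched, gt_matched = !gt_free)
}

# AP by explicit PR-point enumeration and naive envelope integration
oracle_ap <- function(detections, ground_truth, iou_thr = 0.5) {
  n_gt <- nrow(ground_truth)
  tp <- logical(nrow(detections))
  for (img in unique(detections$image_id)) {
    di <- which(detections$image_id == img)
    g <- as.matrix(ground_truth[ground_truth$image_id == img,
                                c("x", "y", "w", "h")])
    m <- oracle_match(as.matrix(detections[di, c("x", "y", "w", "h")]),
                      detections$confidence[di], g, iou_thr,
                      iou_fun = function(a, b) {
                        iw <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
                        ih <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
                        iw * ih / (a[3] * a[4] + b[3] * b[4] - iw * ih)
                      })
    tp[di] <- m$tp
  }
  ord <- order(-detections$confidence)
  tp <- tp[ord]
  prec <- rec <- numeric(length(tp))
  for (k in seq_along(tp)) {
    prec[k] <- sum(tp[seq_len(k)]) / k
    rec[k] <- sum(tp[seq_len(k)]) / n_gt
  }
  ap <- 0; prev_r <- 0
  for (k in seq_along(tp)) {
    env <- max(prec[k:length(prec)])     # best precision at recall >= rec[k]
    ap <- ap + (rec[k] - prev_r) * env
    prev_r <- rec[k]
  }
  ap
}

# ---- small simulation fixtures ----------------------------------------------
# a state with prescribed positions/velocities (velocities default +x)
fixed_state <- function(positions, velocities = NULL) {
  positions <- matrix(positions, ncol = 3, byrow = TRUE)
  if (is.null(velocities))
    velocities <- matrix(rep(c(0.5, 0, 0), nrow(positions)), ncol = 3, byrow = TRUE)
  else velocities <- matrix(velocities, ncol = 3, byrow = TRUE)
  school_state(positions, velocities)
}

# camera whose frame coincides with world coordinates (looking down +z,
# image v growing with world +y)
world_aligned_camera <- function(width = 64, height = 64, hfov = 90,
                                 near = 0.05) {
  camera_spec(position = c(0, 0, 0), view_direction = c(0, 0, 1),
              up = c(0, -1, 0), hfov = hfov, width = width, height = height,
              near = near)
}
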