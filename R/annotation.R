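#' Annotation filter
#'
#' The two inclusion rules applied to extracted instances before boxes are
#' emitted: a fish must cover at least `min_pixels` pixels (tiny slivers and
#' barely visible fish are not useful training signal) and its representative
#' depth must not exceed `max_depth` metres (far fish are blurred into the
#' turbid background and would teach the detector to box noise). The pixel
#' rule is applied first, then the depth rule; exclusion reasons are
#' reported in that order.
#'
#' Both values are deliberate repo defaults, not measured constants; pass
#' them explicitly in production configs.
#'
#' @param min_pixels Minimum instance pixel count, `>= 1`.
#' @param max_depth Maximum representative depth (m), `> 0`.
#' @return An object of class `"annotation_filter"`.
#' @export
annotation_filter <- function(min_pixels = 100, max_depth = 3.0) {
  if (min_pixels < 1) stop_invalid("min_pixels must be >= 1")
  if (max_depth <= 0) stop_invalid("max_depth must be > 0")
  structure(list(min_pixels = as.integer(min_pixels), max_depth = max_depth),
            class = "annotation_filter")
}

#' Extract per-fish instances from the index and depth layers
#'
#' One instance per distinct id `> 0` in the index map. The id defines the
#' instance: no connected-component analysis is performed, so a fish split
#' into disjoint pixel groups by occlusion stays one instance (ids are ground
#' truth in simulation). The representative depth is the median of the depth
#' layer over the instance's pixels. Pixel coordinates are 0-based
#' `(row, col)` with origin at the top-left pixel.
#'
#' @param index H x W integer map (0 = background).
#' @param depth H x W depth map (m), co-registered.
#' @return List of `"instance_mask"` objects sorted by `instance_id`, each
#'   with fields `instance_id`, `pixel_coords` (n x 2 matrix, 0-based
#'   row/col), `pixel_count`, `representative_depth`.
#' @export
extract_instances <- function(index, depth) {
  if (!identical(dim(index), dim(depth)))
    stop_invalid("index and depth layers must have the same shape")
  if (any(index < 0)) stop_invalid("index map must be >= 0")
  ids <- sort(unique(index[index > 0]))
  lapply(ids, function(id) {
    px <- which(index == id, arr.ind = TRUE)     # 1-based (row, col)
    coords <- cbind(row = px[, 1] - 1L, col = px[, 2] - 1L)
    structure(list(instance_id = as.integer(id),
                   pixel_coords = coords,
                   pixel_count = nrow(coords),
                   representative_depth = stats::median(depth[px])),
              class = "instance_mask")
  })
}

#' Filter instances by pixel count and depth
#'
#' Keeps instances with `pixel_count >= min_pixels` and
#' `representative_depth <= max_depth`, preserving order. The pixel-count
#' check runs first; the returned list carries an `"excluded"` attribute, a
#' data frame of `(instance_id, reason)` with reason `"pixel_count"` or
#' `"depth"`, reflecting that order.
#'
#' @param instances List of instance masks from [extract_instances()].
#' @param filter An [annotation_filter()].
#' @return Filtered list, with attribute `"excluded"`.
#' @export
filter_instances <- function(instances, filter) {
  keep <- logical(length(instances))
  ex_id <- integer(); ex_reason <- character()
  for (i in seq_along(instances)) {
    m <- instances[[i]]
    if (m$pixel_count < filter$min_pixels) {
      ex_id <- c(ex_id, m$instance_id); ex_reason <- c(ex_reason, "pixel_count")
    } else if (m$representative_depth > filter$max_depth) {
      ex_id <- c(ex_id, m$instance_id); ex_reason <- c(ex_reason, "depth")
    } else keep[i] <- TRUE
  }
  structure(instances[keep],
            excluded = data.frame(instance_id = ex_id, reason = ex_reason,
                                  stringsAsFactors = FALSE))
}

#' Convert an instance mask to an annotation record
#'
#' The bounding box is the tight axis-aligned box over the instance's pixels
#' in COCO convention: `bbox = (x_min, y_min, width, height)` with
#' `x_min = min col`, `y_min = min row`, `width = max col - min col + 1`
#' (analogously height), all in 0-based pixel coordinates. The centre is the
#' centroid of the pixel coordinates; `area_px` is the pixel count (the true
#' instance area, which can be smaller than the box area).
#'
#' @param mask An `"instance_mask"` from [extract_instances()].
#' @return An `"annotation_record"` with fields `instance_id`, `bbox`,
#'   `area_px`, `center` (u = col, v = row), `depth`, `category`.
#' @export
instance_record <- function(mask) {
  if (mask$pixel_count < 1) stop_invalid("cannot annotate an empty mask")
  rows <- mask$pixel_coords[, "row"]; cols <- mask$pixel_coords[, "col"]
  bbox <- c(x = min(cols), y = min(rows),
            width = max(cols) - min(cols) + 1,
            height = max(rows) - min(rows) + 1)
  structure(list(instance_id = mask$instance_id,
                 bbox = as.numeric(bbox),
                 area_px = mask$pixel_count,
                 center = c(u = mean(cols), v = mean(rows)),
                 depth = mask$representative_depth,
                 category = "fish"),
            class = "annotation_record")
}

#' Automatically annotate a rendered frame
#'
#' The full annotation flow: instances are extracted from the index/depth
#' layers, filtered by pixel count then depth, and converted to bounding-box
#' records. Deterministic. Partial fish at the frame edge are annotated like
#' any other instance whenever they pass the filters.
#'
#' @param frame A [layered_frame()].
#' @param filter An [annotation_filter()].
#' @return List of annotation records (see [instance_record()]), with the
#'   `"excluded"` attribute from [filter_instances()].
#' @examples
#' idx <- matrix(0L, 8, 8); idx[2:5, 3:6] <- 1L
#' dep <- matrix(Inf, 8, 8); dep[idx == 1] <- 1.5
#' fr <- layered_frame(array(0.5, c(8, 8, 3)), dep, idx)
#' annotate_frame(fr, annotation_filter(min_pixels = 4, max_depth = 3))
#' @export
annotate_frame <- function(frame, filter = annotation_filter()) {
  inst <- extract_instances(frame$index, frame$depth)
  kept <- filter_instances(inst, filter)
  structure(lapply(kept, instance_record), excluded = attr(kept, "excluded"))
}
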