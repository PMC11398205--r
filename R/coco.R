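#' Write annotations as a COCO JSON dataset
#'
#' Serialises per-image annotation records into the standard COCO
#' object-detection layout: top-level keys `info`, `licenses`, `categories`
#' (a single category `"fish"`, id 1), `images` (id, file_name, width,
#' height) and `annotations` (id, image_id, category_id, `bbox`
#' `[x, y, w, h]` as floats, `area`, `iscrowd = 0`). Annotation ids number
#' sequentially from 1 across images. Extra per-record fields (`depth`,
#' `center`) are carried in each annotation; standard COCO loaders ignore
#' them.
#'
#' @param annotations List parallel to the rows of `images`: element `i` is
#'   the list of annotation records (from [annotate_frame()]) for image `i`.
#' @param images Data frame with columns `id` (unique), `file_name`,
#'   `width`, `height`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(annotations, images, path) {
  if (length(annotations) != nrow(images))
    stop_invalid("need one annotation list per image (%d lists, %d images)",
                 length(annotations), nrow(images))
  if (anyDuplicated(images$id))
    stop_invalid("duplicate image id: %s",
                 paste(unique(images$id[duplicated(images$id)]), collapse = ", "))
  anns <- list(); aid <- 0L
  for (i in seq_len(nrow(images))) {
    for (rec in annotations[[i]]) {
      aid <- aid + 1L
      anns[[aid]] <- list(id = aid, image_id = images$id[i], category_id = 1L,
                          bbox = as.numeric(rec$bbox),
                          area = as.numeric(rec$area_px), iscrowd = 0L,
                          depth = rec$depth,
                          center = as.numeric(rec$center))
    }
  }
  img_list <- lapply(seq_len(nrow(images)), function(i)
    list(id = images$id[i], file_name = images$file_name[i],
         width = images$width[i], height = images$height[i]))
  doc <- list(
    info = list(description = "finsim virtual RAS fish dataset",
                version = "1.0", date_created = format(Sys.Date())),
    licenses = list(list(id = 1L, name = "synthetic render", url = "")),
    categories = list(list(id = 1L, name = "fish", supercategory = "animal")),
    images = img_list,
    annotations = anns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a COCO JSON dataset
#'
#' Parses and structurally validates a COCO detection file. Missing required
#' top-level keys, or annotations missing `bbox`/`image_id`, raise a format
#' error naming the offending key path.
#'
#' @param path COCO JSON path.
#' @return List with `images` (data frame: id, file_name, width, height),
#'   `annotations` (data frame: id, image_id, category_id, x, y, w, h, area,
#'   iscrowd), and `categories` (data frame: id, name).
#' @export
read_coco <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop_format("cannot parse COCO JSON %s: %s",
                                                  path, conditionMessage(e)))
  for (key in c("info", "licenses", "categories", "images", "annotations"))
    if (is.null(doc[[key]]))
      stop_format("COCO file %s missing required key '%s'", path, key)
  images <- do.call(rbind, lapply(doc$images, function(im) {
    for (key in c("id", "file_name", "width", "height"))
      if (is.null(im[[key]]))
        stop_format("COCO file %s: images entry missing 'images.%s'", path, key)
    data.frame(id = im$id, file_name = im$file_name,
               width = im$width, height = im$height,
               stringsAsFactors = FALSE)
  })) %||% data.frame(id = integer(), file_name = character(),
                      width = integer(), height = integer())
  annotations <- do.call(rbind, lapply(doc$annotations, function(an) {
    for (key in c("id", "image_id", "bbox"))
      if (is.null(an[[key]]))
        stop_format("COCO file %s: annotation missing 'annotations.%s'", path, key)
    bb <- as.numeric(unlist(an$bbox))
    if (length(bb) != 4)
      stop_format("COCO file %s: 'annotations.bbox' must have 4 elements", path)
    data.frame(id = an$id, image_id = an$image_id,
               category_id = an$category_id %||% 1L,
               x = bb[1], y = bb[2], w = bb[3], h = bb[4],
               area = an$area %||% (bb[3] * bb[4]),
               iscrowd = an$iscrowd %||% 0L)
  })) %||% data.frame(id = integer(), image_id = integer(),
                      category_id = integer(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), area = numeric(),
                      iscrowd = integer())
  categories <- do.call(rbind, lapply(doc$categories, function(ct)
    data.frame(id = ct$id, name = ct$name, stringsAsFactors = FALSE)))
  list(images = images, annotations = annotations, categories = categories)
}
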