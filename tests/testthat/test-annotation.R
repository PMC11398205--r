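test_that("instance extraction is an exact pixel partition by id", {
  # background only
  expect_equal(extract_instances(matrix(0L, 4, 4), matrix(Inf, 4, 4)), list())
  # two instances with known pixel counts
  idx <- matrix(0L, 5, 5)
  idx[1, 1:3] <- 1L
  idx[3:4, 2:4] <- 2L; idx[5, 5] <- 2L
  dep <- matrix(Inf, 5, 5)
  dep[idx == 1L] <- 2.0
  dep[idx == 2L] <- c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0)
  inst <- extract_instances(idx, dep)
  expect_length(inst, 2)
  expect_equal(vapply(inst, `[[`, 1L, "pixel_count"), c(3L, 7L))
  expect_equal(inst[[1]]$representative_depth, 2.0)
  expect_equal(inst[[2]]$representative_depth, median(dep[idx == 2L]))
  # full coverage is one instance of H*W pixels
  full <- extract_instances(matrix(1L, 5, 5), matrix(2, 5, 5))
  expect_length(full, 1)
  expect_equal(full[[1]]$pixel_count, 25L)
  expect_error(extract_instances(matrix(0L, 3, 3), matrix(Inf, 2, 2)),
               class = "finsim_invalid_argument")
})

test_that("filtering applies the pixel rule before the depth rule", {
  mk <- function(id, n, d) structure(
    list(instance_id = id,
         pixel_coords = cbind(row = rep(0L, n), col = seq_len(n) - 1L),
         pixel_count = n, representative_depth = d),
    class = "instance_mask")
  inst <- list(mk(1L, 3L, 1), mk(2L, 7L, 1), mk(3L, 50L, 4), mk(4L, 2L, 9))
  # a no-op filter keeps everything
  kept <- filter_instances(inst, annotation_filter(1, Inf))
  expect_length(kept, 4)
  # min_pixels = 5: only the large masks survive the first rule
  kept2 <- filter_instances(inst, annotation_filter(5, Inf))
  expect_equal(vapply(kept2, `[[`, 1L, "instance_id"), c(2L, 3L))
  # depth threshold excludes with reason "depth"; a mask failing both rules
  # reports "pixel_count" because that rule runs first
  kept3 <- filter_instances(inst, annotation_filter(5, 3.5))
  expect_equal(vapply(kept3, `[[`, 1L, "instance_id"), 2L)
  ex <- attr(kept3, "excluded")
  expect_equal(ex$reason[ex$instance_id == 3L], "depth")
  expect_equal(ex$reason[ex$instance_id == 4L], "pixel_count")
})

test_that("records carry tight COCO boxes and mask centroids", {
  mk <- function(coords, d = 1) structure(
    list(instance_id = 1L,
         pixel_coords = cbind(row = coords[, 1], col = coords[, 2]),
         pixel_count = nrow(coords), representative_depth = d),
    class = "instance_mask")
  # singleton pixel at (row 4, col 9)
  r1 <- instance_record(mk(cbind(4L, 9L)))
  expect_equal(r1$bbox, c(9, 4, 1, 1))
  expect_equal(unname(r1$center), c(9, 4))
  expect_equal(r1$area_px, 1L)
  # two pixels spanning (1,1) and (3,5)
  r2 <- instance_record(mk(rbind(c(1L, 1L), c(3L, 5L))))
  expect_equal(r2$bbox, c(1, 1, 5, 3))
  # area never exceeds the box area (random masks)
  set.seed(8)
  for (k in 1:20) {
    n <- sample(1:30, 1)
    coords <- unique(cbind(sample(0:15, n, TRUE), sample(0:15, n, TRUE)))
    r <- instance_record(mk(coords))
    expect_lte(r$area_px, r$bbox[3] * r$bbox[4])
    expect_gte(r$bbox[3], 1); expect_gte(r$bbox[4], 1)
  }
})

test_that("frame annotation equals the brute-force pixel scan", {
  # empty frame
  empty <- layered_frame(array(0, c(6, 6, 3)), matrix(Inf, 6, 6),
                         matrix(0L, 6, 6))
  expect_length(annotate_frame(empty, annotation_filter(1, Inf)), 0)
  # constructed two-fish frame with one fish beyond the depth cut
  idx <- matrix(0L, 10, 10)
  idx[2:4, 2:5] <- 1L     # near fish, 12 px
  idx[7:9, 6:9] <- 2L     # far fish, 12 px
  dep <- matrix(Inf, 10, 10)
  dep[idx == 1L] <- 1.5; dep[idx == 2L] <- 4.0
  fr <- layered_frame(array(0.5, c(10, 10, 3)), dep, idx)
  recs <- annotate_frame(fr, annotation_filter(min_pixels = 5, max_depth = 3))
  expect_length(recs, 1)
  expect_equal(recs[[1]]$instance_id, 1L)
  expect_equal(attr(recs, "excluded")$reason, "depth")
  # oracle equivalence on randomized frames
  set.seed(21)
  for (k in 1:25) {
    frk <- random_layered_frame(32, 32, 6)
    filt <- annotation_filter(min_pixels = sample(c(1, 5, 20), 1),
                              max_depth = sample(c(2, 4, Inf), 1))
    got <- annotate_frame(frk, filt)
    want <- oracle_annotate(frk, filt)
    expect_length(got, length(want))
    for (m in seq_along(got)) {
      expect_equal(got[[m]]$instance_id, want[[m]]$instance_id)
      expect_equal(got[[m]]$bbox, want[[m]]$bbox)
      expect_equal(got[[m]]$area_px, want[[m]]$area_px)
      expect_equal(unname(got[[m]]$center), want[[m]]$center)
      expect_equal(got[[m]]$depth, want[[m]]$depth)
    }
  }
})

test_that("record count responds monotonically to the filter thresholds", {
  set.seed(31)
  fr <- random_layered_frame(48, 48, 8)
  n_at <- function(mp, md)
    length(annotate_frame(fr, annotation_filter(mp, md)))
  counts_mp <- vapply(c(1, 10, 50, 200), n_at, numeric(1), md = Inf)
  expect_true(all(diff(counts_mp) <= 0))
  counts_md <- vapply(c(1, 2, 4, Inf), n_at, numeric(1), mp = 1)
  expect_true(all(diff(counts_md) >= 0))
  # boxes lie within the image bounds and area equals pixel count
  for (rec in annotate_frame(fr, annotation_filter(1, Inf))) {
    expect_gte(rec$bbox[1], 0); expect_gte(rec$bbox[2], 0)
    expect_lte(rec$bbox[1] + rec$bbox[3], 48)
    expect_lte(rec$bbox[2] + rec$bbox[4], 48)
    expect_equal(rec$area_px, sum(fr$index == rec$instance_id))
  }
})

test_that("COCO files hold the standard structure and round-trip boxes", {
  # empty dataset is still a valid file
  p0 <- tempfile(fileext = ".json")
  write_coco(list(), data.frame(id = integer(), file_name = character(),
                                width = integer(), height = integer()), p0)
  cc0 <- read_coco(p0)
  expect_equal(nrow(cc0$images), 0)
  expect_equal(nrow(cc0$annotations), 0)
  expect_equal(cc0$categories$name, "fish")
  # one image, two records
  idx <- matrix(0L, 6, 6); idx[1:2, 1:2] <- 1L; idx[4:5, 3:6] <- 2L
  dep <- matrix(Inf, 6, 6); dep[idx > 0] <- 2
  fr <- layered_frame(array(0, c(6, 6, 3)), dep, idx)
  recs <- annotate_frame(fr, annotation_filter(1, Inf))
  p1 <- tempfile(fileext = ".json")
  write_coco(list(recs), data.frame(id = 7L, file_name = "f.png",
                                    width = 6L, height = 6L), p1)
  cc1 <- read_coco(p1)
  expect_equal(cc1$annotations$id, c(1, 2))
  expect_true(all(cc1$annotations$image_id == 7))
  expect_equal(cc1$annotations$category_id, c(1, 1))
  expect_true(all(cc1$annotations$iscrowd == 0))
  # round trip of many random records is bit-exact on boxes and areas
  set.seed(77)
  frames <- replicate(10, random_layered_frame(24, 24, 5), simplify = FALSE)
  anns <- lapply(frames, annotate_frame, filter = annotation_filter(1, Inf))
  imgs <- data.frame(id = 1:10, file_name = sprintf("fr%02d.png", 1:10),
                     width = 24L, height = 24L)
  p2 <- tempfile(fileext = ".json")
  write_coco(anns, imgs, p2)
  back <- read_coco(p2)
  flat <- do.call(rbind, lapply(seq_along(anns), function(i)
    do.call(rbind, lapply(anns[[i]], function(r)
      c(i, r$bbox, r$area_px)))))
  expect_equal(nrow(back$annotations), nrow(flat))
  expect_identical(as.numeric(back$annotations$x), as.numeric(flat[, 2]))
  expect_identical(as.numeric(back$annotations$y), as.numeric(flat[, 3]))
  expect_identical(as.numeric(back$annotations$w), as.numeric(flat[, 4]))
  expect_identical(as.numeric(back$annotations$h), as.numeric(flat[, 5]))
  expect_identical(as.numeric(back$annotations$area), as.numeric(flat[, 6]))
  # error contracts
  expect_error(write_coco(list(list(), list()),
                          data.frame(id = c(1L, 1L), file_name = c("a", "b"),
                                     width = 4L, height = 4L),
                          tempfile()),
               class = "finsim_invalid_argument")
  pbad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(info = list(), licenses = list(),
                            categories = list(), images = list()),
                       pbad, auto_unbox = TRUE)
  expect_error(read_coco(pbad), "annotations", class = "finsim_format_error")
  pbad2 <- tempfile(fileext = ".json")
  writeLines('{"info": {}, "licenses": [], "categories": [], "images": [{"id": 1}], "annotations": []}', pbad2)
  expect_error(read_coco(pbad2), "images.file_name",
               class = "finsim_format_error")
})
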