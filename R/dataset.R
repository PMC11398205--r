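#' Image-record manifests
#'
#' A manifest is a data frame with one row per image and columns `path`,
#' `source` (`"virtual"` or `"real"`), `annotation_ref` (path or id of the
#' image's annotation payload, `NA` when none) and `split` (`"train"`,
#' `"val"`, `"test"` or `"unassigned"`). `image_manifest()` builds a
#' validated manifest; [read_manifest()]/[write_manifest()] round-trip it as
#' tab-delimited text with a header line.
#'
#' @param path Character vector of image paths.
#' @param source `"virtual"` or `"real"`, recycled to length of `path`.
#' @param annotation_ref Annotation references, recycled; default `NA`.
#' @param split Initial split labels, recycled; default `"unassigned"`.
#' @return A manifest data frame.
#' @export
image_manifest <- function(path, source, annotation_ref = NA_character_,
                           split = "unassigned") {
  m <- data.frame(path = as.character(path),
                  source = as.character(source),
                  annotation_ref = as.character(annotation_ref),
                  split = as.character(split),
                  stringsAsFactors = FALSE)
  if (!all(m$source %in% c("virtual", "real")))
    stop_invalid("source must be 'virtual' or 'real'")
  if (!all(m$split %in% c("train", "val", "test", "unassigned")))
    stop_invalid("split must be train/val/test/unassigned")
  m
}

#' @rdname image_manifest
#' @param manifest A manifest data frame.
#' @param file File path for the tab-delimited manifest.
#' @export
write_manifest <- function(manifest, file) {
  utils::write.table(manifest, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname image_manifest
#' @export
read_manifest <- function(file) {
  m <- utils::read.table(file, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("path", "source", "annotation_ref", "split")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_format("manifest %s missing column(s): %s", file,
                paste(miss, collapse = ", "))
  image_manifest(m$path, m$source, m$annotation_ref, m$split)
}

#' Virtual/real mixing specification
#'
#' How many of the training images are virtual renders versus real
#' photographs. The benchmark design this reproduces trains on 700 images
#' and sweeps the virtual share through
#' 100:0, 99:1, 98:2, 96:4, 94:6, 92:8, 90:10, 75:25, 50:50 and 0:100.
#'
#' @param total_train Total training images, `>= 1`.
#' @param virtual_pct Percentage of virtual images.
#' @param real_pct Percentage of real images; must sum with `virtual_pct`
#'   to 100.
#' @return An object of class `"mix_spec"`.
#' @export
mix_spec <- function(total_train, virtual_pct, real_pct = 100 - virtual_pct) {
  if (abs(virtual_pct + real_pct - 100) > 1e-9)
    stop_invalid("virtual_pct + real_pct must equal 100")
  if (virtual_pct < 0 || real_pct < 0) stop_invalid("percentages must be >= 0")
  if (total_train < 1) stop_invalid("total_train must be >= 1")
  structure(list(total_train = as.integer(total_train),
                 virtual_pct = virtual_pct, real_pct = real_pct),
            class = "mix_spec")
}

#' Virtual/real image counts for a mix
#'
#' `n_virtual = round(total_train * virtual_pct / 100)` and
#' `n_real = total_train - n_virtual`, so the total is always conserved. In
#' strict mode a mix whose virtual share is not an exact integer raises an
#' error instead of rounding — every row of the 700-image benchmark design is
#' exact, so strict mode passes for all of them.
#'
#' @param spec A [mix_spec()].
#' @param strict If `TRUE`, refuse non-integral splits.
#' @return Named integer vector `c(n_virtual, n_real)`.
#' @examples
#' mix_counts(mix_spec(700, 90))   # 630 virtual, 70 real
#' mix_counts(mix_spec(700, 99))   # 693 virtual, 7 real
#' @export
mix_counts <- function(spec, strict = FALSE) {
  exact <- spec$total_train * spec$virtual_pct / 100
  if (strict && abs(exact - round(exact)) > 1e-9)
    stop_invalid("mix %s:%s of %d images is not integral (%.3f virtual)",
                 format(spec$virtual_pct), format(spec$real_pct),
                 spec$total_train, exact)
  n_virtual <- as.integer(round(exact))
  c(n_virtual = n_virtual, n_real = spec$total_train - n_virtual)
}

# largest-remainder apportionment of n into shares proportional to pct
largest_remainder <- function(n, pct) {
  quota <- n * pct / 100
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign train/val/test splits with real-only validation and test
#'
#' Partitions a pool of image records into train/val/test at the given
#' percentages (largest-remainder rounding, so the three sizes always sum to
#' the pool size). Validation and test images are drawn exclusively from the
#' real records — the design constraint that lets a virtually trained
#' detector be judged on real imagery — after a seeded shuffle; everything
#' else becomes training data. If the pool holds fewer real images than
#' val + test require, an infeasibility error states the shortfall.
#'
#' @param pool A manifest data frame (see [image_manifest()]).
#' @param proportions Length-3 percentages `(train, val, test)` summing
#'   to 100.
#' @param seed Integer seed for the shuffle.
#' @return The pool with its `split` column assigned.
#' @examples
#' pool <- image_manifest(sprintf("img%03d.png", 1:100),
#'                        rep(c("virtual", "real"), c(60, 40)))
#' table(build_split(pool, c(70, 20, 10), seed = 1)$split)
#' @export
build_split <- function(pool, proportions = c(70, 20, 10), seed = 1L) {
  if (length(proportions) != 3 || abs(sum(proportions) - 100) > 1e-9)
    stop_invalid("proportions must be three percentages summing to 100")
  n <- nrow(pool)
  sizes <- largest_remainder(n, proportions)     # train, val, test
  real_idx <- which(pool$source == "real")
  need_real <- sizes[2] + sizes[3]
  if (length(real_idx) < need_real)
    stop_infeasible("val+test need %d real images but the pool has only %d (short by %d)",
                    need_real, length(real_idx), need_real - length(real_idx))
  with_seed(seed, {
    real_shuffled <- sample(real_idx)
    val_idx <- real_shuffled[seq_len(sizes[2])]
    test_idx <- real_shuffled[sizes[2] + seq_len(sizes[3])]
  })
  pool$split <- "train"
  pool$split[val_idx] <- "val"
  pool$split[test_idx] <- "test"
  pool
}

#' Build a mixed training manifest
#'
#' Convenience composition of [mix_counts()] and [build_split()]: selects
#' `n_virtual` virtual and `n_real` real training candidates (seeded
#' sampling), appends the real images reserved for validation/test, and
#' assigns splits. `virtual` and `real` are manifests of available images.
#'
#' @param virtual Manifest of available virtual images.
#' @param real Manifest of available real images.
#' @param mix A [mix_spec()] for the training set.
#' @param split_proportions Passed to [build_split()].
#' @param seed Integer seed.
#' @return A manifest with splits assigned; training rows honour the mix
#'   exactly.
#' @export
build_mixed_manifest <- function(virtual, real, mix,
                                 split_proportions = c(70, 20, 10),
                                 seed = 1L) {
  counts <- mix_counts(mix, strict = TRUE)
  n_train <- mix$total_train
  pool_n <- round(n_train * 100 / split_proportions[1])
  sizes <- largest_remainder(pool_n, split_proportions)
  if (sizes[1] != n_train)
    stop_invalid("total_train %d is inconsistent with a %s%% training share",
                 n_train, format(split_proportions[1]))
  need_real <- counts["n_real"] + sizes[2] + sizes[3]
  if (nrow(real) < need_real)
    stop_infeasible("need %d real images (train %d + val %d + test %d) but have %d",
                    need_real, counts["n_real"], sizes[2], sizes[3], nrow(real))
  if (nrow(virtual) < counts["n_virtual"])
    stop_infeasible("need %d virtual images but have %d",
                    counts["n_virtual"], nrow(virtual))
  with_seed(seed, {
    v_pick <- sample(nrow(virtual), counts["n_virtual"])
    r_pick <- sample(nrow(real), need_real)
  })
  pool <- rbind(virtual[v_pick, , drop = FALSE],
                real[r_pick, , drop = FALSE])
  rownames(pool) <- NULL
  build_split(pool, split_proportions, seed = seed + 1L)
}
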