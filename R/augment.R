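#' Photometric augmentation specification
#'
#' The augmentation recipe applied to training images: each image yields
#' `multiplier` augmented variants (appended alongside the original by
#' default — "2X" augmentation triples nothing geometric, only photometry),
#' each with independently sampled brightness, exposure, saturation and blur
#' factors. All transforms are photometric, so bounding boxes carry over
#' unchanged.
#'
#' Ranges follow the common annotation-platform convention: brightness and
#' exposure ±25%, saturation ±25%, blur up to ±5%. The blur percentage has
#' no published unit; here it is interpreted as a Gaussian sigma of up to
#' `blur_range * diagonal / 100` pixels (about 1.1 px at 1920 x 1080).
#'
#' @param multiplier Augmented variants per image, `>= 1` (default 2).
#' @param brightness_range Additive shift range as a fraction of full scale.
#' @param exposure_range Multiplicative gain range about 1.
#' @param saturation_range Saturation scale range about 1.
#' @param blur_range Blur fraction (see Details).
#' @param seed Default RNG seed used by [augment_image()] when none is given.
#' @return An object of class `"augment_spec"`.
#' @export
augment_spec <- function(multiplier = 2L, brightness_range = 0.25,
                         exposure_range = 0.25, saturation_range = 0.25,
                         blur_range = 0.05, seed = 1L) {
  if (multiplier < 1) stop_invalid("multiplier must be >= 1")
  if (any(c(brightness_range, exposure_range, saturation_range, blur_range) < 0))
    stop_invalid("augmentation ranges must be >= 0")
  structure(list(multiplier = as.integer(multiplier),
                 brightness_range = brightness_range,
                 exposure_range = exposure_range,
                 saturation_range = saturation_range,
                 blur_range = blur_range, seed = as.integer(seed)),
            class = "augment_spec")
}

#' Augment one RGB image
#'
#' Produces `spec$multiplier` photometric variants of `rgb`. Per variant the
#' sampled transforms are applied in a fixed order:
#' exposure gain `g ~ U(1 - r_e, 1 + r_e)`, additive brightness shift
#' `b ~ U(-r_b, r_b)`, saturation scale `s ~ U(1 - r_s, 1 + r_s)` about the
#' per-pixel Rec.601 luma, then Gaussian blur with
#' `sigma ~ U(0, blur_range * diagonal / 100)` pixels (skipped below a third
#' of a pixel). The result is clipped to `[0,1]`. Deterministic for a given
#' seed; the caller's RNG state is untouched.
#'
#' @param rgb H x W x 3 array in `[0,1]`.
#' @param spec An [augment_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return List of `spec$multiplier` augmented H x W x 3 arrays.
#' @examples
#' img <- array(runif(12), c(2, 2, 3))
#' out <- augment_image(img, augment_spec(multiplier = 2), seed = 7)
#' length(out)
#' @export
augment_image <- function(rgb, spec, seed = spec$seed) {
  if (min(rgb) < -1e-9 || max(rgb) > 1 + 1e-9)
    stop_invalid("rgb must lie in [0,1]")
  dims <- dim(rgb)
  diag_px <- sqrt(dims[1]^2 + dims[2]^2)
  with_seed(seed, {
    lapply(seq_len(spec$multiplier), function(k) {
      g <- stats::runif(1, 1 - spec$exposure_range, 1 + spec$exposure_range)
      b <- stats::runif(1, -spec$brightness_range, spec$brightness_range)
      s <- stats::runif(1, 1 - spec$saturation_range, 1 + spec$saturation_range)
      sigma <- stats::runif(1, 0, spec$blur_range * diag_px / 100)
      out <- rgb * g + b
      luma <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
      for (c in 1:3) out[, , c] <- luma + s * (out[, , c] - luma)
      if (sigma >= 0.3) out <- as.array(safe_gblur(out, sigma))
      out[out < 0] <- 0; out[out > 1] <- 1
      out
    })
  })
}
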