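#' Compose a training image from kept instances
#'
#' Builds the image half of a training pair: pixels covered by the filtered
#' label map keep their original intensity, everything else becomes black
#' (0). Idempotent.
#'
#' @param image An [intensity_image()].
#' @param filtered Filtered label map of the same shape.
#' @return An [intensity_image()] supported exactly on `filtered > 0`.
#' @export
compose_training_image <- function(image, filtered) {
  if (!all(dim(image) == dim(filtered)))
    abort("image and filtered label map shapes differ")
  out <- image
  out[filtered == 0L] <- 0L
  intensity_image(matrix(out, nrow(image), ncol(image)), image_bit_depth(image))
}

#' Add random noise to the composed background
#'
#' A composed training image has a perfectly homogeneous black background,
#' unlike any real micrograph; segmentation networks trained on it fit the
#' training set but generalize poorly. This step restores background
#' inhomogeneity by adding random noise — Gaussian (`mean`, `sd`) or uniform
#' on `center +/- halfwidth` — to the pixels in scope, then clipping to the
#' bit-depth range. With `scope = "background_only"` (default) foreground
#' pixels are bit-identical to the input, preserving the annotation signal;
#' negative noise on the zero background clips to 0, so the effective
#' background distribution is half-truncated. Deterministic given `seed`.
#'
#' @param image Composed [intensity_image()].
#' @param filtered Label map defining the foreground (`> 0`).
#' @param distribution `"gaussian"` or `"uniform"`.
#' @param sd_or_halfwidth Noise amplitude in intensity units (Gaussian sd,
#'   or half-width of the uniform); 0 returns the input unchanged.
#' @param mean_or_center Center of the noise distribution (default 0).
#' @param scope `"background_only"` or `"whole_image"`.
#' @param seed Integer seed.
#' @return An [intensity_image()].
#' @export
add_background_noise <- function(image, filtered,
                                 distribution = c("gaussian", "uniform"),
                                 sd_or_halfwidth = 3, mean_or_center = 0,
                                 scope = c("background_only", "whole_image"),
                                 seed = 1L) {
  distribution <- match.arg(distribution)
  scope <- match.arg(scope)
  if (!all(dim(image) == dim(filtered)))
    abort("image and filtered label map shapes differ")
  if (sd_or_halfwidth < 0) abort("noise amplitude must be >= 0")
  bd <- image_bit_depth(image)
  if (sd_or_halfwidth == 0 && mean_or_center == 0) return(intensity_image(image, bd))
  out <- with_seed(seed, {
    noise <- if (distribution == "gaussian") {
      rnorm(length(image), mean_or_center, sd_or_halfwidth)
    } else {
      runif(length(image), mean_or_center - sd_or_halfwidth,
            mean_or_center + sd_or_halfwidth)
    }
    y <- as.numeric(image)
    if (scope == "background_only") {
      bg <- as.integer(filtered) == 0L
      y[bg] <- y[bg] + noise[bg]
    } else {
      y <- y + noise
    }
    pmin(pmax(round(y), 0), bit_range(bd))
  })
  intensity_image(matrix(out, nrow(image), ncol(image)), bd)
}
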