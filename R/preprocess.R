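#' Convert pixel depth with optional intensity normalization
#'
#' Prepares raw microscopy data for thresholding and network export.
#' `minmax` maps the observed `[min, max]` onto the full target range;
#' `percentile` first clips at the `(p_lo, p_hi)` intensity percentiles
#' (robust to hot pixels in 16-bit widefield data) and then rescales;
#' `none` rescales linearly between bit-depth ranges without clipping.
#' A constant image maps to all zeros by convention. The mapping is
#' monotone: `x <= y` in the input implies `f(x) <= f(y)`.
#'
#' @param image An [intensity_image()].
#' @param target_bit_depth 8, 16, or `"keep"`.
#' @param normalize One of `"percentile"`, `"minmax"`, `"none"`.
#' @param p_lo,p_hi Percentiles (0-100) used by `normalize = "percentile"`.
#' @return An [intensity_image()] at the target bit depth.
#' @export
convert_depth <- function(image, target_bit_depth = 8L,
                          normalize = c("percentile", "minmax", "none"),
                          p_lo = 1, p_hi = 99) {
  normalize <- match.arg(normalize)
  in_depth <- image_bit_depth(image)
  out_depth <- if (identical(target_bit_depth, "keep")) in_depth
               else as.integer(target_bit_depth)
  out_max <- bit_range(out_depth)
  x <- as.numeric(image)

  if (normalize == "none") {
    y <- x * (out_max / bit_range(in_depth))
  } else {
    if (normalize == "minmax") {
      lo <- min(x); hi <- max(x)
    } else {
      if (!(p_lo < p_hi)) abort("`p_lo` must be smaller than `p_hi`.")
      qs <- quantile(x, c(p_lo, p_hi) / 100, names = FALSE, type = 7)
      lo <- qs[1]; hi <- qs[2]
    }
    if (hi <= lo) {
      y <- rep(0, length(x))   # constant (or degenerate clip window)
    } else {
      y <- (pmin(pmax(x, lo), hi) - lo) / (hi - lo) * out_max
    }
  }
  intensity_image(matrix(round(y), nrow(image), ncol(image)), out_depth)
}

#' Tile an image for fixed-size network input
#'
#' Cuts the image into square tiles of `tile_size` with the requested
#' overlap. Interior tiles advance by `tile_size - tile_overlap`; the final
#' row/column tiles are anchored to the image edge (so they may overlap
#' more), guaranteeing that every pixel is covered at least once without
#' fabricating padded pixels. An image smaller than `tile_size` yields a
#' single zero-padded tile with a warning.
#'
#' @param image An [intensity_image()].
#' @param tile_size Tile edge length in pixels (>= 64).
#' @param tile_overlap Overlap in pixels; `tile_size >= 2 * tile_overlap`.
#' @return Tibble with 0-based top-left offsets `row0`, `col0` and a `tile`
#'   list-column of integer matrices.
#' @export
tile_image <- function(image, tile_size, tile_overlap = 0L) {
  tile_size <- as.integer(tile_size); tile_overlap <- as.integer(tile_overlap)
  if (tile_size < 64L) abort("`tile_size` must be at least 64 pixels.")
  if (tile_overlap < 0L || tile_size < 2L * tile_overlap)
    abort("`tile_overlap` must satisfy 0 <= overlap <= tile_size / 2.")
  h <- nrow(image); w <- ncol(image)
  if (h < tile_size || w < tile_size) {
    warn("image smaller than tile size; emitting one zero-padded tile")
    pad <- matrix(0L, tile_size, tile_size)
    pad[seq_len(h), seq_len(w)] <- image
    return(tibble::tibble(row0 = 0L, col0 = 0L, tile = list(pad)))
  }
  offsets_1d <- function(extent) {
    step <- tile_size - tile_overlap
    off <- seq(0L, extent - tile_size, by = step)
    if (off[length(off)] + tile_size < extent) off <- c(off, extent - tile_size)
    as.integer(off)
  }
  grid <- expand.grid(row0 = offsets_1d(h), col0 = offsets_1d(w))
  tiles <- purrr::map2(grid$row0, grid$col0, function(r0, c0) {
    m <- image[(r0 + 1L):(r0 + tile_size), (c0 + 1L):(c0 + tile_size)]
    matrix(as.integer(m), tile_size, tile_size)
  })
  tibble::tibble(row0 = as.integer(grid$row0), col0 = as.integer(grid$col0),
                 tile = tiles)
}
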