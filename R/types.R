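#' Construct an intensity image
#'
#' An intensity image is an integer matrix of pixel values with a declared
#' bit depth (8 or 16), stored as the `bit_depth` attribute. Pixels are
#' indexed `(row, col)`, 0-based in all exported coordinate tables.
#'
#' @param x Numeric or integer matrix of non-negative pixel values.
#' @param bit_depth Either 8 or 16. Values must fit in `[0, 2^bit_depth - 1]`.
#' @return An integer matrix with attribute `bit_depth`.
#' @export
intensity_image <- function(x, bit_depth = 8L) {
  if (!is.matrix(x)) abort("`x` must be a matrix.")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  maxval <- bit_range(bit_depth)
  v <- as.integer(round(x))
  if (anyNA(v)) abort("image contains missing pixel values")
  if (min(v) < 0L || max(v) > maxval) {
    abort(sprintf("pixel values outside [0, %d] for bit depth %d", maxval, bit_depth))
  }
  out <- matrix(v, nrow = nrow(x), ncol = ncol(x))
  attr(out, "bit_depth") <- bit_depth
  out
}

bit_range <- function(bit_depth) as.integer(2L^as.integer(bit_depth) - 1L)

#' @rdname intensity_image
#' @export
image_bit_depth <- function(x) {
  bd <- attr(x, "bit_depth")
  if (is.null(bd)) {
    bd <- if (max(x) > 255) 16L else 8L
  }
  as.integer(bd)
}

#' Construct or validate an instance label map
#'
#' A label map is an integer matrix: 0 marks background, each positive value
#' `k` marks the pixels of instance `k`. Label identity is not semantic;
#' operations are free to relabel, and all comparisons in this package are
#' permutation-invariant.
#'
#' @param x Integer matrix with values >= 0.
#' @return The validated integer matrix.
#' @export
label_map <- function(x) {
  if (!is.matrix(x)) abort("`x` must be a matrix.")
  v <- as.integer(x)
  if (anyNA(v) || min(v) < 0L) abort("label map must contain non-negative integers")
  matrix(v, nrow = nrow(x), ncol = ncol(x))
}

label_ids <- function(labelmap) {
  u <- sort(unique(as.integer(labelmap)))
  u[u > 0L]
}

#' Renumber labels to 1..K
#'
#' Renumbers the positive labels of a label map to consecutive integers
#' 1..K in increasing order of the original label values, preserving
#' instance identity. Idempotent.
#'
#' @param labelmap Integer label map.
#' @return Relabelled integer matrix.
#' @export
relabel_sequential <- function(labelmap) {
  ids <- label_ids(labelmap)
  if (length(ids) == 0L) return(label_map(labelmap))
  out <- match(as.integer(labelmap), ids, nomatch = 0L)
  matrix(as.integer(out), nrow = nrow(labelmap), ncol = ncol(labelmap))
}

# Internal: run code with a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

as_matrix <- function(x) {
  # EBImage returns Image objects; collapse back to a plain matrix
  m <- as.matrix(x)
  dimnames(m) <- NULL
  m
}
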