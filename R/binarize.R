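#' Otsu's automatic threshold
#'
#' Finds the global intensity threshold separating nuclei from background by
#' minimizing the intra-class variance
#' \deqn{\sigma_W^2(t) = W_0(t)\,\sigma_0^2(t) + W_1(t)\,\sigma_1^2(t),}
#' the weighted sum of the variances of the two classes split at candidate
#' threshold `t` (class 0: values `<= t`; class 1: values `> t`).
#' Candidates are the boundaries of `n_bins` equal-width histogram bins over
#' the observed `[min, max]`; class moments are accumulated from the exact
#' pixel values inside each bin, so the scan is exact whenever distinct
#' values fall in distinct bins. Candidates leaving a class empty are
#' skipped (the criterion is undefined there); ties take the smallest
#' threshold.
#'
#' @param image An [intensity_image()] (or numeric matrix) with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins (default 256, independent of bit
#'   depth).
#' @return Object of class `otsu_result`: list with `threshold` (intensity
#'   units), `scan` (tibble of `t`, `w0`, `w1`, `var0`, `var1`, `sigma_w2`
#'   over all valid candidates), and `n_bins`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("`n_bins` must be at least 2.")
  x <- as.numeric(image)
  mn <- min(x); mx <- max(x)
  if (mx == mn)
    abort("constant image: no two-class split exists (degenerate input)")
  width <- (mx - mn) / n_bins
  b <- pmin(floor((x - mn) / width), n_bins - 1)   # 0-based bin index
  b1 <- as.integer(b) + 1L
  cnt <- tabulate(b1, nbins = n_bins)
  s <- s2 <- numeric(n_bins)
  rs <- rowsum(cbind(x, x^2), group = b1, reorder = TRUE)
  present <- as.integer(rownames(rs))
  s[present] <- rs[, 1]; s2[present] <- rs[, 2]

  n <- length(x)
  c_cnt <- cumsum(cnt); c_s <- cumsum(s); c_s2 <- cumsum(s2)
  k <- seq_len(n_bins - 1L)                        # boundary after bin k
  n0 <- c_cnt[k]; n1 <- n - n0
  valid <- n0 > 0L & n1 > 0L
  if (!any(valid)) abort("no candidate threshold splits the image into two non-empty classes")
  k <- k[valid]; n0 <- n0[valid]; n1 <- n1[valid]
  m0 <- c_s[k] / n0; m1 <- (c_s[n_bins] - c_s[k]) / n1
  v0 <- pmax(c_s2[k] / n0 - m0^2, 0)
  v1 <- pmax((c_s2[n_bins] - c_s2[k]) / n1 - m1^2, 0)
  w0 <- n0 / n; w1 <- n1 / n
  sigma_w2 <- w0 * v0 + w1 * v1
  best <- which.min(sigma_w2)                      # first minimum = smallest t

  scan <- tibble::tibble(t = mn + k * width, w0 = w0, w1 = w1,
                         var0 = v0, var1 = v1, sigma_w2 = sigma_w2)
  structure(list(threshold = scan$t[best], scan = scan, n_bins = n_bins),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("Otsu threshold: %.4g (%d bins, %d candidates scanned)\n",
              x$threshold, x$n_bins, nrow(x$scan)))
  invisible(x)
}

#' Apply an intensity threshold
#'
#' Foreground is strictly above the threshold: `mask = image > t`.
#'
#' @param image An [intensity_image()] or numeric matrix.
#' @param t Threshold in intensity units (e.g. `otsu_threshold(image)$threshold`).
#' @return Logical matrix, `TRUE` = foreground.
#' @export
apply_threshold <- function(image, t) {
  m <- matrix(as.numeric(image) > t, nrow(image), ncol(image))
  m
}
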