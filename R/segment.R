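#' 8-connected component labelling
#'
#' Labels each connected set of foreground pixels with a distinct positive
#' integer, in deterministic column-major order of first encounter.
#'
#' @param binary Logical matrix (`TRUE` = foreground).
#' @param connectivity 8 (default) or 4.
#' @return Integer label map with sequential labels 1..K.
#' @export
connected_components <- function(binary, connectivity = 8L) {
  m <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  if (anyNA(m)) abort("binary mask contains missing values")
  cpp_label_components(m, as.integer(connectivity))
}

#' Seed markers from distance-transform peaks
#'
#' Computes the Euclidean distance transform of the foreground and places
#' one marker per local maximum, thinned so accepted peaks are at least
#' `min_peak_distance` apart (greedy, by decreasing peak height). Every
#' connected foreground component is guaranteed at least one marker: a
#' component whose peaks were all suppressed receives a marker at its
#' distance-transform maximum. An empty foreground yields an empty marker
#' map (not an error).
#'
#' @param binary Logical foreground mask.
#' @param min_peak_distance Minimum distance between markers in pixels; the
#'   canonical choice is about 0.7 times the expected nucleus radius.
#' @return List of class `marker_map`: `markers` (integer matrix, one
#'   labelled pixel per marker), `n_markers`, and `distance` (the distance
#'   transform).
#' @export
make_markers <- function(binary, min_peak_distance = 7) {
  m <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  markers <- matrix(0L, nrow(m), ncol(m))
  if (!any(m)) {
    return(structure(list(markers = markers, n_markers = 0L,
                          distance = matrix(0, nrow(m), ncol(m))),
                     class = "marker_map"))
  }
  dist <- as_matrix(EBImage::distmap(m, metric = "euclidean"))

  # local maxima: pixels attaining the max of their neighbourhood
  win <- 2L * max(1L, floor(min_peak_distance / 2)) + 1L
  dil <- as_matrix(EBImage::dilate(dist, EBImage::makeBrush(win, shape = "box")))
  peak <- which(m & dist >= dil & dist > 0)
  pr <- (peak - 1L) %% nrow(m) + 1L
  pc <- (peak - 1L) %/% nrow(m) + 1L
  ord <- order(-dist[peak], pr, pc)
  pr <- pr[ord]; pc <- pc[ord]

  acc_r <- integer(0); acc_c <- integer(0)
  for (i in seq_along(pr)) {
    if (length(acc_r) == 0L ||
        all((pr[i] - acc_r)^2 + (pc[i] - acc_c)^2 >= min_peak_distance^2)) {
      acc_r <- c(acc_r, pr[i]); acc_c <- c(acc_c, pc[i])
    }
  }

  # fallback: every component must carry a marker
  comps <- connected_components(m, 8L)
  seeded <- unique(comps[cbind(acc_r, acc_c)])
  for (k in setdiff(seq_len(max(comps)), seeded)) {
    idx <- which(comps == k)
    top <- idx[which.max(dist[idx])]
    acc_r <- c(acc_r, (top - 1L) %% nrow(m) + 1L)
    acc_c <- c(acc_c, (top - 1L) %/% nrow(m) + 1L)
  }

  markers[cbind(acc_r, acc_c)] <- seq_along(acc_r)
  structure(list(markers = markers, n_markers = length(acc_r), distance = dist),
            class = "marker_map")
}

#' Marker-based watershed instance labelling
#'
#' Floods the negative Euclidean distance transform from the given markers,
#' restricted to the foreground: every foreground pixel receives the label
#' of exactly one marker (8-connected flooding, deterministic FIFO
#' tie-break), background stays 0, and the number of output labels equals
#' the number of markers. Touching objects are split along the ridge lines
#' of the distance transform.
#'
#' @param binary Logical foreground mask.
#' @param markers A `marker_map` from [make_markers()], or an integer marker
#'   matrix.
#' @return Integer label map.
#' @export
watershed_label <- function(binary, markers) {
  m <- matrix(as.logical(binary), nrow(binary), ncol(binary))
  if (inherits(markers, "marker_map")) {
    dist <- markers$distance
    markers <- markers$markers
  } else {
    dist <- if (any(m)) as_matrix(EBImage::distmap(m, metric = "euclidean"))
            else matrix(0, nrow(m), ncol(m))
  }
  if (!all(dim(markers) == dim(m))) abort("marker map and mask shapes differ")
  if (any(markers > 0L & !m)) abort("markers must lie inside the foreground")
  if (max(markers) == 0L) {
    if (any(m)) abort("non-empty foreground but no markers: contract violation")
    return(matrix(0L, nrow(m), ncol(m)))
  }
  cpp_watershed(dist, matrix(as.integer(markers), nrow(m), ncol(m)), m, 8L)
}

#' One-call instance segmentation of a binary mask
#'
#' Convenience wrapper: [make_markers()] then [watershed_label()], followed
#' by sequential relabelling.
#'
#' @inheritParams make_markers
#' @return Integer label map.
#' @export
segment_instances <- function(binary, min_peak_distance = 7) {
  mk <- make_markers(binary, min_peak_distance)
  relabel_sequential(watershed_label(binary, mk))
}
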