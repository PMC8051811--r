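#' Read a grayscale microscopy image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG into an
#' [intensity_image()] without rescaling. RGB inputs whose channels are
#' identical are collapsed to one channel; genuinely multi-channel images
#' are rejected.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return An [intensity_image()] with the file's bit depth.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(x) > 255) 16L else 8L
    x <- collapse_channels(x, path)
    intensity_image(x, if (bits <= 8) 8L else 16L)
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    bits <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
    x <- collapse_channels(x, path)
    intensity_image(round(x * bit_range(if (bits <= 8) 8L else 16L)),
                    if (bits <= 8) 8L else 16L)
  } else {
    abort(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  }
}

collapse_channels <- function(x, path) {
  if (length(dim(x)) == 2L) return(x)
  if (length(dim(x)) == 3L) {
    ch <- lapply(seq_len(dim(x)[3]), function(k) x[, , k])
    same <- all(vapply(ch[-1], function(m) identical(m, ch[[1]]), logical(1)))
    if (same) return(ch[[1]])
  }
  abort(sprintf("unsupported multi-channel (non-grayscale) image: %s", path))
}

#' Write a grayscale image as TIFF or PNG
#'
#' @param image An [intensity_image()] (or integer matrix).
#' @param path Output path; format chosen by extension. 16-bit data can only
#'   be written as TIFF.
#' @param bit_depth Target bit depth; defaults to the image's own.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = image_bit_depth(image)) {
  bit_depth <- as.integer(bit_depth)
  maxval <- bit_range(bit_depth)
  if (max(image) > maxval) abort("pixel values exceed the target bit depth")
  ext <- tolower(tools::file_ext(path))
  scaled <- matrix(as.numeric(image) / maxval, nrow(image), ncol(image))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bit_depth,
                    compression = "deflate")
  } else if (ext == "png") {
    if (bit_depth > 8L) abort("PNG output supports 8-bit only; use TIFF for 16-bit")
    png::writePNG(scaled, path)
  } else {
    abort(sprintf("unsupported output format '.%s'", ext))
  }
  invisible(path)
}

#' Label-map TIFF round trip
#'
#' Label maps are stored as single-channel 16-bit TIFF with background 0;
#' the round trip is lossless for up to 65535 instances.
#'
#' @param labelmap Integer label map.
#' @param path Output `.tif` path.
#' @return `write_labelmap()`: `path` invisibly; `read_labelmap()`: the
#'   integer label map.
#' @export
write_labelmap <- function(labelmap, path) {
  labelmap <- label_map(labelmap)
  if (max(labelmap) > 65535L)
    abort("label map holds more than 65535 instances; 16-bit TIFF cannot store it")
  tiff::writeTIFF(matrix(as.numeric(labelmap) / 65535, nrow(labelmap), ncol(labelmap)),
                  path, bits.per.sample = 16L, compression = "deflate")
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- tiff::readTIFF(path, as.is = TRUE)
  label_map(matrix(as.integer(x), nrow(x), ncol(x)))
}

#' Export an image/label-map pair as a per-instance mask folder
#'
#' Writes the layout used by public nuclei benchmarks (one folder per image
#' holding `images/` and `masks/` subfolders, one binary PNG per instance):
#' `<out_dir>/<id>/images/<id>.png` and `<out_dir>/<id>/masks/<k>.png`.
#' Masks are pairwise disjoint by construction of the label map, and their
#' union equals the foreground. 16-bit images are rescaled to 8-bit for the
#' PNG export.
#'
#' @param image An [intensity_image()].
#' @param labelmap Matching label map.
#' @param out_dir Output directory root.
#' @param id Folder/file stem for this image.
#' @return The image folder path, invisibly.
#' @export
export_instance_masks <- function(image, labelmap, out_dir, id = "image") {
  if (!all(dim(image) == dim(labelmap))) abort("image and label map shapes differ")
  base <- file.path(out_dir, id)
  dir.create(file.path(base, "images"), recursive = TRUE, showWarnings = FALSE)
  img8 <- if (image_bit_depth(image) > 8L)
    intensity_image(round(as.numeric(image) / 257), 8L) else image
  write_image(matrix(img8, nrow(image), ncol(image)),
              file.path(base, "images", paste0(id, ".png")), bit_depth = 8L)
  ids <- label_ids(labelmap)
  if (length(ids) == 0L) {
    warn(sprintf("label map for '%s' is empty; no masks written", id))
    return(invisible(base))
  }
  dir.create(file.path(base, "masks"), showWarnings = FALSE)
  for (k in ids) {
    m <- matrix(as.numeric(labelmap == k), nrow(labelmap), ncol(labelmap))
    png::writePNG(m, file.path(base, "masks", sprintf("%d.png", k)))
  }
  invisible(base)
}

#' Rebuild a label map from a per-instance mask folder
#'
#' Inverse of [export_instance_masks()] up to label permutation. Masks are
#' checked for pairwise disjointness.
#'
#' @param dir An image folder containing a `masks/` subfolder.
#' @return Integer label map (sequential labels in file order).
#' @export
import_instance_masks <- function(dir) {
  mdir <- file.path(dir, "masks")
  files <- sort(list.files(mdir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) abort(sprintf("no mask files under %s", mdir))
  out <- NULL
  for (i in seq_along(files)) {
    m <- png::readPNG(files[i])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    fg <- m > 0.5
    if (is.null(out)) out <- matrix(0L, nrow(fg), ncol(fg))
    if (any(out[fg] != 0L)) abort("instance masks overlap; invalid mask folder")
    out[fg] <- i
  }
  out
}

object_table_cols <- c("id", "area_px", "bbox_r0", "bbox_c0", "bbox_r1",
                       "bbox_c1", "centroid_r", "centroid_c", "kept", "class")

#' Object table CSV round trip
#'
#' Writes/reads per-instance records with the fixed header
#' `id,area_px,bbox_r0,bbox_c0,bbox_r1,bbox_c1,centroid_r,centroid_c,kept,class`.
#' Bounding boxes are 0-based half-open `[r0, r1) x [c0, c1)`.
#'
#' @param table Tibble as produced by [object_areas()].
#' @param path CSV path.
#' @return `write_object_table()`: `path` invisibly; `read_object_table()`:
#'   the tibble.
#' @export
write_object_table <- function(table, path) {
  miss <- setdiff(object_table_cols, names(table))
  for (m in miss) table[[m]] <- if (m == "class") NA_character_ else NA
  write.csv(table[object_table_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_object_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(object_table_cols, names(df))
  if (length(miss))
    abort(sprintf("malformed object table %s: missing column(s) %s",
                  path, paste(miss, collapse = ", ")))
  num_cols <- setdiff(object_table_cols, c("kept", "class"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      abort(sprintf("malformed object table %s: non-numeric '%s' at data line %d",
                    path, col, bad[1]))
    df[[col]] <- v
  }
  df$id <- as.integer(df$id)
  df$kept <- as.logical(df$kept)
  df$class <- as.character(df$class)
  tibble::as_tibble(df)
}

#' Dataset manifest
#'
#' A manifest is a JSON file listing dataset entries (image path, optional
#' label-map path, `train`/`test` split tag) relative to a root directory.
#' Loading validates that every referenced file exists and that paired
#' image/label files have identical pixel dimensions.
#'
#' @param entries Tibble or data frame with columns `image`, `labels`
#'   (optional, may be `NA`), `split`.
#' @param root Dataset root directory.
#' @param path Manifest JSON path.
#' @return `write_manifest()`: `path` invisibly; `read_manifest()`: a list
#'   with `root` and the `entries` tibble.
#' @export
write_manifest <- function(entries, root, path) {
  entries <- tibble::as_tibble(entries)
  if (!"labels" %in% names(entries)) entries$labels <- NA_character_
  if (!"split" %in% names(entries)) entries$split <- "train"
  bad <- setdiff(unique(entries$split), c("train", "test"))
  if (length(bad)) abort("split tags must be 'train' or 'test'")
  jsonlite::write_json(list(root = root, entries = entries), path,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- tibble::as_tibble(m$entries)
  for (i in seq_len(nrow(entries))) {
    ip <- file.path(m$root, entries$image[i])
    if (!file.exists(ip)) abort(sprintf("manifest entry missing on disk: %s", ip))
    if (!is.na(entries$labels[i])) {
      lp <- file.path(m$root, entries$labels[i])
      if (!file.exists(lp)) abort(sprintf("manifest entry missing on disk: %s", lp))
      if (!all(dim(read_image(ip)) == dim(read_labelmap(lp))))
        abort(sprintf("image/label dimension mismatch for %s", entries$image[i]))
    }
  }
  list(root = m$root, entries = entries)
}
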