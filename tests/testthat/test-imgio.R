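test_that("TIFF and PNG image round-trips are lossless", {
  withr::with_tempdir({
    img16 <- intensity_image(matrix(sample(0:65535, 64 * 64, TRUE), 64, 64), 16L)
    write_image(img16, "a.tif")
    back <- read_image("a.tif")
    expect_equal(as.vector(back), as.vector(img16))
    expect_equal(image_bit_depth(back), 16L)

    img8 <- intensity_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), 8L)
    write_image(img8, "b.png")
    back8 <- read_image("b.png")
    expect_equal(as.vector(back8), as.vector(img8))
    expect_equal(image_bit_depth(back8), 8L)

    zero <- intensity_image(matrix(0L, 64, 64), 8L)
    write_image(zero, "z.png")
    expect_true(all(read_image("z.png") == 0))
  })
})

test_that("unsupported inputs produce explicit errors", {
  withr::with_tempdir({
    expect_error(read_image("missing.tif"), "not found")
    rgb <- array(runif(3 * 16 * 16), dim = c(16, 16, 3))
    png::writePNG(rgb, "rgb.png")
    expect_error(read_image("rgb.png"), "non-grayscale")
    # identical channels collapse instead
    gray <- matrix(runif(16 * 16), 16, 16)
    png::writePNG(array(rep(gray, 3), dim = c(16, 16, 3)), "g3.png")
    expect_equal(dim(read_image("g3.png")), c(16L, 16L))
  })
})

test_that("label-map TIFF round-trip is lossless and bounded at 16 bits", {
  withr::with_tempdir({
    lm <- matrix(0L, 32, 32); lm[3:8, 3:8] <- 7L; lm[20:25, 10:15] <- 10L
    write_labelmap(lm, "lab.tif")
    expect_identical(read_labelmap("lab.tif"), lm)

    write_labelmap(matrix(0L, 16, 16), "zero.tif")
    expect_equal(length(unique(as.vector(read_labelmap("zero.tif")))), 1)

    big <- matrix(seq_len(70000), nrow = 280, ncol = 250)
    expect_error(write_labelmap(big, "big.tif"), "65535")
  })
})

test_that("instance-mask folder export matches the benchmark layout and re-imports", {
  withr::with_tempdir({
    f <- generate_field(small_spec(2, n_touching_pairs = 0, n_clusters = 0,
                                   n_debris = 0, n_single = 3))
    export_instance_masks(f$image, f$label_map, "ds", id = "img1")
    expect_true(file.exists(file.path("ds", "img1", "images", "img1.png")))
    masks <- list.files(file.path("ds", "img1", "masks"))
    expect_length(masks, 3)

    back <- import_instance_masks(file.path("ds", "img1"))
    # identical up to label permutation: every original label maps to exactly
    # one reconstructed label with equal pixel set
    im <- iou_matrix(f$label_map, back)
    expect_equal(nrow(im$pairs), 3)
    expect_true(all(im$pairs$iou == 1))

    expect_warning(export_instance_masks(f$image, matrix(0L, 192, 192),
                                         "ds", id = "empty"),
                   "empty")
    expect_false(dir.exists(file.path("ds", "empty", "masks")))
  })
})

test_that("object table CSV round-trips and flags malformed input", {
  withr::with_tempdir({
    f <- generate_field(small_spec(4))
    tab <- f$objects
    tab$kept <- tab$area_px > 50
    write_object_table(tab, "obj.csv")
    back <- read_object_table("obj.csv")
    expect_equal(back$id, tab$id)
    expect_equal(back$area_px, as.numeric(tab$area_px))
    expect_equal(back$kept, tab$kept)
    expect_equal(back$class, tab$class)

    write_object_table(tab[0, ], "empty.csv")
    expect_equal(nrow(read_object_table("empty.csv")), 0)

    writeLines(c("id,area_px,bbox_r0,bbox_c0,bbox_r1,bbox_c1,centroid_r,centroid_c,kept,class",
                 "1,abc,0,0,5,5,2,2,TRUE,single"), "bad.csv")
    expect_error(read_object_table("bad.csv"), "non-numeric 'area_px' at data line 1")
  })
})

test_that("bounding boxes are 0-based half-open and match brute force", {
  f <- generate_field(small_spec(9))
  obj <- object_areas(f$label_map)
  for (k in sample(obj$id, min(5, nrow(obj)))) {
    px <- which(f$label_map == k, arr.ind = TRUE)
    row <- obj[obj$id == k, ]
    expect_equal(row$bbox_r0, min(px[, 1]) - 1L)
    expect_equal(row$bbox_r1, max(px[, 1]))      # half-open upper edge
    expect_equal(row$bbox_c0, min(px[, 2]) - 1L)
    expect_equal(row$bbox_c1, max(px[, 2]))
    expect_equal(row$centroid_r, mean(px[, 1] - 1))
    expect_equal(row$centroid_c, mean(px[, 2] - 1))
  }
})

test_that("manifest round-trips and validates referenced files", {
  withr::with_tempdir({
    f <- generate_field(small_spec(1))
    dir.create("root")
    write_image(f$image, "root/a.tif")
    write_labelmap(f$label_map, "root/a_labels.tif")
    entries <- tibble::tibble(image = "a.tif", labels = "a_labels.tif",
                              split = "train")
    write_manifest(entries, "root", "root/manifest.json")
    m <- read_manifest("root/manifest.json")
    expect_equal(m$entries$image, "a.tif")

    entries2 <- tibble::tibble(image = "missing.tif", labels = NA, split = "test")
    write_manifest(entries2, "root", "root/bad.json")
    expect_error(read_manifest("root/bad.json"), "missing on disk")
  })
})
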