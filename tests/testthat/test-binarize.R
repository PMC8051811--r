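test_that("a perfectly bimodal image splits exactly between the modes", {
  img <- intensity_image(matrix(rep(c(10L, 200L), each = 500), 25, 40), 8L)
  ot <- otsu_threshold(img)
  mask <- apply_threshold(img, ot$threshold)
  expect_identical(mask, matrix(img == 200L, 25, 40))
})

test_that("constant images are rejected as degenerate", {
  expect_error(otsu_threshold(intensity_image(matrix(7L, 32, 32), 8L)),
               "degenerate")
})

test_that("the scan minimizer matches the exhaustive pixel-level oracle", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      img <- intensity_image(matrix(sample(0:255, 128 * 128, TRUE,
                                           prob = runif(256)), 128, 128), 8L)
      ot <- otsu_threshold(img)
      oracle <- oracle_otsu_split(img)
      expect_identical(apply_threshold(img, ot$threshold),
                       matrix(as.numeric(img) > oracle$split, 128, 128))
      expect_equal(min(ot$scan$sigma_w2), oracle$sigma_w2, tolerance = 1e-10)
    }
  })
})

test_that("class weights sum to one over the whole scan", {
  withr::with_seed(5, {
    img <- intensity_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), 8L)
    sc <- tidy(otsu_threshold(img))
    expect_true(all(abs(sc$w0 + sc$w1 - 1) < 1e-12))
    expect_true(all(sc$w0 > 0 & sc$w1 > 0))
  })
})

test_that("minimizing intra-class variance maximizes between-class variance", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      img <- intensity_image(matrix(sample(0:255, 96 * 96, TRUE), 96, 96), 8L)
      sc <- tidy(otsu_threshold(img))
      mu <- mean(as.numeric(img))
      # sigma_total^2 = sigma_W^2 + sigma_B^2 at every candidate, so the
      # minimizer of one is the maximizer of the other
      tot <- pop_var(as.numeric(img))
      sigma_b2 <- tot - sc$sigma_w2
      expect_equal(which.min(sc$sigma_w2), which.max(sigma_b2))
    }
  })
})

test_that("positive affine intensity transforms shift the threshold affinely", {
  withr::with_seed(23, {
    img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    t0 <- otsu_threshold(intensity_image(img, 8L))$threshold
    t1 <- otsu_threshold(intensity_image(2L * img + 100L, 16L))$threshold
    bin_width <- 2 * (max(img) - min(img)) / 256
    expect_lt(abs(t1 - (2 * t0 + 100)), bin_width + 1e-9)
  })
})

test_that("threshold agrees with an independent Otsu implementation", {
  withr::with_seed(31, {
    img <- matrix(sample(0:255, 128 * 128, TRUE), 128, 128)
    t_pkg <- otsu_threshold(intensity_image(img, 8L))$threshold
    t_ref <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1)) * 255
    expect_lt(abs(t_pkg - t_ref), 2 * 255 / 256)  # within two bin widths
  })
})

test_that("threshold extremes behave as documented", {
  img <- intensity_image(matrix(sample(0:255, 32 * 32, TRUE), 32, 32), 8L)
  expect_false(any(apply_threshold(img, max(img))))
  expect_identical(apply_threshold(img, min(img)),
                   matrix(as.vector(img) > min(img), 32, 32))
})

test_that("foreground pixel count on a synthetic field is close to ground truth", {
  f <- generate_field(small_spec(6))
  ot <- otsu_threshold(f$image)
  mask <- apply_threshold(f$image, ot$threshold)
  expect_lt(abs(sum(mask) - sum(f$label_map > 0)) / sum(f$label_map > 0), 0.15)
})
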