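test_that("a single disc gets exactly one marker at its center", {
  m <- disc_mask(41, 41, 21, 21, 10)
  mk <- make_markers(m, min_peak_distance = 7)
  expect_equal(mk$n_markers, 1L)
  pos <- which(mk$markers > 0, arr.ind = TRUE)
  expect_lte(max(abs(pos - 21)), 1)
})

test_that("two merged discs give two markers and an empty mask gives none", {
  m <- disc_mask(41, 61, 21, 23, 10) | disc_mask(41, 61, 21, 39, 10)
  expect_equal(max(EBImage::bwlabel(m)), 1)  # actually merged
  mk <- make_markers(m, min_peak_distance = 8)
  expect_equal(mk$n_markers, 2L)

  empty <- make_markers(matrix(FALSE, 16, 16))
  expect_equal(empty$n_markers, 0L)
  expect_true(all(empty$markers == 0L))
})

test_that("every foreground component receives at least one marker", {
  withr::with_seed(12, {
    for (rep in 1:5) {
      f <- generate_field(small_spec(rep * 7))
      mask <- f$label_map > 0
      mk <- make_markers(mask, min_peak_distance = 7)
      comps <- connected_components(mask)
      seeded <- unique(comps[mk$markers > 0])
      expect_setequal(seeded, seq_len(max(comps)))
    }
  })
})

test_that("one marker on one disc labels exactly the disc", {
  m <- disc_mask(31, 31, 16, 16, 8)
  lab <- watershed_label(m, make_markers(m))
  expect_identical(lab > 0L, m)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L))
})

test_that("a dumbbell splits along the neck like the geodesic-nearest oracle", {
  m <- disc_mask(41, 61, 21, 23, 10) | disc_mask(41, 61, 21, 39, 10)
  mk <- make_markers(m, min_peak_distance = 8)
  lab <- watershed_label(m, mk)
  # exact partition into two connected labels
  expect_identical(lab > 0L, m)
  expect_equal(max(lab), 2L)
  # boundary crosses the neck: left disc center and right disc center carry
  # different labels
  expect_false(lab[21, 23] == lab[21, 39])
  # agreement with the independent nearest-marker-by-geodesic-distance oracle
  # everywhere except ridge ties
  oracle <- oracle_geodesic_partition(m, mk$markers)
  agree <- mean(lab[m] == oracle[m])
  expect_gt(agree, 0.95)
})

test_that("watershed output partitions the foreground with one label per marker", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      f <- generate_field(small_spec(rep))
      mask <- f$label_map > 0
      mk <- make_markers(mask, min_peak_distance = 7)
      lab <- watershed_label(mask, mk)
      expect_identical(lab > 0L, mask)                 # no pixel lost or created
      expect_equal(length(unique(lab[lab > 0])), mk$n_markers)
      # each label 8-connected
      for (k in sample(unique(lab[lab > 0]), 3)) {
        sub <- oracle_components8(lab == k)
        expect_equal(max(sub), 1)
      }
    }
  })
})

test_that("well-separated nuclei are recovered one to one with high IoU", {
  f <- generate_field(synthetic_spec(n_single = 10, n_touching_pairs = 0,
                                     n_clusters = 0, n_debris = 0, seed = 2))
  lab <- segment_instances(f$label_map > 0, min_peak_distance = 7)
  im <- iou_matrix(f$label_map, lab)
  cc <- match_at_threshold(im, 0.7)
  expect_equal(cc$tp, 10)
  expect_equal(cc$fp + cc$fn, 0)
})

test_that("contract violations are rejected", {
  m <- disc_mask(21, 21, 11, 11, 5)
  bad <- matrix(0L, 21, 21); bad[1, 1] <- 1L   # marker in background
  expect_error(watershed_label(m, bad), "inside the foreground")
  expect_error(watershed_label(m, matrix(0L, 21, 21)), "contract")
  expect_identical(watershed_label(matrix(FALSE, 8, 8), matrix(0L, 8, 8)),
                   matrix(0L, 8, 8))
})

test_that("relabel_sequential renumbers and is idempotent", {
  m <- matrix(0L, 8, 8); m[2, 2] <- 3L; m[6, 6] <- 17L
  r <- relabel_sequential(m)
  expect_setequal(unique(as.vector(r)), c(0L, 1L, 2L))
  expect_identical(relabel_sequential(r), r)
  expect_identical(relabel_sequential(matrix(0L, 4, 4)), matrix(0L, 4, 4))
})
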