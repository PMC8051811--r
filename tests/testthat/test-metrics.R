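test_that("identical maps pair every instance with itself at IoU 1", {
  f <- generate_field(small_spec(31))
  im <- iou_matrix(f$label_map, f$label_map)
  expect_equal(nrow(im$pairs), im$n_gt)
  expect_true(all(im$pairs$iou == 1))
  cc <- match_at_threshold(im, 0.5)
  expect_equal(cc$tp, im$n_gt)
  expect_equal(cc$fp + cc$fn, 0)
})

test_that("hand-counted overlap on a small grid gives IoU 2/6", {
  gt <- matrix(0L, 4, 4); gt[1:2, 1:2] <- 1L        # 4 px
  pred <- matrix(0L, 4, 4); pred[2:3, 1:2] <- 1L    # 4 px, overlap 2
  im <- iou_matrix(gt, pred)
  expect_equal(im$pairs$intersection_px, 2)
  expect_equal(im$pairs$union_px, 6)
  expect_equal(im$pairs$iou, 1 / 3)
  cc <- match_at_threshold(im, 0.5)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(0L, 1L, 1L))

  disj <- matrix(0L, 4, 4); disj[4, 4] <- 1L
  expect_equal(nrow(iou_matrix(gt, disj)$pairs), 0)
  expect_error(iou_matrix(gt, matrix(0L, 5, 5)), "shape")
})

test_that("precision, recall and F1 match direct arithmetic", {
  counts <- structure(list(t = 0.5, tp = 3L, fp = 1L, fn = 2L, tn = 0L,
                           matches = tibble::tibble(gt_id = 1:3, pred_id = 1:3,
                                                    iou = c(0.9, 0.8, 0.7)),
                           n_gt = 5L, n_pred = 4L),
                      class = "confusion_counts")
  m <- prf1(counts)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 3 / 4.5)
  expect_equal(m$mean_iou_matched, 0.8)
  expect_equal(m$mean_iou_all, 2.4 / 5)

  empty <- structure(list(t = 0.5, tp = 0L, fp = 0L, fn = 0L, tn = 0L,
                          matches = tibble::tibble(gt_id = integer(0),
                                                   pred_id = integer(0),
                                                   iou = numeric(0)),
                          n_gt = 0L, n_pred = 0L),
                     class = "confusion_counts")
  me <- prf1(empty)
  expect_equal(c(me$precision, me$recall, me$f1), c(0, 0, 0))

  perfect <- structure(list(t = 0.5, tp = 7L, fp = 0L, fn = 0L, tn = 0L,
                            matches = tibble::tibble(gt_id = 1:7, pred_id = 1:7,
                                                     iou = rep(1, 7)),
                            n_gt = 7L, n_pred = 7L),
                       class = "confusion_counts")
  mp <- prf1(perfect)
  expect_equal(c(mp$precision, mp$recall, mp$f1), c(1, 1, 1))
})

test_that("count conservation holds at every threshold", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      gt <- random_label_map(); pred <- random_label_map()
      im <- iou_matrix(gt, pred)
      for (t in c(0.3, 0.5, 0.7)) {
        cc <- match_at_threshold(im, t)
        expect_equal(cc$tp + cc$fn, im$n_gt)
        expect_equal(cc$tp + cc$fp, im$n_pred)
      }
    }
  })
})

test_that("greedy matching equals brute-force optimal assignment at t = 0.5", {
  withr::with_seed(88, {
    for (rep in 1:20) {
      gt <- random_label_map(); pred <- random_label_map()
      im <- iou_matrix(gt, pred)
      cc <- match_at_threshold(im, 0.5)
      expect_equal(cc$tp, oracle_max_matching(im$pairs, 0.5))
    }
  })
})

test_that("metrics are invariant to relabelling either map", {
  withr::with_seed(55, {
    f <- generate_field(small_spec(32))
    gt <- f$label_map
    pred <- segment_instances(gt > 0)
    perm <- sample(max(gt))
    gt_perm <- matrix(ifelse(gt > 0L, perm[pmax(gt, 1L)], 0L), nrow(gt), ncol(gt))
    c1 <- f1_curve(gt, pred)
    c2 <- f1_curve(gt_perm, pred)
    expect_equal(c1$f1, c2$f1)
    expect_equal(c1$mean_iou_all, c2$mean_iou_all)
  })
})

test_that("the IoU table transposes under argument swap", {
  withr::with_seed(66, {
    a <- random_label_map(); b <- random_label_map()
    ab <- iou_matrix(a, b)$pairs
    ba <- iou_matrix(b, a)$pairs
    merged <- dplyr::inner_join(
      ab, ba, by = c(gt_id = "pred_id", pred_id = "gt_id"))
    expect_equal(nrow(merged), nrow(ab))
    expect_equal(merged$iou.x, merged$iou.y)
  })
})

test_that("F1 is non-increasing in the IoU threshold", {
  withr::with_seed(44, {
    for (rep in 1:5) {
      f <- generate_field(small_spec(rep + 60))
      pred <- segment_instances(f$label_map > 0)
      cur <- f1_curve(f$label_map, pred,
                      thresholds = seq(0.3, 0.95, by = 0.05))
      expect_true(all(diff(cur$f1) <= 1e-12))
    }
  })
})

test_that("identical maps give F1 = 1 at every threshold; erosion only hurts high t", {
  f <- generate_field(synthetic_spec(n_single = 8, n_touching_pairs = 0,
                                     n_clusters = 0, n_debris = 0, seed = 3))
  gt <- f$label_map
  expect_true(all(f1_curve(gt, gt)$f1 == 1))

  # 1-px erosion of every instance: IoU ~ (r-1)^2/r^2 ~ 0.8, so perfect at
  # t = 0.5 but failing at t = 0.95
  dist <- as.matrix(EBImage::distmap(gt > 0))
  eroded <- gt; eroded[dist <= 1] <- 0L
  cur <- f1_curve(gt, eroded)
  expect_equal(cur$f1[cur$t == 0.5], 1)
  expect_lt(cur$f1[cur$t == 0.95], 1)
})

test_that("restricting evaluation to kept nuclei raises the mean IoU", {
  f <- generate_field(synthetic_spec(n_single = 10, n_touching_pairs = 0,
                                     n_clusters = 0, n_debris = 0, seed = 5))
  auto <- segment_instances(f$label_map > 0)
  # drop 3 automatic objects as if the filter had excluded them
  kept <- setdiff(label_ids(auto), c(1L, 2L, 3L))
  unres <- annotation_accuracy(f$label_map, auto, kept, restrict_to_kept = FALSE)
  res <- annotation_accuracy(f$label_map, auto, kept, restrict_to_kept = TRUE)
  expect_lt(unres$mean_iou_all, res$mean_iou_matched)
  expect_equal(res$n_gt_evaluated, 7)
  expect_equal(res$recall, 1)

  # identical maps: mean IoU 1 in either mode
  both <- annotation_accuracy(f$label_map, f$label_map)
  expect_equal(both$mean_iou_all, 1)

  # empty prediction: everything zero
  none <- annotation_accuracy(f$label_map, matrix(0L, 256, 256))
  expect_equal(none$f1, 0)
  expect_equal(none$mean_iou_all, 0)
})
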