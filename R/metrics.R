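#' Pairwise instance IoU table
#'
#' Computes exact pixel-count intersection, union, and intersection-over-
#' union for every overlapping (ground-truth, predicted) instance pair of
#' two label maps of the same shape. Only pairs with positive intersection
#' are listed. All downstream metrics are invariant to relabelling either
#' map.
#'
#' @param gt Ground-truth label map.
#' @param pred Predicted label map, same shape.
#' @return Object of class `iou_matrix`: list with `pairs` (tibble `gt_id`,
#'   `pred_id`, `intersection_px`, `union_px`, `iou`), `n_gt`, `n_pred`,
#'   and the per-instance area lookups `gt_areas`, `pred_areas`.
#' @export
iou_matrix <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) abort("gt and pred label maps differ in shape")
  gt <- label_map(gt); pred <- label_map(pred)
  gt_ids <- label_ids(gt); pred_ids <- label_ids(pred)
  gt_areas <- tabulate(gt[gt > 0L], nbins = max(gt, 1L))
  pred_areas <- tabulate(pred[pred > 0L], nbins = max(pred, 1L))
  both <- gt > 0L & pred > 0L
  if (any(both)) {
    pairs <- tibble::tibble(gt_id = gt[both], pred_id = pred[both]) |>
      dplyr::count(.data$gt_id, .data$pred_id, name = "intersection_px") |>
      dplyr::mutate(
        union_px = gt_areas[.data$gt_id] + pred_areas[.data$pred_id] -
          .data$intersection_px,
        iou = .data$intersection_px / .data$union_px) |>
      dplyr::arrange(.data$gt_id, .data$pred_id)
  } else {
    pairs <- tibble::tibble(gt_id = integer(0), pred_id = integer(0),
                            intersection_px = integer(0),
                            union_px = integer(0), iou = numeric(0))
  }
  structure(list(pairs = pairs, n_gt = length(gt_ids), n_pred = length(pred_ids),
                 gt_ids = gt_ids, pred_ids = pred_ids,
                 gt_areas = gt_areas, pred_areas = pred_areas),
            class = "iou_matrix")
}

#' One-to-one instance matching at an IoU threshold
#'
#' Candidate pairs are those with `iou >= t`; they are matched one-to-one
#' greedily in order of decreasing IoU (ties broken by `gt_id`, then
#' `pred_id`, so the result is deterministic). Matched pairs are true
#' positives, unmatched predictions false positives, unmatched ground-truth
#' instances false negatives. At `t >= 0.5` the greedy result coincides
#' with the optimal assignment, since each instance can then exceed the
#' threshold with at most one partner. Object-level true negatives are
#' undefined and carried as 0; no formula uses them.
#'
#' @param ioumat An [iou_matrix()].
#' @param t IoU threshold in `(0, 1)`.
#' @return Object of class `confusion_counts`: list with `t`, `tp`, `fp`,
#'   `fn`, `tn` (always 0), `matches` (tibble `gt_id`, `pred_id`, `iou`),
#'   `n_gt`, `n_pred`.
#' @export
match_at_threshold <- function(ioumat, t) {
  if (!inherits(ioumat, "iou_matrix")) abort("`ioumat` must come from iou_matrix()")
  if (!(t > 0 && t < 1)) abort("`t` must lie strictly in (0, 1).")
  cand <- ioumat$pairs |>
    dplyr::filter(.data$iou >= t) |>
    dplyr::arrange(dplyr::desc(.data$iou), .data$gt_id, .data$pred_id)
  used_gt <- integer(0); used_pred <- integer(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    g <- cand$gt_id[i]; p <- cand$pred_id[i]
    if (!(g %in% used_gt) && !(p %in% used_pred)) {
      keep[i] <- TRUE
      used_gt <- c(used_gt, g); used_pred <- c(used_pred, p)
    }
  }
  matches <- cand[keep, c("gt_id", "pred_id", "iou")]
  tp <- nrow(matches)
  structure(list(t = t, tp = tp, fp = ioumat$n_pred - tp, fn = ioumat$n_gt - tp,
                 tn = 0L, matches = matches,
                 n_gt = ioumat$n_gt, n_pred = ioumat$n_pred),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' Object-level detection metrics at an IoU threshold `t`:
#' \deqn{P(t) = \frac{TP}{TP + FP}, \quad R(t) = \frac{TP}{TP + FN}, \quad
#'       F_1(t) = \frac{TP}{TP + \tfrac12 (FP + FN)}.}
#' A metric whose denominator is zero is defined as 0. Mean IoU is reported
#' in both conventions: over matched pairs only (`mean_iou_matched`) and
#' over all ground-truth instances with unmatched ones contributing 0
#' (`mean_iou_all`).
#'
#' @param counts A `confusion_counts` from [match_at_threshold()].
#' @return One-row tibble: `t`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `mean_iou_matched`, `mean_iou_all`.
#' @export
prf1 <- function(counts) {
  if (!inherits(counts, "confusion_counts"))
    abort("`counts` must come from match_at_threshold()")
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  safe <- function(num, den) if (den > 0) num / den else 0
  ious <- counts$matches$iou
  tibble::tibble(
    t = counts$t, tp = tp, fp = fp, fn = fn,
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    f1 = safe(tp, tp + 0.5 * (fp + fn)),
    mean_iou_matched = if (tp > 0) mean(ious) else 0,
    mean_iou_all = if (counts$n_gt > 0) sum(ious) / counts$n_gt else 0)
}

#' F1 across a grid of IoU thresholds
#'
#' Evaluates [prf1()] after [match_at_threshold()] at each threshold. The
#' default grid `{0.50, 0.60, 0.70, 0.80, 0.90, 0.95}` is the customary
#' reporting grid for instance-segmentation F1 curves. `F1(t)` is
#' non-increasing in `t` for a fixed map pair.
#'
#' @param gt,pred Label maps of the same shape.
#' @param thresholds Increasing IoU thresholds in `(0, 1)`.
#' @return Tibble of class `f1_curve`, one row per threshold.
#' @export
f1_curve <- function(gt, pred, thresholds = c(0.50, 0.60, 0.70, 0.80, 0.90, 0.95)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    abort("`thresholds` must be strictly increasing.")
  ioumat <- iou_matrix(gt, pred)
  out <- purrr::map_dfr(thresholds, function(t) prf1(match_at_threshold(ioumat, t)))
  class(out) <- c("f1_curve", class(out))
  out
}

#' Annotation accuracy against a reference ground truth
#'
#' Compares an automatically produced (and optionally filtered) label map
#' with reference annotations. In the unrestricted mode every reference
#' instance counts, so nuclei the filter discarded appear as false
#' negatives and drag `mean_iou_all` down. With `restrict_to_kept = TRUE`
#' the evaluation covers only the automatically annotated nuclei: reference
#' instances whose best-overlapping automatic object was excluded by the
#' filter are dropped before counting, measuring the quality of what was
#' actually annotated.
#'
#' @param gt Reference label map.
#' @param auto Automatic label map before filtering.
#' @param kept_ids Labels of `auto` kept by the filter; `NULL` means no
#'   filtering happened.
#' @param restrict_to_kept Evaluate only reference instances whose best
#'   automatic match was kept.
#' @param t IoU threshold for matching (default 0.5).
#' @return One-row tibble as [prf1()], plus `mode` and `n_gt_evaluated`.
#' @export
annotation_accuracy <- function(gt, auto, kept_ids = NULL,
                                restrict_to_kept = FALSE, t = 0.5) {
  gt <- label_map(gt); auto <- label_map(auto)
  filtered <- if (is.null(kept_ids)) auto else apply_keep(auto, kept_ids)
  gt_eval <- gt
  if (restrict_to_kept && !is.null(kept_ids)) {
    full <- iou_matrix(gt, auto)
    best <- full$pairs |>
      dplyr::group_by(.data$gt_id) |>
      dplyr::slice_max(.data$iou, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    dropped <- c(best$gt_id[!(best$pred_id %in% kept_ids)],
                 setdiff(full$gt_ids, best$gt_id))  # gt with no overlap at all
    gt_eval[gt_eval %in% dropped] <- 0L
    gt_eval <- relabel_sequential(gt_eval)
  }
  res <- prf1(match_at_threshold(iou_matrix(gt_eval, filtered), t))
  res$mode <- if (restrict_to_kept) "restricted_to_kept" else "all_reference"
  res$n_gt_evaluated <- length(label_ids(gt_eval))
  res
}
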