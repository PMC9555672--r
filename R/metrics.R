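#' Voxel-wise confusion counts
#'
#' Tallies true/false positives/negatives between a binary prediction and
#' binary ground truth on the same grid. The four counts always sum to the
#' total voxel count.
#'
#' @param pred binary prediction: [label_map()] or array.
#' @param gt binary ground truth, same shape.
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, gt) {
  p <- binary_voxels(pred); g <- binary_voxels(gt)
  if (length(p) != length(g))
    abort_cbctseg("prediction and ground truth shapes differ",
                  "cbctseg_shape_error")
  tp <- sum(p & g)
  fp <- sum(p & !g)
  fn <- sum(!p & g)
  list(TP = tp, TN = length(p) - tp - fp - fn, FP = fp, FN = fn)
}

binary_voxels <- function(x) {
  v <- if (inherits(x, "volume_image")) x$voxels else x
  as.logical(v > 0)
}

#' Dice coefficient between two binary volumes
#'
#' `DC(M, A) = 2|A intersect M| / (|A| + |M|)`: 1 is perfect superposition,
#' 0 none. Symmetric in its arguments; undefined (error) when both volumes
#' are empty.
#'
#' @param a,b binary volumes ([label_map()] or arrays) of the same shape.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  x <- binary_voxels(a); y <- binary_voxels(b)
  if (length(x) != length(y))
    abort_cbctseg("volume shapes differ", "cbctseg_shape_error")
  denom <- sum(x) + sum(y)
  if (denom == 0)
    abort_cbctseg("Dice undefined: both volumes are empty",
                  "cbctseg_undefined_metric_error")
  2 * sum(x & y) / denom
}

#' F2 score from confusion counts
#'
#' `TP / (TP + 0.2 FP + 0.8 FN)` — recall weighted twice as heavily as
#' precision, reflecting the clinical preference for over-segmentation over
#' under-segmentation.
#'
#' @param c confusion counts from [confusion_counts()].
#' @return Scalar in \[0, 1\].
#' @export
f2_score <- function(c) {
  den <- c$TP + 0.2 * c$FP + 0.8 * c$FN
  if (den == 0)
    abort_cbctseg("F2 undefined: TP + FP + FN is zero",
                  "cbctseg_undefined_metric_error")
  c$TP / den
}

#' Accuracy, recall, precision from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`; each errors when its denominator is zero.
#'
#' @param c confusion counts from [confusion_counts()].
#' @return Scalar in \[0, 1\].
#' @export
accuracy_score <- function(c) {
  den <- c$TP + c$TN + c$FP + c$FN
  if (den == 0)
    abort_cbctseg("accuracy undefined on an empty grid",
                  "cbctseg_undefined_metric_error")
  (c$TP + c$TN) / den
}

#' @rdname accuracy_score
#' @export
recall_score <- function(c) {
  if (c$TP + c$FN == 0)
    abort_cbctseg("recall undefined: no positive ground truth",
                  "cbctseg_undefined_metric_error")
  c$TP / (c$TP + c$FN)
}

#' @rdname accuracy_score
#' @export
precision_score <- function(c) {
  if (c$TP + c$FP == 0)
    abort_cbctseg("precision undefined: no positive predictions",
                  "cbctseg_undefined_metric_error")
  c$TP / (c$TP + c$FP)
}

#' Precision-recall curve over probability thresholds
#'
#' Sweeps thresholds over the predicted foreground probabilities (all
#' unique values when there are at most `n_thresholds`, otherwise
#' `n_thresholds` quantiles), binarizing at `probs >= t` and recording
#' (recall, precision) per threshold. The curve is anchored at recall 0
#' (precision of the strictest cut) and recall 1 (precision = prevalence,
#' all voxels positive).
#'
#' @param probs foreground probability volume (array or `prob_volume`, in
#'   which case the last channel is used).
#' @param gt binary ground truth with at least one foreground and one
#'   background voxel.
#' @param n_thresholds maximum number of thresholds (default 1024).
#' @return A `pr_curve` list: `thresholds` (decreasing), `recall`
#'   (non-decreasing), `precision`.
#' @export
pr_curve <- function(probs, gt, n_thresholds = 1024L) {
  p <- foreground_probs(probs)
  g <- binary_voxels(gt)
  if (length(p) != length(g))
    abort_cbctseg("probability and ground truth shapes differ",
                  "cbctseg_shape_error")
  npos <- sum(g); nneg <- sum(!g)
  if (npos == 0 || nneg == 0)
    abort_cbctseg("PR curve undefined for degenerate ground truth",
                  "cbctseg_undefined_metric_error")
  thr <- sort(unique(p), decreasing = TRUE)
  if (length(thr) > n_thresholds)
    thr <- sort(unique(stats::quantile(p, probs = seq(0, 1,
      length.out = n_thresholds), names = FALSE, type = 1)),
      decreasing = TRUE)
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; gs <- g[ord]
  ctp <- cumsum(gs)
  cpp <- seq_along(ps)
  # number of predictions >= each threshold (ps is sorted decreasing)
  pos <- length(ps) - findInterval(thr, rev(ps), left.open = TRUE)
  tp <- ctp[pos]; pp <- cpp[pos]
  recall <- tp / npos
  precision <- tp / pp
  # anchors
  if (recall[1] > 0) {
    recall <- c(0, recall)
    precision <- c(precision[1], precision)
    thr <- c(Inf, thr)
  }
  if (recall[length(recall)] < 1) {
    recall <- c(recall, 1)
    precision <- c(precision, npos / length(p))
    thr <- c(thr, -Inf)
  }
  structure(list(thresholds = thr, recall = recall, precision = precision,
                 n = length(thr)), class = "pr_curve")
}

foreground_probs <- function(probs) {
  if (inherits(probs, "prob_volume")) {
    d <- dim(probs$probs)
    as.numeric(probs$probs[, , , d[4]])
  } else if (inherits(probs, "volume_image")) {
    as.numeric(probs$voxels)
  } else {
    as.numeric(probs)
  }
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration over the recall-sorted curve:
#' `sum (R[n] - R[n-1]) * (P[n] + P[n-1]) / 2`. The printed form of the
#' source formula differs (difference of precisions in the integrand); that
#' variant is available as `integrand = "difference"` for auditability but
#' integrates flat curves to ~0 and is not used anywhere.
#'
#' @param curve a [pr_curve()].
#' @param integrand `"trapezoid"` (default) or `"difference"`.
#' @return Scalar in \[0, 1\] for the trapezoid integrand.
#' @export
auprc <- function(curve, integrand = c("trapezoid", "difference")) {
  integrand <- match.arg(integrand)
  r <- curve$recall; p <- curve$precision
  if (length(r) < 2L || any(is.na(r)) || any(is.na(p)) || is.unsorted(r))
    abort_cbctseg("PR curve must be recall-sorted with >= 2 finite points",
                  "cbctseg_contract_error")
  dr <- diff(r)
  if (integrand == "trapezoid") sum(dr * (p[-1] + p[-length(p)]) / 2)
  else sum(dr * diff(p) / 2)
}

#' Chance baseline of the AUPRC
#'
#' The AUPRC of an uninformative predictor equals the foreground
#' prevalence of the ground truth — the quantity that makes AUPRC
#' interpretable under the heavy class imbalance of skull segmentations
#' (bone structures occupy roughly 1-10% of a scan).
#'
#' @param gt binary ground truth ([label_map()] or array), non-empty grid.
#' @return Foreground voxel fraction in \[0, 1\].
#' @export
auprc_baseline <- function(gt) {
  g <- binary_voxels(gt)
  if (length(g) == 0)
    abort_cbctseg("empty grid has no prevalence",
                  "cbctseg_undefined_metric_error")
  mean(g)
}

#' Full evaluation report for one segmentation
#'
#' Computes the seven headline quantities — AUPRC (from the pre-argmax
#' probability volume), its prevalence baseline, Dice, F2, accuracy,
#' recall and precision (from the binarized post-processed prediction).
#'
#' @param pred_probs foreground probability volume (pre-argmax), or `NULL`
#'   to skip the AUPRC.
#' @param pred_label binary predicted [label_map()].
#' @param gt binary ground-truth [label_map()].
#' @param partial return `NA` for metrics whose denominator is undefined
#'   (e.g. precision of an empty prediction) instead of raising; the
#'   default surfaces such degeneracies as errors.
#' @return An `eval_report` list with fields `auprc`, `auprc_baseline`,
#'   `dice`, `f2`, `accuracy`, `recall`, `precision`.
#' @export
evaluate_segmentation <- function(pred_probs, pred_label, gt,
                                  partial = FALSE) {
  cc <- confusion_counts(pred_label, gt)
  maybe <- function(expr) {
    if (!partial) return(expr)
    tryCatch(expr, cbctseg_undefined_metric_error = function(e) NA_real_)
  }
  rep <- list(
    auprc = if (is.null(pred_probs)) NA_real_ else
      maybe(auprc(pr_curve(pred_probs, gt))),
    auprc_baseline = auprc_baseline(gt),
    dice = maybe(dice_coefficient(pred_label, gt)),
    f2 = maybe(f2_score(cc)),
    accuracy = maybe(accuracy_score(cc)),
    recall = maybe(recall_score(cc)),
    precision = maybe(precision_score(cc)))
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (nm in names(x))
    cat(sprintf("  %-14s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.4f", x[[nm]]))))
  invisible(x)
}
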