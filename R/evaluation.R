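#' Pixel-wise confusion counts
#'
#' @param pred,truth `change_mask` objects or logical matrices of equal shape.
#' @param fov Optional field-of-view mask (logical matrix); pixels outside it
#'   are excluded from all counts (fundus photographs have an uninformative
#'   black surround). `NULL` counts every pixel.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, truth, fov = NULL) {
  p <- mask_pixels(pred)
  t <- mask_pixels(truth)
  if (!identical(dim(p), dim(t))) {
    stop(sprintf(
      "prediction and truth shapes differ: %d x %d vs %d x %d",
      nrow(p), ncol(p), nrow(t), ncol(t)
    ), call. = FALSE)
  }
  if (!is.null(fov)) {
    keep <- mask_pixels(fov)
    p <- p[keep]
    t <- t[keep]
  }
  structure(
    list(
      tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t)
    ),
    class = "confusion_counts"
  )
}

#' Classification rates from confusion counts
#'
#' True-positive rate TP/(TP+FN), false-positive rate FP/(TN+FP), precision
#' TP/(TP+FP) and recall TP/(TP+FN), with the 0/0 convention of returning 0.
#'
#' @param c A `confusion_counts`.
#' @return A tibble with one row: `tpr`, `fpr`, `precision`, `recall`.
#' @export
rates <- function(c) {
  div0 <- function(num, den) if (den == 0) 0 else num / den
  tibble::tibble(
    tpr = div0(c$tp, c$tp + c$fn),
    fpr = div0(c$fp, c$tn + c$fp),
    precision = div0(c$tp, c$tp + c$fp),
    recall = div0(c$tp, c$tp + c$fn)
  )
}

#' ROC and precision-recall curves of a soft change map
#'
#' Sweeps every distinct score value of the map as a decision threshold
#' (pixels with score >= threshold are predicted changed), and computes the
#' ROC curve with its trapezoidal area (AUC; ties handled so the value equals
#' the Mann-Whitney pair-counting statistic) and the precision-recall curve
#' with its mean average precision. `map_method = "envelope"` (default)
#' integrates the interpolated precision envelope, the standard AP;
#' `"trapezoid"` integrates the raw PR points.
#'
#' @param score_map A `change_map` (its `absolute` component is ranked) or a
#'   numeric matrix of scores.
#' @param truth A `change_mask` or logical matrix with at least one positive
#'   and one negative pixel.
#' @param fov Optional field-of-view mask, as in [confusion()].
#' @param map_method `"envelope"` or `"trapezoid"`.
#' @return An `eval_curves`: list with `curve` (tibble: `threshold`, `tp`,
#'   `fp`, `tpr`, `fpr`, `precision`, `recall`), `auc` and `map`.
#' @export
roc_pr_curves <- function(score_map, truth, fov = NULL,
                          map_method = c("envelope", "trapezoid")) {
  map_method <- match.arg(map_method)
  s <- if (inherits(score_map, "change_map")) score_map$absolute else as_matrix(score_map)
  t <- mask_pixels(truth)
  if (!identical(dim(s), dim(t))) {
    stop("score map and truth shapes differ", call. = FALSE)
  }
  if (!is.null(fov)) {
    keep <- mask_pixels(fov)
    s <- s[keep]
    t <- t[keep]
  }
  s <- as.numeric(s)
  t <- as.logical(t)
  P <- sum(t)
  N <- sum(!t)
  if (P == 0L || N == 0L) {
    stop("truth must contain at least one positive and one negative pixel",
      call. = FALSE
    )
  }
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]
  t_ord <- t[ord]
  # group tied scores: one operating point per distinct threshold
  grp_last <- cumsum(rle(s_ord)$lengths)
  tp <- cumsum(t_ord)[grp_last]
  fp <- cumsum(!t_ord)[grp_last]
  thresholds <- s_ord[grp_last]
  tpr <- tp / P
  fpr <- fp / N
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- tpr
  auc <- sum(diff(c(0, fpr)) * (tpr + c(0, utils::head(tpr, -1))) / 2)
  if (map_method == "envelope") {
    prec_env <- rev(cummax(rev(precision)))
    ap <- sum(diff(c(0, recall)) * prec_env)
  } else {
    p0 <- c(precision[1], utils::head(precision, -1))
    ap <- sum(diff(c(0, recall)) * (precision + p0) / 2)
  }
  structure(
    list(
      curve = tibble::tibble(
        threshold = thresholds, tp = tp, fp = fp,
        tpr = tpr, fpr = fpr, precision = precision, recall = recall
      ),
      auc = auc, map = ap, n_pos = P, n_neg = N
    ),
    class = "eval_curves"
  )
}

#' @export
print.eval_curves <- function(x, ...) {
  cat(sprintf(
    "<eval_curves> %d thresholds, AUC %.4f, mAP %.4f (%d pos / %d neg px)\n",
    nrow(x$curve), x$auc, x$map, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Intersection over union of two binary masks
#'
#' @param pred,truth `change_mask` objects or logical matrices.
#' @param fov Optional field-of-view mask.
#' @return IOU in `[0, 1]`; two empty masks give 1 (perfect agreement).
#' @export
iou <- function(pred, truth, fov = NULL) {
  p <- mask_pixels(pred)
  t <- mask_pixels(truth)
  if (!identical(dim(p), dim(t))) {
    stop("prediction and truth shapes differ", call. = FALSE)
  }
  if (!is.null(fov)) {
    keep <- mask_pixels(fov)
    p <- p[keep]
    t <- t[keep]
  }
  u <- sum(p | t)
  if (u == 0L) return(1)
  sum(p & t) / u
}

#' Evaluate a detection against ground truth
#'
#' Convenience wrapper combining threshold-free (AUC, mAP from the soft map)
#' and thresholded (confusion rates, IOU from the final mask) evaluation.
#'
#' @param detection A `fundus_detection` from [detect()], or a list with
#'   elements `map` (`change_map`) and `mask` (`change_mask`).
#' @param truth A `change_mask` or logical matrix.
#' @param fov Optional field-of-view mask.
#' @return An `eval_report`: list with `curves` (`eval_curves`), `counts`,
#'   `rates` (tibble row), `iou`, `auc`, `map`.
#' @export
evaluate_detection <- function(detection, truth, fov = NULL) {
  score <- if (!is.null(detection$fused_map)) detection$fused_map else detection$map
  curves <- roc_pr_curves(score, truth, fov = fov)
  cts <- confusion(detection$mask, truth, fov = fov)
  structure(
    list(
      curves = curves, counts = cts, rates = rates(cts),
      iou = iou(detection$mask, truth, fov = fov),
      auc = curves$auc, map = curves$map
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUC %.4f, mAP %.4f, IOU %.4f, TPR %.4f, FPR %.4f\n",
    x$auc, x$map, x$iou, x$rates$tpr, x$rates$fpr
  ))
  invisible(x)
}
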