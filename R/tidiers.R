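#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a detection into a table of change regions
#'
#' One row per 8-connected component of the final change mask, with its area
#' and centroid (0-based pixel coordinates).
#'
#' @param x A `fundus_detection` from [detect()].
#' @param ... Unused.
#' @return A tibble with columns `region`, `area`, `centroid_row`,
#'   `centroid_col`.
#' @exportS3Method generics::tidy
tidy.fundus_detection <- function(x, ...) {
  m <- mask_pixels(x$mask)
  if (!any(m)) {
    return(tibble::tibble(
      region = integer(0), area = integer(0),
      centroid_row = numeric(0), centroid_col = numeric(0)
    ))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1.0)))
  idx <- which(lab > 0, arr.ind = TRUE)
  lbl <- lab[lab > 0]
  tibble::tibble(
    region = as.integer(sort(unique(lbl))),
    area = as.integer(tabulate(lbl)[sort(unique(lbl))]),
    centroid_row = as.numeric(tapply(idx[, 1] - 1, lbl, mean)),
    centroid_col = as.numeric(tapply(idx[, 2] - 1, lbl, mean))
  )
}

#' One-row summary of a detection
#'
#' @param x A `fundus_detection`.
#' @param ... Unused.
#' @return A one-row tibble: mode, threshold, lambda, mean nonzero
#'   coefficients and mean residual per patch, mask area fraction, and the
#'   number of detected regions.
#' @exportS3Method generics::glance
glance.fundus_detection <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    threshold = x$config$threshold,
    lambda = x$background$lam,
    mean_nnz = x$background$mean_nnz,
    mean_residual = x$background$mean_residual,
    mask_area_fraction = mask_area_fraction(x$mask),
    n_regions = nrow(tidy(x))
  )
}

#' @describeIn roc_pr_curves Tidy the operating points into a tibble.
#' @param x An `eval_curves` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eval_curves <- function(x, ...) x$curve

#' @describeIn roc_pr_curves One-row summary (`auc`, `map`, class counts).
#' @exportS3Method generics::glance
glance.eval_curves <- function(x, ...) {
  tibble::tibble(auc = x$auc, map = x$map, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @describeIn evaluate_detection One-row summary with AUC, mAP, IOU and the
#'   thresholded rates.
#' @param x An `eval_report` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, map = x$map, iou = x$iou,
    tpr = x$rates$tpr, fpr = x$rates$fpr,
    precision = x$rates$precision, recall = x$rates$recall
  )
}
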