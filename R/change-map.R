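#' Difference image between current image and reconstructed background
#'
#' `signed = current - background`; `absolute` is `|signed|` rescaled to
#' `[0, 1]` by its maximum so that the fixed binarisation thresholds
#' (0.15, 0.3) are well-defined across exposures. Maps whose dynamic range is
#' below `rescale_floor` are not stretched: a numerically negligible residual
#' (e.g. from an identical pair, where only the lasso shrinkage remains) must
#' not be amplified into a full-scale map, so the divisor is
#' `max(max|signed|, rescale_floor)`.
#'
#' @param current A [gray_image] (or matrix).
#' @param background A `background_image` or [gray_image]/matrix.
#' @param rescale_floor Minimum dynamic range (intensity units) at which
#'   rescaling engages; default 1e-3.
#' @return A `change_map`: list with `signed`, `absolute`, and `scale` (the
#'   divisor used).
#' @export
difference <- function(current, background, rescale_floor = 1e-3) {
  bg <- if (inherits(background, "background_image")) background$pixels else background
  cur <- as_matrix(current)
  bg <- as_matrix(bg)
  if (!identical(dim(cur), dim(bg))) {
    stop(sprintf(
      "current and background shapes differ: %d x %d vs %d x %d",
      nrow(cur), ncol(cur), nrow(bg), ncol(bg)
    ), call. = FALSE)
  }
  signed <- cur - bg
  m <- max(abs(signed))
  scale <- max(m, rescale_floor)
  absolute <- if (m == 0) abs(signed) else abs(signed) / scale
  structure(list(signed = signed, absolute = absolute, scale = scale),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf(
    "<change_map> %d x %d, |signed| max %.4g, scale %.4g\n",
    nrow(x$signed), ncol(x$signed), max(abs(x$signed)), x$scale
  ))
  invisible(x)
}

#' Threshold a change map into a binary change mask
#'
#' @param map A `change_map` (its `absolute` component, already in `[0, 1]`,
#'   is thresholded).
#' @param threshold Real in `[0, 1]`; pixels with `absolute >= threshold`
#'   are marked changed.
#' @return A `change_mask` (list with logical matrix `mask`).
#' @export
binarize <- function(map, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  new_change_mask(map$absolute >= threshold)
}

new_change_mask <- function(m) {
  structure(list(mask = m), class = "change_mask")
}

#' @export
print.change_mask <- function(x, ...) {
  cat(sprintf(
    "<change_mask> %d x %d, %d positive (%.3f%%)\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask), 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Area fraction of a change mask
#' @param mask A `change_mask` or logical matrix.
#' @return Fraction of positive pixels in `[0, 1]`.
#' @export
mask_area_fraction <- function(mask) mean(mask_pixels(mask))

disc_kernel <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Morphologically clean a binary change mask
#'
#' Binary opening (removes speckle smaller than the opening disc), then
#' closing (bridges small gaps), then removal of 8-connected components
#' smaller than `min_area` pixels, optionally followed by hole filling. The
#' defaults suit fundus images at a few hundred pixels per side.
#'
#' @param mask A `change_mask` or logical matrix.
#' @param open_radius,close_radius Disc radii in pixels (0 skips the step).
#' @param min_area Minimum surviving component area in pixels (0 keeps all).
#' @param fill_holes Fill enclosed holes of surviving components (used for
#'   the coarse region-of-interest mask in the fusion pathway).
#' @param dilate_radius Final dilation disc radius (0 skips; used to let the
#'   coarse fusion gate over-cover the lesion rim).
#' @return A cleaned `change_mask`.
#' @export
clean_mask <- function(mask, open_radius = 1L, close_radius = 3L,
                       min_area = 20L, fill_holes = FALSE,
                       dilate_radius = 0L) {
  m <- mask_pixels(mask)
  if (open_radius < 0L || close_radius < 0L || dilate_radius < 0L) {
    stop("morphology radii must be >= 0", call. = FALSE)
  }
  img <- EBImage::Image(m * 1.0)
  if (open_radius > 0L) img <- EBImage::opening(img, disc_kernel(open_radius))
  if (close_radius > 0L) img <- EBImage::closing(img, disc_kernel(close_radius))
  out <- EBImage::imageData(img) > 0.5
  if (min_area > 0L && any(out)) {
    lab <- EBImage::bwlabel(EBImage::Image(out * 1.0))
    labm <- EBImage::imageData(lab)
    sizes <- tabulate(labm[labm > 0])
    keep <- which(sizes >= min_area)
    out <- matrix(labm %in% keep, nrow(out), ncol(out))
  }
  if (fill_holes && any(out)) {
    filled <- EBImage::fillHull(EBImage::Image(out * 1.0))
    out <- EBImage::imageData(filled) > 0.5
  }
  if (dilate_radius > 0L && any(out)) {
    dil <- EBImage::dilate(EBImage::Image(out * 1.0), disc_kernel(dilate_radius))
    out <- EBImage::imageData(dil) > 0.5
  }
  new_change_mask(out)
}

#' Gate an illumination-corrected difference with the SRC mask
#'
#' Elementwise product of the binary sparse-representation change mask with
#' the illumination-corrected difference map: the mask supplies a coarse but
#' illumination-robust localisation, the difference map the fine evidence
#' inside it. The gated absolute map is re-rescaled to `[0, 1]` (same floor
#' rule as [difference()]) so the fusion threshold applies on the fused map's
#' own scale.
#'
#' @param src_mask A `change_mask` from the sparse-representation pathway.
#' @param illum_corrected_diff A `change_map` (see
#'   [illum_corrected_difference()]).
#' @param rescale_floor As in [difference()].
#' @return A fused `change_map`.
#' @export
fuse <- function(src_mask, illum_corrected_diff, rescale_floor = 1e-3) {
  m <- mask_pixels(src_mask)
  d <- illum_corrected_diff
  if (!identical(dim(m), dim(d$absolute))) {
    stop(sprintf(
      "mask and map shapes differ: %d x %d vs %d x %d",
      nrow(m), ncol(m), nrow(d$absolute), ncol(d$absolute)
    ), call. = FALSE)
  }
  signed <- d$signed * m
  mx <- max(abs(d$absolute * m))
  scale <- max(mx, rescale_floor)
  absolute <- if (mx == 0) d$absolute * m else (d$absolute * m) / scale
  structure(list(signed = signed, absolute = absolute, scale = scale * d$scale),
            class = "change_map")
}

#' Default detection configuration
#'
#' @param mode `"src"` (small lesions: background subtraction alone, default
#'   threshold 0.3) or `"fusion"` (large lesions: SRC mask gating the
#'   illumination-corrected difference, default threshold 0.15).
#' @param threshold Binarisation threshold on the rescaled absolute map;
#'   `NULL` picks the mode default.
#' @param geometry A [patch_geometry].
#' @param lam `"auto"` (1/m) or a number.
#' @param stride Patch stride; `NULL` = patch size (tiling).
#' @param open_radius,close_radius,min_area Mask cleaning, see [clean_mask()].
#' @param coarse_close_radius,coarse_dilate_radius,coarse_fill In fusion
#'   mode, the closing radius, final dilation and hole-filling used to turn
#'   the thresholded SRC map (for a large lesion, often only its outline)
#'   into a filled region-of-interest gate. The gate is deliberately
#'   generous — closing at roughly half the dictionary window bridges
#'   outline fragments of lesions up to the window scale, and a small
#'   dilation admits the lesion rim — because precision inside the gate is
#'   supplied by the illumination-corrected difference, not by the gate.
#' @param illum_order,illum_iters,illum_epsilon Illumination surface
#'   parameters for the fusion pathway.
#' @param rescale_floor See [difference()].
#' @return A named list of settings (class `detect_config`).
#' @export
detect_config <- function(mode = c("src", "fusion"), threshold = NULL,
                          geometry = patch_geometry(), lam = "auto",
                          stride = NULL, open_radius = 1L, close_radius = 3L,
                          min_area = 20L, coarse_close_radius = 15L,
                          coarse_dilate_radius = 3L, coarse_fill = TRUE, illum_order = 4L,
                          illum_iters = 5L, illum_epsilon = 1e-3,
                          rescale_floor = 1e-3) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "src") 0.3 else 0.15
  structure(
    list(
      mode = mode, threshold = threshold, geometry = geometry, lam = lam,
      stride = stride, open_radius = open_radius, close_radius = close_radius,
      min_area = min_area, coarse_close_radius = coarse_close_radius,
      coarse_dilate_radius = coarse_dilate_radius, coarse_fill = coarse_fill, illum_order = illum_order,
      illum_iters = illum_iters, illum_epsilon = illum_epsilon,
      rescale_floor = rescale_floor
    ),
    class = "detect_config"
  )
}

#' Detect change regions in a registered fundus image pair
#'
#' End-to-end pipeline: reconstruct the background of the current image from
#' local reference dictionaries, subtract, rescale, threshold and
#' morphologically clean. In `"fusion"` mode the cleaned (closed,
#' hole-filled) SRC mask additionally gates an illumination-corrected
#' difference of the pair, and the final mask is the thresholded, cleaned
#' fused map — the large-lesion pathway.
#'
#' @param pair An [as_pair] image pair (grayscale, registered).
#' @param config A [detect_config()].
#' @return A `fundus_detection`: list with `map` (the SRC `change_map`),
#'   `mask` (final `change_mask`), `background`, `config`, and in fusion
#'   mode also `src_mask` (the coarse gate), `illum_diff` and `fused_map`.
#' @export
detect <- function(pair, config = detect_config()) {
  if (!inherits(pair, "image_pair")) pair <- as_pair(pair$reference, pair$current)
  bg <- reconstruct_background(pair, config$geometry, config$lam, config$stride)
  map <- difference(pair$current, bg, rescale_floor = config$rescale_floor)
  src_mask <- clean_mask(
    binarize(map, config$threshold),
    open_radius = config$open_radius, close_radius = config$close_radius,
    min_area = config$min_area
  )
  if (config$mode == "src") {
    res <- list(
      map = map, mask = src_mask, background = bg, config = config,
      mode = "src"
    )
  } else {
    coarse <- clean_mask(
      binarize(map, config$threshold),
      open_radius = config$open_radius,
      close_radius = config$coarse_close_radius,
      min_area = config$min_area, fill_holes = config$coarse_fill,
      dilate_radius = config$coarse_dilate_radius
    )
    idiff <- illum_corrected_difference(
      pair, order = config$illum_order, robust_iters = config$illum_iters,
      epsilon = config$illum_epsilon, rescale_floor = config$rescale_floor
    )
    fused <- fuse(coarse, idiff, rescale_floor = config$rescale_floor)
    final <- clean_mask(
      binarize(fused, config$threshold),
      open_radius = config$open_radius, close_radius = config$close_radius,
      min_area = config$min_area
    )
    res <- list(
      map = map, mask = final, background = bg, config = config,
      mode = "fusion", src_mask = coarse, illum_diff = idiff,
      fused_map = fused
    )
  }
  structure(res, class = "fundus_detection")
}

#' @export
print.fundus_detection <- function(x, ...) {
  cat(sprintf(
    "<fundus_detection> mode %s, %d x %d, mask area %.3f%%, mean nnz %.2f\n",
    x$mode, nrow(x$map$signed), ncol(x$map$signed),
    100 * mask_area_fraction(x$mask), x$background$mean_nnz
  ))
  invisible(x)
}
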