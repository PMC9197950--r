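#' Intensity statistics of an image
#'
#' Mean and population standard deviation of the pixel intensities, the
#' quantities used by inter-image intensity normalisation. The population
#' definition (divide by n, not n - 1) makes the normalisation postcondition
#' "output std equals target std" exact for any image size.
#'
#' @param img A [gray_image] or numeric matrix.
#' @return A list with elements `mean` and `std` (class `intensity_stats`).
#' @export
intensity_stats <- function(img) {
  x <- as.numeric(as_matrix(img))
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  structure(list(mean = m, std = s), class = "intensity_stats")
}

#' Normalise one image's intensity to another's statistics
#'
#' The affine map `(sigma_t / sigma_s) * (img - mu_s) + mu_t` that carries the
#' source image's mean/std onto the target's. Applied in both directions it
#' puts a registered pair at a common intensity level before differencing.
#' Output values may leave `[0, 1]`; they are deliberately not clipped, since
#' thresholding happens later on difference maps.
#'
#' @param source A [gray_image].
#' @param target_stats An [intensity_stats] (or list with `mean`, `std`).
#' @return A [gray_image] (possibly with values outside `[0, 1]`).
#' @export
normalize_to <- function(source, target_stats) {
  s <- intensity_stats(source)
  if (s$std <= 0) {
    stop("source image has zero intensity variance; cannot normalize",
      call. = FALSE
    )
  }
  out <- (target_stats$std / s$std) * (as_matrix(source) - s$mean) +
    target_stats$mean
  gray_image(out, allow_outside = TRUE)
}

poly_basis <- function(h, w, order) {
  # bivariate monomials r^i * c^j, i + j <= order, on [-1, 1] coordinates
  r <- if (h > 1) seq(-1, 1, length.out = h) else 0
  c <- if (w > 1) seq(-1, 1, length.out = w) else 0
  R <- matrix(r, h, w)
  C <- matrix(c, h, w, byrow = TRUE)
  cols <- list()
  for (d in 0:order) {
    for (i in d:0) {
      j <- d - i
      cols[[length(cols) + 1L]] <- as.numeric(R^i * C^j)
    }
  }
  do.call(cbind, cols)
}

#' Fit a smooth illumination surface to an image
#'
#' Fits a low-order bivariate polynomial to the log-intensity of the image by
#' iteratively reweighted least squares with Tukey biweight weights, so that
#' high-residual structures (vessels, lesions, the optic disc) are
#' down-weighted and the surface tracks the smooth illumination component.
#' This is a simplified homomorphic surface fit: it plays the role of the
#' anatomical-segmentation-based illumination models used for fundus images,
#' without requiring a segmentation.
#'
#' @param img A [gray_image].
#' @param order Polynomial order of the surface (default 4).
#' @param robust_iters Number of reweighting iterations (default 5; >= 1).
#' @param tukey_c Tukey biweight tuning constant on MAD-scaled residuals
#'   (default 4.685, the conventional 95%-efficiency value).
#' @param epsilon Offset added before taking logs (default 1e-3).
#' @return An `illumination_surface`: list with `coefficients`, `order`,
#'   `surface` (the fitted log-gain matrix), `epsilon`, and the per-iteration
#'   weighted RMS residuals.
#' @export
fit_illumination_surface <- function(img, order = 4L, robust_iters = 5L,
                                     tukey_c = 4.685, epsilon = 1e-3) {
  if (order < 0L) stop("order must be >= 0", call. = FALSE)
  if (robust_iters < 1L) stop("robust_iters must be >= 1", call. = FALSE)
  x <- as_matrix(img)
  if (!all(is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  h <- nrow(x); w <- ncol(x)
  z <- log(as.numeric(x) + epsilon)
  B <- poly_basis(h, w, order)
  wts <- rep(1, length(z))
  rms <- numeric(robust_iters)
  beta <- NULL
  for (it in seq_len(robust_iters)) {
    fit <- stats::lm.wfit(B, z, wts)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    res <- z - B %*% beta
    rms[it] <- sqrt(sum(wts * res^2) / sum(wts))
    s <- stats::mad(res, center = 0)
    if (s <= .Machine$double.eps) break # exact fit; weights irrelevant
    u <- res / (tukey_c * s)
    wts <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(wts) < ncol(B)) wts <- rep(1, length(z)) # degenerate reweighting
  }
  surface <- matrix(B %*% beta, h, w)
  structure(
    list(
      coefficients = as.numeric(beta), order = as.integer(order),
      surface = surface, epsilon = epsilon, rms = rms[rms > 0 | seq_along(rms) == 1],
      fitted_log_domain = TRUE
    ),
    class = "illumination_surface"
  )
}

#' Divide out a fitted illumination surface
#'
#' Removes the fitted smooth log-gain from the image:
#' `exp(log(img + eps) - S + mean(S)) - eps`. Re-adding the surface's mean
#' keeps the corrected image at the original brightness level: a constant
#' image is returned unchanged, an image generated as flat field x smooth
#' mean-zero log-gain is restored to the flat field when corrected with the
#' true gain surface, and for small smooth illumination the output mean
#' stays close to the input mean (exactly so only in the log domain).
#'
#' @param img A [gray_image].
#' @param surface An `illumination_surface` fitted on a grid of the same shape.
#' @return A [gray_image] (values may marginally leave `[0, 1]`).
#' @export
correct_illumination <- function(img, surface) {
  x <- as_matrix(img)
  if (!identical(dim(x), dim(surface$surface))) {
    stop("surface was fitted on a different grid shape", call. = FALSE)
  }
  eps <- surface$epsilon
  out <- exp(log(x + eps) - surface$surface + mean(surface$surface)) - eps
  gray_image(out, allow_outside = TRUE)
}

#' Illumination-corrected difference of a registered pair
#'
#' The classical differencing pathway used alongside sparse-representation
#' detection for large lesions: each image is corrected by its own fitted
#' illumination surface, the corrected current image is intensity-normalised
#' to the corrected reference, and the two are differenced.
#'
#' @param pair An [as_pair] image pair.
#' @inheritParams fit_illumination_surface
#' @param rescale_floor Passed to [difference()].
#' @return A [change_map][difference].
#' @export
illum_corrected_difference <- function(pair, order = 4L, robust_iters = 5L,
                                       tukey_c = 4.685, epsilon = 1e-3,
                                       rescale_floor = 1e-3) {
  s1 <- fit_illumination_surface(pair$reference, order, robust_iters, tukey_c, epsilon)
  s2 <- fit_illumination_surface(pair$current, order, robust_iters, tukey_c, epsilon)
  c1 <- correct_illumination(pair$reference, s1)
  c2 <- correct_illumination(pair$current, s2)
  c2n <- normalize_to(c2, intensity_stats(c1))
  difference(c2n, c1, rescale_floor = rescale_floor)
}
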