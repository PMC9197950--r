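#' Grayscale image container
#'
#' A `gray_image` is a plain numeric matrix (rows x cols) with intensities in
#' `[0, 1]`, the canonical working representation for a fundus image. The
#' constructor validates finiteness and, unless `allow_outside = TRUE`, the
#' intensity range. Images produced by inter-image normalisation may legally
#' leave `[0, 1]`; they are tagged but not clipped.
#'
#' @param pixels Numeric matrix of intensities.
#' @param allow_outside Allow values outside `[0, 1]` (used for normalised
#'   intermediates, never for freshly loaded images).
#' @return A `gray_image` object (numeric matrix with a class attribute).
#' @export
gray_image <- function(pixels, allow_outside = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  if (!allow_outside && (min(pixels) < 0 || max(pixels) > 1)) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(pixels, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, range [%.4f, %.4f], mean %.4f\n",
    nrow(x), ncol(x), min(x), max(x), mean(x)
  ))
  invisible(x)
}

as_matrix <- function(img) {
  x <- unclass(img)
  attr(x, "class") <- NULL
  x
}

#' Load a raster image as a grayscale intensity matrix
#'
#' Reads PNG, TIFF or JPEG, scales intensities to `[0, 1]` by the source bit
#' depth, and collapses RGB to a single channel. Fundus photographs are often
#' analysed on the green channel (best vessel/lesion contrast), so
#' `channel_policy = "green"` is offered alongside the BT.601 luma default
#' and the plain channel mean.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @param channel_policy One of `"luma"` (0.299 R + 0.587 G + 0.114 B),
#'   `"green"`, or `"mean"`. Ignored for single-channel sources.
#' @return A [gray_image].
#' @export
load_image <- function(path, channel_policy = c("luma", "green", "mean")) {
  channel_policy <- match.arg(channel_policy)
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  collapse_channels(arr, channel_policy)
}

# png/tiff/jpeg readers already divide by the bit-depth maximum, so `arr`
# arrives in [0,1]; only the channel geometry needs handling here.
collapse_channels <- function(arr, channel_policy) {
  if (length(dim(arr)) == 2L) {
    return(gray_image(arr))
  }
  if (length(dim(arr)) != 3L) {
    stop("unsupported image array with ", length(dim(arr)), " dimensions",
      call. = FALSE
    )
  }
  nch <- dim(arr)[3L]
  if (nch == 1L) {
    return(gray_image(arr[, , 1L]))
  }
  if (nch == 2L) { # gray + alpha
    return(gray_image(arr[, , 1L]))
  }
  if (nch %in% c(3L, 4L)) { # RGB(A); alpha ignored
    g <- switch(channel_policy,
      luma  = 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L],
      green = arr[, , 2L],
      mean  = (arr[, , 1L] + arr[, , 2L] + arr[, , 3L]) / 3
    )
    return(gray_image(g))
  }
  stop("unsupported channel count: ", nch, call. = FALSE)
}

#' Write a grayscale image or mask to disk
#'
#' `save_image()` writes real-valued maps: 8-bit PNG (values clipped to
#' `[0, 1]` and quantised), 16-bit integer TIFF, or 32-bit float TIFF
#' (values stored as-is). `save_mask()` writes a binary mask as an 8-bit PNG
#' with values 0/255.
#'
#' @param img A [gray_image] or numeric matrix.
#' @param path Output path; format chosen by extension (.png/.tif/.tiff).
#' @param bit_depth For TIFF output, 16 (quantised) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bit_depth = 32L) {
  x <- as_matrix(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(x, 0), 1), target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bit_depth %in% c(16L, 32L)) stop("bit_depth must be 16 or 32", call. = FALSE)
    if (bit_depth == 16L) x <- pmin(pmax(x, 0), 1)
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bit_depth),
                    compression = "none")
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname save_image
#' @param mask A logical matrix or `change_mask`.
#' @export
save_mask <- function(mask, path) {
  m <- mask_pixels(mask)
  png::writePNG(m * 1.0, target = path)
  invisible(path)
}

#' Pair two registered grayscale images
#'
#' Bundles the earlier (reference) and later (current) image of the same
#' retina. The images must already be registered and therefore co-dimensional.
#'
#' @param reference,current [gray_image] objects of identical shape.
#' @return An `image_pair` (list with elements `reference` and `current`).
#' @export
as_pair <- function(reference, current) {
  reference <- if (inherits(reference, "gray_image")) reference else gray_image(reference)
  current <- if (inherits(current, "gray_image")) current else gray_image(current)
  if (!identical(dim(reference), dim(current))) {
    stop(sprintf(
      "reference and current image shapes differ: %d x %d vs %d x %d",
      nrow(reference), ncol(reference), nrow(current), ncol(current)
    ), call. = FALSE)
  }
  structure(list(reference = reference, current = current), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf(
    "<image_pair> %d x %d (reference + current)\n",
    nrow(x$reference), ncol(x$reference)
  ))
  invisible(x)
}

mask_pixels <- function(mask) {
  m <- if (inherits(mask, "change_mask")) mask$mask else mask
  if (is.matrix(m) && is.numeric(m)) m <- m > 0.5
  if (!is.matrix(m) || !is.logical(m)) {
    stop("mask must be a logical matrix or change_mask", call. = FALSE)
  }
  m
}
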