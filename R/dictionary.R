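#' Patch/dictionary geometry
#'
#' The geometry of local background dictionaries: square patches of side
#' `patch_size` (s, odd so a patch has a centre pixel), drawn from a square
#' neighbourhood window of side `window_size` (l > s) in the reference image,
#' with `grid` (g) atom centres per axis, giving q = g^2 atoms. The defaults
#' (s = 25, l = 50, g = 5) give 25 atoms of 625 pixels each, i.e. a 625 x 25
#' dictionary per patch.
#'
#' @param patch_size Odd integer >= 3, patch side in pixels.
#' @param window_size Neighbourhood window side in pixels; must exceed
#'   `patch_size`.
#' @param grid Atom centres per axis (>= 1).
#' @return A `patch_geometry` list with `patch_size`, `window_size`, `grid`,
#'   and the derived `p` (= s^2) and `q` (= g^2).
#' @export
patch_geometry <- function(patch_size = 25L, window_size = 50L, grid = 5L) {
  patch_size <- as.integer(patch_size)
  window_size <- as.integer(window_size)
  grid <- as.integer(grid)
  if (patch_size < 3L || patch_size %% 2L == 0L) {
    stop("patch_size must be odd and >= 3", call. = FALSE)
  }
  if (window_size <= patch_size) {
    stop("window_size must be larger than patch_size", call. = FALSE)
  }
  if (grid < 1L) stop("grid must be >= 1", call. = FALSE)
  structure(
    list(
      patch_size = patch_size, window_size = window_size, grid = grid,
      p = patch_size^2L, q = grid^2L
    ),
    class = "patch_geometry"
  )
}

#' Margin needed to zero-pad the reference for dictionary extraction
#'
#' Every atom of every dictionary fits inside the padded reference when the
#' pad margin is at least `(window_size + patch_size) / 2` (rounded up).
#'
#' @param geometry A [patch_geometry].
#' @return Integer margin in pixels.
#' @export
pad_margin <- function(geometry) {
  as.integer(ceiling((geometry$window_size + geometry$patch_size) / 2))
}

#' Zero-pad an image border
#'
#' @param img A [gray_image].
#' @param margin Non-negative pad width in pixels on every side.
#' @return A [gray_image] of shape `(h + 2*margin, w + 2*margin)` with the
#'   original image centred and a zero border.
#' @export
pad_reference <- function(img, margin) {
  margin <- as.integer(margin)
  if (margin < 0L) stop("margin must be >= 0", call. = FALSE)
  x <- as_matrix(img)
  if (margin == 0L) return(gray_image(x))
  out <- matrix(0, nrow(x) + 2L * margin, ncol(x) + 2L * margin)
  out[(margin + 1L):(margin + nrow(x)), (margin + 1L):(margin + ncol(x))] <- x
  gray_image(out)
}

#' Extract and vectorise a square patch
#'
#' Coordinates are 0-based `(row, col)`; a patch of odd side s centred on
#' pixel `center` covers rows and columns `center +/- (s - 1) / 2`. The patch
#' is vectorised row-major (first row, then second row, ...).
#'
#' @param img A [gray_image] (typically the padded reference).
#' @param center Length-2 integer vector, 0-based `(row, col)` centre.
#' @param patch_size Odd patch side.
#' @return Numeric vector of length `patch_size^2`.
#' @export
extract_patch <- function(img, center, patch_size) {
  x <- as_matrix(img)
  half <- (patch_size - 1L) %/% 2L
  r0 <- center[1L] - half
  c0 <- center[2L] - half
  if (r0 < 0L || c0 < 0L ||
      r0 + patch_size > nrow(x) || c0 + patch_size > ncol(x)) {
    stop(sprintf(
      "patch of size %d centred at (%d, %d) exceeds image bounds %d x %d; pad first",
      patch_size, center[1L], center[2L], nrow(x), ncol(x)
    ), call. = FALSE)
  }
  # 1-based slice, then row-major vectorisation via the transpose
  as.numeric(t(x[(r0 + 1L):(r0 + patch_size), (c0 + 1L):(c0 + patch_size)]))
}

grid_offsets <- function(window_size, grid) {
  if (grid == 1L) return(0L)
  as.integer(round(seq(-window_size / 2, window_size / 2, length.out = grid)))
}

#' Build the local background dictionary at one pixel
#'
#' Takes `g^2` neighbourhood patches of the (zero-padded) reference image,
#' centred on a uniform g x g grid spanning the l x l window centred at
#' `center` (window border included, grid positions rounded to the nearest
#' pixel), vectorises each patch and stacks them as columns, ordered row-major
#' over the grid. With the default geometry this reproduces 25 atoms of
#' 25 x 25 pixels spread over a 50-pixel square.
#'
#' @param reference The zero-padded reference [gray_image] (pad by at least
#'   [pad_margin()]).
#' @param center 0-based `(row, col)` centre *in the padded image*.
#' @param geometry A [patch_geometry].
#' @return A `patch_dictionary`: list with `matrix` (p x q), `center`,
#'   `geometry`, and `atom_centers` (q x 2 matrix of 0-based centres).
#' @export
build_local_dictionary <- function(reference, center, geometry) {
  off <- grid_offsets(geometry$window_size, geometry$grid)
  centers <- as.matrix(expand.grid(dc = off, dr = off))[, c("dr", "dc"), drop = FALSE]
  # expand.grid varies its first factor fastest; selecting (dr, dc) from
  # (dc, dr) order yields row-major traversal of the grid
  atom_centers <- cbind(center[1L] + centers[, "dr"], center[2L] + centers[, "dc"])
  D <- matrix(0, geometry$p, geometry$q)
  for (j in seq_len(geometry$q)) {
    D[, j] <- extract_patch(reference, atom_centers[j, ], geometry$patch_size)
  }
  structure(
    list(matrix = D, center = center, geometry = geometry,
         atom_centers = atom_centers),
    class = "patch_dictionary"
  )
}
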