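#' Configuration of the synthetic fundus-pair generator
#'
#' Defines the simulated study conditions: a smooth fundus-like background
#' with dark curvilinear vessels, smooth multiplicative/additive illumination
#' fields drawn independently for the two images, bright lesions
#' alpha-blended into the current image (default blend 0.5, the coefficient
#' used for pasted-lesion simulation), additive Gaussian noise, and an
#' optional sub-pixel jitter standing in for residual registration error.
#' Every component is independently switchable so tests can isolate causes.
#'
#' @param height,width Image size in pixels.
#' @param seed Integer seed; one seed, one output (bitwise).
#' @param n_vessels Number of vessel walks (0 disables vessels and the
#'   optic-disc blob they emanate from, leaving a pure radial vignette).
#' @param vessel_contrast Vessel darkening in intensity units.
#' @param n_lesions Number of lesions blended into the current image.
#' @param lesion_size_range Length-2 range of lesion diameters in pixels.
#' @param lesion_contrast Lesion plateau contrast (sign gives polarity).
#' @param blend_alpha Alpha-blend coefficient in `[0, 1]` (0.5 default).
#' @param gain_order Polynomial order of the multiplicative gain field.
#' @param gain_amplitude Maximum absolute gain (0.2 default).
#' @param bias_amplitude Maximum absolute additive bias (0.05 default).
#' @param bump_count Number of Gaussian illumination bumps (2 default).
#' @param bump_sigma Bump width in pixels.
#' @param noise_sigma Additive Gaussian noise SD in intensity units.
#' @param jitter Maximum sub-pixel translation of the current image (pixels).
#' @return A `sim_config` list.
#' @export
sim_config <- function(height = 192L, width = 192L, seed = 1L,
                       n_vessels = 8L, vessel_contrast = 0.25,
                       n_lesions = 5L, lesion_size_range = c(7L, 15L),
                       lesion_contrast = 0.3, blend_alpha = 0.5,
                       gain_order = 2L, gain_amplitude = 0.2,
                       bias_amplitude = 0.05, bump_count = 2L,
                       bump_sigma = 25, noise_sigma = 0.005, jitter = 0.5) {
  stopifnot(
    height >= 8, width >= 8, n_vessels >= 0, vessel_contrast >= 0,
    n_lesions >= 0, length(lesion_size_range) == 2,
    lesion_size_range[1] > 0, lesion_size_range[2] >= lesion_size_range[1],
    blend_alpha >= 0, blend_alpha <= 1, gain_order >= 0,
    gain_amplitude >= 0, bias_amplitude >= 0, bump_count >= 0,
    bump_sigma > 0, noise_sigma >= 0, jitter >= 0
  )
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      seed = as.integer(seed), n_vessels = as.integer(n_vessels),
      vessel_contrast = vessel_contrast, n_lesions = as.integer(n_lesions),
      lesion_size_range = lesion_size_range, lesion_contrast = lesion_contrast,
      blend_alpha = blend_alpha, gain_order = as.integer(gain_order),
      gain_amplitude = gain_amplitude, bias_amplitude = bias_amplitude,
      bump_count = as.integer(bump_count), bump_sigma = bump_sigma,
      noise_sigma = noise_sigma, jitter = jitter
    ),
    class = "sim_config"
  )
}

# run expr under a stage-specific deterministic seed, restoring RNG state
with_stage_seed <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((abs(cfg$seed) %% 100000000L) * 10L + offset)
  force(expr)
}

radial_field <- function(h, w, r0 = NULL, c0 = NULL) {
  if (is.null(r0)) r0 <- (h - 1) / 2
  if (is.null(c0)) c0 <- (w - 1) / 2
  R <- matrix(0:(h - 1), h, w)
  C <- matrix(0:(w - 1), h, w, byrow = TRUE)
  sqrt((R - r0)^2 + (C - c0)^2)
}

gaussian_bump <- function(h, w, r0, c0, sigma) {
  exp(-radial_field(h, w, r0, c0)^2 / (2 * sigma^2))
}

blur <- function(x, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma))
}

#' Generate a fundus-like background image
#'
#' A bright disc with a quadratic radial vignette; when `n_vessels > 0`, a
#' bright optic-disc-like blob is added and dark curvilinear vessels are
#' drawn as random smoothed walks branching out of it. Deterministic per
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A [gray_image] with attribute `"vessel_pixels"` (n x 2 matrix of
#'   1-based centreline coordinates, possibly empty).
#' @export
generate_background <- function(cfg) {
  h <- cfg$height
  w <- cfg$width
  rmax <- sqrt(((h - 1) / 2)^2 + ((w - 1) / 2)^2)
  img <- 0.70 - 0.35 * (radial_field(h, w) / rmax)^2
  vessel_px <- matrix(numeric(0), 0, 2)
  if (cfg$n_vessels > 0L) {
    res <- with_stage_seed(cfg, 1L, {
      disc_r <- (h - 1) / 2 + 0.05 * h * stats::rnorm(1)
      disc_c <- 0.72 * (w - 1)
      disc <- 0.18 * gaussian_bump(h, w, disc_r, disc_c, w / 14)
      vmask <- matrix(0, h, w)
      pts <- list()
      for (v in seq_len(cfg$n_vessels)) {
        ang <- stats::runif(1, 0, 2 * pi)
        pos <- c(disc_r, disc_c)
        thick <- sample(1:2, 1)
        nsteps <- as.integer(1.1 * max(h, w))
        for (st in seq_len(nsteps)) {
          ang <- ang + stats::rnorm(1, 0, 0.10)
          pos <- pos + c(sin(ang), cos(ang))
          rr <- round(pos[1]) + 1L
          cc <- round(pos[2]) + 1L
          if (rr < 1L || rr > h || cc < 1L || cc > w) break
          ri <- max(1L, rr - thick + 1L):min(h, rr + thick - 1L)
          ci <- max(1L, cc - thick + 1L):min(w, cc + thick - 1L)
          vmask[ri, ci] <- 1
          pts[[length(pts) + 1L]] <- c(rr, cc)
        }
      }
      list(disc = disc, vmask = vmask, pts = pts)
    })
    img <- img + res$disc
    vfield <- blur(res$vmask, 0.8)
    if (max(vfield) > 0) vfield <- vfield / max(vfield)
    img <- img - cfg$vessel_contrast * vfield
    if (length(res$pts) > 0) vessel_px <- do.call(rbind, res$pts)
  }
  img <- pmin(pmax(img, 0.02), 0.98)
  out <- gray_image(img)
  attr(out, "vessel_pixels") <- vessel_px
  out
}

random_poly_field <- function(h, w, order, amplitude) {
  if (amplitude <= 0) return(matrix(0, h, w))
  B <- poly_basis(h, w, order)
  f <- matrix(B %*% stats::rnorm(ncol(B)), h, w)
  m <- max(abs(f))
  if (m == 0) return(matrix(0, h, w))
  f / m * amplitude
}

#' Apply a random smooth illumination field
#'
#' `out = clip(img * (1 + gain) + bias, 0, 1)`, where the gain is a random
#' polynomial of order `gain_order` scaled to `max|gain| = gain_amplitude`
#' plus `bump_count` Gaussian bumps of width `bump_sigma` (random centre,
#' sign and 50-100% of the gain amplitude), and the bias is a random planar
#' field scaled to `bias_amplitude`. The reference and current draws are
#' independent, emulating the illumination difference between two visits.
#'
#' @param img A [gray_image].
#' @param cfg A [sim_config()].
#' @param which `"reference"` or `"current"` (separate random draws).
#' @return A [gray_image] in `[0, 1]`.
#' @export
apply_illumination <- function(img, cfg, which = c("reference", "current")) {
  which <- match.arg(which)
  offset <- if (which == "reference") 2L else 3L
  x <- as_matrix(img)
  h <- nrow(x)
  w <- ncol(x)
  out <- with_stage_seed(cfg, offset, {
    gain <- random_poly_field(h, w, cfg$gain_order, cfg$gain_amplitude)
    if (cfg$bump_count > 0L && cfg$gain_amplitude > 0) {
      for (b in seq_len(cfg$bump_count)) {
        r0 <- stats::runif(1, 0.1 * h, 0.9 * h)
        c0 <- stats::runif(1, 0.1 * w, 0.9 * w)
        amp <- cfg$gain_amplitude * stats::runif(1, 0.5, 1) * sample(c(-1, 1), 1)
        gain <- gain + amp * gaussian_bump(h, w, r0, c0, cfg$bump_sigma)
      }
    }
    bias <- random_poly_field(h, w, 1L, cfg$bias_amplitude)
    x * (1 + gain) + bias
  })
  gray_image(pmin(pmax(out, 0), 1))
}

#' Blend lesions into an image and return the exact ground truth
#'
#' Each lesion is an elliptical support with diameters drawn from
#' `lesion_size_range`, placed uniformly away from the image border. The
#' lesion texture is the background plus a constant plateau of
#' `lesion_contrast` with a Gaussian-smoothed edge (sigma 1 px), and is
#' alpha-blended: inside the support,
#' `out = (1 - blend_alpha) * img + blend_alpha * texture`. The ground-truth
#' mask is exactly the union of the supports.
#'
#' @param img A [gray_image] (the current image's anatomy).
#' @param cfg A [sim_config()].
#' @return A list: `image` ([gray_image]), `truth` (`change_mask`), and
#'   `lesions` (tibble of realized centres/diameters, 0-based coordinates).
#' @export
inject_lesions <- function(img, cfg) {
  x <- as_matrix(img)
  h <- nrow(x)
  w <- ncol(x)
  truth <- matrix(FALSE, h, w)
  if (cfg$n_lesions == 0L) {
    return(list(
      image = gray_image(x), truth = new_change_mask(truth),
      lesions = tibble::tibble(
        row = numeric(0), col = numeric(0),
        diam_r = numeric(0), diam_c = numeric(0), area = integer(0)
      )
    ))
  }
  margin <- ceiling(max(cfg$lesion_size_range) / 2) + 2
  if (2 * margin >= min(h, w)) {
    stop("image too small to place lesions of the requested size", call. = FALSE)
  }
  out <- x
  les <- with_stage_seed(cfg, 4L, {
    rows <- list()
    for (i in seq_len(cfg$n_lesions)) {
      dr <- stats::runif(1, cfg$lesion_size_range[1], cfg$lesion_size_range[2])
      dc <- stats::runif(1, cfg$lesion_size_range[1], cfg$lesion_size_range[2])
      placed <- FALSE
      for (try in 1:100) {
        r0 <- stats::runif(1, margin, h - 1 - margin)
        c0 <- stats::runif(1, margin, w - 1 - margin)
        R <- matrix(0:(h - 1), h, w)
        C <- matrix(0:(w - 1), h, w, byrow = TRUE)
        supp <- ((R - r0) / (dr / 2))^2 + ((C - c0) / (dc / 2))^2 <= 1
        if (any(supp)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place lesion after 100 attempts", call. = FALSE)
      rows[[i]] <- list(supp = supp, row = r0, col = c0, dr = dr, dc = dc)
    }
    rows
  })
  meta <- vector("list", length(les))
  for (i in seq_along(les)) {
    supp <- les[[i]]$supp
    edge <- blur(supp * 1.0, 1)
    if (max(edge) > 0) edge <- edge / max(edge)
    texture <- pmin(1, x + cfg$lesion_contrast * edge)
    out[supp] <- (1 - cfg$blend_alpha) * out[supp] +
      cfg$blend_alpha * texture[supp]
    truth <- truth | supp
    meta[[i]] <- tibble::tibble(
      row = les[[i]]$row, col = les[[i]]$col,
      diam_r = les[[i]]$dr, diam_c = les[[i]]$dc, area = sum(supp)
    )
  }
  list(
    image = gray_image(pmin(pmax(out, 0), 1)),
    truth = new_change_mask(truth),
    lesions = do.call(rbind, meta)
  )
}

# sub-pixel translation by bilinear interpolation, replicated edges
shift_subpixel <- function(x, dy, dx) {
  if (dy == 0 && dx == 0) return(x)
  h <- nrow(x)
  w <- ncol(x)
  r <- (1:h) - dy
  c <- (1:w) - dx
  r0 <- pmin(pmax(floor(r), 1), h)
  r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(c), 1), w)
  c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(r - r0, 0), 1)
  fc <- pmin(pmax(c - c0, 0), 1)
  A <- x[r0, c0, drop = FALSE]
  B <- x[r0, c1, drop = FALSE]
  C <- x[r1, c0, drop = FALSE]
  D <- x[r1, c1, drop = FALSE]
  FR <- matrix(fr, h, w)
  FC <- matrix(fc, h, w, byrow = TRUE)
  A * (1 - FR) * (1 - FC) + B * (1 - FR) * FC + C * FR * (1 - FC) + D * FR * FC
}

#' Generate a registered synthetic fundus image pair with ground truth
#'
#' Composes one shared anatomy (background + vessels) into a reference image
#' (own illumination draw + noise) and a current image (lesions blended in,
#' optional sub-pixel jitter, own illumination draw + noise). With lesions,
#' illumination, noise and jitter all disabled, the two images are identical.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_pair`: list with `pair` ([as_pair]), `truth`
#'   (`change_mask`), `lesions` (tibble) and `config`.
#' @export
generate_pair <- function(cfg) {
  base <- generate_background(cfg)
  h <- cfg$height
  w <- cfg$width
  ref <- apply_illumination(base, cfg, "reference")
  if (cfg$noise_sigma > 0) {
    ref <- gray_image(pmin(pmax(
      as_matrix(ref) +
        with_stage_seed(cfg, 5L, matrix(stats::rnorm(h * w, 0, cfg$noise_sigma), h, w)),
      0
    ), 1))
  }
  lesioned <- inject_lesions(base, cfg)
  cur_anat <- as_matrix(lesioned$image)
  if (cfg$jitter > 0) {
    sh <- with_stage_seed(cfg, 7L, stats::runif(2, -cfg$jitter, cfg$jitter))
    cur_anat <- shift_subpixel(cur_anat, sh[1], sh[2])
  }
  cur <- apply_illumination(gray_image(cur_anat), cfg, "current")
  if (cfg$noise_sigma > 0) {
    cur <- gray_image(pmin(pmax(
      as_matrix(cur) +
        with_stage_seed(cfg, 6L, matrix(stats::rnorm(h * w, 0, cfg$noise_sigma), h, w)),
      0
    ), 1))
  }
  structure(
    list(
      pair = as_pair(ref, cur), truth = lesioned$truth,
      lesions = lesioned$lesions, config = cfg
    ),
    class = "sim_pair"
  )
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf(
    "<sim_pair> %d x %d, %d lesion(s), truth area %.2f%%, seed %d\n",
    x$config$height, x$config$width,
    if (is.null(nrow(x$lesions))) 0L else nrow(x$lesions),
    100 * mask_area_fraction(x$truth), x$config$seed
  ))
  invisible(x)
}
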