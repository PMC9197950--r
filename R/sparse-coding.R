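#' Solve the patch sparse-coding problem
#'
#' Minimises the elastic objective used for background representation,
#' \deqn{\|x - D\alpha\|_2^2 + \lambda \|\alpha\|_1,}
#' exactly as written (no 1/2 on the quadratic term), by the LARS-lasso
#' homotopy: the full regularisation path is traced from the empty model
#' downwards, with the lasso modification (atoms whose coefficient crosses
#' zero are dropped), and stopped at the requested \eqn{\lambda}. At a
#' stationary point the active-atom correlations satisfy
#' \eqn{|d_j'(x - D\alpha)| = \lambda / 2}, so the path is run to correlation
#' level \eqn{\lambda / 2}.
#'
#' Ties on entry are broken by the lowest column index; atoms numerically
#' collinear with the active set (e.g. duplicated atoms from a constant
#' image region) are skipped, which keeps the solver deterministic and
#' well-defined on degenerate dictionaries. An all-zero dictionary returns
#' the zero code.
#'
#' @param x Numeric signal vector of length p.
#' @param D A `patch_dictionary` or a p x q numeric matrix of atoms.
#' @param lam Non-negative penalty \eqn{\lambda}.
#' @return A `sparse_code`: list with `alpha` (length q), `lam`, `objective`
#'   (the objective value at `alpha`), `nnz`, and `residual` (x - D alpha).
#' @export
solve_lasso <- function(x, D, lam) {
  Dm <- if (inherits(D, "patch_dictionary")) D$matrix else as.matrix(D)
  if (length(x) != nrow(Dm)) {
    stop("length(x) must equal nrow(D)", call. = FALSE)
  }
  if (lam < 0) stop("lam must be >= 0", call. = FALSE)
  alpha <- lars_lasso(x, Dm, target = lam / 2)
  r <- x - Dm %*% alpha
  structure(
    list(
      alpha = alpha, lam = lam,
      objective = sum(r^2) + lam * sum(abs(alpha)),
      nnz = sum(alpha != 0), residual = as.numeric(r)
    ),
    class = "sparse_code"
  )
}

# LARS-lasso path, stopped when the maximal absolute correlation d_j'(x - D a)
# reaches `target`. Deterministic; ties broken by lowest column index.
lars_lasso <- function(x, D, target, tol = 1e-12, max_steps = NULL) {
  q <- ncol(D)
  alpha <- numeric(q)
  cvec <- as.numeric(crossprod(D, x)) # current correlations
  excluded <- rep(FALSE, q)           # atoms collinear with the active set
  active <- integer(0)
  signs <- numeric(0)
  if (is.null(max_steps)) max_steps <- 8L * q + 50L
  Cmax <- max(abs(cvec), 0)
  if (Cmax <= target + tol) return(alpha)
  # first entry: lowest index among the (near-)maximal correlations
  j <- which(abs(cvec) >= Cmax - tol)[1L]
  active <- j
  signs <- sign(cvec[j])

  for (step in seq_len(max_steps)) {
    DA <- D[, active, drop = FALSE]
    G <- crossprod(DA)
    w <- tryCatch(solve(G, signs), error = function(e) NULL)
    if (is.null(w)) {
      # rank-deficient active set: drop the most recent atom for good
      k <- length(active)
      excluded[active[k]] <- TRUE
      active <- active[-k]
      signs <- signs[-k]
      if (length(active) == 0L) break
      next
    }
    u <- DA %*% w              # equiangular direction in signal space
    a <- as.numeric(crossprod(D, u))
    # active correlations all sit at Cmax and decrease at unit rate along w
    gamma_stop <- Cmax - target
    gamma <- gamma_stop
    event <- "stop"
    enter_j <- NA_integer_

    cand <- which(!excluded & !(seq_len(q) %in% active))
    if (length(cand) > 0L) {
      g1 <- (Cmax - cvec[cand]) / (1 - a[cand])
      g2 <- (Cmax + cvec[cand]) / (1 + a[cand])
      g1[!is.finite(g1) | g1 <= tol | abs(1 - a[cand]) < tol] <- Inf
      g2[!is.finite(g2) | g2 <= tol | abs(1 + a[cand]) < tol] <- Inf
      ge <- pmin(g1, g2)
      if (any(is.finite(ge))) {
        gmin <- min(ge)
        if (gmin < gamma - tol) {
          gamma <- gmin
          event <- "enter"
          enter_j <- cand[which(ge <= gmin + tol)[1L]]
        }
      }
    }
    # lasso modification: coefficient sign crossings
    gd <- -alpha[active] / w
    gd[!is.finite(gd) | gd <= tol] <- Inf
    if (any(is.finite(gd))) {
      gdmin <- min(gd)
      if (gdmin < gamma - tol) {
        gamma <- gdmin
        event <- "drop"
      }
    }

    alpha[active] <- alpha[active] + gamma * w
    cvec <- cvec - gamma * a
    Cmax <- Cmax - gamma
    if (event == "stop" || Cmax <= target + tol) {
      break
    } else if (event == "drop") {
      k <- which(gd <= gamma + tol)[1L]
      alpha[active[k]] <- 0
      active <- active[-k]
      signs <- signs[-k]
      if (length(active) == 0L) {
        if (Cmax <= target + tol) break
        j <- which(abs(cvec) >= Cmax - tol & !excluded)[1L]
        if (is.na(j)) break
        active <- j
        signs <- sign(cvec[j])
      }
    } else { # enter
      active <- c(active, enter_j)
      signs <- c(signs, sign(cvec[enter_j]))
    }
  }
  alpha
}

#' Reconstruct the background of a single patch
#'
#' The sparse code of the current patch under its local reference dictionary
#' is computed and the background estimate `D %*% alpha` returned; pixels of
#' the patch not explained by the reference neighbourhood (lesions) remain in
#' the residual `x - D %*% alpha`.
#'
#' @inheritParams solve_lasso
#' @return Numeric vector of length p (the background patch), with the
#'   `sparse_code` attached as attribute `"code"`.
#' @export
reconstruct_patch_background <- function(x, D, lam) {
  Dm <- if (inherits(D, "patch_dictionary")) D$matrix else as.matrix(D)
  code <- solve_lasso(x, Dm, lam)
  out <- as.numeric(Dm %*% code$alpha)
  attr(out, "code") <- code
  out
}

patch_centers_1d <- function(extent, patch_size, stride) {
  half <- (patch_size - 1L) %/% 2L
  last <- extent - 1L - half
  centers <- seq.int(half, last, by = stride)
  if (centers[length(centers)] != last) centers <- c(centers, last)
  centers
}

#' Reconstruct the background of the current image
#'
#' Slides a patch grid over the current image (stride-spaced centres plus
#' final row/column centres so every pixel is covered), solves the lasso
#' problem for each patch against its local reference dictionary, and
#' accumulates the reconstructed background patches into the background image
#' B2. Where patches overlap, contributions are averaged per pixel.
#'
#' The default `lam = "auto"` uses \eqn{\lambda = 1/m} with m the pixel count
#' of the current image. The default stride equals the patch size
#' (non-overlapping tiling).
#'
#' @param pair An [as_pair] image pair.
#' @param geometry A [patch_geometry].
#' @param lam `"auto"` (= 1/m) or a non-negative number.
#' @param stride Patch-centre spacing in pixels (>= 1); defaults to the patch
#'   size.
#' @return A `background_image`: list with `pixels` ([gray_image], values may
#'   slightly leave `[0,1]`), `coverage` (integer matrix, >= 1 everywhere),
#'   `lam`, `mean_nnz` and `mean_residual` (mean per-patch L2 residual).
#' @export
reconstruct_background <- function(pair, geometry = patch_geometry(),
                                   lam = "auto", stride = NULL) {
  s <- geometry$patch_size
  half <- (s - 1L) %/% 2L
  if (is.null(stride)) stride <- s
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  cur <- as_matrix(pair$current)
  h <- nrow(cur); w <- ncol(cur)
  if (identical(lam, "auto")) lam <- 1 / (h * w)
  if (!is.numeric(lam) || lam < 0) stop("lam must be >= 0 or \"auto\"", call. = FALSE)

  # pad the current image only if it is smaller than one patch
  pad_cur <- max(0L, s - h, s - w)
  if (pad_cur > 0L) {
    cur_p <- matrix(0, h + 2L * pad_cur, w + 2L * pad_cur)
    cur_p[pad_cur + seq_len(h), pad_cur + seq_len(w)] <- cur
  } else {
    cur_p <- cur
  }
  hp <- nrow(cur_p); wp <- ncol(cur_p)

  margin <- pad_margin(geometry) + pad_cur
  ref_p <- pad_reference(pair$reference, margin)

  rows <- patch_centers_1d(hp, s, stride)
  cols <- patch_centers_1d(wp, s, stride)
  B <- matrix(0, hp, wp)
  coverage <- matrix(0L, hp, wp)
  nnz_sum <- 0; res_sum <- 0; npatch <- 0L

  for (r in rows) {
    for (cc in cols) {
      x <- extract_patch(gray_image(cur_p, allow_outside = TRUE), c(r, cc), s)
      # identity correspondence: the dictionary window in the padded reference
      # is centred on the same (row, col), offset by the pad margins
      Dd <- build_local_dictionary(
        ref_p, c(r - pad_cur + margin, cc - pad_cur + margin), geometry
      )
      code <- solve_lasso(x, Dd$matrix, lam)
      bp <- matrix(Dd$matrix %*% code$alpha, s, s, byrow = TRUE)
      ri <- (r - half + 1L):(r + half + 1L)
      ci <- (cc - half + 1L):(cc + half + 1L)
      B[ri, ci] <- B[ri, ci] + bp
      coverage[ri, ci] <- coverage[ri, ci] + 1L
      nnz_sum <- nnz_sum + code$nnz
      res_sum <- res_sum + sqrt(sum(code$residual^2))
      npatch <- npatch + 1L
    }
  }
  B <- B / pmax(coverage, 1L)
  if (pad_cur > 0L) {
    B <- B[pad_cur + seq_len(h), pad_cur + seq_len(w), drop = FALSE]
    coverage <- coverage[pad_cur + seq_len(h), pad_cur + seq_len(w), drop = FALSE]
  }
  structure(
    list(
      pixels = gray_image(B, allow_outside = TRUE), coverage = coverage,
      lam = lam, mean_nnz = nnz_sum / npatch, mean_residual = res_sum / npatch,
      n_patches = npatch
    ),
    class = "background_image"
  )
}

#' @export
print.background_image <- function(x, ...) {
  cat(sprintf(
    "<background_image> %d x %d, %d patches, lambda %.3g, mean nnz %.2f, mean residual %.4g\n",
    nrow(x$pixels), ncol(x$pixels), x$n_patches, x$lam, x$mean_nnz, x$mean_residual
  ))
  invisible(x)
}
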