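# Independent oracles used to cross-check the implementation.
# These deliberately use different algorithms from the package code paths.

# Cyclic coordinate descent on ||x - D a||_2^2 + lam * ||a||_1, run to
# convergence. Independent of the homotopy solver in the package.
cd_lasso_oracle <- function(x, D, lam, max_iters = 100000, tol = 1e-13) {
  q <- ncol(D)
  a <- numeric(q)
  nrm <- colSums(D^2)
  r <- as.numeric(x)
  for (it in seq_len(max_iters)) {
    delta_max <- 0
    for (j in seq_len(q)) {
      if (nrm[j] == 0) next
      rho <- sum(D[, j] * r) + nrm[j] * a[j]
      new <- sign(rho) * max(abs(rho) - lam / 2, 0) / nrm[j]
      d <- new - a[j]
      if (d != 0) {
        r <- r - D[, j] * d
        a[j] <- new
      }
      delta_max <- max(delta_max, abs(d))
    }
    if (delta_max < tol) break
  }
  a
}

lasso_objective <- function(x, D, a, lam) {
  sum((x - D %*% a)^2) + lam * sum(abs(a))
}

# Mann-Whitney pair-counting AUC: fraction of concordant positive-negative
# pairs, ties counted half.
auc_pair_oracle <- function(scores, truth) {
  s_pos <- scores[truth]
  s_neg <- scores[!truth]
  total <- 0
  for (sp in s_pos) {
    total <- total + sum(sp > s_neg) + 0.5 * sum(sp == s_neg)
  }
  total / (length(s_pos) * length(s_neg))
}

# brute-force re-extraction of a dictionary column for cross-checking
extract_patch_oracle <- function(mat, center, s) {
  half <- (s - 1) %/% 2
  rows <- (center[1] - half):(center[1] + half) + 1
  cols <- (center[2] - half):(center[2] + half) + 1
  out <- numeric(s * s)
  k <- 1
  for (r in rows) {
    for (cc in cols) {
      out[k] <- mat[r, cc]
      k <- k + 1
    }
  }
  out
}

make_random_dictionary <- function(p, q, seed) {
  set.seed(seed)
  matrix(stats::rnorm(p * q), p, q)
}

# small smooth test image: vignette plus a diagonal gradient, in [0,1]
smooth_test_image <- function(h, w) {
  R <- matrix(seq(0, 1, length.out = h), h, w)
  C <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  gray_image(0.3 + 0.3 * R * C + 0.2 * (1 - (R - 0.5)^2 - (C - 0.5)^2))
}

# strip classes/attributes for matrix comparisons
as_matrix_test <- function(img) {
  matrix(as.numeric(img), nrow(img), ncol(img))
}
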