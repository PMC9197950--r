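test_that("trivial codes: zero signal, zero dictionary, single atom", {
  D <- make_random_dictionary(9, 4, seed = 1)
  sc <- solve_lasso(numeric(9), D, 0.5)
  expect_equal(sc$alpha, numeric(4))
  expect_equal(sc$objective, 0)
  expect_equal(sc$nnz, 0L)

  x <- rnorm(9)
  z <- solve_lasso(x, matrix(0, 9, 3), 0.1)
  expect_equal(z$alpha, numeric(3))
  expect_equal(z$objective, sum(x^2))

  # one-dimensional soft-threshold closed form
  set.seed(3)
  d <- rnorm(16)
  for (c0 in c(2.5, -1.2, 0.01)) {
    for (lam in c(0, 0.05, 0.4, 100)) {
      sc1 <- solve_lasso(c0 * d, matrix(d), lam)
      expected <- sign(c0) * max(abs(c0) - lam / (2 * sum(d^2)), 0)
      expect_equal(sc1$alpha, expected, tolerance = 1e-12)
    }
  }
})

test_that("the homotopy solution matches the coordinate-descent oracle", {
  set.seed(17)
  for (i in 1:40) {
    p <- sample(10:25, 1)
    q <- sample(1:10, 1)
    D <- matrix(rnorm(p * q), p, q)
    if (i %% 4 == 0 && q >= 2) D[, 1] <- D[, 2] # duplicated atoms
    x <- rnorm(p)
    lam <- sample(c(0, 1e-3, 0.05, 0.5, 2), 1)
    sc <- solve_lasso(x, D, lam)
    a_cd <- cd_lasso_oracle(x, D, lam)
    expect_lt(
      abs(sc$objective - lasso_objective(x, D, a_cd, lam)),
      1e-8
    )
    expect_equal(sc$objective, lasso_objective(x, D, sc$alpha, lam))
    expect_lte(sc$objective, sum(x^2) + 1e-12)
    expect_equal(sc$nnz, sum(sc$alpha != 0))
  }
})

test_that("solutions are stable under random perturbations (optimality)", {
  set.seed(23)
  D <- matrix(rnorm(25 * 10), 25, 10)
  x <- rnorm(25)
  lam <- 0.1
  sc <- solve_lasso(x, D, lam)
  for (scale in c(1e-3, 1e-2, 0.1)) {
    objs <- replicate(2000, {
      lasso_objective(x, D, sc$alpha + rnorm(10, 0, scale), lam)
    })
    expect_gte(min(objs), sc$objective - 1e-12)
  }
})

test_that("the glmnet penalty mapping lambda' = lambda / (2p) agrees", {
  skip_if_not_installed("glmnet")
  set.seed(29)
  p <- 50; q <- 8
  D <- matrix(rnorm(p * q), p, q)
  x <- rnorm(p)
  lam <- 0.3
  sc <- solve_lasso(x, D, lam)
  fit <- glmnet::glmnet(D, x,
    lambda = lam / (2 * p), standardize = FALSE,
    intercept = FALSE, thresh = 1e-14
  )
  a_g <- as.numeric(fit$beta)
  expect_lt(abs(sc$objective - lasso_objective(x, D, a_g, lam)), 1e-6)
})

test_that("sparsity and l1 norm are monotone in lambda; lambda -> 0 gives the projection", {
  set.seed(37)
  D <- matrix(rnorm(30 * 8), 30, 8)
  x <- rnorm(30)
  lams <- c(0, 0.01, 0.1, 0.5, 1, 5, 20)
  fits <- lapply(lams, function(l) solve_lasso(x, D, l))
  l1 <- vapply(fits, function(f) sum(abs(f$alpha)), numeric(1))
  nnz <- vapply(fits, function(f) f$nnz, numeric(1))
  expect_true(all(diff(l1) <= 1e-10))
  expect_true(all(diff(nnz) <= 0L))

  a_ls <- qr.solve(D, x)
  expect_equal(
    as.numeric(D %*% fits[[1]]$alpha), as.numeric(D %*% a_ls),
    tolerance = 1e-6
  )
})

test_that("patch background reconstruction recovers representable signals", {
  set.seed(41)
  D <- make_random_dictionary(16, 5, seed = 41)
  # exact representability at tiny lambda
  bg <- reconstruct_patch_background(D[, 3], D, 1e-10)
  expect_equal(bg, D[, 3], tolerance = 1e-6, ignore_attr = TRUE)

  # orthogonal signal: optimal code is zero, reconstruction zero
  Q <- qr.Q(qr(D), complete = TRUE)
  x_orth <- Q[, 6] # orthogonal to span(D)
  bg2 <- reconstruct_patch_background(x_orth, D, 0.01)
  expect_equal(bg2, numeric(16), tolerance = 1e-10, ignore_attr = TRUE)

  # a spike on one pixel stays in the residual
  spike <- numeric(16); spike[7] <- 0.8
  x3 <- D[, 2] + spike
  bg3 <- reconstruct_patch_background(x3, D, 1e-6)
  res <- x3 - bg3
  expect_gte(res[7]^2 / sum(res^2), 0.5)
})

test_that("full-image reconstruction reproduces the current image and absorbs gain", {
  img <- smooth_test_image(64, 64)
  geom <- patch_geometry(9L, 18L, 3L)
  pair_id <- as_pair(img, img)
  bg <- reconstruct_background(pair_id, geom)
  expect_true(all(bg$coverage >= 1L))
  expect_lt(mean(abs(as_matrix_test(bg$pixels) - as_matrix_test(img))), 1e-3)

  cur <- gray_image(pmin(1.2 * as_matrix_test(img) + 0.05, 1))
  bg2 <- reconstruct_background(as_pair(img, cur), geom)
  expect_lt(mean(abs(as_matrix_test(bg2$pixels) - as_matrix_test(cur))), 5e-3)
})

test_that("tiling covers every pixel and overlapping strides average", {
  img <- smooth_test_image(50, 41)
  geom <- patch_geometry(9L, 18L, 3L)
  bg <- reconstruct_background(as_pair(img, img), geom, stride = 9L)
  expect_true(all(bg$coverage >= 1L))
  bg2 <- reconstruct_background(as_pair(img, img), geom, stride = 4L)
  expect_true(all(bg2$coverage >= 1L))
  expect_gt(max(bg2$coverage), 1L)
  expect_lt(mean(abs(as_matrix_test(bg2$pixels) - as_matrix_test(img))), 1e-3)
})

test_that("smooth gain fields leave residuals below small-lesion contrast", {
  # the central illumination-robustness property: a lesion of contrast 0.15
  # must stand clear of the gain-only residual
  cfg <- sim_config(
    seed = 51, n_lesions = 0, noise_sigma = 0, jitter = 0,
    height = 128, width = 128
  )
  sim <- generate_pair(cfg)
  bg <- reconstruct_background(sim$pair)
  resid <- abs(as_matrix_test(sim$pair$current) - as_matrix_test(bg$pixels))
  expect_lt(quantile(resid, 0.99), 0.5 * 0.3) # blend 0.5 x contrast 0.3
})
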