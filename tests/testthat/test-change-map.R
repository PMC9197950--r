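test_that("difference maps: identity, single-pixel support, integral linearity", {
  img <- smooth_test_image(20, 20)
  d0 <- difference(img, img)
  expect_equal(d0$signed, matrix(0, 20, 20), ignore_attr = TRUE)
  expect_equal(d0$absolute, matrix(0, 20, 20), ignore_attr = TRUE)

  cur <- as_matrix_test(img)
  cur[7, 9] <- cur[7, 9] + 0.2
  d1 <- difference(gray_image(pmin(cur, 1)), img)
  expect_equal(d1$absolute[7, 9], 1)
  expect_equal(sum(d1$absolute > 0), 1L)

  set.seed(61)
  a <- gray_image(matrix(runif(100), 10, 10))
  b <- gray_image(matrix(runif(100), 10, 10))
  d2 <- difference(a, b)
  expect_equal(sum(d2$signed), sum(a) - sum(b))
  expect_equal(max(d2$absolute), 1)

  expect_error(difference(img, gray_image(matrix(0.5, 3, 3))), "differ")
})

test_that("sub-floor dynamic range is not stretched to full scale", {
  base <- smooth_test_image(16, 16)
  tiny <- gray_image(as_matrix_test(base) + 1e-6)
  d <- difference(tiny, base)
  expect_lt(max(d$absolute), 0.01)
})

test_that("binarize thresholds the rescaled map and is monotone", {
  m <- structure(
    list(
      signed = matrix(c(0.1, 0.2, 0.4, 0.05), 2, 2),
      absolute = matrix(c(0.1, 0.2, 0.4, 0.05), 2, 2) / 0.4, scale = 0.4
    ),
    class = "change_map"
  )
  # absolute [[0.1, 0.4], [0.2, 0.05]] with threshold 0.15 on the raw scale
  got <- binarize(m, 0.15 / m$scale)$mask
  expect_equal(got, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_true(all(binarize(m, 1)$mask == (m$absolute == 1)))
  expect_true(all(binarize(m, 0)$mask))
  expect_error(binarize(m, 1.5), "\\[0, 1\\]")

  ths <- seq(0, 1, by = 0.1)
  areas <- vapply(ths, function(t) sum(binarize(m, t)$mask), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("morphological cleaning removes speckle and small components only", {
  m <- matrix(FALSE, 40, 40)
  m[20, 20] <- TRUE # isolated pixel
  m[5:9, 5:14] <- TRUE # 50-pixel blob
  m[30, 30:32] <- TRUE # 3-pixel blob
  cleaned <- clean_mask(m, open_radius = 1L, close_radius = 0L, min_area = 10L)
  expect_false(cleaned$mask[20, 20])
  expect_true(all(cleaned$mask[6:8, 6:13]))
  expect_false(any(cleaned$mask[30, 30:32]))

  # identity settings change nothing
  same <- clean_mask(m, open_radius = 0L, close_radius = 0L, min_area = 0L)
  expect_equal(same$mask, m)

  # component removal never adds pixels
  set.seed(71)
  rnd <- matrix(runif(900) < 0.2, 30, 30)
  cc <- clean_mask(rnd, open_radius = 0L, close_radius = 0L, min_area = 5L)
  expect_true(all(!cc$mask | rnd))
})

test_that("fusion gates the corrected difference without leaking", {
  set.seed(73)
  dmap <- structure(
    list(
      signed = matrix(rnorm(400, 0, 0.1), 20, 20),
      absolute = NULL, scale = 1
    ),
    class = "change_map"
  )
  dmap$absolute <- abs(dmap$signed) / max(abs(dmap$signed))

  off <- fuse(matrix(FALSE, 20, 20), dmap)
  expect_equal(off$absolute, matrix(0, 20, 20))

  on <- fuse(matrix(TRUE, 20, 20), dmap)
  expect_equal(on$absolute, dmap$absolute)

  block <- matrix(FALSE, 20, 20)
  block[5:14, 5:14] <- TRUE
  g <- fuse(block, dmap)
  expect_true(all(g$absolute[!block] == 0))
  expect_true(all((g$absolute > 0) == (block & dmap$absolute > 0)))
  expect_equal(max(g$absolute), 1) # re-rescaled to its own max

  expect_error(fuse(matrix(TRUE, 3, 3), dmap), "differ")
})

test_that("detect on an identical pair yields an essentially empty mask", {
  cfg <- sim_config(
    seed = 81, n_lesions = 0, gain_amplitude = 0, bias_amplitude = 0,
    bump_count = 0, noise_sigma = 0, jitter = 0, height = 128, width = 128
  )
  sim <- generate_pair(cfg)
  expect_identical(
    as_matrix_test(sim$pair$reference),
    as_matrix_test(sim$pair$current)
  )
  det <- detect(sim$pair)
  expect_lt(mask_area_fraction(det$mask), 0.001)
})

test_that("a 41x41 lesion blended at 0.5 is localised with IOU above 0.5", {
  cfg <- sim_config(
    seed = 103, n_lesions = 1, lesion_size_range = c(41, 41),
    noise_sigma = 0, jitter = 0
  )
  sim <- generate_pair(cfg)
  det <- detect(sim$pair, detect_config(mode = "fusion"))
  expect_gt(iou(det$mask, sim$truth), 0.5)
  # gating excludes regions the sparse-representation mask rejects
  expect_true(all(!det$fused_map$absolute[!det$src_mask$mask]))
})

test_that("fusion mode keeps an illumination bump out of the final mask", {
  cfg <- sim_config(
    seed = 91, n_lesions = 1, lesion_size_range = c(31, 41),
    gain_amplitude = 0.2, bump_count = 1, noise_sigma = 0, jitter = 0
  )
  sim <- generate_pair(cfg)
  det <- detect(sim$pair, detect_config(mode = "fusion"))
  # false positives outside truth stay small relative to the truth area
  fp <- sum(det$mask$mask & !sim$truth$mask)
  expect_lt(fp, sum(sim$truth$mask))
  expect_gt(iou(det$mask, sim$truth), 0.3)
})
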