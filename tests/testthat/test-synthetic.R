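test_that("generation is deterministic per seed", {
  cfg <- sim_config(seed = 5, height = 96, width = 96)
  a <- generate_pair(cfg)
  b <- generate_pair(cfg)
  expect_identical(as_matrix_test(a$pair$reference), as_matrix_test(b$pair$reference))
  expect_identical(as_matrix_test(a$pair$current), as_matrix_test(b$pair$current))
  expect_identical(a$truth$mask, b$truth$mask)
  c <- generate_pair(sim_config(seed = 6, height = 96, width = 96))
  expect_false(identical(as_matrix_test(a$pair$current), as_matrix_test(c$pair$current)))
})

test_that("a vessel-free noiseless background is radially non-increasing", {
  cfg <- sim_config(seed = 7, n_vessels = 0, noise_sigma = 0, height = 80, width = 80)
  bgr <- generate_background(cfg)
  x <- as_matrix_test(bgr)
  ctr <- (c(nrow(x), ncol(x)) - 1) / 2
  # intensity sorted by radius from the disc centre is non-increasing
  r <- sqrt(outer(((0:(nrow(x) - 1)) - ctr[1])^2,
                  ((0:(ncol(x) - 1)) - ctr[2])^2, `+`))
  ord <- order(as.numeric(r))
  expect_true(all(diff(x[ord]) <= 1e-9))
})

test_that("vessels darken the image along their centrelines", {
  cfg <- sim_config(seed = 9, n_vessels = 6, noise_sigma = 0)
  with_v <- generate_background(cfg)
  no_v <- generate_background(sim_config(
    seed = 9, n_vessels = 0, noise_sigma = 0
  ))
  px <- attr(with_v, "vessel_pixels")
  expect_gt(nrow(px), 0)
  idx <- cbind(px[, 1], px[, 2])
  expect_gt(mean(as_matrix_test(no_v)[idx] - as_matrix_test(with_v)[idx]), 0.05)
})

test_that("illumination fields respect their amplitude budget and clip range", {
  img <- smooth_test_image(64, 64)
  cfg0 <- sim_config(seed = 11, gain_amplitude = 0, bias_amplitude = 0, bump_count = 0)
  expect_equal(
    as_matrix_test(apply_illumination(img, cfg0, "reference")),
    as_matrix_test(img)
  )
  cfg <- sim_config(seed = 11, height = 64, width = 64)
  out <- apply_illumination(img, cfg, "current")
  expect_true(all(out >= 0 & out <= 1))
  # reference and current draws differ
  out2 <- apply_illumination(img, cfg, "reference")
  expect_false(identical(as_matrix_test(out), as_matrix_test(out2)))
  # mean absolute change bounded by worst-case gain x intensity + bias;
  # bumps can add up to another gain_amplitude each where they overlap
  budget <- (cfg$gain_amplitude * (1 + cfg$bump_count)) * max(img) + cfg$bias_amplitude
  expect_lt(mean(abs(as_matrix_test(out) - as_matrix_test(img))), budget)
})

test_that("lesions blend exactly at the stated coefficient with exact truth", {
  img <- smooth_test_image(128, 128)
  cfg0 <- sim_config(seed = 13, n_lesions = 0)
  r0 <- inject_lesions(img, cfg0)
  expect_equal(as_matrix_test(r0$image), as_matrix_test(img))
  expect_false(any(r0$truth$mask))

  cfg1 <- sim_config(
    seed = 13, n_lesions = 1, lesion_size_range = c(41, 41),
    blend_alpha = 0.5, height = 128, width = 128
  )
  r1 <- inject_lesions(img, cfg1)
  supp <- r1$truth$mask
  expect_gt(sum(supp), 1000) # a 41 x 41 ellipse
  expect_equal(sum(supp), sum(r1$lesions$area))
  # inside the support the output is exactly (background + texture) / 2,
  # equivalently out - background = (texture - background) / 2 <= contrast/2
  delta <- as_matrix_test(r1$image) - as_matrix_test(img)
  expect_true(all(delta[supp] > 0))
  expect_lte(max(delta[supp]), 0.5 * cfg1$lesion_contrast + 1e-12)
  # plateau: interior pixels carry exactly half the full contrast
  interior <- EBImage::imageData(EBImage::erode(
    EBImage::Image(supp * 1.0), EBImage::makeBrush(9, "disc")
  )) > 0.5
  headroom <- as_matrix_test(img)[interior] + cfg1$lesion_contrast <= 1
  expect_equal(
    delta[interior][headroom],
    rep(0.5 * cfg1$lesion_contrast, sum(headroom)),
    tolerance = 0.01
  )
  expect_true(all(!delta[!supp]))

  # truth area equals the union of supports for several lesions
  cfg5 <- sim_config(seed = 17, n_lesions = 5, height = 128, width = 128)
  r5 <- inject_lesions(img, cfg5)
  expect_lte(sum(r5$truth$mask), sum(r5$lesions$area))
  expect_equal(nrow(r5$lesions), 5L)
})

test_that("every pairwise difference is attributable to a switchable cause", {
  base_cfg <- function(...) {
    args <- utils::modifyList(
      list(
        seed = 19, height = 96, width = 96, n_lesions = 0, gain_amplitude = 0,
        bias_amplitude = 0, bump_count = 0, noise_sigma = 0, jitter = 0
      ),
      list(...)
    )
    do.call(sim_config, args)
  }
  all_off <- generate_pair(base_cfg())
  expect_identical(
    as_matrix_test(all_off$pair$reference),
    as_matrix_test(all_off$pair$current)
  )
  expect_false(any(all_off$truth$mask))

  with_lesions <- generate_pair(base_cfg(n_lesions = 3))
  dif <- as_matrix_test(with_lesions$pair$current) !=
    as_matrix_test(with_lesions$pair$reference)
  expect_true(all(dif == with_lesions$truth$mask))

  with_noise <- generate_pair(base_cfg(noise_sigma = 0.01))
  expect_false(identical(
    as_matrix_test(with_noise$pair$reference),
    as_matrix_test(with_noise$pair$current)
  ))

  with_jitter <- generate_pair(base_cfg(jitter = 0.8))
  expect_false(identical(
    as_matrix_test(with_jitter$pair$reference),
    as_matrix_test(with_jitter$pair$current)
  ))

  # default small-lesion condition separates lesion pixels in expectation
  full <- generate_pair(sim_config(seed = 23))
  lesion_diff <- abs(
    as_matrix_test(full$pair$current) - as_matrix_test(full$pair$reference)
  )[full$truth$mask]
  expect_gt(mean(lesion_diff), 0.05)
})
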