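test_that("inversion is the affine involution on [0,1]", {
  img <- matrix(0.3, 4, 4)
  expect_equal(invert_image(img), matrix(0.7, 4, 4))
  expect_equal(invert_image(matrix(1, 3, 3)), matrix(0, 3, 3))
  rnd <- matrix(runif(25), 5, 5)
  expect_equal(invert_image(invert_image(rnd)), rnd)
  expect_error(invert_image(matrix(1.5, 2, 2)), "normalize")
})

test_that("compensation handles constant structural images analytically", {
  flow <- matrix(runif(100), 10, 10)
  # structural == 1: inverted structural is zero, compensated is all zero
  expect_equal(compensate(flow, matrix(1, 10, 10), compensation_params(),
                          pixel_size_um = 7.5),
               matrix(0, 10, 10))
  # constant structural + rescale: the constant multiplier cancels
  comp <- compensate(flow, matrix(0.6, 10, 10), compensation_params(),
                     pixel_size_um = 7.5)
  expect_equal(comp, (flow - min(flow)) / (max(flow) - min(flow)), tolerance = 1e-12)
  # pixel ordering is preserved wherever the structural image is constant
  expect_equal(order(comp), order(flow))
  expect_error(compensate(flow, matrix(0.6, 9, 10), compensation_params(), 7.5),
               "same shape")
})

test_that("gaussian blur is normalized and reflect-padded", {
  img <- matrix(0.42, 20, 20)
  expect_equal(gaussian_blur(img, 2), img, tolerance = 1e-12)  # constants are fixed points
  rnd <- matrix(runif(400), 20, 20)
  expect_equal(mean(gaussian_blur(rnd, 1.5)), mean(rnd), tolerance = 0.01)
  expect_identical(gaussian_blur(rnd, 0), rnd)
})

test_that("compensation recovers flow under a drusen shadow", {
  gt <- small_scene(target = 0.4, seed = 31)
  sh <- shadow_field(256, extent_mm = 0.75, n_drusen = 1, drusen_radius_um = 100,
                     seed = 31)
  dev <- small_sd_device(0)
  base <- render_device_image(gt, NULL, dev, seed = 1)
  shadowed <- render_device_image(gt, sh, dev, seed = 1)
  comp <- compensate(shadowed$flow, shadowed$structural, compensation_params(),
                     dev_pitch <- pixel_size_um(dev))
  # inside the shadow, the compensated mean flow relative to outside is closer
  # to the (unshadowed) truth ratio than the uncompensated one
  att_dev <- render_device_image(
    structure(list(flow_field = sh$attenuation_map,
                   fd_mask_true = sh$attenuation_map == 0,
                   fd_fraction_true = 0, pixel_size_um = gt$pixel_size_um,
                   extent_mm = 0.75, params = gt$params), class = "GroundTruth"),
    NULL, dev, seed = 1)$flow
  inside <- att_dev < 0.5 & base$flow > 0
  outside <- att_dev > 0.99 & base$flow > 0
  truth_ratio <- mean(base$flow[inside]) / mean(base$flow[outside])
  un_ratio <- mean(shadowed$flow[inside]) / mean(shadowed$flow[outside])
  comp_ratio <- mean(comp[inside]) / mean(comp[outside])
  expect_lt(abs(comp_ratio - truth_ratio), abs(un_ratio - truth_ratio))
})

test_that("compensation reduces the FD error induced by shadows on average", {
  errs <- sapply(1:5, function(i) {
    gt <- small_scene(target = 0.45, seed = 40 + i)
    sh <- shadow_field(256, extent_mm = 0.75, n_drusen = 2, drusen_radius_um = 80,
                       seed = 50 + i)
    dev <- small_sd_device(0)
    pair <- render_device_image(gt, sh, dev, seed = i)
    pp <- phansalkar_params(4)
    comp <- compensate(pair$flow, pair$structural, compensation_params(),
                       pixel_size_um(dev))
    e_comp <- quantify_fd(phansalkar_threshold(comp, pp, pixel_size_um(dev)))$fd_percent -
      100 * gt$fd_fraction_true
    e_raw <- quantify_fd(phansalkar_threshold(pair$flow, pp, pixel_size_um(dev)))$fd_percent -
      100 * gt$fd_fraction_true
    c(comp = abs(e_comp), raw = abs(e_raw))
  })
  expect_lt(mean(errs["comp", ]), mean(errs["raw", ]))
})
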