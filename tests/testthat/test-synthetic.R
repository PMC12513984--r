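test_that("device profiles carry the correct geometry", {
  expect_equal(pixel_size_um(device_profile("sd_v1")), 7.5)
  expect_equal(pixel_size_um(device_profile("sd_v4")), 7.5)
  expect_equal(pixel_size_um(device_profile("ss")), 3000 / 1024)
  expect_equal(device_profile("sd_v4")$n_averaged_volumes, 4L)
  expect_error(device_profile("os"), "unknown device")
})

test_that("generator hits the target flow-deficit fraction and is deterministic", {
  gt1 <- small_scene(target = 0.45, seed = 11)
  gt2 <- small_scene(target = 0.45, seed = 11)
  expect_identical(gt1$flow_field, gt2$flow_field)
  expect_lte(abs(gt1$fd_fraction_true - 0.45), 0.01)
  expect_identical(gt1$fd_mask_true, gt1$flow_field == 0)
  expect_equal(gt1$fd_fraction_true, mean(gt1$fd_mask_true))

  # degenerate all-void field
  gt0 <- generate_cc_pattern(vessel_params(target_fd_fraction = 1, seed = 1),
                             fine_grid_px = 64, extent_mm = 0.1875)
  expect_true(all(gt0$flow_field == 0))
  expect_equal(gt0$fd_fraction_true, 1)
})

test_that("fixed duty cycle makes low targets unreachable with a reported floor", {
  vp <- vessel_params(target_fd_fraction = 0.2, duty_cycle = 0.6, seed = 1)
  expect_error(generate_cc_pattern(vp, fine_grid_px = 128, extent_mm = 0.375),
               "achievable floor")
})

test_that("mesh spatial period peaks inside the intercapillary distance band", {
  gt <- generate_cc_pattern(vessel_params(target_fd_fraction = 0.4, seed = 5),
                            fine_grid_px = 512, extent_mm = 1.5)
  f <- gt$flow_field
  n <- nrow(f)
  P <- Mod(stats::fft(f - mean(f)))^2
  fax <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * gt$pixel_size_um)
  fr <- sqrt(outer(fax^2, fax^2, `+`))
  sel <- fr > 0.01 & fr < 0.2          # search periods between 5 and 100 um
  breaks <- seq(0.01, 0.2, by = 0.002)
  pow <- tapply(P[sel], cut(fr[sel], breaks), mean)
  f_peak <- breaks[which.max(pow)] + 0.001
  period <- 1 / f_peak
  expect_gte(period, 21)
  expect_lte(period, 40)
})

test_that("rendering preserves truth on a clean pass and refuses upsampling", {
  gt <- small_scene(target = 0.4, seed = 3)
  dev <- small_sd_device(noise_sd = 0)
  pair <- render_device_image(gt, NULL, dev, seed = 1)
  # zero-flow set survives point sampling; fraction conserved on the device grid
  expect_lt(abs(mean(pair$flow == 0) - gt$fd_fraction_true), 0.02)
  expect_true(all(pair$flow >= 0 & pair$flow <= 1))
  # native-grid rendering is the identity on the flow channel
  dev_native <- device_profile("ss", scan_extent_mm = 0.75, grid_px = 256L, noise_sd = 0)
  pair_native <- render_device_image(gt, NULL, dev_native, seed = 1)
  expect_equal(pair_native$flow, gt$flow_field)
  # no upsampling of truth
  dev_big <- device_profile("ss", scan_extent_mm = 0.75, grid_px = 512L)
  expect_error(render_device_image(gt, NULL, dev_big, seed = 1), "upsample")
})

test_that("four-volume averaging halves the rendered noise SD", {
  gt <- small_scene(target = 0.4, seed = 9)
  v1 <- device_profile("sd_v1", scan_extent_mm = 0.75, grid_px = 100L)
  v4 <- device_profile("sd_v4", scan_extent_mm = 0.75, grid_px = 100L)
  clean <- render_device_image(gt, NULL, small_sd_device(0), seed = 1)
  p1 <- render_device_image(gt, NULL, v1, seed = 21)
  p4 <- render_device_image(gt, NULL, v4, seed = 22)
  flat <- clean$flow > 0.3 & clean$flow < 0.7   # away from the clip limits
  ratio <- sd((p4$flow - clean$flow)[flat]) / sd((p1$flow - clean$flow)[flat])
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("shadow field is multiplicative, bounded and identical on both channels", {
  sh <- shadow_field(256, extent_mm = 0.75, n_drusen = 3, drusen_radius_um = 60,
                     seed = 4)
  expect_true(all(sh$attenuation_map > 0 & sh$attenuation_map <= 1))
  expect_true(any(sh$attenuation_map < 1))
  none <- shadow_field(64, extent_mm = 0.1875, n_drusen = 0)
  expect_true(all(none$attenuation_map == 1))

  gt <- small_scene(target = 0.4, seed = 2)
  dev <- small_sd_device(0)
  base <- render_device_image(gt, NULL, dev, seed = 1)
  shadowed <- render_device_image(gt, sh, dev, seed = 1)
  ok <- base$flow > 0
  ratio_flow <- shadowed$flow[ok] / base$flow[ok]
  ratio_struct <- shadowed$structural[ok] / base$structural[ok]
  expect_equal(ratio_flow, ratio_struct, tolerance = 1e-12)
})

test_that("synthetic volumes honor BM geometry and depth profiles", {
  gt <- generate_cc_pattern(vessel_params(target_fd_fraction = 0.4, seed = 6),
                            fine_grid_px = 64, extent_mm = 0.1875)
  n <- 64
  bm_flat <- matrix(20, n, n)
  vol <- generate_volume(gt, bm_flat, axial_step_um = 2)
  # constant band profile: slabs inside the band reproduce the truth field
  # (one axial plane of margin at the band edge for exact interpolation)
  for (s in list(slab_spec("a", 11, 21), slab_spec("c", 16, 31))) {
    expect_equal(extract_enface(vol, s), gt$flow_field, tolerance = 1e-12)
  }
  vol_wide <- generate_volume(gt, bm_flat, axial_step_um = 2,
                              depth_profile = function(d) as.numeric(d <= 43))
  expect_equal(extract_enface(vol_wide, slab_spec("b", 31, 41)), gt$flow_field,
               tolerance = 1e-12)
  # disjoint support: signal at 11-21 um only leaves 31-41 um empty
  vol_shallow <- generate_volume(gt, bm_flat, axial_step_um = 2,
                                 depth_profile = function(d) as.numeric(d >= 11 & d <= 21))
  expect_true(all(extract_enface(vol_shallow, slab_spec("b", 31, 41)) == 0))
  # tilted BM gives the same projection as flat BM
  bm_ramp <- matrix(rep(seq(5, 35, length.out = n), each = n), n, n)
  vol_ramp <- generate_volume(gt, bm_ramp, axial_step_um = 2)
  expect_equal(extract_enface(vol_ramp, slab_spec("a", 11, 21)),
               extract_enface(vol, slab_spec("a", 11, 21)), tolerance = 1e-12)
  # shape mismatch refused
  expect_error(generate_volume(gt, matrix(20, 32, 32)), "shape")
})
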