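test_that("phantom generation is deterministic under a fixed seed", {
  cfg <- small_phantom_config(seed = 80L)
  g1 <- generate_phantom(cfg)
  g2 <- generate_phantom(cfg)
  expect_identical(g1$tumors, g2$tumors)
  expect_identical(g1$surface_mesh$vertices, g2$surface_mesh$vertices)

  s1 <- simulate_sweep(g1, cfg)
  s2 <- simulate_sweep(g2, cfg)
  expect_identical(s1$frames[[5]]$image, s2$frames[[5]]$image)
  expect_identical(s1$frames[[5]]$c_t_ms$matrix, s2$frames[[5]]$c_t_ms$matrix)
})

test_that("tumor diameters follow the configured truncated normal and depths the uniform band", {
  cfg <- phantom_config(seed = 81L)
  set.seed(81L)
  d <- sample_tumor_diameters(10000, cfg)
  expect_lt(abs(mean(d) - 12.1), 0.1)
  expect_lt(abs(sd(d) - 2.5), 0.1)
  expect_true(all(d > 4))

  gts <- lapply(1:12, function(s) generate_phantom(phantom_config(seed = s)))
  depths <- unlist(lapply(gts, function(g) g$tumors$depth_mm))
  expect_true(all(depths >= 10 & depths <= 20))
  # tumors really sit below the surface by their stated depth
  for (g in gts) {
    zs <- surface_height(g, g$tumors$cx, g$tumors$cy)
    expect_equal(zs - g$tumors$cz, g$tumors$depth_mm, tolerance = 1e-9)
  }
})

test_that("rendering reproduces the configured lesion contrast and null contrast", {
  cfg <- small_phantom_config(seed = 82L, lesion_contrast = 2.0,
                              attenuation_per_mm = 0)
  gt <- generate_phantom(cfg)
  cal <- probe_calibration(pixel_spacing_mm = cfg$pixel_spacing_mm)
  tu <- gt$tumors[1, ]
  pose <- sononav:::probe_pose_at(
    c(tu$cx, tu$cy, surface_height(gt, tu$cx, tu$cy)), cal, cfg$image_size_px)
  set.seed(82)
  rb <- render_bmode(gt, pose, cfg)
  expect_gt(sum(rb$mask), 100)
  ratio <- mean(rb$image[rb$mask]) / mean(rb$image[!rb$mask])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)

  # contrast 1: lesion statistically indistinguishable from background
  cfg1 <- small_phantom_config(seed = 82L, lesion_contrast = 1.0,
                               attenuation_per_mm = 0)
  gt1 <- generate_phantom(cfg1)
  set.seed(83)
  rb1 <- render_bmode(gt1, pose, cfg1)
  expect_lt(abs(mean(rb1$image[rb$mask]) - mean(rb1$image[!rb$mask])), 1.5)

  # a plane missing every tumor has an empty ground-truth mask
  pose_far <- sononav:::probe_pose_at(c(-55, -55, 0), cal, cfg$image_size_px)
  rb_far <- render_bmode(gt, pose_far, cfg)
  expect_false(any(rb_far$mask))
})

test_that("the lesion mask equals the analytic sphere-plane rasterisation", {
  cfg <- small_phantom_config(seed = 84L)
  gt <- generate_phantom(cfg)
  cal <- probe_calibration(pixel_spacing_mm = cfg$pixel_spacing_mm)
  tu <- gt$tumors[1, ]
  pose <- sononav:::probe_pose_at(
    c(tu$cx + 1, tu$cy, surface_height(gt, tu$cx + 1, tu$cy)), cal,
    cfg$image_size_px)
  rb <- render_bmode(gt, pose, cfg)
  fr <- tracked_frame(rb$image, pose)
  W <- cfg$image_size_px[1]; H <- cfg$image_size_px[2]
  px <- cbind(rep(0:(W - 1), each = H), rep(0:(H - 1), times = W))
  world <- pixel_to_world(fr, cal, px)
  inside <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(gt$tumors))) {
    t_i <- gt$tumors[i, ]
    inside <- inside | matrix(
      rowSums(sweep(world, 2, c(t_i$cx, t_i$cy, t_i$cz))^2) <= (t_i$diameter_mm / 2)^2,
      H, W)
  }
  expect_identical(unname(rb$mask), unname(inside))
})

test_that("contact frames touch the surface and the no-contact schedule is honoured", {
  cfg <- small_phantom_config(
    seed = 85L,
    sweep = list(n_frames = 100L, n_rows = 4L, pose_noise_mm = 0,
                 pose_noise_deg = 0, no_contact_fraction = 0.3,
                 region = c(-25, 25, -15, 15)))
  gt <- generate_phantom(cfg)
  sw <- simulate_sweep(gt, cfg)
  expect_equal(mean(!sw$contact), 0.3)

  cal <- sw$calib
  for (i in which(sw$contact)[1:20]) {
    fr <- tracked_frame(sw$frames[[i]]$image, sw$true_poses[[i]], i - 1L)
    p <- pixel_to_world(fr, cal, c(cfg$image_size_px[1] / 2, 0))
    expect_lt(abs(p[3] - surface_height(gt, p[1], p[2])), 1e-9)
  }
})

test_that("phantoms refuse impossible tumor packings", {
  cfg <- phantom_config(seed = 86L, n_tumors = 60L, tumor_clearance_mm = 25)
  expect_error(generate_phantom(cfg), "fewer tumors")
})

test_that("simulated perfect cuts recover the planned margin; heavy noise can breach it", {
  cfg <- small_phantom_config(seed = 87L)
  gt <- generate_phantom(cfg)
  tu <- gt$tumors[1, ]
  tm <- tumor_model(c(tu$cx, tu$cy, tu$cz), tu$diameter_mm)
  plan <- fit_resection_shape(tm, gt$surface_mesh, 10, half_angle_deg = 30)

  cut0 <- simulate_resection(gt, plan, 0)
  r0 <- measure_margin(cut0$tumor, cut0$specimen, max_edge_mm = 1,
                       cut_surface = cut0$cut_surface)
  expect_lt(abs(r0$min_margin_mm - 10), 0.5)
  expect_equal(r0$r_status, "R0")

  # zero margin, zero noise: the cut grazes the tumor -> R1
  plan0 <- fit_resection_shape(tm, gt$surface_mesh, 0, half_angle_deg = 30)
  cutz <- simulate_resection(gt, plan0, 0)
  rz <- measure_margin(cutz$tumor, cutz$specimen, max_edge_mm = 1,
                       cut_surface = cutz$cut_surface)
  expect_lt(rz$min_margin_mm, 0.5)
  expect_equal(rz$r_status, "R1")

  # noise moves the measured margin away from the plan
  cut5 <- simulate_resection(gt, plan, 5, seed = 99L)
  r5 <- measure_margin(cut5$tumor, cut5$specimen, max_edge_mm = 1,
                       cut_surface = cut5$cut_surface)
  expect_gt(abs(r5$min_margin_mm - 10), 0.5)
})
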