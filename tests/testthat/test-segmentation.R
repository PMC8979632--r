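px_calib <- function(s = 1) probe_calibration(pixel_spacing_mm = c(s, s))

test_that("init_labels rasterises the seed disk and annulus", {
  cal <- px_calib(1)
  lab <- init_labels(c(220, 220), seed_init(c(100, 100), 10, 20), cal)
  px <- matrix(rep(0:219, each = 220), 220, 220)
  py <- matrix(rep(0:219, times = 220), 220, 220)
  d <- sqrt((px - 100)^2 + (py - 100)^2)
  expect_true(all(lab[d <= 5] == 2))
  expect_true(all(lab[d > 5 & d <= 25] == 1))
  expect_true(all(lab[d > 25] == 0))
  # areas match the analytic counts within a perimeter's worth of pixels
  expect_lt(abs(sum(lab == 2) - pi * 25), 2 * pi * 5 + 1)
  expect_lt(abs(sum(lab == 1) - pi * (625 - 25)), 2 * pi * 30 + 2)

  # degenerate sub-pixel disk keeps the single centre pixel
  lab2 <- init_labels(c(50, 50), seed_init(c(20, 30), 0.5), cal)
  expect_equal(sum(lab2 == 2), 1)
  expect_equal(which(lab2 == 2, arr.ind = TRUE)[1, ], c(row = 31, col = 21),
               ignore_attr = TRUE)

  expect_error(init_labels(c(50, 50), seed_init(c(80, 10), 5), cal), "outside")
})

test_that("a uniform image segments to exactly the definite-foreground disk", {
  cal <- px_calib(1)
  img <- matrix(120, 80, 80)
  lab <- init_labels(dim(img), seed_init(c(40, 40), 10, 15), cal)
  seg <- suppressWarnings(graph_cut_segment(img, lab, cal))
  expect_identical(unname(seg$mask), unname(lab == 2))
})

test_that("the cut reproduces the exhaustive minimiser on tiny instances", {
  set.seed(50)
  worst_gap <- 0
  for (rep in 1:25) {
    H <- 6L; W <- 6L
    img <- matrix(sample(c(60, 180), H * W, replace = TRUE) + rnorm(H * W, sd = 5),
                  H, W)
    img <- pmin(pmax(img, 0), 255)
    lab <- matrix(0L, H, W)
    lab[3, 3] <- 2L                        # one definite-foreground pixel
    free <- sample(setdiff(seq_len(H * W), which(lab == 2L)), sample(8:14, 1))
    lab[free] <- 1L                        # free pixels; rest hard background
    lab <- structure(lab, class = "label_mask", center_px = c(2, 2))
    lambda <- runif(1, 0.5, 3)

    oracle <- graphcut_exhaustive(img, lab, lambda, connectivity = 4)
    seg <- suppressWarnings(graph_cut_segment(
      img, lab, px_calib(1), lambda = lambda, connectivity = 4L,
      smooth_sigma_px = 0, component_filter = FALSE))
    # compare energies under the oracle's own energy function
    gap <- oracle$energy_of(seg$mask | (lab == 2L)) - oracle$energy
    worst_gap <- max(worst_gap, gap)
  }
  expect_lt(worst_gap, 1e-4)
})

test_that("hard constraints hold and the cut energy never exceeds the seed labelling's", {
  cfg <- small_phantom_config(seed = 51L)
  gt <- generate_phantom(cfg)
  cal <- probe_calibration(pixel_spacing_mm = cfg$pixel_spacing_mm)
  tu <- gt$tumors[1, ]
  pose <- sononav:::probe_pose_at(
    c(tu$cx, tu$cy, surface_height(gt, tu$cx, tu$cy)), cal, cfg$image_size_px)
  rb <- render_bmode(gt, pose, cfg)
  w <- which(rb$mask, arr.ind = TRUE)
  click <- c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)
  lab <- init_labels(dim(rb$image), seed_init(click, tu$diameter_mm), cal)
  seg <- graph_cut_segment(rb$image, lab, cal)

  expect_true(all(seg$mask[lab == 2]))
  e_init <- segmentation_energy(rb$image, lab, lab == 2)
  expect_lte(seg$energy, e_init)
})

test_that("lesions segment with Dice >= 0.9 and refinement clicks add/remove as clicked", {
  cfg <- small_phantom_config(seed = 52L, lesion_contrast = 1.8)
  gt <- generate_phantom(cfg)
  cal <- probe_calibration(pixel_spacing_mm = cfg$pixel_spacing_mm)
  tu <- gt$tumors[1, ]
  pose <- sononav:::probe_pose_at(
    c(tu$cx, tu$cy, surface_height(gt, tu$cx, tu$cy)), cal, cfg$image_size_px)
  rb <- render_bmode(gt, pose, cfg)
  w <- which(rb$mask, arr.ind = TRUE)
  click <- c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)
  lab <- init_labels(dim(rb$image), seed_init(click, round(tu$diameter_mm)), cal)
  seg <- graph_cut_segment(rb$image, lab, cal)
  expect_gte(dice_coefficient(seg$mask, rb$mask), 0.9)

  # click inside the mask -> the neighbourhood is removed
  seg_rm <- refine_click(rb$image, seg, click)
  expect_false(seg_rm$mask[round(click[2]) + 1, round(click[1]) + 1])
  expect_lt(sum(seg_rm$mask), sum(seg$mask))

  # clicking the same point again re-adds it (approximate involution)
  seg_back <- refine_click(rb$image, seg_rm, click)
  expect_gte(dice_coefficient(seg_back$mask, seg$mask), 0.98)
})

test_that("mask_to_tumor_model lifts centroid and equivalent diameter through the pose", {
  cal <- px_calib(1)
  img <- matrix(0, 220, 220)
  px <- matrix(rep(0:219, each = 220), 220, 220)
  py <- matrix(rep(0:219, times = 220), 220, 220)
  disk <- (px - 100)^2 + (py - 100)^2 <= 25
  seg <- sononav:::segmentation_result(disk, cal)

  fr <- tracked_frame(img)
  tm <- mask_to_tumor_model(seg, fr, cal)
  expect_equal(tm$center, c(100, 100, 0), tolerance = 1e-6)
  expect_equal(tm$diameter_mm, 2 * sqrt(sum(disk) / pi))

  fr2 <- tracked_frame(img, rigid_from_rt(translation = c(0, 0, 30)))
  tm2 <- mask_to_tumor_model(seg, fr2, cal)
  expect_equal(tm2$center, c(100, 100, 30), tolerance = 1e-6)

  # elliptical mask: equivalent diameter follows the area formula
  ell <- ((px - 100) / 20)^2 + ((py - 100) / 10)^2 <= 1
  seg_e <- sononav:::segmentation_result(ell, px_calib(0.5))
  expect_equal(seg_e$equiv_diameter_mm, 2 * sqrt(sum(ell) * 0.25 / pi))
})
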