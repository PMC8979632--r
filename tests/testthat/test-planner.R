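flat_mesh <- function(half = 60, by = 2) {
  g <- seq(-half, half, by = by)
  mesh_heightfield(g, g, matrix(0, length(g), length(g)))
}

test_that("cone fit on a flat surface reproduces the closed-form geometry", {
  tm <- tumor_model(c(0, 0, -20), 12)
  plan <- fit_resection_shape(tm, flat_mesh(), 10, half_angle_deg = 45)

  expect_equal(plan$axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(plan$depth_mm, 16 / sin(pi / 4), tolerance = 1e-9)

  # independent cone-sphere clearance oracle: exactly the margin
  clr <- cone_sphere_clearance(plan$apex, plan$axis, plan$half_angle,
                               tm$center, 6)
  expect_lt(abs(clr - 10), 1e-6)

  # tumor containment inside the cone
  v <- tm$center - plan$apex
  t_ax <- sum(v * plan$axis)
  expect_gt(t_ax * tan(plan$half_angle), 6)

  # resection line: circle of radius (apex depth to plane) * tan(alpha)
  rl <- plan$resection_line
  rad <- sqrt(rl[, 1]^2 + rl[, 2]^2)
  expected_r <- (20 + plan$depth_mm) * tan(plan$half_angle)
  expect_lt(max(abs(rad - expected_r)), 0.5)
  expect_lt(max(abs(rl[, 3])), 0.5)
})

test_that("zero margin makes the cone tangent to the tumor sphere itself", {
  tm <- tumor_model(c(0, 0, -25), 14)
  plan <- fit_resection_shape(tm, flat_mesh(), 0, half_angle_deg = 40)
  clr <- cone_sphere_clearance(plan$apex, plan$axis, plan$half_angle,
                               tm$center, 7)
  expect_lt(abs(clr), 1e-6)
})

test_that("the axis points to the true closest surface point on a tilted plane", {
  # plane through origin tilted 30 degrees about x: z = tan(30) * y
  g <- seq(-60, 60, by = 1.5)
  tilted <- mesh_heightfield(g, g, outer(g, g, function(x, y) tan(pi / 6) * y))
  tm <- tumor_model(c(5, -3, -22), 10)
  plan <- fit_resection_shape(tm, tilted, 8, half_angle_deg = 45)

  # dense-sampling nearest-point oracle
  xs <- seq(-30, 40, by = 0.05)
  best <- Inf; best_p <- NULL
  for (y in seq(-35, 30, by = 0.05)) {
    p <- cbind(5, y, tan(pi / 6) * y)       # nearest point lies in the x = 5 slice
    d <- sum((p - tm$center)^2)
    if (d < best) { best <- d; best_p <- p }
  }
  axis_oracle <- (best_p - tm$center) / sqrt(sum((best_p - tm$center)^2))
  expect_lt(max(abs(plan$axis - axis_oracle)), 0.02)
  # and analytically: the plane normal is (0, -sin30, cos30)
  expect_lt(max(abs(plan$axis - c(0, -sin(pi / 6), cos(pi / 6)))), 0.02)
})

test_that("infeasible or invalid plans error informatively", {
  tm_above <- tumor_model(c(0, 0, 15), 10)
  expect_error(fit_resection_shape(tm_above, flat_mesh(), 10), "above|outside")
  tm_breach <- tumor_model(c(0, 0, -3), 10)
  expect_error(fit_resection_shape(tm_breach, flat_mesh(), 10), "breach")
  tm <- tumor_model(c(0, 0, -20), 12)
  expect_error(fit_resection_shape(tm, flat_mesh(), 10, half_angle_deg = 0), "half_angle")
  expect_error(fit_resection_shape(tm, flat_mesh(), 10, half_angle_deg = 95), "half_angle")
})

test_that("resection-line vertices satisfy both implicit surfaces on a wavy phantom", {
  cfg <- small_phantom_config(seed = 60L)
  gt <- generate_phantom(cfg)
  tu <- gt$tumors[1, ]
  tm <- tumor_model(c(tu$cx, tu$cy, tu$cz), tu$diameter_mm)
  plan <- fit_resection_shape(tm, gt$surface_mesh, 10, half_angle_deg = 35)
  rl <- plan$resection_line
  expect_gt(nrow(rl), 20)

  d_mesh <- point_mesh_distance(rl, gt$surface_mesh)
  expect_lt(max(d_mesh), 0.5)

  v <- sweep(rl, 2, plan$apex)
  t_ax <- v %*% plan$axis
  r_perp <- sqrt(rowSums(v^2) - t_ax^2)
  cone_res <- abs(r_perp - t_ax * tan(plan$half_angle)) * cos(plan$half_angle)
  expect_lt(max(cone_res), 0.5)

  # segments respect the resolution
  seg_len <- sqrt(rowSums((rl - rl[c(2:nrow(rl), 1), ])^2))
  expect_lt(stats::quantile(seg_len, 0.99), 1.5)
})

test_that("increasing margin strictly enlarges the resection-line area on a flat phantom", {
  tm <- tumor_model(c(0, 0, -20), 12)
  areas <- sapply(c(5, 10, 15), function(m) {
    rl <- fit_resection_shape(tm, flat_mesh(), m)$resection_line
    r <- mean(sqrt(rl[, 1]^2 + rl[, 2]^2))
    pi * r^2
  })
  expect_true(all(diff(areas) > 0))
})

test_that("overlay projection slices spheres analytically and round-trips pixels", {
  tm <- tumor_model(c(30, 20, -20), 12)
  plan <- fit_resection_shape(tm, flat_mesh(), 10)
  cal <- probe_calibration(pixel_spacing_mm = c(0.5, 0.5))

  # frame whose plane x = 30 passes through the sphere centre
  pose <- sononav:::probe_pose_at(c(30, 0, 5), cal, c(128L, 96L))
  fr <- tracked_frame(matrix(0, 96, 128), compose(pose, rigid_invert(cal$ms_t_us)))
  ov <- project_overlay(plan, tm, fr, cal)
  ctr <- ov$contours$tumor
  expect_gt(nrow(ctr), 10)
  # contour pixels map back to 3D points exactly 6 mm from the centre
  world <- pixel_to_world(fr, cal, ctr)
  expect_lt(max(abs(sqrt(rowSums(sweep(world, 2, tm$center)^2)) - 6)), 1e-6)

  # plane at 4 mm from the centre: radius sqrt(36 - 16)
  pose2 <- sononav:::probe_pose_at(c(34, 0, 5), cal, c(128L, 96L))
  fr2 <- tracked_frame(matrix(0, 96, 128), compose(pose2, rigid_invert(cal$ms_t_us)))
  ov2 <- project_overlay(plan, tm, fr2, cal)
  w2 <- pixel_to_world(fr2, cal, ov2$contours$tumor)
  in_plane <- sqrt(rowSums(sweep(w2[, 2:3, drop = FALSE], 2,
                                 tm$center[2:3])^2))
  expect_lt(max(abs(in_plane - sqrt(36 - 16))), 1e-6)

  # plane missing the tumor: empty tumor contour, cone contour persists,
  # visibility flags preserved
  pose3 <- sononav:::probe_pose_at(c(50, 0, 5), cal, c(128L, 96L))
  fr3 <- tracked_frame(matrix(0, 96, 128), compose(pose3, rigid_invert(cal$ms_t_us)))
  ov3 <- project_overlay(plan, tm, fr3, cal)
  expect_equal(nrow(ov3$contours$tumor), 0)
  expect_gt(nrow(ov3$contours$shape), 0)
  expect_true(all(ov3$visible))

  # toggling hides a structure
  ov4 <- project_overlay(plan, tm, fr, cal,
                         show = c(tumor = FALSE, margin = TRUE,
                                  shape = TRUE, line = TRUE))
  expect_equal(nrow(ov4$contours$tumor), 0)
})

test_that("plans and tumor models serialise through JSON", {
  tm <- tumor_model(c(1, 2, -20), 11.5)
  plan <- fit_resection_shape(tm, flat_mesh(), 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(back$apex, plan$apex, tolerance = 1e-12)
  expect_equal(back$half_angle, plan$half_angle, tolerance = 1e-12)
  expect_equal(back$resection_line, unname(plan$resection_line), tolerance = 1e-12)

  f2 <- withr::local_tempfile(fileext = ".json")
  write_tumor_model(tm, f2)
  tm2 <- read_tumor_model(f2)
  expect_equal(tm2$center, tm$center)
  expect_equal(tm2$diameter_mm, tm$diameter_mm)
})
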