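test_that("rigid transform validation rejects non-rigid matrices", {
  m <- diag(4); m[1, 1] <- 2
  expect_error(rigid_transform(m), "orthonormal")
  m <- diag(4); m[1:3, 1:3] <- diag(c(1, 1, -1))
  expect_error(rigid_transform(m), "determinant")
  m <- diag(4); m[4, 1] <- 0.1
  expect_error(rigid_transform(m), "last row")
})

test_that("compose multiplies, cancels with the inverse, and matches a hand matrix product", {
  id <- rigid_identity()
  expect_equal(compose(id, id)$matrix, diag(4))

  set.seed(1)
  t1 <- random_rigid()
  expect_lt(max(abs(compose(t1, rigid_invert(t1))$matrix - diag(4))), 1e-9)

  rot <- rotation_about("z", pi / 2)
  trn <- rigid_from_rt(translation = c(1, 0, 0))
  combo <- compose(rot, trn)
  expect_equal(combo$matrix, rot$matrix %*% trn$matrix)
  # point (1,0,0): translate to (2,0,0), rotate 90 deg about z -> (0,2,0)
  expect_equal(transform_points(combo, c(1, 0, 0)), c(0, 2, 0))
})

test_that("compose is associative on random rigid inputs", {
  set.seed(2)
  for (i in 1:200) {
    a <- random_rigid(); b <- random_rigid(); c <- random_rigid()
    lhs <- compose(compose(a, b), c)$matrix
    rhs <- compose(a, compose(b, c))$matrix
    expect_lt(max(abs(lhs - rhs)), 1e-12 * max(1, max(abs(lhs))))
  }
})

test_that("pixel_to_world follows the calibration chain", {
  fr <- tracked_frame(matrix(0, 50, 60))
  cal1 <- probe_calibration(pixel_spacing_mm = c(1, 1))
  expect_equal(pixel_to_world(fr, cal1, c(0, 0)), c(0, 0, 0))

  cal <- probe_calibration(pixel_spacing_mm = c(0.2, 0.2))
  expect_equal(pixel_to_world(fr, cal, c(10, 5)), c(2, 1, 0))

  # matrix-product oracle on a random chain
  set.seed(3)
  for (i in 1:20) {
    pose <- random_rigid()
    ms_t_us <- random_rigid()
    calr <- probe_calibration(ms_t_us, c(0.13, 0.21))
    frr <- tracked_frame(matrix(0, 50, 60), pose)
    px <- c(runif(1, 0, 59), runif(1, 0, 49))
    expected <- pose$matrix %*% ms_t_us$matrix %*%
      diag(c(0.13, 0.21, 1, 1)) %*% c(px, 0, 1)
    expect_equal(pixel_to_world(frr, calr, px), expected[1:3], tolerance = 1e-12)
  }

  expect_error(pixel_to_world(fr, cal, c(100, 5)), "bounds")
})

test_that("neighbouring pixels map pixel_spacing apart under identity poses", {
  fr <- tracked_frame(matrix(0, 20, 20))
  cal <- probe_calibration(pixel_spacing_mm = c(0.31, 0.17))
  a <- pixel_to_world(fr, cal, c(4, 7))
  b <- pixel_to_world(fr, cal, c(5, 7))
  expect_equal(sqrt(sum((a - b)^2)), 0.31)
})

test_that("frame_plane returns a consistent oriented plane", {
  fr <- tracked_frame(matrix(0, 40, 50))
  cal <- probe_calibration(pixel_spacing_mm = c(0.2, 0.2))
  pl <- frame_plane(fr, cal)
  expect_equal(pl$origin, c(0, 0, 0))
  expect_equal(pl$ax, c(1, 0, 0))
  expect_equal(pl$ay, c(0, 1, 0))
  expect_equal(pl$normal, c(0, 0, 1))

  # pure translation moves the origin, not the directions
  fr2 <- tracked_frame(matrix(0, 40, 50), rigid_from_rt(translation = c(3, -2, 7)))
  pl2 <- frame_plane(fr2, cal)
  expect_equal(pl2$origin, c(3, -2, 7))
  expect_equal(pl2$ax, pl$ax)
  expect_equal(pl2$normal, pl$normal)

  # all four world-mapped corners lie on the plane for an arbitrary pose
  set.seed(4)
  fr3 <- tracked_frame(matrix(0, 40, 50), random_rigid())
  pl3 <- frame_plane(fr3, cal)
  corners <- rbind(c(0, 0), c(49, 0), c(0, 39), c(49, 39))
  wc <- pixel_to_world(fr3, cal, corners)
  res <- abs(sweep(wc, 2, pl3$origin) %*% pl3$normal)
  expect_lt(max(res), 1e-9)
})

test_that("world_to_pixel inverts pixel_to_world on the image plane", {
  set.seed(5)
  cal <- probe_calibration(random_rigid(), c(0.2, 0.3))
  fr <- tracked_frame(matrix(0, 60, 80), random_rigid())
  px <- cbind(runif(50, 0, 79), runif(50, 0, 59))
  world <- pixel_to_world(fr, cal, px)
  back <- world_to_pixel(fr, cal, world)
  expect_lt(max(abs(back - px)), 1e-6)
  expect_lt(max(abs(attr(back, "z_mm"))), 1e-9)
})

test_that("pose logs and calibration files round-trip through CSV/JSON/YAML", {
  set.seed(6)
  poses <- lapply(1:5, function(i) random_rigid())
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pose_log(poses, csv)
  back <- read_pose_log(csv)
  expect_equal(length(back), 5)
  for (i in 1:5) expect_equal(back[[i]]$matrix, poses[[i]]$matrix, tolerance = 1e-12)

  cal <- probe_calibration(poses[[1]], c(0.2, 0.25))
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_calibration(cal, yml)
  cal2 <- read_calibration(yml)
  expect_equal(cal2$ms_t_us$matrix, cal$ms_t_us$matrix, tolerance = 1e-9)
  expect_equal(cal2$pixel_spacing_mm, cal$pixel_spacing_mm)

  expect_error(probe_calibration(pixel_spacing_mm = c(0.2, 0)), "positive")
})
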