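test_that("concentric and offset sphere pairs reproduce closed-form margins", {
  tu <- mesh_uv_sphere(c(0, 0, 0), 6, 48, 24)
  sp <- mesh_uv_sphere(c(0, 0, 0), 16, 80, 40)
  r <- measure_margin(tu, sp)
  expect_lt(abs(r$min_margin_mm - 10), 0.1)
  expect_lt(abs(r$median_margin_mm - 10), 0.1)
  expect_equal(r$r_status, "R0")
  expect_lte(r$min_margin_mm, r$median_margin_mm)

  sp_off <- mesh_uv_sphere(c(4, 0, 0), 16, 80, 40)
  r2 <- measure_margin(tu, sp_off)
  expect_lt(abs(r2$min_margin_mm - 6), 0.1)
  expect_lt(abs(r2$max_margin_mm - 14), 0.1)
})

test_that("minimum distance agrees with the exhaustive search on small mesh pairs", {
  set.seed(70)
  tu <- mesh_uv_sphere(c(0.5, -0.2, 0.1), 3, 10, 5)
  sp <- mesh_uv_sphere(c(0, 0, 0), 8, 14, 7)
  d_pkg <- min(point_mesh_distance(tu$vertices, sp))
  d_naive <- min_point_mesh_dist_naive(tu$vertices, sp, n_grid = 120)
  expect_lt(abs(d_pkg - d_naive), 2e-3)
})

test_that("the R0 rule is strict at the 1 mm threshold", {
  mk <- function(min_m) {
    structure(list(min_margin_mm = min_m, r0_threshold_mm = 1.0),
              class = "margin_report")
  }
  expect_equal(classify_resection(mk(1.1)), "R0")
  expect_equal(classify_resection(mk(0.9)), "R1")
  expect_equal(classify_resection(mk(1.0)), "R1")
  expect_equal(classify_resection(mk(0.9), threshold_mm = 0.5), "R0")
})

test_that("protruding tumors report a zero margin and R1", {
  tu <- mesh_uv_sphere(c(6, 0, 0), 3, 16, 8)     # pokes through the specimen
  sp <- mesh_uv_sphere(c(0, 0, 0), 8, 24, 12)
  r <- measure_margin(tu, sp)
  expect_true(r$protruding)
  expect_equal(r$min_margin_mm, 0)
  expect_equal(r$r_status, "R1")
})

test_that("open specimen meshes warn but still yield distances", {
  tu <- mesh_uv_sphere(c(0, 0, 0), 3, 16, 8)
  sp <- mesh_uv_sphere(c(0, 0, 0), 8, 24, 12)
  open_sp <- triangle_mesh(sp$vertices, sp$faces[-(1:10), ])
  expect_warning(r <- measure_margin(tu, open_sp), "watertight")
  expect_true(is.finite(r$min_margin_mm))
})

test_that("margin is robust to tumor mesh refinement", {
  tu <- mesh_uv_sphere(c(1, 1, 0), 5, 32, 16)
  sp <- mesh_uv_sphere(c(0, 0, 0), 14, 64, 32)
  r1 <- measure_margin(tu, sp, max_edge_mm = 1.0)
  r2 <- measure_margin(tu, sp, max_edge_mm = 0.5)
  expect_lt(abs(r1$min_margin_mm - r2$min_margin_mm), 0.05)
})

test_that("cohort_summary computes median, IQR and R0 rate", {
  mk <- function(m) {
    r <- structure(list(min_margin_mm = m, median_margin_mm = m,
                        max_margin_mm = m, distances_mm = m,
                        sample_points = matrix(0, 1, 3), protruding = FALSE,
                        r0_threshold_mm = 1, r_status = NA_character_),
                   class = "margin_report")
    r$r_status <- classify_resection(r)
    r
  }
  s <- cohort_summary(lapply(c(2, 5.9, 8), mk))
  expect_equal(s$median_margin_mm, 5.9)

  # 22 R0 out of 23 prints as 95.7%
  s2 <- cohort_summary(lapply(c(rep(5, 22), 0.5), mk))
  expect_equal(s2$n_r0, 22)
  expect_equal(round(s2$r0_rate_pct, 1), 95.7)

  # quantiles match an independent sort-based computation (type 7)
  set.seed(71)
  ms <- runif(40, 0, 12)
  s3 <- cohort_summary(lapply(ms, mk))
  srt <- sort(ms)
  q_lin <- function(p) {
    h <- (length(srt) - 1) * p
    srt[floor(h) + 1] + (h - floor(h)) * (srt[min(floor(h) + 2, length(srt))] - srt[floor(h) + 1])
  }
  expect_equal(s3$median_margin_mm, q_lin(0.5), tolerance = 1e-12)
  expect_equal(s3$iqr_lo_mm, q_lin(0.25), tolerance = 1e-12)
  expect_equal(s3$iqr_hi_mm, q_lin(0.75), tolerance = 1e-12)

  expect_error(cohort_summary(list()), "at least one")
})

test_that("margin reports export tidy tables and PLY heat maps", {
  tu <- mesh_uv_sphere(c(0, 0, 0), 3, 16, 8)
  sp <- mesh_uv_sphere(c(0, 0, 0), 8, 24, 12)
  r <- measure_margin(tu, sp)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(r$distances_mm))
  f <- withr::local_tempfile(fileext = ".ply")
  write_margin_heatmap(r, f)
  expect_true(any(grepl("property double quality", readLines(f, n = 10))))
})
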