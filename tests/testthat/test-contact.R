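test_that("upper-third features match a direct per-pixel recomputation", {
  img <- matrix(100, 9, 12)
  f <- suppressWarnings(extract_contact_features(img))
  expect_equal(unname(f), c(100, 100, 100, 0, 0))

  img2 <- matrix(0, 3, 2)
  img2[1, ] <- c(0, 255)
  f2 <- extract_contact_features(img2)
  expect_equal(unname(f2[c("fmin", "fmax", "fmean")]), c(0, 255, 127.5))

  set.seed(20)
  img3 <- matrix(runif(40 * 30, 0, 255), 40, 30)
  f3 <- extract_contact_features(img3)
  band <- as.numeric(img3[1:13, ])
  m <- mean(band); n <- length(band)
  kurt <- mean((band - m)^4) / (sum((band - m)^2) / n)^2 - 3
  expect_equal(unname(f3),
               c(min(band), max(band), m, sd(band), kurt), tolerance = 1e-12)
})

test_that("features ignore the lower two-thirds of the image", {
  set.seed(21)
  img <- matrix(runif(60 * 40, 0, 255), 60, 40)
  f1 <- extract_contact_features(img)
  img[21:60, ] <- runif(40 * 40, 0, 255)   # rows >= floor(H/3) mutated
  expect_identical(extract_contact_features(img), f1)
  expect_error(extract_contact_features(matrix(1, 2, 5)), "upper third")
})

test_that("SVM training demands both classes and separates a separable set", {
  f <- rbind(c(0, 10, 5, 2, 0), c(200, 250, 225, 5, 0))
  colnames(f) <- c("fmin", "fmax", "fmean", "fstd", "fkurtosis")
  expect_error(train_contact_model(f, c("contact", "contact")), "both")
  m <- train_contact_model(f, c("no_contact", "contact"))
  expect_equal(predict_contact(m, f), c("no_contact", "contact"))
})

test_that("shuffled labels give chance-level held-out accuracy", {
  set.seed(22)
  n <- 200
  feats <- cbind(fmin = runif(n, 0, 50), fmax = runif(n, 150, 255),
                 fmean = runif(n, 60, 120), fstd = runif(n, 20, 60),
                 fkurtosis = rnorm(n))
  labs <- sample(rep(c("contact", "no_contact"), each = n / 2))
  tr_idx <- sample(n, n / 2)
  m <- train_contact_model(feats[tr_idx, ], labs[tr_idx], seed = 5)
  acc <- mean(predict_contact(m, feats[-tr_idx, ]) == labs[-tr_idx])
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("phantom-trained classifier reaches high held-out accuracy and fixed conventions", {
  model <- cached_contact_model()
  cfg <- small_phantom_config(seed = 78L)
  gt <- generate_phantom(cfg)
  te <- phantom_training_set(gt, n = 120L, cfg, seed = 781L)
  acc <- mean(predict_contact(model, te$features) == te$labels)
  expect_gte(acc, 0.95)

  # an all-black frame (air gap, no echo) is no-contact
  dark <- matrix(0, cfg$image_size_px[2], cfg$image_size_px[1])
  expect_equal(suppressWarnings(predict_contact(model, dark)), "no_contact")

  # a bright speckled near field is contact
  set.seed(23)
  bright <- matrix(90 * sqrt(-2 * log(runif(prod(cfg$image_size_px)))) / sqrt(pi / 2),
                   cfg$image_size_px[2], cfg$image_size_px[1])
  expect_equal(predict_contact(model, pmin(bright, 255)), "contact")
})

test_that("contact model persists through the JSON archive bit-for-bit", {
  model <- cached_contact_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_contact_model(model, path)
  restored <- read_contact_model(path)

  cfg <- small_phantom_config(seed = 79L)
  gt <- generate_phantom(cfg)
  te <- phantom_training_set(gt, n = 60L, cfg, seed = 791L)
  expect_identical(predict_contact(restored, te$features),
                   predict_contact(model, te$features))
  expect_error(predict_contact(list(), te$features), "trained")
})
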