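test_that("density maps superpose unit-peak Gaussians", {
  expect_equal(density_map(data.frame(row = integer(0), col = integer(0)),
                           c(16, 16), 2),
               matrix(0, 16, 16))
  d <- density_map(data.frame(row = 10, col = 10), c(21, 21), 2)
  expect_equal(which(d == max(d)), cellpath:::rc_to_index(10, 10, 21))
  expect_equal(max(d), 1)
  # two dots 1 px apart: the midpoint value exceeds a single Gaussian there
  d2 <- density_map(data.frame(row = c(10, 11), col = c(10, 10)), c(21, 21), 2)
  # at each dot pixel: own peak 1 plus the neighbour's tail exp(-1/8)
  expect_equal(d2[cbind(c(11, 12), c(11, 11))],
               rep(1 + exp(-1 / (2 * 4)), 2), tolerance = 1e-12)
  expect_gt(d2[11, 11], exp(-0.5^2 / (2 * 4)))
  expect_error(density_map(data.frame(row = 30, col = 2), c(21, 21), 2),
               "bounds")
})

test_that("pixel sampling respects the density thresholds and masks", {
  expect_error(sample_training_pixels(data.frame(row = integer(0),
                                                 col = integer(0)),
                                      c(32, 32), density_sampling_params()),
               "no positive")
  expect_error(density_sampling_params(sigma_pos = 5, sigma_neg = 3),
               "sigma_pos")

  s <- sample_training_pixels(data.frame(row = 15, col = 15), c(31, 31),
                              density_sampling_params(sigma_pos = 1,
                                                      pos_threshold = 0.99,
                                                      sigma_neg = 6),
                              seed = 1)
  expect_true(any(s$row == 15 & s$col == 15 & s$label == 1))

  # on a generated scene positives fall inside instances, negatives outside
  sc <- generate_scene(scene_spec_easy(image_height = 96, image_width = 96,
                                       n_cells = 10, seed = 2))
  sp <- density_sampling_params(sigma_pos = 2, sigma_neg = 8,
                                neg_threshold = 0.3)
  s <- sample_training_pixels(sc$dots, dim(sc$image), sp, seed = 1)
  lab_at <- sc$mask[cbind(s$row + 1L, s$col + 1L)]
  expect_true(all(lab_at[s$label == 1] > 0))
  expect_true(all(lab_at[s$label == 0] == 0))
  # deterministic subsampling
  s2 <- sample_training_pixels(sc$dots, dim(sc$image), sp, seed = 1)
  expect_identical(s, s2)
})

pixel_fixture <- function() {
  fixture("pixel_model", function() {
    spec <- scene_spec_easy(image_height = 96, image_width = 96, n_cells = 10,
                            noise_sigma = 0)
    scenes <- lapply(1:3, function(i) {
      sp <- spec; sp$seed <- 40L + i
      generate_scene(sp)
    })
    sp <- density_sampling_params(sigma_pos = 2, sigma_neg = 8,
                                  neg_threshold = 0.3)
    samples <- lapply(scenes, function(s)
      sample_training_pixels(s$dots, dim(s$image), sp, seed = 5))
    model <- train_pixel_classifier(lapply(scenes[1:2], `[[`, "image"),
                                    samples[1:2], seed = 5)
    list(scenes = scenes, samples = samples, model = model)
  })
}

test_that("the pixel classifier separates cells from background", {
  fx <- pixel_fixture()
  # held-out scene: accuracy on its density-derived samples
  s3 <- fx$scenes[[3]]
  prob <- predict_probability_map(fx$model, s3$image)
  expect_true(all(prob >= 0 & prob <= 1))
  at <- prob[cbind(fx$samples[[3]]$row + 1L, fx$samples[[3]]$col + 1L)]
  acc <- mean((at > 0.5) == (fx$samples[[3]]$label == 1))
  expect_gt(acc, 0.99)
  # thresholding the map at 0.5 recovers the foreground well (noiseless)
  fg <- prob > 0.5
  gt <- s3$mask > 0
  iou <- sum(fg & gt) / sum(fg | gt)
  expect_gt(iou, 0.8)
  # the generator smooths instance boundaries by ~1 px, so the operational
  # foreground is the mask eroded by that band; it must be fully recovered
  core <- as.matrix(EBImage::erode(gt * 1, EBImage::makeBrush(3, "box"))) > 0
  expect_gt(sum(fg & core) / sum(core), 0.95)
  # determinism
  prob2 <- predict_probability_map(fx$model, s3$image)
  expect_identical(prob, prob2)
})

test_that("pixel classifier rejects degenerate training input", {
  img <- matrix(0.5, 32, 32)
  samp <- data.frame(row = c(1, 2, 3), col = c(1, 2, 3), label = c(1, 1, 1))
  expect_error(train_pixel_classifier(list(img), list(samp)), "two")
  expect_error(train_pixel_classifier(list(img, img), list(samp, samp)),
               "single class")
})

test_that("a signal-free image scores near the class prior everywhere", {
  with_seed_local <- function(code) cellpath:::with_seed(99, code)
  img <- matrix(0.5, 48, 48)
  samp <- with_seed_local({
    data.frame(row = sample(0:47, 60, TRUE), col = sample(0:47, 60, TRUE),
               label = rep(c(0L, 1L), 30))
  })
  m <- train_pixel_classifier(list(img, img), list(samp, samp), seed = 1)
  prob <- predict_probability_map(m, img)
  expect_lt(max(abs(prob - 0.5)), 0.25)
})

test_that("pixel models persist and validate their feature configuration", {
  fx <- pixel_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  write_pixel_model(fx$model, path)
  m2 <- read_pixel_model(path)
  s3 <- fx$scenes[[3]]
  expect_identical(predict_probability_map(m2, s3$image),
                   predict_probability_map(fx$model, s3$image))
  expect_error(predict_probability_map(fx$model, "not an image"), "matrix")
})
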