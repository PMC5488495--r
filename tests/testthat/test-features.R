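square_pixels <- function(r0, r1, c0, c1, H) {
  sort(cellpath:::rc_to_index(rep(r0:r1, r1 - r0 + 1),
                              rep(c0:c1, each = r1 - r0 + 1), H))
}

disk_pixels <- function(ctr, rad, H) {
  g <- expand.grid(row = 0:(H - 1), col = 0:(H - 1))
  keep <- (g$row - ctr)^2 + (g$col - ctr)^2 <= rad^2
  sort(cellpath:::rc_to_index(g$row[keep], g$col[keep], H))
}

test_that("intensity features: uniform regions and maximal contrast", {
  img <- matrix(0, 32, 32)
  pix <- square_pixels(10, 17, 10, 17, 32)
  img[pix] <- 1
  f <- intensity_features(pix, img)
  h <- f[grep("^int_hist", names(f))]
  expect_equal(sum(h), 1)
  expect_equal(unname(h[16]), 1)          # all mass in the top bin
  # cross-dilated border: 28 border + 20 inner-ring + 32 outside pixels,
  # 48 of the 80 carry value 1, so |mean(border) - mean(dilation)| = 0.4
  expect_equal(unname(f["int_dmean_r1"]), 0.4, tolerance = 1e-12)
  expect_error(intensity_features(integer(0), img), "empty")
  # uniform image: no contrast anywhere
  img2 <- matrix(0.5, 32, 32)
  f2 <- intensity_features(pix, img2)
  expect_equal(unname(f2["int_dmean_r3"]), 0)
  expect_equal(unname(f2["int_l1_r1"]), 0)
})

test_that("intensity histogram distances match direct recomputation", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  pix <- disk_pixels(15, 8, 32)
  f <- intensity_features(pix, img)
  bord <- cellpath:::region_border(pix, 32, 32)
  hb <- cellpath:::norm_hist(img[bord$border], 16)
  for (rad in c(1, 3)) {
    dil <- cellpath:::dilate_pixels(bord$border, 32, 32, rad)
    hd <- cellpath:::norm_hist(img[dil], 16)
    expect_equal(unname(f[paste0("int_l1_r", rad)]), sum(abs(hb - hd)))
    expect_equal(unname(f[paste0("int_l2_r", rad)]), sqrt(sum((hb - hd)^2)))
  }
})

test_that("area features scale exactly with image geometry", {
  H <- 24
  all_pix <- seq_len(H * H)
  f <- area_features(all_pix, c(H, H))
  expect_equal(unname(f["area_norm"]), 1)
  expect_equal(unname(area_features(1L, c(H, H))["area_norm"]), 1 / H^2)
  # square of side s: crack boundary length 4 s
  s <- 7
  pix <- square_pixels(5, 5 + s - 1, 6, 6 + s - 1, H)
  f <- area_features(pix, c(H, H))
  expect_equal(unname(f["boundary_norm"]) * sqrt(2 * H^2), 4 * s)
  # normalization reference can differ from the pixel frame
  f2 <- area_features(pix, c(H, H), norm_dim = c(2 * H, 2 * H))
  expect_equal(unname(f2["area_norm"]), s^2 / (4 * H^2))
})

test_that("shape features rank disks, ellipses, and lines correctly", {
  H <- 64
  disk <- disk_pixels(31, 14, H)
  f_disk <- shape_features(disk, c(H, H))
  expect_gt(unname(f_disk["shape_roundness"]), 0.9)
  expect_lt(unname(f_disk["shape_roundness"]), 1.15)
  hpolar <- f_disk[grep("^shape_polar", names(f_disk))]
  expect_lt(diff(range(hpolar)), 0.15)    # near-uniform polar profile
  # 2:1 ellipse is less round (direct formula: 4 pi A / P^2 with Ramanujan P)
  g <- expand.grid(row = 0:(H - 1), col = 0:(H - 1))
  ell <- sort(cellpath:::rc_to_index(
    g$row[(g$row - 31)^2 / 400 + (g$col - 31)^2 / 100 <= 1],
    g$col[(g$row - 31)^2 / 400 + (g$col - 31)^2 / 100 <= 1], H))
  f_ell <- shape_features(ell, c(H, H))
  expect_lt(unname(f_ell["shape_roundness"]),
            unname(f_disk["shape_roundness"]))
  # line-like region: roundness near zero
  line <- square_pixels(30, 31, 5, 58, H)
  f_line <- shape_features(line, c(H, H))
  expect_lt(unname(f_line["shape_roundness"]), 0.35)
  # degenerate region: uniform histogram, zero curvature, finite everywhere
  f_tiny <- shape_features(c(1L, 2L), c(H, H))
  expect_true(all(is.finite(f_tiny)))
  expect_equal(unname(f_tiny["shape_curvature"]), 0)
  expect_equal(unname(f_tiny[grep("^shape_polar", names(f_tiny))]),
               rep(1 / 16, 16))
})

test_that("texture features: flat regions are textureless, checkerboards not", {
  img <- matrix(0.4, 32, 32)
  tm <- texture_maps(img)
  pix <- square_pixels(8, 19, 8, 19, 32)
  f <- texture_features(pix, tm)
  expect_equal(unname(f), c(0, 0, 0), tolerance = 1e-10)
  # checkerboard: local range equals the amplitude
  cb <- matrix(0.2, 32, 32)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 0.8
  tmcb <- texture_maps(cb)
  fcb <- texture_features(pix, tmcb)
  expect_equal(unname(fcb["tex_range"]), 0.6, tolerance = 1e-12)
  expect_gt(unname(fcb["tex_std"]), 0.25)
})

test_that("features are invariant to joint translation", {
  set.seed(8)
  patch <- matrix(runif(100), 10, 10)
  img1 <- matrix(0.1, 40, 40); img1[6:15, 6:15] <- patch
  img2 <- matrix(0.1, 40, 40); img2[21:30, 16:25] <- patch
  pix1 <- square_pixels(6, 13, 6, 13, 40)
  pix2 <- square_pixels(21, 28, 16, 23, 40)
  cfg <- feature_config()
  f1 <- c(intensity_features(pix1, img1, cfg), area_features(pix1, c(40, 40)),
          shape_features(pix1, c(40, 40), cfg),
          texture_features(pix1, texture_maps(img1, cfg)))
  f2 <- c(intensity_features(pix2, img2, cfg), area_features(pix2, c(40, 40)),
          shape_features(pix2, c(40, 40), cfg),
          texture_features(pix2, texture_maps(img2, cfg)))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("assembled features are finite, named, bias-terminated, standardizable", {
  sc <- generate_scene(scene_spec(image_height = 96, image_width = 96,
                                  n_cells = 12, seed = 6))
  f <- build_forest(sc$image, min_area = 10, max_area = 400)
  X <- region_features(f, sc$image)
  expect_equal(nrow(X), nrow(f$nodes))
  expect_true(all(is.finite(X)))
  expect_equal(colnames(X)[ncol(X)], "bias")
  expect_true(all(X[, "bias"] == 1))
  # identical regions give identical vectors
  expect_equal(X[1, ], region_features(f, sc$image)[1, ])
  std <- fit_standardizer(X)
  Z <- apply_standardizer(X, std)
  keep <- apply(X, 2, stats::sd) > 1e-8
  expect_lt(max(abs(colMeans(Z[, keep]))), 1e-10)
  expect_equal(unname(apply(Z[, keep], 2, stats::sd)),
               rep(1, sum(keep)), tolerance = 1e-10)
  expect_true(all(Z[, "bias"] == 1))
})
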