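test_that("separated uniform squares become single-node trees", {
  img <- matrix(0, 32, 32)
  img[5:10, 5:10] <- 1      # 36 px
  img[20:27, 18:25] <- 1    # 64 px
  f <- build_forest(img, min_area = 10, max_area = 100)
  expect_equal(nrow(f$nodes), 2)
  expect_true(all(is.na(f$nodes$parent)))
  keys <- forest_pixel_keys(f)
  sq1 <- sort(cellpath:::rc_to_index(rep(4:9, 6), rep(4:9, each = 6), 32))
  expect_true(paste(sq1, collapse = ",") %in% keys)
})

test_that("a nested three-maxima component matches the thresholding oracle", {
  img <- matrix(0, 40, 40)
  img[8:32, 8:32] <- 0.3            # common base
  img[10:14, 10:14] <- 0.6          # three local maxima inside
  img[10:14, 24:28] <- 0.7
  img[24:28, 16:20] <- 0.9
  f <- build_forest(img, min_area = 5, max_area = 700)
  ch <- cellpath:::forest_children(f)
  leaves <- sum(vapply(ch, length, 1L) == 0)
  expect_equal(leaves, 3)
  expect_setequal(forest_pixel_keys(f),
                  threshold_components_oracle(img, 5, 700))
})

test_that("forests equal exhaustive thresholding on random smooth images", {
  set.seed(42)
  for (rep in 1:3) {
    img <- cellpath:::gaussian_blur(matrix(runif(32 * 32), 32, 32), 2)
    img <- (img - min(img)) / diff(range(img))
    f <- build_forest(img, min_area = 8, max_area = 300, n_levels = 32)
    expect_setequal(forest_pixel_keys(f),
                    threshold_components_oracle(img, 8, 300, n_levels = 32))
    expect_true(check_nestedness(f))
  }
})

test_that("area bounds are validated and empty foreground gives empty forest", {
  img <- matrix(0, 16, 16)
  expect_error(build_forest(img, min_area = 50, max_area = 10), "exceeds")
  f <- build_forest(img, min_area = 5, max_area = 50)
  expect_equal(nrow(f$nodes), 0)
  expect_length(enumerate_paths(f), 0)
})

test_that("stability selection keeps sharp regions and prunes gradual halos", {
  img <- matrix(0, 48, 48)
  # a sharp square: one stable candidate expected
  img[10:19, 10:19] <- 0.9
  # a smooth blob: many nested components, few stable ones
  blob <- cellpath:::gaussian_blur({
    m <- matrix(0, 48, 48); m[34, 34] <- 60; m
  }, 4)
  img <- pmax(img, blob)
  full <- build_forest(img, min_area = 10, max_area = 500)
  mser <- build_forest(img, min_area = 10, max_area = 500,
                       max_variation = 1, min_diversity = 0.3)
  expect_lt(nrow(mser$nodes), nrow(full$nodes))
  expect_true(check_nestedness(mser))
  sq <- sort(cellpath:::rc_to_index(rep(9:18, 10), rep(9:18, each = 10), 48))
  expect_true(paste(sq, collapse = ",") %in% forest_pixel_keys(mser))
})

test_that("paths enumerate exactly one chain per leaf", {
  # single node
  f1 <- make_forest(NA_integer_)
  p1 <- enumerate_paths(f1)
  expect_equal(length(p1), 1)
  expect_equal(p1[[1]], 1L)
  # balanced binary tree of depth 3: 4 leaves, all paths root -> leaf
  parent <- c(NA, 1L, 1L, 2L, 2L, 3L, 3L)
  f2 <- make_forest(parent)
  p2 <- enumerate_paths(f2)
  expect_equal(length(p2), 4)
  expect_true(all(vapply(p2, length, 1L) == 3))
  expect_true(all(vapply(p2, function(p) p[1] == 1L, TRUE)))
  expect_setequal(unlist(p2), 1:7)
  # consecutive entries are parent -> child
  for (p in p2)
    for (k in seq_len(length(p) - 1))
      expect_equal(f2$nodes$parent[p[k + 1]], p[k])
})

test_that("path count equals leaf count and paths cover all nodes", {
  set.seed(11)
  for (rep in 1:10) {
    f <- make_forest(random_parent(sample(2:15, 1)))
    paths <- enumerate_paths(f)
    ch <- cellpath:::forest_children(f)
    expect_equal(length(paths), sum(vapply(ch, length, 1L) == 0))
    expect_setequal(unlist(paths), seq_len(nrow(f$nodes)))
  }
})

test_that("descendants equal brute-force reachability", {
  expect_equal(descendants(make_forest(c(NA, 1L, 2L)), 3L), integer(0))
  expect_equal(descendants(make_forest(c(NA, 1L, 2L)), 1L), c(2L, 3L))
  expect_error(descendants(make_forest(NA_integer_), 5L), "unknown")
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(3:14, 1)
    parent <- random_parent(n)
    f <- make_forest(parent)
    # reachability oracle: repeated expansion of the child relation
    reach <- function(i) {
      out <- integer(0)
      frontier <- which(!is.na(parent) & parent == i)
      while (length(frontier)) {
        out <- c(out, frontier)
        frontier <- which(!is.na(parent) & parent %in% frontier)
      }
      sort(out)
    }
    i <- sample.int(n, 1)
    expect_equal(descendants(f, i), reach(i))
  }
})

test_that("forests serialize to JSON and back", {
  img <- matrix(0, 24, 24)
  img[4:9, 4:9] <- 0.8
  img[14:21, 10:19] <- c(0.5, 0.9)[1 + (matrix(1:80, 8) %% 2)] * 0.6 + 0.2
  f <- build_forest(img, min_area = 5, max_area = 200)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest(f, path)
  g <- read_forest(path)
  expect_equal(g$nodes$parent, f$nodes$parent)
  expect_equal(g$nodes$area, f$nodes$area)
  expect_identical(lapply(g$pixels, as.integer), f$pixels)
})
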