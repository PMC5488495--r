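rand_problem <- function(seed, D = 8, Ns = 8, R = 14) {
  set.seed(seed)
  X_s <- cbind(matrix(rnorm(Ns * (D - 1)), Ns), 1)
  y_s <- rep(c(0, 1), length.out = Ns)
  X_u <- cbind(matrix(rnorm(R * (D - 1)), R), 1)
  parent <- random_parent(sample(4:10, 1))
  f <- make_forest(parent)
  paths <- lapply(enumerate_paths(f), function(p) {
    # map structural ids into feature rows (wrap if needed)
    ((p - 1L) %% R) + 1L
  })
  list(X_s = X_s, y_s = y_s, X_u = X_u, paths = paths)
}

test_that("the MLP scores are probabilities with the declared architecture", {
  p <- mlp_init(9, seed = 1)
  expect_equal(p$hidden, 4L)          # floor(D / 2)
  x <- c(rnorm(8), 1)
  expect_error(score_region(p, rnorm(5)), "dimension")
  # zero weights: sigmoid(0) = 0.5 for any input
  p0 <- p; p0$W1[] <- 0; p0$w2[] <- 0
  expect_equal(score_region(p0, x), 0.5)
  # monotone in the output bias
  p1 <- p0; p1$w2[p1$hidden + 1] <- 2
  expect_gt(score_region(p1, x), 0.5)
  # matches an independent forward implementation on random weights
  set.seed(2)
  X <- cbind(matrix(rnorm(30 * 8), 30), 1)
  manual <- 1 / (1 + exp(-(cbind(tanh(X %*% t(p$W1)), 1) %*% p$w2)))
  expect_equal(score_region(p, X), as.vector(manual), tolerance = 1e-12)
})

test_that("the exact path indicator is the at-most-one function", {
  expect_equal(path_indicator_exact(c(1, 0)), 1L)
  expect_equal(path_indicator_exact(c(0, 0)), 1L)   # empty selection allowed
  expect_equal(path_indicator_exact(c(1, 1)), 0L)
  for (n in 1:5) {
    for (m in 0:(2^n - 1)) {
      f <- as.integer(intToBits(m)[1:n])
      expect_identical(path_indicator_exact(f), as.integer(sum(f) <= 1))
    }
  }
})

test_that("the relaxed path loss matches hand-computed values and bounds", {
  expect_equal(path_loss_relaxed(c(1, 0)), 1)
  expect_equal(path_loss_relaxed(c(1, 1)), 0)
  # (0.5, 0.5): each of the three disjunct products is 0.25
  expect_equal(path_loss_relaxed(c(0.5, 0.5)), 1 - 0.75^3)
  # always within [0, 1], even for long paths near saturation
  set.seed(4)
  for (rep in 1:20) {
    f <- runif(sample(1:40, 1))
    v <- path_loss_relaxed(f)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # reduces to the exact indicator at binary scores
  for (n in 1:6) {
    for (m in 0:(2^n - 1)) {
      f <- as.integer(intToBits(m)[1:n])
      expect_equal(path_loss_relaxed(f), path_indicator_exact(f))
    }
  }
})

test_that("the objective decomposes into its published terms", {
  pr <- rand_problem(5)
  params <- mlp_init(ncol(pr$X_s), seed = 3)
  prob <- cellpath:::training_problem(pr$X_s, pr$y_s, pr$X_u, pr$paths)
  sigma_s <- 0.7; sigma_u <- 0.4
  L <- map_objective(params, sigma_s, sigma_u, prob)
  w <- cellpath:::params_to_vec(params)
  f_s <- score_region(params, pr$X_s)
  Fi <- vapply(pr$paths, function(p)
    path_loss_relaxed(score_region(params, pr$X_u)[p]), numeric(1))
  manual <- length(pr$paths) * log(sigma_u) +
    sum((1 - Fi)^2) / (2 * sigma_u^2) + sum(w^2) / 2 +
    sum((pr$y_s - f_s)^2) / (2 * sigma_s^2) +
    length(pr$y_s) * log(sigma_s)
  expect_equal(L, manual, tolerance = 1e-12)
  # perfect supervised predictions and unit scales: only the prior remains
  prob0 <- cellpath:::training_problem(pr$X_s, round(f_s))
  fhat <- score_region(params, pr$X_s)
  Lsup <- map_objective(params, 1, 1, prob0, include_unsup = FALSE)
  expect_equal(Lsup, sum(w^2) / 2 + sum((round(fhat) - fhat)^2) / 2)
})

test_that("closed-form sigma updates match their formulas and floors", {
  up <- update_sigmas(c(0.1, 0.3), c(0, 0))
  expect_equal(up$sigma_u, sqrt(0.1 / 2), tolerance = 1e-12)
  expect_equal(up$sigma_s, 1e-4)                  # floored at zero residual
  expect_true(is.na(update_sigmas(numeric(0), c(0.2))$sigma_u))
})

test_that("sigma updates are stationary points of the objective", {
  set.seed(6)
  for (rep in 1:5) {
    ru <- runif(12, 0, 0.9)
    rs <- runif(7, 0, 0.9)
    up <- update_sigmas(ru, rs)
    Lsig <- function(su, ss) {
      12 * log(su) + sum(ru^2) / (2 * su^2) +
        7 * log(ss) + sum(rs^2) / (2 * ss^2)
    }
    h <- 1e-5
    d_su <- (Lsig(up$sigma_u + h, up$sigma_s) -
               Lsig(up$sigma_u - h, up$sigma_s)) / (2 * h)
    d_ss <- (Lsig(up$sigma_u, up$sigma_s + h) -
               Lsig(up$sigma_u, up$sigma_s - h)) / (2 * h)
    expect_lt(abs(d_su), 1e-6)
    expect_lt(abs(d_ss), 1e-6)
  }
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:5) {
    pr <- rand_problem(seed)
    D <- ncol(pr$X_s)
    params <- mlp_init(D, seed = seed + 50)
    prob <- cellpath:::training_problem(pr$X_s, pr$y_s, pr$X_u, pr$paths)
    w0 <- cellpath:::params_to_vec(params)
    for (unsup in c(TRUE, FALSE)) {
      g <- map_gradient(params, 0.6, 0.5, prob, unsup)
      idx <- sample(length(w0), 12)
      fd <- vapply(idx, function(i) {
        h <- 1e-5
        wp <- w0; wp[i] <- wp[i] + h
        wm <- w0; wm[i] <- wm[i] - h
        (map_objective(cellpath:::vec_to_params(wp, D, params$hidden),
                       0.6, 0.5, prob, unsup) -
           map_objective(cellpath:::vec_to_params(wm, D, params$hidden),
                         0.6, 0.5, prob, unsup)) / (2 * h)
      }, numeric(1))
      expect_equal(g[idx], fd, tolerance = 1e-6)
    }
    # prior-only check: gradient of ||w||^2/2 is w itself
    prob_perfect <- cellpath:::training_problem(
      pr$X_s, round(score_region(params, pr$X_s)))
    g0 <- map_gradient(params, 1, 1, prob_perfect, include_unsup = FALSE)
    resid <- round(score_region(params, pr$X_s)) -
      score_region(params, pr$X_s)
    expect_equal(g0, w0 - as.vector(
      cellpath:::mlp_backprop(params, pr$X_s, resid)), tolerance = 1e-10)
  }
})

test_that("training descends, is seeded, and reduces correctly without paths", {
  pr <- rand_problem(9, Ns = 10, R = 16)
  cfg <- model_config(iters_sup = 80, iters_joint = 80, seed = 2)
  st <- train_model(pr$X_s, pr$y_s, pr$X_u, pr$paths, cfg)
  expect_s3_class(st, "model_state")
  expect_true(all(is.finite(st$log$objective)))
  # backtracking + closed-form sigma updates: objective never increases
  # within a phase (phase 2 adds the path terms, so levels differ across
  # the boundary)
  for (ph in unique(st$log$phase)) {
    L <- st$log$objective[st$log$phase == ph]
    expect_true(all(diff(L) <= 1e-8))
  }
  st2 <- train_model(pr$X_s, pr$y_s, pr$X_u, pr$paths, cfg)
  expect_identical(st$params, st2$params)
  # with no unlabeled paths phase 2 is continued supervised training
  st3 <- train_model(pr$X_s, pr$y_s, NULL, list(), cfg)
  expect_true(all(st3$log$sigma_u == 1))
  expect_error(train_model(pr$X_s, rep(1, length(pr$y_s))), "positive and one negative")
})
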