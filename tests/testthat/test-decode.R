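# --- shrinkage LDA -------------------------------------------------------

test_that("prediction follows nearest-class-mean geometry", {
  # training sets whose sample means are exactly (0,0) and (10,0), with
  # identical within-class scatter
  x <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
             c(9, 0), c(11, 0), c(10, -1), c(10, 1))
  y <- rep(c(1, 2), each = 4)
  fit <- fit_lda(x, y, lambda = 0.01)
  expect_equal(predict(fit, rbind(c(9, 1))), "2")
  expect_equal(predict(fit, rbind(c(1, -1))), "1")
  expect_equal(predict(fit, rbind(c(5, 0))), "1")   # tie -> lowest class
})

test_that("full shrinkage reduces to the nearest-centroid rule", {
  withr::with_seed(11, {
    x <- matrix(rnorm(60 * 4), 60, 4)
    y <- rep(1:3, each = 20)
    xt <- matrix(rnorm(40 * 4), 40, 4)
  })
  fit <- fit_lda(x, y, lambda = 1)
  centroids <- rowsum(x, y) / 20
  nearest <- apply(xt, 1, function(v) {
    which.min(colSums((t(centroids) - v)^2))
  })
  expect_equal(predict(fit, xt), as.character(nearest))
})

test_that("accuracy on Gaussian classes matches the Bayes-optimal grid oracle", {
  mu <- rbind(c(0, 0), c(2.5, 0), c(0, 2.5))
  withr::with_seed(21, {
    ytr <- rep(1:3, each = 100)
    xtr <- mu[ytr, ] + matrix(rnorm(600), 300, 2)
    yte <- rep(1:3, each = 400)
    xte <- mu[yte, ] + matrix(rnorm(2400), 1200, 2)
  })
  fit <- fit_lda(xtr, ytr, lambda = 0.01)
  acc <- mean(predict(fit, xte) == as.character(yte))

  # Bayes rate by grid integration of the class densities over the optimal
  # (nearest-true-mean) decision regions
  g <- seq(-6, 9, by = 0.02)
  grid <- expand.grid(x = g, y = g)
  dens <- vapply(1:3, function(k) {
    dnorm(grid$x, mu[k, 1]) * dnorm(grid$y, mu[k, 2])
  }, numeric(nrow(grid)))
  bayes_rate <- sum(apply(dens, 1, max)) * 0.02^2 / 3
  band <- binom_band(bayes_rate, 1200, level = 0.999)
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("unshrunk LDA predictions are invariant to invertible linear maps", {
  withr::with_seed(31, {
    x <- matrix(rnorm(90 * 3), 90, 3) + rep(c(0, 2, 4), each = 30)
    y <- rep(1:3, each = 30)
    xt <- matrix(rnorm(30 * 3), 30, 3)
    a <- matrix(rnorm(9), 3, 3) + diag(3)
  })
  p1 <- predict(fit_lda(x, y, lambda = 0), xt)
  p2 <- predict(fit_lda(x %*% a, y, lambda = 0), xt %*% a)
  expect_equal(p1, p2)
})

test_that("degenerate fits fail with instructive errors", {
  x <- matrix(rnorm(8), 4, 2)
  expect_error(fit_lda(x, c(1, 1, 1, 2)), ">= 2 samples")
  # p > n makes the pooled covariance singular at lambda = 0
  xs <- matrix(rnorm(4 * 10), 4, 10)
  expect_error(fit_lda(xs, c(1, 1, 2, 2), lambda = 0), "lambda > 0")
  expect_s3_class(tidy(fit_lda(x, c(1, 1, 2, 2))), "tbl_df")
  expect_equal(glance(fit_lda(x, c(1, 1, 2, 2)))$n_classes, 2)
})

# --- cross-validation schemes --------------------------------------------

test_that("fixed and tolerant folds implement the matched-budget contract", {
  labels <- rotadecode:::add_repetition_index(scaled_design())
  n_obj <- 12; n_reps <- 7
  fixed <- build_scheme(labels, "fixed_rotation", test_rotation = 0,
                        left_out_rep = 1)
  tol <- build_scheme(labels, "rotation_tolerant", test_rotation = 0,
                      left_out_rep = 1)

  # identical test trials: the left-out repetition of every object at 0 deg
  expect_identical(fixed$test_idx, tol$test_idx)
  expect_equal(length(fixed$test_idx), n_obj)
  expect_true(all(labels$rotation_deg[fixed$test_idx] == 0))
  expect_true(all(labels$repetition_index[fixed$test_idx] == 1))

  # same training budget: n_reps - 1 trials per object in both schemes
  expect_equal(length(fixed$train_idx), n_obj * (n_reps - 1))
  expect_equal(length(tol$train_idx), n_obj * (n_reps - 1))
  expect_length(intersect(fixed$train_idx, fixed$test_idx), 0)
  expect_length(intersect(tol$train_idx, tol$test_idx), 0)

  # fixed trains only on the test rotation; tolerant never on it
  expect_true(all(labels$rotation_deg[fixed$train_idx] == 0))
  expect_true(all(labels$rotation_deg[tol$train_idx] != 0))

  # tolerant: 2 repetitions per object per non-test rotation, and the
  # deterministic rule picks repetitions left_out + 1, left_out + 2
  per_cell <- dplyr::count(labels[tol$train_idx, ], object_id, rotation_deg)
  expect_true(all(per_cell$n == 2))
  expect_setequal(unique(labels$repetition_index[tol$train_idx]), c(2, 3))
})

test_that("swapping scheme changes training rows only, fold by fold", {
  labels <- tiny_labels(n_objects = 3, n_rotations = 2, n_reps = 3)
  ff <- rotadecode:::cv_folds(labels, "fixed_rotation")
  ft <- rotadecode:::cv_folds(labels, "rotation_tolerant")
  expect_equal(length(ff), 2 * 3)
  for (i in seq_along(ff)) {
    expect_identical(ff[[i]]$test_idx, ft[[i]]$test_idx)
    expect_false(identical(ff[[i]]$train_idx, ft[[i]]$train_idx))
  }
})

test_that("a matched tolerant budget is refused when repetitions cannot split", {
  # 3 trainable repetitions cannot split evenly over 2 non-test rotations
  labels <- tiny_labels(n_objects = 2, n_rotations = 3, n_reps = 4)
  expect_error(build_scheme(labels, "rotation_tolerant", 0, 1),
               class = "rotadecode_error_insufficient_reps")
})

# --- decoding time-courses -----------------------------------------------

test_that("a noiseless separable signal decodes perfectly at its peak", {
  ep <- scaled_subject(list(signal_component("rotation_specific", 192,
                                             amplitude = 50)),
                       seed = 301L)
  peak_idx <- which(ep$times_ms == 192)
  tc <- decode_timecourse(ep, "fixed_rotation", time_idx = peak_idx)
  expect_equal(tc$accuracy, 1.0)
  expect_equal(attr(tc, "chance"), 1 / 12)
})

test_that("missing design cells abort decoding with the absent cell named", {
  ep <- scaled_subject(list(), seed = 302L)
  drop <- which(ep$labels$object_id == 3 & ep$labels$rotation_deg == 90 &
                  ep$labels$repetition_index == 2)[1]
  ep_bad <- filter_epochs(ep, trials = setdiff(seq_len(nrow(ep$labels)), drop))
  expect_error(decode_timecourse(ep_bad, "fixed_rotation", time_idx = 1),
               "object 3, 90 deg", class = "rotadecode_error_missing_cells")
})

test_that("decoding requires a single presentation-rate condition", {
  d <- scaled_design(rates = c(5, 20))
  cfg <- synth_config(n_subjects = 1, n_channels = 8,
                      epoch_window_ms = c(-20, 20), components = list(),
                      seed = 1)
  ep <- generate_subject(d, cfg, 1)
  expect_error(decode_timecourse(ep, "fixed_rotation"), "filter_epochs")
})

# --- searchlight ---------------------------------------------------------

test_that("the full-neighbourhood searchlight equals whole-scalp decoding", {
  ep <- scaled_subject(list(signal_component("rotation_specific", 100,
                                             amplitude = 2)),
                       seed = 303L, n_channels = 6, window = c(-20, 120))
  tidx <- which(ep$times_ms %in% c(0, 100))
  sl <- searchlight_timecourse(ep, "fixed_rotation", n_neighbours = 5,
                               time_idx = tidx)
  tc <- decode_timecourse(ep, "fixed_rotation", time_idx = tidx)
  for (ch in 1:6) {
    expect_equal(sl$accuracy[sl$channel == ch], tc$accuracy)
  }
})

test_that("searchlight maxima localize a spatially restricted signal", {
  labels <- tiny_labels(n_objects = 4, n_rotations = 2, n_reps = 5)
  n_ch <- 10
  coords <- rotadecode:::fibonacci_sphere(n_ch)
  d <- as.matrix(dist(coords))
  centre <- 1L
  lit <- order(d[centre, ], seq_len(n_ch))[1:5]   # channel 1's neighbourhood
  pats <- withr::with_seed(7, matrix(rnorm(4 * 5, sd = 3), 4, 5))
  ep <- manual_epochs(labels, function(obj, rot) {
    p <- numeric(n_ch); p[lit] <- pats[obj, ]; p
  }, n_channels = n_ch, seed = 8)
  sl <- searchlight_timecourse(ep, "fixed_rotation", n_neighbours = 4,
                               time_idx = which(ep$times_ms == 20))
  far <- which.max(d[centre, ])
  acc <- sl$accuracy[order(sl$channel)]
  expect_gt(acc[centre], acc[far])
  expect_equal(which.max(acc) %in% lit, TRUE)
})
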