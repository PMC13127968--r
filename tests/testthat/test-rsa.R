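# --- model RDMs ----------------------------------------------------------

test_that("the rotation-tolerant model scores object identity only", {
  labels <- tiny_labels(n_objects = 5, n_rotations = 4, n_reps = 1)
  m <- rotation_tolerant_model(labels)
  conds <- attr(m, "condition_labels")
  i <- which(conds$object_id == 3 & conds$rotation_deg == 0)
  j <- which(conds$object_id == 3 & conds$rotation_deg == 180)
  k <- which(conds$object_id == 4 & conds$rotation_deg == 0)
  expect_equal(m[i, j], 0)
  expect_equal(m[i, k], 1)
  expect_true(isSymmetric(unclass(m)))
  expect_true(all(diag(m) == 0))
  # every condition is dissimilar to all conditions of the other objects
  expect_equal(unname(rowSums(m)), rep(nrow(conds) - 4, nrow(conds)))
})

test_that("cosine feature RDMs match closed forms", {
  f <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 2), d = c(1, 1))
  m <- feature_model_rdm(f)
  expect_equal(m[1, 2], 0)
  expect_equal(m[1, 3], 1)
  expect_equal(m[1, 4], 1 - 1 / sqrt(2))
  expect_error(feature_model_rdm(rbind(c(1, 1), c(0, 0))), "zero-norm")
})

# --- neural RDMs ---------------------------------------------------------

test_that("pairwise decoding separates distinct conditions and not identical ones", {
  labels <- tiny_labels(n_objects = 2, n_rotations = 2, n_reps = 8)
  hits_sep <- 0; hits_same <- 0; n_entries <- 0
  for (s in 1:25) {
    # object 1 carries a strong pattern; object 2's two rotations share a
    # distribution, so their pairwise entry should sit at 0.5
    ep <- manual_epochs(labels, function(obj, rot) {
      if (obj == 1) c(4, -4, 4, 0, 0, 0) * (1 + rot / 180) else rep(0, 6)
    }, seed = s)
    rdm <- neural_rdm(ep, time_idx = which(ep$times_ms == 20))
    conds <- rdm$condition_labels
    sep <- rdm$rdm[1, which(conds$object_id == 1 & conds$rotation_deg == 0),
                   which(conds$object_id == 2 & conds$rotation_deg == 0)]
    same <- rdm$rdm[1, which(conds$object_id == 2 & conds$rotation_deg == 0),
                    which(conds$object_id == 2 & conds$rotation_deg == 180)]
    hits_sep <- hits_sep + sep * 16
    hits_same <- hits_same + same * 16
    n_entries <- n_entries + 16
  }
  expect_gt(hits_sep / n_entries, 0.95)
  band <- binom_band(0.5, n_entries, level = 0.999)
  expect_gte(hits_same / n_entries, band[1])
  expect_lte(hits_same / n_entries, band[2])
})

test_that("the fast pairwise path agrees with a per-fold LDA refit oracle", {
  labels <- tiny_labels(n_objects = 3, n_rotations = 1, n_reps = 5)
  labels$rotation_deg <- 0
  ep <- manual_epochs(labels, function(obj, rot) c(obj, -obj, 0, 1, 0, 0),
                      seed = 99)
  tidx <- which(ep$times_ms %in% c(0, 20))
  rdm <- neural_rdm(ep, lambda = 0.05, time_idx = tidx)
  # brute force: refit fit_lda() on raw trials for every pair and fold
  for (i in 1:2) for (j in (i + 1):3) {
    ri <- which(labels$object_id == i)
    rj <- which(labels$object_id == j)
    for (tt in seq_along(tidx)) {
      correct <- 0
      for (r in 1:5) {
        xtr <- rbind(ep$data[ri[-r], , tidx[tt]], ep$data[rj[-r], , tidx[tt]])
        fit <- fit_lda(xtr, rep(c("a", "b"), each = 4), lambda = 0.05)
        pred <- predict(fit, ep$data[c(ri[r], rj[r]), , tidx[tt]])
        correct <- correct + sum(pred == c("a", "b"))
      }
      expect_equal(rdm$rdm[tt, i, j], correct / 10, tolerance = 1e-10)
    }
  }
})

test_that("duplicated noise-free trials trigger the degenerate-variance guard", {
  labels <- tiny_labels(n_objects = 2, n_rotations = 1, n_reps = 3)
  labels$rotation_deg <- 0
  ep <- manual_epochs(labels, function(obj, rot) c(obj, 0, 0, 0, 0, 0),
                      noise_sd = 0, seed = 1)
  expect_error(neural_rdm(ep, time_idx = 1), "zero within-pair variance")
})

# --- stand-in control features -------------------------------------------

test_that("stand-in features are deterministic and rotation-sensitive", {
  labels <- tiny_labels(n_objects = 4, n_rotations = 2, n_reps = 1)
  f1 <- standin_features(labels, layer = 1, seed = 5)
  f2 <- standin_features(labels, layer = 1, seed = 5)
  expect_identical(f1, f2)
  conds <- attr(f1, "condition_labels")
  m <- feature_model_rdm(f1)
  i <- which(conds$object_id == 1 & conds$rotation_deg == 0)
  j <- which(conds$object_id == 1 & conds$rotation_deg == 180)
  expect_gt(m[i, j], 0)
  expect_error(standin_features(labels, kind = "wavelet"), "unknown feature kind")
})

test_that("pseudo-layer RDM similarity decreases with layer separation", {
  labels <- tiny_labels(n_objects = 6, n_rotations = 4, n_reps = 1)
  rdm_cor <- function(a, b) cor(a[lower.tri(a)], b[lower.tri(b)])
  for (s in 1:5) {
    ms <- lapply(1:3, function(l) {
      feature_model_rdm(standin_features(labels, layer = l, seed = s))
    })
    expect_gt(rdm_cor(ms[[1]], ms[[2]]), rdm_cor(ms[[1]], ms[[3]]))
  }
})

# --- partial correlation -------------------------------------------------

test_that("partial correlation matches a brute-force residualization oracle", {
  # 6-condition worked example: 15 lower-triangle entries per matrix
  withr::with_seed(13, {
    sym <- function() {
      m <- matrix(0, 6, 6)
      m[lower.tri(m)] <- runif(15)
      m + t(m)
    }
    neural <- sym(); model <- sym(); c1 <- sym(); c2 <- sym()
  })
  got <- rdm_partial_cor(neural, model, list(c1, c2), method = "spearman")
  lt <- function(m) rank(m[lower.tri(m)])
  rv <- resid(lm(lt(neural) ~ lt(c1) + lt(c2)))
  rx <- resid(lm(lt(model) ~ lt(c1) + lt(c2)))
  expect_equal(got, cor(rv, rx), tolerance = 1e-12)

  gp <- rdm_partial_cor(neural, model, list(c1, c2), method = "pearson")
  ltp <- function(m) m[lower.tri(m)]
  expect_equal(gp, cor(resid(lm(ltp(neural) ~ ltp(c1) + ltp(c2))),
                       resid(lm(ltp(model) ~ ltp(c1) + ltp(c2)))),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(got, gp)))
})

test_that("an RDM correlates perfectly with itself and is rank-invariant", {
  withr::with_seed(17, {
    m <- matrix(0, 8, 8)
    m[lower.tri(m)] <- runif(28)
    m <- m + t(m)
    other <- matrix(0, 8, 8)
    other[lower.tri(other)] <- runif(28)
    other <- other + t(other)
  })
  expect_equal(rdm_partial_cor(m, m), 1.0)
  # any strictly monotone transform of the dissimilarities leaves the
  # rank-based coefficient untouched
  warped <- exp(3 * m); diag(warped) <- 0
  expect_equal(rdm_partial_cor(warped, other, list(exp(other))),
               rdm_partial_cor(m, other, list(exp(other))))
  expect_warning(out <- rdm_partial_cor(matrix(1, 4, 4), other[1:4, 1:4]),
                 "constant")
  expect_true(is.na(out))
})

test_that("partial-correlation time-courses validate label alignment", {
  labels <- tiny_labels(n_objects = 3, n_rotations = 2, n_reps = 4)
  ep <- manual_epochs(labels, function(obj, rot) rep(obj, 6), seed = 3)
  rdm <- neural_rdm(ep, time_idx = c(1, 2))
  model <- rotation_tolerant_model(labels)
  pc <- partial_corr_timecourse(rdm, model)
  expect_equal(nrow(pc), 2)
  expect_true(all(abs(pc$r_partial) <= 1))
  wrong <- rotation_tolerant_model(tiny_labels(n_objects = 4, n_rotations = 2,
                                               n_reps = 1))
  expect_error(partial_corr_timecourse(rdm, wrong), "condition")
})

test_that("model RDMs round-trip through labelled TSV", {
  labels <- tiny_labels(n_objects = 3, n_rotations = 2, n_reps = 1)
  m <- rotation_tolerant_model(labels)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_rdm_tsv(m, path)
  back <- read_model_rdm_tsv(path)
  expect_equal(array(as.numeric(back), dim(m)), array(as.numeric(m), dim(m)))
  expect_equal(as.data.frame(attr(back, "condition_labels")),
               as.data.frame(attr(m, "condition_labels")))
})
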