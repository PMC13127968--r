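#' Fit a shrinkage-regularized linear discriminant classifier
#'
#' Multiclass LDA with equal priors: a sample is assigned to the nearest
#' class mean under the Mahalanobis metric induced by the pooled
#' within-class covariance, shrunk towards a scaled identity,
#' `(1 - lambda) * S + lambda * (tr(S) / p) * I`.
#'
#' @param x Numeric matrix, samples in rows, features (channels) in columns.
#' @param y Class labels, one per row of `x`; every class needs at least two
#'   samples.
#' @param lambda Shrinkage weight in `[0, 1]`. `lambda = 0` is plain LDA and
#'   fails on singular covariance; `lambda = 1` reduces to a scaled
#'   nearest-centroid (Euclidean) rule.
#' @return An `lda_model` with class means, the shrunk pooled covariance and
#'   the linear scoring weights. Ties in the discriminant scores resolve to
#'   the lowest class index.
#' @export
fit_lda <- function(x, y, lambda = 0.01) {
  x <- as.matrix(x)
  if (lambda < 0 || lambda > 1) stop_rd("lambda must lie in [0, 1]")
  if (nrow(x) != length(y)) stop_rd("length(y) must match nrow(x)")
  counts <- table(y)
  if (any(counts < 2L)) {
    stop_rd(sprintf("every class needs >= 2 samples; offending: %s",
                    paste(names(counts)[counts < 2L], collapse = ", ")))
  }
  core <- lda_fit_core(x, y, lambda)
  structure(c(core, list(lambda = lambda, n = nrow(x))), class = "lda_model")
}

# internal fast path used by all decoding loops (no input validation)
lda_fit_core <- function(x, y, lambda) {
  f <- factor(y)
  classes <- levels(f)
  k <- length(classes)
  p <- ncol(x)
  idx <- as.integer(f)
  counts <- tabulate(idx, k)
  means <- rowsum(x, idx, reorder = TRUE) / counts
  centered <- x - means[idx, , drop = FALSE]
  sw <- crossprod(centered) / (nrow(x) - k)
  s <- (1 - lambda) * sw
  diag(s) <- diag(s) + lambda * (sum(diag(sw)) / p)
  ch <- tryCatch(chol(s), error = function(e) {
    stop_rd("pooled covariance is singular; use shrinkage lambda > 0",
            class = "rotadecode_error_singular")
  })
  w <- chol2inv(ch) %*% t(means)           # p x k
  b <- -0.5 * colSums(t(means) * w)        # length k
  list(classes = classes, means = means, weights = w, bias = b,
       covariance = s)
}

lda_predict_idx <- function(model, newx) {
  scores <- newx %*% model$weights +
    rep(model$bias, each = nrow(newx))
  max.col(scores, ties.method = "first")
}

#' @param object An `lda_model`.
#' @param newdata Matrix of samples to classify.
#' @param ... Unused.
#' @rdname fit_lda
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  object$classes[lda_predict_idx(object, newdata)]
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model: %d classes, %d features, lambda = %g, n = %d>\n",
              length(x$classes), ncol(x$means), x$lambda, x$n))
  invisible(x)
}

#' @rdname fit_lda
#' @export
tidy.lda_model <- function(x, ...) {
  as_tibble(x$means, .name_repair = "minimal") |>
    setNames(paste0("feature_", seq_len(ncol(x$means)))) |>
    dplyr::mutate(class = x$classes, .before = 1)
}

#' @rdname fit_lda
#' @export
glance.lda_model <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_features = ncol(x$means),
         lambda = x$lambda, n_samples = x$n)
}

check_complete_cells <- function(labels) {
  cells <- dplyr::count(labels, .data$object_id, .data$rotation_deg)
  n_reps <- max(labels$repetition_index)
  full <- tidyr::expand_grid(object_id = sort(unique(labels$object_id)),
                             rotation_deg = sort(unique(labels$rotation_deg)))
  bad <- dplyr::anti_join(full, cells[cells$n == n_reps, c(1, 2)],
                          by = c("object_id", "rotation_deg"))
  if (nrow(bad) > 0) {
    stop_rd(sprintf(
      "incomplete design cells (need %d repetitions each): %s",
      n_reps,
      paste(sprintf("(object %s, %s deg)", bad$object_id, bad$rotation_deg),
            collapse = ", ")),
      class = "rotadecode_error_missing_cells")
  }
  n_reps
}

#' Build one cross-validation fold for object decoding
#'
#' Both schemes test on the *identical* trials — the left-out repetition of
#' every object at the test rotation — and train on the same budget of
#' `n_reps - 1` trials per object. They differ only in where the training
#' trials come from:
#'
#' * `fixed_rotation`: the remaining repetitions of every object at the
#'   test rotation itself.
#' * `rotation_tolerant`: repetitions of every object at the *other*
#'   rotations only, `(n_reps - 1) / (n_rotations - 1)` per rotation. With
#'   the default rule the repetitions used at every other rotation are
#'   `left_out_rep + 1, left_out_rep + 2, ...` cyclically; with
#'   `tolerant_reps = "random"` they are drawn per rotation from `seed`.
#'
#' @param labels Trial label tibble (`object_id`, `rotation_deg`,
#'   `repetition_index`), one rate condition.
#' @param scheme_name `"fixed_rotation"` or `"rotation_tolerant"`.
#' @param test_rotation Rotation angle of the test trials.
#' @param left_out_rep Repetition index held out for testing.
#' @param tolerant_reps `"deterministic"` (default) or `"random"`.
#' @param seed Seed for `tolerant_reps = "random"`.
#' @return A `cv_fold` list with integer `train_idx` and `test_idx` into the
#'   rows of `labels`.
#' @export
build_scheme <- function(labels, scheme_name = c("fixed_rotation", "rotation_tolerant"),
                         test_rotation, left_out_rep,
                         tolerant_reps = c("deterministic", "random"),
                         seed = NULL) {
  scheme_name <- match.arg(scheme_name)
  tolerant_reps <- match.arg(tolerant_reps)
  n_reps <- check_complete_cells(labels)
  angles <- sort(unique(labels$rotation_deg))
  if (!test_rotation %in% angles) {
    stop_rd(sprintf("test_rotation %s not present in labels", test_rotation))
  }
  test_idx <- which(labels$rotation_deg == test_rotation &
                      labels$repetition_index == left_out_rep)
  if (length(test_idx) == 0L) stop_rd("no trials at (test_rotation, left_out_rep)")

  if (scheme_name == "fixed_rotation") {
    train_idx <- which(labels$rotation_deg == test_rotation &
                         labels$repetition_index != left_out_rep)
  } else {
    n_other <- length(angles) - 1L
    if ((n_reps - 1L) %% n_other != 0L) {
      stop_rd(sprintf(
        "insufficient repetitions for a matched training budget: n_reps - 1 = %d is not divisible by the %d other rotations",
        n_reps - 1L, n_other), class = "rotadecode_error_insufficient_reps")
    }
    k <- (n_reps - 1L) %/% n_other
    others <- setdiff(angles, test_rotation)
    if (tolerant_reps == "deterministic") {
      use_reps <- ((left_out_rep - 1L + seq_len(k)) %% n_reps) + 1L
      train_idx <- which(labels$rotation_deg != test_rotation &
                           labels$repetition_index %in% use_reps)
    } else {
      if (is.null(seed)) stop_rd("tolerant_reps = 'random' requires a seed")
      train_idx <- withr::with_seed(seed, {
        unlist(lapply(others, function(a) {
          pool <- setdiff(seq_len(n_reps), left_out_rep)
          reps <- pool[sample.int(length(pool), k)]
          which(labels$rotation_deg == a & labels$repetition_index %in% reps)
        }))
      })
    }
  }
  structure(list(scheme = scheme_name, test_rotation = test_rotation,
                 left_out_rep = left_out_rep,
                 train_idx = as.integer(train_idx),
                 test_idx = as.integer(test_idx)),
            class = "cv_fold")
}

# all (rotation x left-out repetition) folds for a scheme
cv_folds <- function(labels, scheme_name, tolerant_reps = "deterministic",
                     seed = NULL) {
  n_reps <- check_complete_cells(labels)
  angles <- sort(unique(labels$rotation_deg))
  folds <- list()
  for (a in angles) {
    for (r in seq_len(n_reps)) {
      fseed <- if (is.null(seed)) NULL else seed + 1000L * match(a, angles) + r
      folds[[length(folds) + 1L]] <-
        build_scheme(labels, scheme_name, a, r, tolerant_reps, fseed)
    }
  }
  folds
}

ensure_single_rate <- function(ep) {
  rates <- unique(ep$labels$rate_hz)
  if (length(rates) != 1L) {
    stop_rd(sprintf(
      "epoch set mixes rates (%s); restrict to one with filter_epochs(ep, rate_hz = ...)",
      paste(rates, collapse = ", ")))
  }
  rates
}

resolve_time_idx <- function(ep, time_idx) {
  if (is.null(time_idx)) seq_along(ep$times_ms) else as.integer(time_idx)
}

#' Time-resolved multiclass object decoding
#'
#' For every time-point, trains a [fit_lda()] classifier on the channel
#' vector at that time and evaluates it under the leave-one-repetition-out
#' scheme, averaging accuracy over all (test rotation x left-out repetition)
#' folds. Chance is `1 / n_objects` (1.67% for 60 objects).
#'
#' @param ep An `epoch_set` restricted to a single rate condition.
#' @param scheme_name `"fixed_rotation"` or `"rotation_tolerant"`.
#' @param lambda Shrinkage for [fit_lda()].
#' @param time_idx Optional integer index into `ep$times_ms` to decode a
#'   subset of time-points.
#' @param keep_folds Keep the per-fold accuracy matrix as an attribute.
#' @inheritParams build_scheme
#' @return A `decoding_timecourse` tibble (`time_ms`, `accuracy`) with
#'   attributes `chance`, `scheme`, `rate_hz`, `lambda` and (optionally)
#'   `per_fold` (folds x time matrix).
#' @export
decode_timecourse <- function(ep, scheme_name = c("fixed_rotation", "rotation_tolerant"),
                              lambda = 0.01, time_idx = NULL,
                              tolerant_reps = "deterministic", seed = NULL,
                              keep_folds = FALSE) {
  scheme_name <- match.arg(scheme_name)
  rate <- ensure_single_rate(ep)
  folds <- cv_folds(ep$labels, scheme_name, tolerant_reps, seed)
  tis <- resolve_time_idx(ep, time_idx)
  y <- ep$labels$object_id
  acc <- matrix(NA_real_, nrow = length(folds), ncol = length(tis))
  for (j in seq_along(tis)) {
    x <- ep$data[, , tis[j]]
    for (i in seq_along(folds)) {
      f <- folds[[i]]
      model <- lda_fit_core(x[f$train_idx, , drop = FALSE], y[f$train_idx], lambda)
      pred <- model$classes[lda_predict_idx(model, x[f$test_idx, , drop = FALSE])]
      acc[i, j] <- mean(pred == as.character(y[f$test_idx]))
    }
  }
  out <- tibble(time_ms = ep$times_ms[tis], accuracy = colMeans(acc))
  structure_timecourse(out, ep, scheme_name, rate, lambda,
                       if (keep_folds) acc else NULL)
}

structure_timecourse <- function(out, ep, scheme_name, rate, lambda, per_fold) {
  attr(out, "chance") <- 1 / length(unique(ep$labels$object_id))
  attr(out, "scheme") <- scheme_name
  attr(out, "rate_hz") <- rate
  attr(out, "lambda") <- lambda
  attr(out, "subject_id") <- ep$subject_id
  if (!is.null(per_fold)) attr(out, "per_fold") <- per_fold
  class(out) <- c("decoding_timecourse", class(out))
  out
}

#' Channel-searchlight decoding topography
#'
#' Repeats [decode_timecourse()] on small channel neighbourhoods: for each
#' channel, the feature set is that channel plus its `n_neighbours` nearest
#' neighbours (Euclidean distance on the electrode coordinates), and the
#' resulting accuracy is stored at the centre channel. Duplicate electrode
#' positions are tie-broken by channel index with a warning.
#'
#' @inheritParams decode_timecourse
#' @param n_neighbours Neighbourhood size (default 4).
#' @return A tibble with columns `channel`, `time_ms`, `accuracy` plus the
#'   same attributes as [decode_timecourse()].
#' @export
searchlight_timecourse <- function(ep, scheme_name = c("fixed_rotation", "rotation_tolerant"),
                                   n_neighbours = 4L, lambda = 0.01,
                                   time_idx = NULL,
                                   tolerant_reps = "deterministic", seed = NULL) {
  scheme_name <- match.arg(scheme_name)
  n_ch <- dim(ep$data)[2]
  if (n_neighbours >= n_ch) stop_rd("n_neighbours must be smaller than n_channels")
  d <- as.matrix(stats::dist(ep$channel_coords))
  if (any(d[upper.tri(d)] == 0)) {
    warn("duplicate channel coordinates; neighbour ties broken by channel index")
  }
  maps <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    nb <- order(d[ch, ], seq_len(n_ch))   # self first (distance 0), then index ties
    sel <- nb[seq_len(n_neighbours + 1L)]
    sub <- ep
    sub$data <- ep$data[, sel, , drop = FALSE]
    tc <- decode_timecourse(sub, scheme_name, lambda, time_idx,
                            tolerant_reps, seed)
    maps[[ch]] <- tibble(channel = ch, time_ms = tc$time_ms,
                         accuracy = tc$accuracy)
  }
  out <- dplyr::bind_rows(maps)
  attr(out, "chance") <- 1 / length(unique(ep$labels$object_id))
  attr(out, "scheme") <- scheme_name
  attr(out, "rate_hz") <- ensure_single_rate(ep)
  attr(out, "lambda") <- lambda
  attr(out, "n_neighbours") <- n_neighbours
  class(out) <- c("searchlight_map", class(out))
  out
}
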