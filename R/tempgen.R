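new_tg_matrix <- function(accuracy, train_times, test_times, scheme,
                          train_rate, test_rate, chance, lambda) {
  structure(list(accuracy = accuracy, train_times_ms = train_times,
                 test_times_ms = test_times, scheme = scheme,
                 train_rate_hz = train_rate, test_rate_hz = test_rate,
                 chance = chance, lambda = lambda),
            class = "tg_matrix")
}

#' Within-condition temporal generalization
#'
#' Trains the decoder at every time-point and tests it at every other,
#' using exactly the same leave-one-repetition-out folds as
#' [decode_timecourse()]; the diagonal of the resulting matrix therefore
#' equals the decoding time-course of the same scheme to machine precision.
#'
#' @inheritParams decode_timecourse
#' @return A `tg_matrix`: train x test accuracy matrix with time axes,
#'   scheme, rates and chance level.
#' @export
tg_within <- function(ep, scheme_name = c("fixed_rotation", "rotation_tolerant"),
                      lambda = 0.01, time_idx = NULL,
                      tolerant_reps = "deterministic", seed = NULL) {
  scheme_name <- match.arg(scheme_name)
  rate <- ensure_single_rate(ep)
  folds <- cv_folds(ep$labels, scheme_name, tolerant_reps, seed)
  tis <- resolve_time_idx(ep, time_idx)
  y <- ep$labels$object_id
  n_t <- length(tis)
  acc_sum <- matrix(0, n_t, n_t)
  for (f in folds) {
    ytest <- as.character(y[f$test_idx])
    test_x <- ep$data[f$test_idx, , tis, drop = FALSE]
    for (a in seq_len(n_t)) {
      model <- lda_fit_core(ep$data[f$train_idx, , tis[a]], y[f$train_idx], lambda)
      for (b in seq_len(n_t)) {
        pred <- model$classes[lda_predict_idx(model, test_x[, , b])]
        acc_sum[a, b] <- acc_sum[a, b] + mean(pred == ytest)
      }
    }
  }
  times <- ep$times_ms[tis]
  new_tg_matrix(acc_sum / length(folds), times, times, scheme_name,
                rate, rate, 1 / length(unique(y)), lambda)
}

# full-data cross-rate folds: one per test rotation; training uses every
# repetition of the training rate (train and test conditions are disjoint
# by construction, so no repetition needs to be held out)
cross_rate_folds <- function(labels_train, labels_test, scheme_name) {
  angles <- sort(unique(labels_test$rotation_deg))
  lapply(angles, function(a) {
    train_idx <- if (scheme_name == "fixed_rotation") {
      which(labels_train$rotation_deg == a)
    } else {
      which(labels_train$rotation_deg != a)
    }
    list(train_idx = train_idx, test_idx = which(labels_test$rotation_deg == a))
  })
}

tg_between <- function(ep_train, ep_test, scheme_name, lambda, tis_train, tis_test) {
  folds <- cross_rate_folds(ep_train$labels, ep_test$labels, scheme_name)
  y_train <- ep_train$labels$object_id
  y_test <- ep_test$labels$object_id
  acc_sum <- matrix(0, length(tis_train), length(tis_test))
  for (f in folds) {
    ytest <- as.character(y_test[f$test_idx])
    test_x <- ep_test$data[f$test_idx, , tis_test, drop = FALSE]
    for (a in seq_along(tis_train)) {
      model <- lda_fit_core(ep_train$data[f$train_idx, , tis_train[a]],
                            y_train[f$train_idx], lambda)
      for (b in seq_along(tis_test)) {
        pred <- model$classes[lda_predict_idx(model, test_x[, , b])]
        acc_sum[a, b] <- acc_sum[a, b] + mean(pred == ytest)
      }
    }
  }
  acc_sum / length(folds)
}

#' Cross-rate temporal generalization with transpose-averaging
#'
#' Trains on one presentation rate and tests on the other, in both
#' directions, then averages the train-slow/test-fast matrix with the
#' transpose of the train-fast/test-slow matrix. Rows of the result are
#' indexed by the slow-rate (first argument) time axis and columns by the
#' fast-rate time axis. Training uses all repetitions of the training rate
#' (the conditions are disjoint, so no leave-out is needed) and testing all
#' repetitions of the testing rate, with one fold per test rotation.
#'
#' @param ep_slow,ep_fast `epoch_set`s for the two rate conditions, sharing
#'   the same object and rotation label structure.
#' @inheritParams decode_timecourse
#' @param time_idx_slow,time_idx_fast Optional time subsets per condition.
#' @return A `tg_matrix` with rows on the slow-rate and columns on the
#'   fast-rate time axis.
#' @export
tg_cross_rate <- function(ep_slow, ep_fast,
                          scheme_name = c("fixed_rotation", "rotation_tolerant"),
                          lambda = 0.01, time_idx_slow = NULL,
                          time_idx_fast = NULL) {
  scheme_name <- match.arg(scheme_name)
  rate_slow <- ensure_single_rate(ep_slow)
  rate_fast <- ensure_single_rate(ep_fast)
  same_cells <- isTRUE(all.equal(
    dplyr::arrange(dplyr::distinct(ep_slow$labels, .data$object_id, .data$rotation_deg),
                   .data$object_id, .data$rotation_deg),
    dplyr::arrange(dplyr::distinct(ep_fast$labels, .data$object_id, .data$rotation_deg),
                   .data$object_id, .data$rotation_deg)))
  if (!same_cells) stop_rd("the two epoch sets must share object/rotation label structure")
  tis_s <- resolve_time_idx(ep_slow, time_idx_slow)
  tis_f <- resolve_time_idx(ep_fast, time_idx_fast)
  m_a <- tg_between(ep_slow, ep_fast, scheme_name, lambda, tis_s, tis_f)
  m_b <- tg_between(ep_fast, ep_slow, scheme_name, lambda, tis_f, tis_s)
  new_tg_matrix((m_a + t(m_b)) / 2, ep_slow$times_ms[tis_s],
                ep_fast$times_ms[tis_f], scheme_name, rate_slow, rate_fast,
                1 / length(unique(ep_slow$labels$object_id)), lambda)
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat(sprintf(
    "<tg_matrix (%s): %d train x %d test time-points, rates %g/%g Hz, chance %.3f>\n",
    x$scheme, length(x$train_times_ms), length(x$test_times_ms),
    x$train_rate_hz, x$test_rate_hz, x$chance))
  invisible(x)
}

#' @param x A `tg_matrix`.
#' @param ... Unused.
#' @rdname tg_within
#' @export
tidy.tg_matrix <- function(x, ...) {
  tidyr::expand_grid(train_time_ms = x$train_times_ms,
                     test_time_ms = x$test_times_ms) |>
    dplyr::mutate(accuracy = as.vector(t(x$accuracy)),
                  scheme = x$scheme, train_rate_hz = x$train_rate_hz,
                  test_rate_hz = x$test_rate_hz)
}

#' @rdname tg_within
#' @export
glance.tg_matrix <- function(x, ...) {
  tibble(scheme = x$scheme, train_rate_hz = x$train_rate_hz,
         test_rate_hz = x$test_rate_hz, chance = x$chance,
         lambda = x$lambda, max_accuracy = max(x$accuracy),
         mean_accuracy = mean(x$accuracy))
}

#' Write a temporal-generalization matrix as a long-format table
#'
#' @param x A `tg_matrix`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_tg_tsv <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
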