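#' Cross-validated pairwise-decoding neural RDM
#'
#' Builds a time-resolved representational dissimilarity matrix over all
#' (object, rotation) conditions: entry (i, j) is the leave-one-repetition-
#' out cross-validated two-class shrinkage-LDA accuracy for discriminating
#' condition i from condition j at each time-point. More dissimilar neural
#' responses decode better, so entries near 0.5 mean indistinguishable and
#' entries near 1 mean fully distinct. Each unordered pair is computed once;
#' the diagonal is 0 by convention. With the full design this is a 480 x 480
#' matrix per time-point (60 objects x 8 rotations).
#'
#' @param ep An `epoch_set` restricted to one rate condition.
#' @param lambda Shrinkage for the pairwise LDA.
#' @param time_idx Optional integer index into `ep$times_ms`.
#' @return An `rdm_stack`: list with `rdm` (time x C x C array), `times_ms`,
#'   `condition_labels` (tibble `object_id`, `rotation_deg`) and
#'   `metric = "pairwise_decoding"`.
#' @export
neural_rdm <- function(ep, lambda = 0.01, time_idx = NULL) {
  ensure_single_rate(ep)
  n_reps <- check_complete_cells(ep$labels)
  if (n_reps < 2L) stop_rd("pairwise cross-validation needs >= 2 repetitions per condition")
  tis <- resolve_time_idx(ep, time_idx)
  conds <- dplyr::distinct(ep$labels, .data$object_id, .data$rotation_deg) |>
    dplyr::arrange(.data$object_id, .data$rotation_deg)
  n_c <- nrow(conds)
  # trial rows per condition, ordered by repetition
  cond_rows <- lapply(seq_len(n_c), function(i) {
    sel <- which(ep$labels$object_id == conds$object_id[i] &
                   ep$labels$rotation_deg == conds$rotation_deg[i])
    sel[order(ep$labels$repetition_index[sel])]
  })
  n_t <- length(tis)
  n_ch <- dim(ep$data)[2]
  rdm <- array(0, dim = c(n_t, n_c, n_c))
  # per-condition sufficient statistics per time-point: rep x channel data,
  # channel sums and Gram matrices; leave-one-rep-out means and scatters
  # then follow by rank-1 downdates instead of refitting from raw trials
  xs <- lapply(seq_len(n_c), function(i) ep$data[cond_rows[[i]], , tis, drop = FALSE])
  sums <- lapply(xs, function(x) apply(x, c(2, 3), sum))          # ch x time
  grams <- lapply(xs, function(x) {
    g <- array(0, dim = c(n_ch, n_ch, n_t))
    for (tt in seq_len(n_t)) g[, , tt] <- crossprod(x[, , tt])
    g
  })
  m <- n_reps - 1L
  dof <- 2L * m - 2L
  eye <- diag(n_ch)
  for (i in seq_len(n_c - 1L)) {
    for (j in (i + 1L):n_c) {
      acc_t <- numeric(n_t)
      for (tt in seq_len(n_t)) {
        xi <- xs[[i]][, , tt]; xj <- xs[[j]][, , tt]
        gi <- grams[[i]][, , tt]; gj <- grams[[j]][, , tt]
        si <- sums[[i]][, tt]; sj <- sums[[j]][, tt]
        for (r in seq_len(n_reps)) {
          ti_ <- xi[r, ]; tj_ <- xj[r, ]
          m1 <- (si - ti_) / m; m2 <- (sj - tj_) / m
          sw <- (gi - tcrossprod(ti_) - m * tcrossprod(m1) +
                   gj - tcrossprod(tj_) - m * tcrossprod(m2)) / dof
          s <- (1 - lambda) * sw +
            (lambda * sum(diag(sw)) / n_ch) * eye
          w <- tryCatch(solve(s, m1 - m2), error = function(e) {
            stop_rd(sprintf(
              "zero within-pair variance between conditions (object %s, %s deg) and (object %s, %s deg)",
              conds$object_id[i], conds$rotation_deg[i],
              conds$object_id[j], conds$rotation_deg[j]))
          })
          b <- (m1 + m2) / 2
          # score >= 0 assigns class 1 (lowest class index wins ties)
          acc_t[tt] <- acc_t[tt] + (sum((ti_ - b) * w) >= 0) +
            (sum((tj_ - b) * w) < 0)
        }
      }
      rdm[, i, j] <- rdm[, j, i] <- acc_t / (2 * n_reps)
    }
  }
  structure(list(rdm = rdm, times_ms = ep$times_ms[tis],
                 condition_labels = conds, metric = "pairwise_decoding",
                 subject_id = ep$subject_id),
            class = "rdm_stack")
}

#' @export
print.rdm_stack <- function(x, ...) {
  cat(sprintf("<rdm_stack: %d x %d conditions at %d time-points, metric %s>\n",
              nrow(x$condition_labels), nrow(x$condition_labels),
              length(x$times_ms), x$metric))
  invisible(x)
}

#' @param x An `rdm_stack`.
#' @param ... Unused.
#' @rdname neural_rdm
#' @export
tidy.rdm_stack <- function(x, ...) {
  n_c <- nrow(x$condition_labels)
  idx <- which(lower.tri(matrix(0, n_c, n_c)), arr.ind = TRUE)
  purrr::map_dfr(seq_along(x$times_ms), function(t) {
    tibble(time_ms = x$times_ms[t],
           row = idx[, "row"], col = idx[, "col"],
           dissimilarity = x$rdm[t, , ][idx])
  })
}

new_model_rdm <- function(m, name, source, labels = NULL) {
  structure(m, class = c("model_rdm", "matrix", "array"),
            name = name, source = source, condition_labels = labels)
}

#' Rotation-tolerant object model RDM
#'
#' Predicts identical responses to the same object in any rotation
#' (dissimilarity 0) and maximally distinct responses to different objects
#' (dissimilarity 1).
#'
#' @param labels Tibble of condition labels with `object_id` and
#'   `rotation_deg` (extra columns and duplicate rows are reduced to the
#'   distinct condition set, sorted by object then rotation).
#' @return A `model_rdm` matrix (C x C, zero diagonal).
#' @export
rotation_tolerant_model <- function(labels) {
  conds <- dplyr::distinct(labels, .data$object_id, .data$rotation_deg) |>
    dplyr::arrange(.data$object_id, .data$rotation_deg)
  m <- 1 - outer(conds$object_id, conds$object_id, "==")
  storage.mode(m) <- "double"
  new_model_rdm(m, "rotation_tolerant", "rotation_tolerant_model", conds)
}

#' Model RDM from condition feature vectors
#'
#' Dissimilarity between two conditions is the cosine distance
#' `1 - cos(f_i, f_j)` between their feature rows.
#'
#' @param features C x d numeric matrix, one row per condition; no row may
#'   be all zeros.
#' @param name Model name stored on the result.
#' @return A `model_rdm` matrix (C x C, zero diagonal).
#' @export
feature_model_rdm <- function(features, name = "feature_model") {
  features <- as.matrix(features)
  nrm <- sqrt(rowSums(features^2))
  if (any(nrm == 0)) {
    stop_rd(sprintf("zero-norm feature rows: %s",
                    paste(which(nrm == 0), collapse = ", ")))
  }
  u <- features / nrm
  m <- 1 - tcrossprod(u)
  m[m < 0] <- 0           # clamp numerical negatives from collinear rows
  diag(m) <- 0
  m <- (m + t(m)) / 2
  new_model_rdm(m, name, "feature_model",
                attr(features, "condition_labels"))
}

#' Synthetic low-level visual control features
#'
#' A deterministic stand-in for early convolutional-network layers used as
#' low-level control models: each object is a small synthetic image (a
#' seeded mixture of Gaussian blobs), each rotation condition is that image
#' rotated in the plane, and the three pseudo-layers apply increasing
#' receptive-field pooling (1 x 1, 2 x 2, 4 x 4 average pooling of the
#' rectified image). Features are therefore strongly rotation-sensitive,
#' like genuine low-level visual models, with sensitivity decreasing over
#' layers.
#'
#' @param labels Condition label tibble (`object_id`, `rotation_deg`).
#' @param kind Feature family; only `"pixel_gabor"` is implemented.
#' @param layer Pseudo-layer, 1 (finest) to 3 (coarsest pooling).
#' @param seed Seed making features reproducible per condition.
#' @param img_size Side length of the synthetic image (default 16).
#' @return A C x d feature matrix with the condition labels attached as the
#'   `condition_labels` attribute; rows sorted by (object, rotation).
#' @export
standin_features <- function(labels, kind = "pixel_gabor", layer = 1L,
                             seed = 1L, img_size = 16L) {
  if (!identical(kind, "pixel_gabor")) {
    stop_rd(sprintf("unknown feature kind '%s'", kind))
  }
  if (!layer %in% 1:3) stop_rd("layer must be 1, 2 or 3")
  conds <- dplyr::distinct(labels, .data$object_id, .data$rotation_deg) |>
    dplyr::arrange(.data$object_id, .data$rotation_deg)
  gx <- seq(-1, 1, length.out = img_size)
  grid <- expand.grid(x = gx, y = gx)
  n_blobs <- 5L
  render <- function(object_id, rotation_deg) {
    blobs <- withr::with_seed(seed + 7919L * object_id, list(
      cx = runif(n_blobs, -0.55, 0.55), cy = runif(n_blobs, -0.55, 0.55),
      amp = rnorm(n_blobs), sd = runif(n_blobs, 0.08, 0.25)
    ))
    th <- rotation_deg * pi / 180
    cx <- cos(th) * blobs$cx - sin(th) * blobs$cy
    cy <- sin(th) * blobs$cx + cos(th) * blobs$cy
    img <- numeric(nrow(grid))
    for (b in seq_len(n_blobs)) {
      img <- img + blobs$amp[b] *
        exp(-((grid$x - cx[b])^2 + (grid$y - cy[b])^2) / (2 * blobs$sd[b]^2))
    }
    abs(img)
  }
  pool <- function(img, k) {
    if (k == 1L) return(img)
    m <- matrix(img, img_size, img_size)
    blocks <- (seq_len(img_size) - 1L) %/% k
    as.vector(t(rowsum(t(rowsum(m, blocks)), blocks)) / k^2)
  }
  k <- c(1L, 2L, 4L)[layer]
  feats <- t(vapply(seq_len(nrow(conds)),
                    function(i) pool(render(conds$object_id[i],
                                            conds$rotation_deg[i]), k),
                    numeric((img_size %/% k)^2)))
  attr(feats, "condition_labels") <- conds
  feats
}

lower_tri_vec <- function(m) m[lower.tri(m)]

#' Partial correlation between two RDMs given control RDMs
#'
#' Vectorizes the strict lower triangles, optionally rank-transforms them
#' (Spearman-style, the default), residualizes the neural and model vectors
#' on the controls plus an intercept, and returns the Pearson correlation of
#' the residuals. With no controls this is a plain (rank) correlation.
#'
#' @param neural A square dissimilarity matrix.
#' @param model A `model_rdm` (or square matrix).
#' @param controls List of control `model_rdm`s to partial out.
#' @param method `"spearman"` (rank-based, default) or `"pearson"`.
#' @return The partial correlation coefficient; `NA` with a warning when a
#'   vector is constant after ranking.
#' @export
rdm_partial_cor <- function(neural, model, controls = list(),
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  dims <- vapply(c(list(neural, model), controls), nrow, integer(1))
  if (length(unique(dims)) != 1L) stop_rd("all RDMs must share condition set and order")
  v <- lower_tri_vec(as.matrix(neural))
  x <- lower_tri_vec(as.matrix(model))
  z <- vapply(controls, function(m) lower_tri_vec(as.matrix(m)),
              numeric(length(v)))
  if (method == "spearman") {
    v <- rank(v); x <- rank(x)
    if (length(controls) > 0) z <- apply(z, 2, rank)
  }
  if (sd(v) == 0 || sd(x) == 0) {
    warn("constant dissimilarity vector; partial correlation undefined")
    return(NA_real_)
  }
  if (length(controls) > 0) {
    q <- qr(cbind(1, z))
    v <- qr.resid(q, v)
    x <- qr.resid(q, x)
    if (sd(v) == 0 || sd(x) == 0) {
      warn("dissimilarities fully explained by controls; partial correlation undefined")
      return(NA_real_)
    }
  }
  cor(v, x)
}

#' Partial-correlation RSA time-course
#'
#' Correlates the neural RDM at every time-point with a model RDM while
#' partialling out control models (see [rdm_partial_cor()]).
#'
#' @param neural An `rdm_stack` from [neural_rdm()].
#' @inheritParams rdm_partial_cor
#' @return A `partial_corr_timecourse` tibble (`time_ms`, `r_partial`) with
#'   attributes `model`, `controls`, `method`.
#' @export
partial_corr_timecourse <- function(neural, model, controls = list(),
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ml <- attr(model, "condition_labels")
  if (!is.null(ml) && !isTRUE(all.equal(as.data.frame(ml),
                                        as.data.frame(neural$condition_labels)))) {
    stop_rd("model RDM condition labels do not match the neural RDM")
  }
  r <- vapply(seq_along(neural$times_ms), function(t) {
    rdm_partial_cor(neural$rdm[t, , ], model, controls, method)
  }, numeric(1))
  out <- tibble(time_ms = neural$times_ms, r_partial = r)
  attr(out, "model") <- attr(model, "name") %||% "model"
  attr(out, "controls") <- vapply(controls, function(m) {
    attr(m, "name") %||% "control"
  }, character(1))
  attr(out, "method") <- method
  attr(out, "subject_id") <- neural$subject_id
  class(out) <- c("partial_corr_timecourse", class(out))
  out
}

#' Read or write a model RDM as a labelled tab-separated matrix
#'
#' @param m A `model_rdm`.
#' @param path File path.
#' @return `read_model_rdm_tsv()` returns the `model_rdm`;
#'   `write_model_rdm_tsv()` invisibly returns `path`.
#' @export
write_model_rdm_tsv <- function(m, path) {
  labels <- attr(m, "condition_labels")
  lab <- if (is.null(labels)) {
    as.character(seq_len(nrow(m)))
  } else {
    sprintf("obj%s_rot%s", labels$object_id, labels$rotation_deg)
  }
  df <- as.data.frame(unclass(m))
  names(df) <- lab
  readr::write_tsv(dplyr::bind_cols(tibble(condition = lab), df), path)
  invisible(path)
}

#' @rdname write_model_rdm_tsv
#' @export
read_model_rdm_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$condition
  parsed <- regmatches(df$condition,
                       regexec("^obj(\\d+)_rot([0-9.]+)$", df$condition))
  labels <- NULL
  if (all(lengths(parsed) == 3L)) {
    labels <- tibble(object_id = as.integer(vapply(parsed, `[`, "", 2)),
                     rotation_deg = as.numeric(vapply(parsed, `[`, "", 3)))
  }
  new_model_rdm(m, name = sub("\\.tsv$", "", basename(path)),
                source = "file", labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
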