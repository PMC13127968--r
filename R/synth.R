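#' Define a signal component for the epoch simulator
#'
#' A component injects a transient multivariate pattern with a Gaussian
#' temporal envelope into every epoch. Three kinds of pattern structure are
#' supported, matching the representational stages the analysis is designed
#' to dissect:
#'
#' * `rotation_specific`: a distinct channel pattern for every
#'   (object, rotation) image — low-level, orientation-bound information.
#' * `rotation_tolerant`: one pattern per object, identical across all its
#'   rotations — abstract object identity that generalizes over rotation.
#' * `category_level`: one pattern per object category (objects are grouped
#'   into consecutive blocks of `exemplars_per_category`).
#'
#' @param name One of `"rotation_specific"`, `"rotation_tolerant"`,
#'   `"category_level"`.
#' @param peak_latency_ms Time of the envelope peak, ms after stimulus onset.
#' @param width_ms Temporal Gaussian SD of the envelope, ms.
#' @param amplitude Peak pattern norm in units of the per-channel noise SD.
#' @param rate_attenuation Multiplier applied to the amplitude in the fast
#'   (20 Hz) condition, in `[0, 1]`.
#' @param envelope `"gaussian"` (transient bump, SD `width_ms`) or
#'   `"boxcar"` (sustained plateau over `peak_latency_ms +- width_ms`).
#' @return A `signal_component` list.
#' @export
signal_component <- function(name, peak_latency_ms, width_ms = 30,
                             amplitude = 1, rate_attenuation = 0.5,
                             envelope = c("gaussian", "boxcar")) {
  kinds <- c("rotation_specific", "rotation_tolerant", "category_level")
  if (!name %in% kinds) {
    stop_rd(sprintf("unknown signal component '%s' (expected one of %s)",
                    name, paste(kinds, collapse = ", ")))
  }
  if (width_ms <= 0) stop_rd("width_ms must be positive")
  if (amplitude < 0) stop_rd("amplitude must be non-negative")
  if (rate_attenuation < 0 || rate_attenuation > 1) {
    stop_rd("rate_attenuation must lie in [0, 1]")
  }
  envelope <- match.arg(envelope)
  structure(list(name = name, peak_latency_ms = peak_latency_ms,
                 width_ms = width_ms, amplitude = amplitude,
                 rate_attenuation = rate_attenuation, envelope = envelope),
            class = "signal_component")
}

#' Default two-stage signal structure
#'
#' An early rotation-specific component peaking at 116 ms and a later
#' rotation-tolerant component peaking at 192 ms, both attenuated to half
#' amplitude in the fast presentation condition.
#'
#' @param amp_specific,amp_tolerant Component amplitudes.
#' @return A list of two [signal_component()]s.
#' @export
default_components <- function(amp_specific = 2.5, amp_tolerant = 2.5) {
  list(
    signal_component("rotation_specific", peak_latency_ms = 116,
                     amplitude = amp_specific),
    signal_component("rotation_tolerant", peak_latency_ms = 192,
                     amplitude = amp_tolerant)
  )
}

#' Configure the synthetic epoch generator
#'
#' @param n_subjects Number of subjects in a cohort (default 16).
#' @param n_channels Number of EEG channels (default 32, minimum 5 so the
#'   channel searchlight has 4 neighbours).
#' @param sfreq_hz Sampling rate of the epochs, Hz (default 250).
#' @param epoch_window_ms Two-element epoch window around stimulus onset
#'   (default `c(-100, 800)`; must span 0).
#' @param components List of [signal_component()]s.
#' @param noise_sd Per-channel noise standard deviation.
#' @param channel_corr Common spatial correlation of the noise across
#'   channels, in `[0, 1)`.
#' @param ar_coef Lag-1 autoregressive coefficient of the noise in time.
#' @param subject_sd Between-subject SD of the multiplicative component
#'   gain (gain ~ Normal(1, subject_sd), floored at 0).
#' @param exemplars_per_category Objects per category for the
#'   `category_level` component (default 5, i.e. 12 categories of 5 with
#'   60 objects).
#' @param seed Integer seed; together with the subject index it fully
#'   determines a subject's data.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 16, n_channels = 32, sfreq_hz = 250,
                         epoch_window_ms = c(-100, 800),
                         components = default_components(),
                         noise_sd = 1, channel_corr = 0.3, ar_coef = 0.7,
                         subject_sd = 0.2, exemplars_per_category = 5,
                         seed = 1L) {
  if (n_channels < 5) stop_rd("n_channels must be >= 5 (searchlight needs 4 neighbours)")
  if (epoch_window_ms[1] > 0 || epoch_window_ms[2] < 0) {
    stop_rd("epoch_window_ms must span stimulus onset at 0 ms")
  }
  if (channel_corr < 0 || channel_corr >= 1) stop_rd("channel_corr must lie in [0, 1)")
  if (abs(ar_coef) >= 1) stop_rd("ar_coef must lie in (-1, 1)")
  for (cmp in components) {
    if (!inherits(cmp, "signal_component")) {
      stop_rd("components must be a list of signal_component objects")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    sfreq_hz = sfreq_hz, epoch_window_ms = as.numeric(epoch_window_ms),
    components = components, noise_sd = noise_sd,
    channel_corr = channel_corr, ar_coef = ar_coef, subject_sd = subject_sd,
    exemplars_per_category = as.integer(exemplars_per_category),
    seed = as.integer(seed)
  ), class = "synth_config")
}

# deterministic quasi-uniform electrode positions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

epoch_times_ms <- function(cfg) {
  step <- 1000 / cfg$sfreq_hz
  seq(ceiling(cfg$epoch_window_ms[1] / step) * step, cfg$epoch_window_ms[2],
      by = step)
}

# per-trial repetition index: occurrence order of each (object, rotation,
# rate) cell over the session
add_repetition_index <- function(design) {
  design |>
    dplyr::arrange(.data$sequence_index, .data$position_in_sequence) |>
    dplyr::group_by(.data$object_id, .data$rotation_deg, .data$rate_hz) |>
    dplyr::mutate(repetition_index = dplyr::row_number()) |>
    dplyr::ungroup()
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Simulate one subject's epoched EEG
#'
#' Every presentation in `design` becomes one epoch. Each signal component
#' contributes `envelope(t) * amplitude * subject_gain * rate_gain * pattern`
#' where the envelope is a Gaussian bump truncated to post-stimulus time
#' (pre-stimulus samples carry noise only) and the pattern is a fixed
#' unit-norm channel vector determined by the trial's labels (see
#' [signal_component()]). Noise is zero-mean Gaussian with compound-symmetric
#' spatial correlation `channel_corr` and AR(1) temporal correlation
#' `ar_coef`, unit marginal variance scaled by `noise_sd`. The fast-rate
#' attenuation applies to every rate above the slowest in the design.
#'
#' @param design A design table from [generate_design()].
#' @param cfg A [synth_config()].
#' @param subject_index 1-based subject number; `(cfg$seed, subject_index)`
#'   fully determines the output.
#' @return An `epoch_set`: list with `data` (trials x channels x time
#'   array), `labels` (tibble: `object_id`, `rotation_deg`, `rate_hz`,
#'   `repetition_index`), `times_ms`, `channel_coords`, `subject_id`.
#' @export
generate_subject <- function(design, cfg, subject_index = 1L) {
  force(design)
  if (subject_index < 1L || subject_index > cfg$n_subjects) {
    stop_rd(sprintf("subject_index %d outside 1..n_subjects (%d)",
                    subject_index, cfg$n_subjects))
  }
  labels <- add_repetition_index(design) |>
    dplyr::select("object_id", "rotation_deg", "rate_hz", "repetition_index")
  subject_seed <- (cfg$seed + 104729L * as.integer(subject_index)) %%
    .Machine$integer.max
  withr::with_seed(subject_seed, build_subject(labels, cfg, subject_index))
}

build_subject <- function(labels, cfg, subject_index) {

  times <- epoch_times_ms(cfg)
  n_trials <- nrow(labels)
  n_ch <- cfg$n_channels
  n_t <- length(times)

  objects <- sort(unique(labels$object_id))
  angles <- sort(unique(labels$rotation_deg))
  slow_rate <- min(labels$rate_hz)

  # correlated noise: AR(1) along time, compound-symmetric across channels
  data <- array(rnorm(n_trials * n_ch * n_t), dim = c(n_trials, n_ch, n_t))
  if (cfg$ar_coef != 0) {
    innov_sd <- sqrt(1 - cfg$ar_coef^2)
    for (t in 2:n_t) {
      data[, , t] <- cfg$ar_coef * data[, , t - 1L] + innov_sd * data[, , t]
    }
  }
  if (cfg$channel_corr > 0) {
    cmat <- matrix(cfg$channel_corr, n_ch, n_ch)
    diag(cmat) <- 1
    lt <- t(chol(cmat))
    for (t in seq_len(n_t)) data[, , t] <- data[, , t] %*% t(lt)
  }
  if (cfg$noise_sd != 1) data <- data * cfg$noise_sd

  for (cmp in cfg$components) {
    gain <- max(0, rnorm(1, mean = 1, sd = cfg$subject_sd))
    # unit-norm patterns per label cell
    pat <- switch(cmp$name,
      rotation_specific = {
        p <- unit_rows(matrix(rnorm(length(objects) * length(angles) * n_ch),
                              ncol = n_ch))
        idx <- match(labels$object_id, objects) +
          (match(labels$rotation_deg, angles) - 1L) * length(objects)
        p[idx, , drop = FALSE]
      },
      rotation_tolerant = {
        p <- unit_rows(matrix(rnorm(length(objects) * n_ch), ncol = n_ch))
        p[match(labels$object_id, objects), , drop = FALSE]
      },
      category_level = {
        cat_of <- (match(labels$object_id, objects) - 1L) %/%
          cfg$exemplars_per_category + 1L
        n_cat <- max(cat_of)
        p <- unit_rows(matrix(rnorm(n_cat * n_ch), ncol = n_ch))
        p[cat_of, , drop = FALSE]
      }
    )
    env <- if (cmp$envelope == "boxcar") {
      as.numeric(abs(times - cmp$peak_latency_ms) <= cmp$width_ms)
    } else {
      exp(-(times - cmp$peak_latency_ms)^2 / (2 * cmp$width_ms^2))
    }
    env[times < 0] <- 0
    rate_gain <- ifelse(labels$rate_hz > slow_rate, cmp$rate_attenuation, 1)
    scaled <- pat * (cmp$amplitude * gain * rate_gain)
    for (t in which(env > 1e-12)) data[, , t] <- data[, , t] + scaled * env[t]
  }

  structure(list(
    data = data, labels = labels, times_ms = times,
    channel_coords = fibonacci_sphere(n_ch),
    subject_id = sprintf("S%02d", subject_index)
  ), class = "epoch_set")
}

#' Simulate a cohort of subjects
#'
#' @inheritParams generate_subject
#' @return A list of [generate_subject()] `epoch_set`s, one per subject.
#' @export
generate_cohort <- function(design, cfg) {
  if (cfg$n_subjects < 2L) stop_rd("a cohort needs n_subjects >= 2")
  lapply(seq_len(cfg$n_subjects), function(i) generate_subject(design, cfg, i))
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set %s: %d trials x %d channels x %d time-points (%g..%g ms)>\n",
    x$subject_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Restrict an epoch set to a subset of trials
#'
#' @param ep An `epoch_set`.
#' @param rate_hz Optional single rate to keep.
#' @param trials Optional logical or integer trial index.
#' @return The filtered `epoch_set`.
#' @export
filter_epochs <- function(ep, rate_hz = NULL, trials = NULL) {
  keep <- rep(TRUE, nrow(ep$labels))
  if (!is.null(rate_hz)) keep <- keep & ep$labels$rate_hz == rate_hz
  if (!is.null(trials)) {
    sel <- rep(FALSE, nrow(ep$labels))
    sel[trials] <- TRUE
    keep <- keep & sel
  }
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$labels <- ep$labels[keep, ]
  ep
}

#' Save or load an epoch set
#'
#' The container is a single hierarchical file holding the data tensor,
#' label table, time axis and channel coordinates (R native serialization).
#'
#' @param ep An `epoch_set`.
#' @param path File path.
#' @return `read_epochs()` returns the `epoch_set`; `write_epochs()`
#'   invisibly returns `path`.
#' @export
write_epochs <- function(ep, path) {
  saveRDS(ep, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  ep <- readRDS(path)
  if (!inherits(ep, "epoch_set")) stop_rd("file does not contain an epoch_set")
  ep
}
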