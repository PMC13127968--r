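# Shared desk-scale fixtures, built lazily and cached for the session.
# The scaled study profile (12 objects x 4 rotations x 7 repetitions)
# preserves the matched-training-budget arithmetic of the full design:
# (n_reps - 1) = 6 trains per object split as 2 repetitions over each of
# the 3 non-test rotations.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

scaled_design_config <- function(rates = 5, seed = 101L) {
  design_config(n_objects = 12, n_rotations = 4, n_reps = 7, rates = rates,
                seq_length = 24, targets_per_seq = c(1L, 2L),
                min_target_gap = 3L, edge_exclusion = 2L, seed = seed)
}

scaled_design <- function(rates = 5, seed = 101L) {
  key <- sprintf("design_%s_%d", paste(rates, collapse = "_"), seed)
  cached(key, generate_design(scaled_design_config(rates, seed)))
}

# one scaled subject with configurable signal components
scaled_subject <- function(components, seed = 201L, rates = 5,
                           n_channels = 16, window = c(-100, 400)) {
  cfg <- synth_config(n_subjects = 1, n_channels = n_channels,
                      epoch_window_ms = window, components = components,
                      seed = seed)
  generate_subject(scaled_design(rates = rates), cfg, 1)
}

# minimal label table for scheme tests (no data needed)
tiny_labels <- function(n_objects = 3, n_rotations = 2, n_reps = 3) {
  tidyr::expand_grid(object_id = seq_len(n_objects),
                     rotation_deg = (seq_len(n_rotations) - 1) * 180,
                     repetition_index = seq_len(n_reps)) |>
    dplyr::mutate(rate_hz = 5)
}

# hand-built epoch_set: deterministic signal patterns plus seeded noise,
# for tests that need full control over what each condition contains
manual_epochs <- function(labels, pattern_fun, noise_sd = 1, n_channels = 6,
                          times_ms = seq(-20, 40, by = 4), seed = 1L) {
  withr::with_seed(seed, {
    n <- nrow(labels)
    data <- array(rnorm(n * n_channels * length(times_ms), sd = noise_sd),
                  dim = c(n, n_channels, length(times_ms)))
    for (i in seq_len(n)) {
      pat <- pattern_fun(labels$object_id[i], labels$rotation_deg[i])
      for (t in which(times_ms >= 0)) data[i, , t] <- data[i, , t] + pat
    }
    structure(list(data = data, labels = labels, times_ms = times_ms,
                   channel_coords = rotadecode:::fibonacci_sphere(n_channels),
                   subject_id = "manual"),
              class = "epoch_set")
  })
}

# two-sided binomial acceptance band for an accuracy estimate
binom_band <- function(p, n_trials, level = 0.99) {
  a <- (1 - level) / 2
  c(qbinom(a, n_trials, p), qbinom(1 - a, n_trials, p)) / n_trials
}
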