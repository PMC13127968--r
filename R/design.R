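#' Configure a rapid serial visual presentation design
#'
#' Describes the stimulus schedule of the experiment: objects shown in
#' several in-plane rotations, embedded in fixed-length sequences presented
#' at one of two rates, with occasional fixation-target events.
#'
#' Each sequence holds `seq_length = 2 * n_objects` presentations, every
#' object appearing exactly twice in two different rotations. A *block* of
#' `n_rotations / 2` consecutive sequences at a single rate covers the full
#' object-by-rotation grid exactly once, so `n_reps` blocks per rate yield
#' `n_reps` presentations of every (object, rotation, rate) cell.
#'
#' @param n_objects Number of distinct objects (default 60).
#' @param n_rotations Number of in-plane rotations, evenly spaced over 360
#'   degrees (default 8, i.e. 0-315 in 45-degree steps). Must be even.
#' @param n_reps Presentations per object, rotation and rate (default 15).
#' @param rates Presentation rates in Hz (default `c(5, 20)`).
#' @param stim_duration_ms Stimulus duration in ms (default 33).
#' @param seq_length Presentations per sequence; must equal `2 * n_objects`.
#' @param targets_per_seq Inclusive range for the number of fixation-target
#'   events per sequence (default `c(2, 4)`).
#' @param min_target_gap Minimum spacing between targets, in presentations.
#' @param edge_exclusion Number of presentations at the start and end of a
#'   sequence that can never be targets.
#' @param seed Integer seed making the generated schedule reproducible.
#' @return A `design_config` list.
#' @export
design_config <- function(n_objects = 60, n_rotations = 8, n_reps = 15,
                          rates = c(5, 20), stim_duration_ms = 33,
                          seq_length = 2 * n_objects,
                          targets_per_seq = c(2L, 4L),
                          min_target_gap = 10L, edge_exclusion = 10L,
                          seed = 1L) {
  cfg <- list(
    n_objects = as.integer(n_objects), n_rotations = as.integer(n_rotations),
    n_reps = as.integer(n_reps), rates = as.numeric(rates),
    stim_duration_ms = as.numeric(stim_duration_ms),
    seq_length = as.integer(seq_length),
    targets_per_seq = as.integer(targets_per_seq),
    min_target_gap = as.integer(min_target_gap),
    edge_exclusion = as.integer(edge_exclusion), seed = as.integer(seed)
  )
  class(cfg) <- "design_config"
  check_design_config(cfg)
  cfg
}

check_design_config <- function(cfg) {
  if (cfg$seq_length != 2L * cfg$n_objects) {
    stop_rd(sprintf(
      "constraint `seq_length = 2 * n_objects` violated: seq_length = %d, n_objects = %d",
      cfg$seq_length, cfg$n_objects
    ), class = "rotadecode_error_constraint")
  }
  if (cfg$n_rotations < 2L || cfg$n_rotations %% 2L != 0L) {
    stop_rd("constraint `n_rotations even and >= 2` violated (each sequence pairs two distinct rotations per object)",
            class = "rotadecode_error_constraint")
  }
  if (any(duplicated(cfg$rates)) || any(cfg$rates <= 0)) {
    stop_rd("rates must be distinct and positive", class = "rotadecode_error_constraint")
  }
  for (r in cfg$rates) stimulus_timing(r, cfg$stim_duration_ms)
  # target placement feasibility for the maximum target count
  span <- cfg$seq_length - 2L * cfg$edge_exclusion
  need <- (max(cfg$targets_per_seq) - 1L) * cfg$min_target_gap + 1L
  if (cfg$targets_per_seq[1] > cfg$targets_per_seq[2] || cfg$targets_per_seq[1] < 0L) {
    stop_rd("constraint `targets_per_seq` must be a non-negative inclusive range",
            class = "rotadecode_error_constraint")
  }
  if (span < need) {
    stop_rd(sprintf(
      "constraint `min_target_gap` infeasible: %d targets with gap %d need %d positions but only %d remain after edge exclusion",
      max(cfg$targets_per_seq), cfg$min_target_gap, need, span
    ), class = "rotadecode_error_constraint")
  }
  invisible(cfg)
}

rotation_angles <- function(n_rotations) (seq_len(n_rotations) - 1) * (360 / n_rotations)

# sample() treats a scalar as 1:x; shuffle must not
shuffle <- function(x) if (length(x) <= 1L) x else sample(x)

#' Stimulus-onset asynchrony and inter-stimulus interval for a rate
#'
#' @param rate_hz Presentation rate in Hz.
#' @param stim_duration_ms Stimulus duration in ms.
#' @return A named list with `soa_ms` (onset-to-onset) and `isi_ms`
#'   (offset-to-onset), both integer milliseconds.
#' @examples
#' stimulus_timing(5, 33)   # SOA 200 ms, ISI 167 ms
#' stimulus_timing(20, 33)  # SOA 50 ms, ISI 17 ms
#' @export
stimulus_timing <- function(rate_hz, stim_duration_ms) {
  if (rate_hz <= 0) stop_rd("rate_hz must be positive")
  soa <- round(1000 / rate_hz)
  if (stim_duration_ms >= soa) {
    stop_rd(sprintf("stimulus duration %s ms does not fit in the %s ms SOA at %s Hz",
                    stim_duration_ms, soa, rate_hz))
  }
  list(soa_ms = soa, isi_ms = soa - stim_duration_ms)
}

# Place k targets in 1..L honouring edge exclusion and minimum gap.
# Sampling k gap-respecting positions uniformly via the standard
# "subtract the forced gaps, sample, add them back" bijection.
place_targets <- function(k, seq_length, edge_exclusion, min_target_gap) {
  if (k == 0L) return(integer(0))
  lo <- edge_exclusion + 1L
  hi <- seq_length - edge_exclusion
  m <- hi - lo + 1L - (k - 1L) * min_target_gap
  if (m < k) {
    stop_rd(sprintf(
      "constraint `min_target_gap` infeasible: cannot place %d targets with gap %d in positions %d..%d",
      k, min_target_gap, lo, hi
    ), class = "rotadecode_error_constraint")
  }
  base <- sort(sample.int(m, k))
  lo - 1L + base + (seq_len(k) - 1L) * min_target_gap
}

#' Generate a full presentation schedule
#'
#' Builds the complete table of stimulus presentations under the design's
#' counterbalancing constraints: per sequence each object appears twice in
#' two different rotations with all (object, rotation) pairs unique, each
#' block of `n_rotations / 2` consecutive same-rate sequences covers the
#' grid exactly once, rate blocks are interleaved pseudo-randomly with both
#' rates equally represented, and fixation targets respect spacing and edge
#' constraints. Targets replace the fixation bullseye only; the presentation
#' keeps its object and rotation labels.
#'
#' @param cfg A [design_config()].
#' @return A tibble with one row per presentation and columns
#'   `sequence_index`, `position_in_sequence`, `object_id`, `rotation_deg`,
#'   `rate_hz`, `is_target`, `onset_ms`. With the defaults this is 14,400
#'   rows in 120 sequences of 120.
#' @export
generate_design <- function(cfg = design_config()) {
  check_design_config(cfg)
  withr::with_seed(cfg$seed, build_design(cfg))
}

build_design <- function(cfg) {
  angles <- rotation_angles(cfg$n_rotations)
  seqs_per_block <- cfg$n_rotations %/% 2L
  n_blocks_per_rate <- cfg$n_reps

  # pseudo-random block order, both rates equally represented
  block_rates <- shuffle(rep(cfg$rates, each = n_blocks_per_rate))

  seq_tables <- vector("list", length(block_rates) * seqs_per_block)
  seq_no <- 0L
  for (b in seq_along(block_rates)) {
    rate <- block_rates[b]
    soa <- stimulus_timing(rate, cfg$stim_duration_ms)$soa_ms
    # per object, shuffle its rotations and split into disjoint pairs:
    # pair j goes to sequence j of the block, guaranteeing "twice per
    # sequence, two different rotations" and exact grid coverage per block
    pair_assign <- vapply(seq_len(cfg$n_objects),
                          function(o) shuffle(angles),
                          numeric(cfg$n_rotations))
    for (s in seq_len(seqs_per_block)) {
      seq_no <- seq_no + 1L
      rot <- as.vector(pair_assign[c(2L * s - 1L, 2L * s), ])
      obj <- rep(seq_len(cfg$n_objects), each = 2L)
      ord <- sample.int(cfg$seq_length)
      n_targ <- cfg$targets_per_seq[1] +
        sample.int(cfg$targets_per_seq[2] - cfg$targets_per_seq[1] + 1L, 1L) - 1L
      targ_pos <- place_targets(n_targ, cfg$seq_length,
                                cfg$edge_exclusion, cfg$min_target_gap)
      seq_tables[[seq_no]] <- tibble(
        sequence_index = seq_no,
        position_in_sequence = seq_len(cfg$seq_length),
        object_id = obj[ord],
        rotation_deg = rot[ord],
        rate_hz = rate,
        is_target = seq_len(cfg$seq_length) %in% targ_pos,
        onset_ms = (seq_len(cfg$seq_length) - 1L) * soa
      )
    }
  }
  out <- dplyr::bind_rows(seq_tables)
  class(out) <- c("design_table", class(out))
  out
}

#' Check a presentation schedule against its design constraints
#'
#' Never raises on content: every violated constraint becomes a row of the
#' returned report, naming the constraint and locating it.
#'
#' @param tbl A design table as produced by [generate_design()].
#' @param cfg The [design_config()] the table should satisfy.
#' @return A tibble with columns `constraint`, `sequence_index`, `detail`;
#'   zero rows when the table satisfies every invariant.
#' @export
validate_design <- function(tbl, cfg) {
  bad <- list()
  note <- function(constraint, sequence_index, detail) {
    bad[[length(bad) + 1L]] <<- tibble(constraint = constraint,
                                       sequence_index = as.integer(sequence_index),
                                       detail = detail)
  }
  seqs_per_block <- cfg$n_rotations %/% 2L

  split_seq <- split(tbl, tbl$sequence_index)
  for (s in split_seq) {
    sid <- s$sequence_index[1]
    cnt <- table(s$object_id)
    if (length(cnt) != cfg$n_objects || any(cnt != 2L)) {
      note("object_twice_per_sequence", sid,
           "some object does not appear exactly twice")
    }
    two_rot <- tapply(s$rotation_deg, s$object_id, function(r) length(unique(r)))
    if (any(two_rot != 2L)) {
      note("two_different_rotations", sid, sprintf(
        "objects in one rotation twice: %s",
        paste(names(two_rot)[two_rot != 2L], collapse = ", ")))
    }
    if (anyDuplicated(s[c("object_id", "rotation_deg")])) {
      note("object_rotation_unique", sid, "duplicated (object, rotation) pair")
    }
    if (length(unique(s$rate_hz)) != 1L) {
      note("single_rate_per_sequence", sid, "mixed rates within a sequence")
    }
    tpos <- sort(s$position_in_sequence[s$is_target])
    if (length(tpos) < cfg$targets_per_seq[1] || length(tpos) > cfg$targets_per_seq[2]) {
      note("targets_per_seq", sid, sprintf("%d targets outside [%d, %d]",
           length(tpos), cfg$targets_per_seq[1], cfg$targets_per_seq[2]))
    }
    if (length(tpos) >= 2L && any(diff(tpos) < cfg$min_target_gap)) {
      note("min_target_gap", sid, sprintf("target positions %s closer than %d",
           paste(tpos, collapse = ","), cfg$min_target_gap))
    }
    if (any(tpos <= cfg$edge_exclusion | tpos > cfg$seq_length - cfg$edge_exclusion)) {
      note("edge_exclusion", sid, "target within excluded edge positions")
    }
    soa <- stimulus_timing(s$rate_hz[1], cfg$stim_duration_ms)$soa_ms
    expected <- (s$position_in_sequence - 1L) * soa
    if (any(s$onset_ms != expected)) {
      note("onset_spacing", sid, sprintf("onsets not on the %d ms grid", soa))
    }
  }

  # block structure: runs of constant rate split into blocks of
  # seqs_per_block sequences, each covering the object x rotation grid once
  seq_rate <- vapply(split_seq, function(s) s$rate_hz[1], numeric(1))
  runs <- rle(seq_rate)
  if (any(runs$lengths %% seqs_per_block != 0L)) {
    note("block_structure", NA_integer_,
         sprintf("same-rate runs not a multiple of %d sequences", seqs_per_block))
  } else {
    sids <- as.integer(names(seq_rate))
    offset <- 0L
    for (r in seq_along(runs$lengths)) {
      run_ids <- sids[(offset + 1L):(offset + runs$lengths[r])]
      offset <- offset + runs$lengths[r]
      for (chunk in split(run_ids, (seq_along(run_ids) - 1L) %/% seqs_per_block)) {
        blk <- tbl[tbl$sequence_index %in% chunk, ]
        cells <- table(blk$object_id, blk$rotation_deg)
        if (!all(dim(cells) == c(cfg$n_objects, cfg$n_rotations)) || any(cells != 1L)) {
          note("block_covers_grid_once", chunk[1], sprintf(
            "block of sequences %s does not cover every (object, rotation) exactly once",
            paste(chunk, collapse = ",")))
        }
      }
    }
  }

  counts <- dplyr::count(tbl, .data$object_id, .data$rotation_deg, .data$rate_hz)
  n_cells <- cfg$n_objects * cfg$n_rotations * length(cfg$rates)
  if (nrow(counts) != n_cells || any(counts$n != cfg$n_reps)) {
    note("reps_per_cell", NA_integer_, sprintf(
      "per-(object, rotation, rate) count must be exactly %d", cfg$n_reps))
  }

  if (length(bad) == 0L) {
    tibble(constraint = character(), sequence_index = integer(), detail = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Read or write a design table as a tab-separated file
#'
#' @param tbl A design table.
#' @param path File path.
#' @return `read_design_tsv()` returns the design tibble;
#'   `write_design_tsv()` invisibly returns `path`.
#' @export
write_design_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sequence_index = readr::col_integer(),
                           position_in_sequence = readr::col_integer(),
                           object_id = readr::col_integer(),
                           rotation_deg = readr::col_double(),
                           rate_hz = readr::col_double(),
                           is_target = readr::col_logical(),
                           onset_ms = readr::col_double()
                         ))
  class(out) <- c("design_table", class(out))
  out
}
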