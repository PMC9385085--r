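# Experimental design constants and stimulus scheduling for the 4-choice
# vibrotactile oddball paradigm.

#' Tactor positions of the 4-choice paradigm
#'
#' Fixed position order used throughout the package, including for
#' deterministic tie-breaking during classification.
#'
#' @export
tactor_positions <- c("front", "back", "left", "right")

#' Paradigm configuration
#'
#' Bundles the design constants of the vibrotactile 4-choice P300 paradigm:
#' stimulus timing, number of stimulation sequences per selection, EEG
#' montage and run structure. Defaults encode the standard study design
#' (220 ms stimuli at 250 Hz, 400 ms offset-to-onset inter-stimulus gap,
#' eight sequences per selection, 512 Hz sampling over 12 electrodes,
#' three calibration runs of ten selections, three copy runs of eight
#' commands).
#'
#' @param n_positions Number of stimulus positions (alternatives). The
#'   paradigm is built around 4 (front, back, left, right).
#' @param n_sequences Stimulation sequences per selection; in each sequence
#'   every position is activated once.
#' @param stim_duration Vibration duration in ms.
#' @param isi_gap Offset-to-onset inter-stimulus gap in ms, so the
#'   stimulus-onset asynchrony is `stim_duration + isi_gap`.
#' @param vibration_freq Tactor carrier frequency in Hz (metadata only).
#' @param sampling_rate EEG sampling rate in Hz.
#' @param channels Ordered electrode labels.
#' @param calib_runs,calib_selections_per_run Calibration run structure.
#' @param copy_runs,commands_per_copy_run Copy task run structure.
#'
#' @return An object of class `paradigm_config` (a list).
#' @examples
#' cfg <- paradigm_config()
#' count_calibration_trials(cfg)
#' selections_per_minute(cfg)
#' @export
paradigm_config <- function(n_positions = 4L,
                            n_sequences = 8L,
                            stim_duration = 220,
                            isi_gap = 400,
                            vibration_freq = 250,
                            sampling_rate = 512,
                            channels = c("Fz", "FC1", "FC2", "C3", "Cz", "C4",
                                         "P3", "Pz", "P4", "O1", "Oz", "O2"),
                            calib_runs = 3L,
                            calib_selections_per_run = 10L,
                            copy_runs = 3L,
                            commands_per_copy_run = 8L) {
  counts <- c(n_positions = n_positions, n_sequences = n_sequences,
              calib_runs = calib_runs,
              calib_selections_per_run = calib_selections_per_run,
              copy_runs = copy_runs,
              commands_per_copy_run = commands_per_copy_run)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all design counts must be integers >= 1")
  }
  if (stim_duration + isi_gap <= 0) stop("stim_duration + isi_gap must be positive")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(
    list(
      n_positions = as.integer(n_positions),
      n_sequences = as.integer(n_sequences),
      stim_duration = stim_duration,
      isi_gap = isi_gap,
      soa = stim_duration + isi_gap,
      vibration_freq = vibration_freq,
      sampling_rate = sampling_rate,
      channels = channels,
      positions = tactor_positions[seq_len(n_positions)],
      calib_runs = as.integer(calib_runs),
      calib_selections_per_run = as.integer(calib_selections_per_run),
      copy_runs = as.integer(copy_runs),
      commands_per_copy_run = as.integer(commands_per_copy_run)
    ),
    class = "paradigm_config"
  )
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("<paradigm_config>\n")
  cat(sprintf("  %d positions x %d sequences, SOA %g ms (stim %g + gap %g)\n",
              x$n_positions, x$n_sequences, x$soa, x$stim_duration, x$isi_gap))
  cat(sprintf("  %g Hz, %d channels: %s\n", x$sampling_rate,
              length(x$channels), paste(x$channels, collapse = " ")))
  cat(sprintf("  calibration: %d runs x %d selections; copy: %d runs x %d commands\n",
              x$calib_runs, x$calib_selections_per_run,
              x$copy_runs, x$commands_per_copy_run))
  invisible(x)
}

# Draw one pseudorandomized stimulus order: a concatenation of per-cycle
# permutations of the positions with no repeated position across cycle
# boundaries. Rejection sampling on the boundary constraint.
random_cycle_order <- function(positions, n_sequences, max_attempts = 1000L) {
  n <- length(positions)
  for (attempt in seq_len(max_attempts)) {
    order <- unlist(lapply(seq_len(n_sequences), function(i) sample(positions, n)))
    # within-cycle repeats are impossible (each cycle is a permutation), so
    # only cycle boundaries need checking
    boundary_ok <- TRUE
    if (n_sequences > 1 && n > 1) {
      idx <- seq_len(n_sequences - 1) * n
      boundary_ok <- all(order[idx] != order[idx + 1])
    }
    if (boundary_ok) return(order)
  }
  stop("could not draw a no-repeat stimulus order after ", max_attempts,
       " attempts")
}

#' Generate a pseudorandomized stimulus schedule for one selection
#'
#' One selection consists of `n_sequences` cycles; in every cycle each tactor
#' position is activated exactly once, in random order, with no position
#' repeated back-to-back (also across cycle boundaries). Onsets are spaced by
#' the stimulus-onset asynchrony `stim_duration + isi_gap`.
#'
#' @param config A [paradigm_config()].
#' @param target Target position, one of `config$positions`.
#' @param seed Integer seed; schedules are reproducible for a fixed seed.
#' @param t0 Onset time (ms) of the first stimulus.
#'
#' @return A tibble of class `selection_schedule` with columns `onset_ms`,
#'   `position`, `is_target` and attributes `target` and `config`.
#' @examples
#' sched <- generate_selection_schedule(paradigm_config(), "front", seed = 1)
#' sum(sched$is_target)  # 8: the target position appears once per sequence
#' @export
generate_selection_schedule <- function(config, target, seed, t0 = 0) {
  stopifnot(inherits(config, "paradigm_config"))
  if (!target %in% config$positions) {
    stop("target must be one of: ", paste(config$positions, collapse = ", "))
  }
  withr_seed(seed)
  order <- random_cycle_order(config$positions, config$n_sequences)
  n <- length(order)
  out <- tibble::tibble(
    onset_ms = t0 + (seq_len(n) - 1) * config$soa,
    position = order,
    is_target = order == target
  )
  attr(out, "target") <- target
  attr(out, "config") <- config
  class(out) <- c("selection_schedule", class(out))
  out
}

# local seed helper: sets the RNG seed without clobbering the caller's stream
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

#' Derive reproducible child seeds from a master seed
#'
#' Splits one master seed into `n` independent child seeds (all below
#' 2^31), so per-selection, per-run or per-participant randomness is
#' reproducible independently of evaluation order.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate the copy-task target sequence
#'
#' Draws the order of cued targets for one copy run: each position is used
#' `commands_per_copy_run / n_positions` times with no immediate repetition.
#'
#' @inheritParams generate_selection_schedule
#' @return Character vector of target positions of length
#'   `commands_per_copy_run`.
#' @examples
#' generate_copy_target_sequence(paradigm_config(), seed = 2)
#' @export
generate_copy_target_sequence <- function(config, seed) {
  stopifnot(inherits(config, "paradigm_config"))
  k <- config$commands_per_copy_run
  if (k %% config$n_positions != 0) {
    stop("commands_per_copy_run (", k, ") must be divisible by n_positions (",
         config$n_positions, ")")
  }
  reps <- k %/% config$n_positions
  withr_seed(seed)
  pool <- rep(config$positions, each = reps)
  for (attempt in 1:1000) {
    cand <- sample(pool)
    if (length(cand) == 1 || all(cand[-1] != cand[-length(cand)])) return(cand)
  }
  stop("could not draw a no-repeat target sequence after 1000 attempts")
}

#' Count calibration trials implied by a configuration
#'
#' With the default design (3 runs of 10 selections, 8 sequences each, 4
#' positions) calibration yields 240 target and 720 non-target trials.
#'
#' @inheritParams generate_selection_schedule
#' @return A tibble with columns `n_target` and `n_nontarget`.
#' @export
count_calibration_trials <- function(config) {
  stopifnot(inherits(config, "paradigm_config"))
  n_target <- config$calib_runs * config$calib_selections_per_run *
    config$n_sequences
  tibble::tibble(
    n_target = as.integer(n_target),
    n_nontarget = as.integer(n_target * (config$n_positions - 1))
  )
}

#' Selections per minute fixed by stimulus timing
#'
#' `60000 / (n_positions * n_sequences * SOA)`; no inter-selection pause is
#' modeled. Under the default timing this is 3.02, i.e. the 3.0
#' selections/min conventionally quoted for the paradigm.
#'
#' @inheritParams generate_selection_schedule
#' @return Selections per minute (numeric scalar).
#' @export
selections_per_minute <- function(config) {
  stopifnot(inherits(config, "paradigm_config"))
  60000 / (config$n_positions * config$n_sequences * config$soa)
}

#' Write a stimulus schedule as TSV
#'
#' @param schedule A `selection_schedule` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  readr::write_tsv(tibble::as_tibble(schedule)[c("onset_ms", "position", "is_target")],
                   path)
  invisible(path)
}

#' Serialize / deserialize a paradigm configuration as JSON
#'
#' @param config A [paradigm_config()].
#' @param path File path.
#' @return `write_paradigm_json()` returns `path` invisibly;
#'   `read_paradigm_json()` returns a `paradigm_config`.
#' @export
write_paradigm_json <- function(config, path) {
  stopifnot(inherits(config, "paradigm_config"))
  fields <- config[c("n_positions", "n_sequences", "stim_duration", "isi_gap",
                     "vibration_freq", "sampling_rate", "channels",
                     "calib_runs", "calib_selections_per_run", "copy_runs",
                     "commands_per_copy_run")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_paradigm_json
#' @export
read_paradigm_json <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(paradigm_config, fields)
}
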