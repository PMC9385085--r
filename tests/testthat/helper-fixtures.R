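# Shared fixtures. Reduced designs keep EEG simulation fast while keeping
# every pipeline stage exercised at its real sampling rate and timing.

small_paradigm <- function(...) {
  paradigm_config(calib_runs = 1, calib_selections_per_run = 4,
                  copy_runs = 1, ...)
}

# build a continuous_recording directly from a signal matrix + events
make_recording <- function(signal, events, fs = 512,
                           labels = paste0("ch", seq_len(nrow(signal)))) {
  structure(list(sampling_rate = fs, channel_labels = labels,
                 signal = signal, events = events),
            class = "continuous_recording")
}

# single-channel recording holding given per-epoch values around events
flat_events <- function(n_events, fs = 512, soa_ms = 1000) {
  tibble::tibble(onset_ms = 1000 + (seq_len(n_events) - 1) * soa_ms,
                 position = rep(tactor_positions, length.out = n_events),
                 is_target = rep(c(TRUE, FALSE), length.out = n_events),
                 selection = 1L)
}

# minimal feature_matrix for decision-rule tests (bypasses EEG generation)
make_feature_matrix <- function(x, labels, positions) {
  structure(
    list(x = x, labels = labels,
         info = tibble::tibble(epoch = seq_len(nrow(x)),
                               position = positions,
                               is_target = labels > 0,
                               selection = 1L,
                               rejected = FALSE,
                               reject_reason = NA_character_),
         layout = tibble::tibble(feature = seq_len(ncol(x)),
                                 channel = "ch1",
                                 bin = seq_len(ncol(x)),
                                 bin_start_ms = 0, bin_end_ms = 0),
         bin_width = NA, window = c(0, 800)),
    class = "feature_matrix")
}

reported <- function(name) {
  readr::read_tsv(system.file("extdata", paste0("reported_", name, ".tsv"),
                              package = "tactrain"),
                  show_col_types = FALSE)
}

# memoised small end-to-end study shared by the study-runner tests
small_study_cache <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(small_study_cache$result)) {
    cfg <- study_config(
      n_participants = 3, n_sessions = 2,
      session_amp_schedule = c(1, 1.6),
      dual_sessions = c(1, 2), dual_runs = 1,
      discrimination_sessions = c(1, 2),
      paradigm = small_paradigm(),
      gen_params = erp_gen_params(noise_sigma = 8),
      master_seed = 42)
    small_study_cache$result <- run_study(cfg)
  }
  small_study_cache$result
}
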