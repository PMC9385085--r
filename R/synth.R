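# Synthetic continuous EEG for scheduled runs and simulated forced-choice
# observers. The generator provides exactly the statistical structure the
# downstream analysis assumes: a stimulus-locked target ERP, a weak late
# non-target drift, 1/f background noise and occasional large artifacts.

#' ERP generator parameters
#'
#' Controls the synthetic EEG generator. The target response is a Gaussian
#' bump (amplitude per electrode, peak latency, width); non-targets carry a
#' small sustained offset in the 400-600 ms window, emulating the late
#' frontal non-target drift seen in tactile oddball data. Background noise
#' is spectrally shaped (power ~ 1/f^exponent) and independent across
#' channels. Artifacts are injected per epoch-window with probability
#' `artifact_rate` as brief excursions of `artifact_amp` microvolts.
#'
#' Default target amplitudes follow the topography typical of the tactile
#' paradigm (frontocentral maximum: Cz > Pz ~ Fz > lateral/occipital);
#' `noise_sigma` is calibrated so that with eight sequences per selection
#' a freshly trained decoder scores in the high 70s percent, the operating
#' point of an untrained user.
#'
#' @param target_p300_amp Named numeric vector mapping electrode label to
#'   target bump amplitude (microvolts). Unnamed scalar recycles to all
#'   channels.
#' @param p300_latency Peak latency in ms post-stimulus.
#' @param p300_width Gaussian SD in ms.
#' @param nontarget_offset Named numeric vector (or scalar) of sustained
#'   non-target offset amplitude (microvolts) applied over
#'   `nontarget_window`; may be negative.
#' @param nontarget_window ms window carrying the non-target offset.
#' @param noise_sigma Broadband noise SD in microvolts.
#' @param noise_exponent Spectral slope: noise power ~ 1/f^exponent.
#' @param artifact_rate Probability per stimulus epoch of an injected
#'   large excursion.
#' @param artifact_amp Amplitude (microvolts) of injected artifacts.
#' @param dual_attenuation Factor in \[0, 1\] multiplying target amplitudes
#'   under dual-task (divided attention) runs.
#'
#' @return An object of class `erp_gen_params`.
#' @export
erp_gen_params <- function(target_p300_amp = c(Fz = 1.9, FC1 = 2.2, FC2 = 2.2,
                                               C3 = 2.0, Cz = 3.0, C4 = 2.0,
                                               P3 = 2.0, Pz = 2.5, P4 = 2.0,
                                               O1 = 1.2, Oz = 1.4, O2 = 1.2),
                           p300_latency = 400,
                           p300_width = 80,
                           nontarget_offset = c(Fz = -0.4, FC1 = -0.3,
                                                FC2 = -0.3, C3 = -0.2,
                                                Cz = -0.3, C4 = -0.2,
                                                P3 = -0.1, Pz = -0.1,
                                                P4 = -0.1, O1 = 0, Oz = 0,
                                                O2 = 0),
                           nontarget_window = c(400, 600),
                           noise_sigma = 13,
                           noise_exponent = 1,
                           artifact_rate = 0.02,
                           artifact_amp = 150,
                           dual_attenuation = 0.85) {
  stopifnot(all(is.finite(target_p300_amp)), all(is.finite(nontarget_offset)),
            noise_sigma >= 0, p300_width > 0,
            dual_attenuation >= 0, dual_attenuation <= 1,
            artifact_rate >= 0, artifact_rate <= 1)
  structure(
    list(target_p300_amp = target_p300_amp,
         p300_latency = p300_latency,
         p300_width = p300_width,
         nontarget_offset = nontarget_offset,
         nontarget_window = nontarget_window,
         noise_sigma = noise_sigma,
         noise_exponent = noise_exponent,
         artifact_rate = artifact_rate,
         artifact_amp = artifact_amp,
         dual_attenuation = dual_attenuation),
    class = "erp_gen_params"
  )
}

# expand a scalar or named amplitude spec to the channel vector
amp_for_channels <- function(amp, channels) {
  if (is.null(names(amp))) {
    if (length(amp) == 1) return(stats::setNames(rep(amp, length(channels)), channels))
    if (length(amp) == length(channels)) return(stats::setNames(amp, channels))
    stop("amplitude vector must be scalar, named, or match channel count")
  }
  out <- stats::setNames(rep(0, length(channels)), channels)
  known <- intersect(names(amp), channels)
  out[known] <- amp[known]
  out
}

# 1/f^a noise: frequency-domain shaping of white Gaussian noise, rescaled to
# the requested SD. DC is zeroed so the noise is mean-free.
pink_noise <- function(n, sigma, exponent) {
  if (sigma == 0) return(numeric(n))
  white <- stats::rnorm(n)
  if (exponent == 0) return(sigma * white)
  spec <- stats::fft(white)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))
  shape <- c(0, freq[-1]^(-exponent / 2))
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  sd_x <- stats::sd(x)
  if (sd_x == 0) return(numeric(n))
  sigma * x / sd_x
}

#' Generate synthetic continuous EEG for scheduled runs
#'
#' Renders one continuous multichannel recording from one or more selection
#' schedules: spectrally shaped background noise plus, for every stimulus
#' event, an ERP template (target: Gaussian bump with electrode-specific
#' amplitude at `p300_latency`; non-target: sustained offset over the
#' non-target window), plus occasional artifact excursions. Schedules are
#' concatenated in order with a gap of one stimulus-onset asynchrony between
#' them; event onsets are shifted to global recording time.
#'
#' @param schedules A `selection_schedule` or list of them.
#' @param params An [erp_gen_params()].
#' @param config The [paradigm_config()] used to build the schedules.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param dual If `TRUE`, target amplitudes are multiplied by
#'   `params$dual_attenuation` (divided-attention run).
#'
#' @return An object of class `continuous_recording`: list with
#'   `sampling_rate`, `channel_labels`, `signal` (channels x samples matrix,
#'   microvolts), and `events` (tibble: `onset_ms`, `position`, `is_target`,
#'   `selection`).
#' @examples
#' cfg <- paradigm_config()
#' sched <- generate_selection_schedule(cfg, "front", seed = 1)
#' rec <- generate_run_eeg(sched, erp_gen_params(noise_sigma = 2), cfg, seed = 1)
#' dim(rec$signal)
#' @export
generate_run_eeg <- function(schedules, params, config, seed, dual = FALSE) {
  stopifnot(inherits(params, "erp_gen_params"),
            inherits(config, "paradigm_config"))
  if (inherits(schedules, "selection_schedule")) schedules <- list(schedules)
  if (length(schedules) == 0) stop("schedules must be non-empty")

  fs <- config$sampling_rate
  soa <- config$soa
  # concatenate schedules with one SOA of padding between selections
  events <- dplyr::bind_rows(lapply(seq_along(schedules), function(i) {
    s <- tibble::as_tibble(schedules[[i]])[c("onset_ms", "position", "is_target")]
    s$selection <- i
    s
  }))
  sel_dur <- config$n_positions * config$n_sequences * soa
  offsets <- (match(events$selection, unique(events$selection)) - 1) * (sel_dur + soa)
  events$onset_ms <- events$onset_ms + offsets
  # leave 1 s of head/tail room so every event has full pre/post context
  t_head <- 1000
  events$onset_ms <- events$onset_ms + t_head
  total_ms <- max(events$onset_ms) + 1000 + t_head
  n_samples <- ceiling(total_ms / 1000 * fs)

  channels <- config$channels
  amp <- amp_for_channels(params$target_p300_amp, channels)
  if (dual) amp <- amp * params$dual_attenuation
  ntoff <- amp_for_channels(params$nontarget_offset, channels)

  withr_seed(seed)
  sig <- matrix(0, nrow = length(channels), ncol = n_samples,
                dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    sig[ci, ] <- pink_noise(n_samples, params$noise_sigma, params$noise_exponent)
  }

  t_template <- (0:(ceiling(0.9 * fs) - 1)) / fs * 1000  # 0..900 ms post-onset
  bump <- exp(-((t_template - params$p300_latency)^2) / (2 * params$p300_width^2))
  ntwin <- as.numeric(t_template >= params$nontarget_window[1] &
                      t_template < params$nontarget_window[2])
  onset_idx <- round(events$onset_ms / 1000 * fs) + 1L

  for (ei in seq_len(nrow(events))) {
    idx <- onset_idx[ei] + seq_along(t_template) - 1L
    idx <- idx[idx <= n_samples]
    k <- seq_along(idx)
    if (events$is_target[ei]) {
      sig[, idx] <- sig[, idx] + outer(amp, bump[k])
    } else {
      sig[, idx] <- sig[, idx] + outer(ntoff, ntwin[k])
    }
    if (params$artifact_rate > 0 && stats::runif(1) < params$artifact_rate) {
      # brief square excursion of ~40 ms on one random channel, placed
      # inside the event's own [0, 760) ms so it falls within the epoch
      a_ch <- sample(length(channels), 1)
      a_start <- idx[1] + sample(0:max(0, round(0.76 * fs) - 1), 1)
      a_idx <- a_start:(a_start + round(0.04 * fs))
      a_idx <- a_idx[a_idx <= n_samples]
      sig[a_ch, a_idx] <- sig[a_ch, a_idx] +
        sample(c(-1, 1), 1) * params$artifact_amp
    }
  }

  structure(
    list(sampling_rate = fs,
         channel_labels = channels,
         signal = sig,
         events = events),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Write / read a continuous recording as TSV
#'
#' Plain-text serialization: a wide signal table (`time_s`, one column per
#' channel, microvolts) and a sidecar events table
#' (`onset_ms`, `position`, `is_target`, `selection`).
#'
#' @param recording A `continuous_recording`.
#' @param path Signal TSV path; events are written to
#'   `sub("\\\\.tsv$", "_events.tsv", path)`.
#' @return `path` invisibly, or the recording for the reader.
#' @export
write_recording_tsv <- function(recording, path) {
  stopifnot(inherits(recording, "continuous_recording"))
  sig <- tibble::as_tibble(t(recording$signal), .name_repair = "minimal")
  names(sig) <- recording$channel_labels
  sig <- dplyr::bind_cols(
    tibble::tibble(time_s = (seq_len(ncol(recording$signal)) - 1) /
                     recording$sampling_rate),
    sig)
  readr::write_tsv(sig, path)
  ev_path <- sub("\\.tsv$", "_events.tsv", path)
  readr::write_tsv(recording$events, ev_path)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  sig <- readr::read_tsv(path, show_col_types = FALSE)
  ev <- readr::read_tsv(sub("\\.tsv$", "_events.tsv", path),
                        show_col_types = FALSE)
  fs <- 1 / stats::median(diff(sig$time_s))
  labels <- setdiff(names(sig), "time_s")
  structure(
    list(sampling_rate = round(fs, 6),
         channel_labels = labels,
         signal = t(as.matrix(sig[labels])),
         events = ev),
    class = "continuous_recording"
  )
}

#' Simulated forced-choice observer
#'
#' A psychometric observer for the two-interval intensity-discrimination
#' task: the probability of responding "equal" falls with the intensity
#' difference following a logistic with midpoint `true_threshold` and scale
#' `slope`; with probability `lapse_rate` the observer guesses at random.
#'
#' @param true_threshold Intensity difference (%) at which p(equal) = 0.5
#'   (absent lapses); in (0, 50].
#' @param slope Logistic scale in % units (> 0); smaller is steeper.
#' @param lapse_rate Probability of a random response, in \[0, 0.5).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(true_threshold = 25, slope = 3, lapse_rate = 0.02) {
  stopifnot(true_threshold > 0, true_threshold <= 50, slope >= 0,
            lapse_rate >= 0, lapse_rate < 0.5)
  structure(list(true_threshold = true_threshold, slope = slope,
                 lapse_rate = lapse_rate),
            class = "observer_model")
}

#' Probability that an observer reports "equal"
#'
#' @param observer An [observer_model()].
#' @param intensity_diff Intensity difference(s) in percent (>= 0).
#' @return Numeric vector of probabilities.
#' @export
p_equal <- function(observer, intensity_diff) {
  stopifnot(inherits(observer, "observer_model"), all(intensity_diff >= 0))
  core <- if (observer$slope == 0) {
    as.numeric(intensity_diff < observer$true_threshold) +
      0.5 * (intensity_diff == observer$true_threshold)
  } else {
    stats::plogis(-(intensity_diff - observer$true_threshold) / observer$slope)
  }
  (1 - observer$lapse_rate) * core + observer$lapse_rate / 2
}

#' Simulate one forced-choice response
#'
#' @inheritParams p_equal
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return `"equal"` or `"unequal"`.
#' @export
simulate_observer_response <- function(observer, intensity_diff, seed = NULL) {
  if (!is.null(seed)) withr_seed(seed)
  p <- p_equal(observer, intensity_diff)
  ifelse(stats::runif(length(p)) < p, "equal", "unequal")
}
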