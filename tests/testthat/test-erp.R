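fs <- 512

test_that("offline band-pass removes DC and 50 Hz but keeps 10 Hz", {
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  mk <- function(x) make_recording(matrix(x, nrow = 1),
                                   flat_events(1), fs = fs)
  amp_out <- function(freq) {
    rec <- mk(sin(2 * pi * freq * t))
    filt <- bandpass_offline(rec)
    mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
    max(abs(filt$signal[1, mid]))
  }
  expect_lt(amp_out(50), 0.1)                  # >= 90% attenuation
  expect_gt(amp_out(10), 0.95)                 # passband within 5%
  const <- bandpass_offline(mk(rep(7, length(t))))
  expect_lt(abs(mean(const$signal)), 1e-6)     # DC removed
  expect_error(bandpass_offline(mk(t), low = 0.1, high = 300), "Nyquist|<")
})

test_that("epoch extraction baseline-corrects and copies labels", {
  sig <- matrix(3, nrow = 2, ncol = fs * 10)
  rec <- make_recording(sig, flat_events(4, soa_ms = 2000), fs = fs,
                        labels = c("Fz", "Cz"))
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$epochs), c(4, 2, 461))
  expect_true(all(abs(ep$epochs) < 1e-9))      # constant input -> all zero
  expect_equal(ep$info$is_target, c(TRUE, FALSE, TRUE, FALSE))
  base_sel <- ep$time_ms < 0
  expect_lt(max(abs(apply(ep$epochs[, , base_sel], 1:2, mean))), 1e-9)
})

test_that("a full selection yields 32 epochs with 8 targets", {
  cfg <- paradigm_config()
  sched <- generate_selection_schedule(cfg, "right", seed = 5)
  rec <- generate_run_eeg(sched, erp_gen_params(noise_sigma = 2), cfg, seed = 5)
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$epochs)[1], 32)
  expect_equal(sum(ep$info$is_target), 8)
})

test_that("events too close to the recording edge are edge-rejected", {
  sig <- matrix(0, nrow = 1, ncol = fs)
  ev <- tibble::tibble(onset_ms = c(50, 500), position = "front",
                       is_target = TRUE, selection = 1L)
  ep <- extract_epochs(make_recording(sig, ev, fs = fs))
  expect_true(ep$info$rejected[1])
  expect_equal(ep$info$reject_reason[1], "edge")
  expect_true(ep$info$rejected[2])  # < 800 ms post also missing
})

test_that("amplitude rejection uses a strict threshold", {
  sig <- matrix(0, nrow = 1, ncol = fs * 6)
  ev <- flat_events(3, soa_ms = 1500)
  on_idx <- round(ev$onset_ms / 1000 * fs) + 1
  sig[1, on_idx[1] + 100] <- 101   # rejected
  sig[1, on_idx[2] + 100] <- 100   # kept: exactly at threshold
  sig[1, on_idx[3] + 100] <- -99   # kept
  ep <- reject_artifacts(extract_epochs(make_recording(sig, ev, fs = fs)))
  expect_equal(ep$info$rejected, c(TRUE, FALSE, FALSE))
  expect_equal(ep$info$reject_reason[1], "amplitude")
  # non-strict variant rejects the boundary epoch too
  ep2 <- reject_artifacts(extract_epochs(make_recording(sig, ev, fs = fs)),
                          strict = FALSE)
  expect_equal(ep2$info$rejected, c(TRUE, TRUE, FALSE))
})

test_that("class averaging is a pointwise mean over non-rejected epochs", {
  sig <- matrix(0, nrow = 1, ncol = fs * 8)
  ev <- flat_events(4, soa_ms = 1500)
  on_idx <- round(ev$onset_ms / 1000 * fs) + 1
  # epochs 1, 3 are targets valued +2/-2 post-stimulus; baseline stays 0
  post <- 1:400
  sig[1, on_idx[1] + post] <- 2
  sig[1, on_idx[3] + post] <- -2
  ep <- extract_epochs(make_recording(sig, ev, fs = fs))
  av <- average_erp(ep)
  tgt <- dplyr::filter(av, class == "target")
  expect_lt(max(abs(tgt$amplitude)), 1e-9)  # +2 and -2 cancel
  # single-epoch class equals that epoch
  ep1 <- extract_epochs(make_recording(sig, ev[1:2, ], fs = fs))
  av1 <- average_erp(ep1)
  expect_equal(dplyr::filter(av1, class == "target")$amplitude,
               ep1$epochs[1, 1, ])
  # empty class errors
  ep_all_t <- ep
  ep_all_t$info$is_target <- TRUE
  expect_error(average_erp(ep_all_t), "per class")
})

test_that("label permutation swaps the output curves exactly", {
  cfg <- paradigm_config()
  sched <- generate_selection_schedule(cfg, "front", seed = 6)
  rec <- generate_run_eeg(sched, erp_gen_params(noise_sigma = 5), cfg, seed = 6)
  ep <- extract_epochs(rec)
  av <- average_erp(ep)
  ep_sw <- ep
  ep_sw$info$is_target <- !ep_sw$info$is_target
  av_sw <- average_erp(ep_sw)
  expect_equal(dplyr::filter(av, class == "target")$amplitude,
               dplyr::filter(av_sw, class == "nontarget")$amplitude)
  expect_equal(dplyr::filter(av, class == "nontarget")$amplitude,
               dplyr::filter(av_sw, class == "target")$amplitude)
})

test_that("window features match their defining means and the type invariant", {
  time_ms <- extract_epochs(make_recording(matrix(0, 1, fs * 2),
                                           flat_events(1), fs = fs))$time_ms
  mk_curves <- function(target_fun, nontarget_fun) {
    grid <- expand.grid(channel = c("Fz", "Cz", "Pz"), time_ms = time_ms,
                        stringsAsFactors = FALSE)
    dplyr::bind_rows(
      dplyr::mutate(grid, class = "target",
                    amplitude = target_fun(time_ms)),
      dplyr::mutate(grid, class = "nontarget",
                    amplitude = nontarget_fun(time_ms))) |>
      structure(class = c("erp_average", class(tibble::tibble())))
  }
  # constants: amp 5 vs 1 -> difference 4; identical curves -> 0
  f1 <- extract_features(mk_curves(function(t) 5, function(t) 1))
  expect_equal(f1$mean_target_amp, rep(5, 3))
  expect_equal(f1$curve_difference, rep(4, 3))
  f2 <- extract_features(mk_curves(function(t) sin(t), function(t) sin(t)))
  expect_equal(f2$curve_difference, rep(0, 3))
  expect_equal(f2$curve_difference,
               f2$mean_target_amp - f2$mean_nontarget_amp, tolerance = 1e-9)

  # Gaussian bump amp 4, peak 400 ms, SD 80: window mean from the direct
  # numeric integral of the template over [300, 500)
  bump <- function(t) 4 * exp(-((t - 400)^2) / (2 * 80^2))
  sel <- time_ms >= 300 & time_ms < 500
  oracle <- mean(bump(time_ms[sel]))
  f3 <- extract_features(mk_curves(bump, function(t) 0))
  expect_equal(f3$mean_target_amp, rep(oracle, 3), tolerance = 1e-9)
  # closed form: 4 * sigma * sqrt(2*pi) * (2*pnorm(100/80) - 1) / 200
  expect_equal(oracle, 4 * 80 * sqrt(2 * pi) * (2 * pnorm(1.25) - 1) / 200,
               tolerance = 5e-3)  # grid mean vs continuous integral

  # commutes with channel subsetting
  f_sub <- extract_features(mk_curves(bump, function(t) 0),
                            electrodes = c("Cz"))
  expect_equal(f_sub$mean_target_amp,
               f3$mean_target_amp[f3$electrode == "Cz"])
  expect_error(extract_features(mk_curves(bump, function(t) 0),
                                electrodes = "XX"), "electrode")
})

test_that("clean low-noise epochs are never amplitude-rejected", {
  cfg <- paradigm_config(n_sequences = 2)
  for (seed in 1:20) {
    sched <- generate_selection_schedule(cfg, "front", seed = seed)
    rec <- generate_run_eeg(sched, erp_gen_params(noise_sigma = 10,
                                                  artifact_rate = 0),
                            cfg, seed = seed)
    ep <- reject_artifacts(extract_epochs(rec))
    expect_equal(sum(ep$info$rejected), 0)
  }
})
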