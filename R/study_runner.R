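# Orchestration of a full synthetic training study: per participant and
# session, calibrate a decoder on fresh synthetic EEG, simulate copy (and,
# where configured, dual) runs, run the intensity-discrimination
# assessment, aggregate workload, and hand everything to the statistical
# battery.

# default per-session, per-subscale NASA-TLX contribution means used by the
# workload simulator (weighted contributions on the 0-100 scale; rows are
# sessions of the default 5-session design)
default_tlx_profile <- function(n_sessions) {
  base <- matrix(c(
    23.10, 0.63, 5.74, 7.98, 18.67, 6.62,
    18.04, 1.31, 4.65, 6.11, 15.69, 5.26,
    16.45, 1.75, 6.10, 6.03, 13.51, 5.15,
    16.57, 1.69, 5.39, 6.90, 14.37, 4.08,
    19.41, 1.54, 5.80, 9.88, 15.09, 6.87),
    nrow = 5, byrow = TRUE,
    dimnames = list(NULL, tlx_subscales))
  base[pmin(seq_len(n_sessions), 5), , drop = FALSE]
}

#' Study configuration
#'
#' Assembles everything needed to simulate a multi-session training study:
#' cohort size, number of sessions, the per-session target-amplitude
#' schedule emulating training gains, which sessions carry the dual-task
#' and intensity-discrimination assessments, observer threshold
#' distribution, and the master seed all per-participant randomness is
#' derived from.
#'
#' @param n_participants Cohort size.
#' @param n_sessions Number of training sessions.
#' @param session_amp_schedule Multiplier applied to all target amplitudes
#'   per session; its rise across sessions is what emulates training.
#' @param participant_amp_sd SD of the log-normal participant factor
#'   multiplying amplitudes (between-subject ability spread).
#' @param dual_sessions Sessions including dual-task runs.
#' @param dual_runs Number of dual runs in those sessions.
#' @param discrimination_sessions Sessions including the
#'   intensity-discrimination task.
#' @param threshold_mean,threshold_sd Mean/SD (percent intensity
#'   difference) of the simulated observers' first-session thresholds.
#' @param threshold_improvement Multiplicative pre-to-post threshold change
#'   (values < 1 mean increased sensitivity after training).
#' @param observer_slope,observer_lapse Psychometric observer parameters.
#' @param tlx_weights Fixed pairwise-comparison weight profile (sums
#'   to 15).
#' @param tlx_rating_sd SD of simulated subscale ratings.
#' @param paradigm A [paradigm_config()].
#' @param gen_params An [erp_gen_params()].
#' @param master_seed Integer master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_participants = 29,
                         n_sessions = 5,
                         session_amp_schedule = seq(1, 1.5,
                                                    length.out = n_sessions),
                         participant_amp_sd = 0.3,
                         dual_sessions = c(1, n_sessions),
                         dual_runs = 3,
                         discrimination_sessions = c(1, n_sessions),
                         threshold_mean = 25,
                         threshold_sd = 8,
                         threshold_improvement = 0.8,
                         observer_slope = 3,
                         observer_lapse = 0.02,
                         tlx_weights = c(mental = 5, physical = 1,
                                         temporal = 1, performance = 2,
                                         effort = 4, frustration = 2),
                         tlx_rating_sd = 12,
                         paradigm = paradigm_config(),
                         gen_params = erp_gen_params(),
                         master_seed = 1) {
  stopifnot(length(session_amp_schedule) == n_sessions,
            all(dual_sessions %in% seq_len(n_sessions)),
            all(discrimination_sessions %in% seq_len(n_sessions)),
            sum(tlx_weights) == 15)
  structure(
    list(n_participants = as.integer(n_participants),
         n_sessions = as.integer(n_sessions),
         session_amp_schedule = session_amp_schedule,
         participant_amp_sd = participant_amp_sd,
         dual_sessions = as.integer(dual_sessions),
         dual_runs = as.integer(dual_runs),
         discrimination_sessions = as.integer(discrimination_sessions),
         threshold_mean = threshold_mean, threshold_sd = threshold_sd,
         threshold_improvement = threshold_improvement,
         observer_slope = observer_slope, observer_lapse = observer_lapse,
         tlx_weights = tlx_weights, tlx_rating_sd = tlx_rating_sd,
         tlx_profile = default_tlx_profile(n_sessions),
         paradigm = paradigm, gen_params = gen_params,
         master_seed = as.integer(master_seed)),
    class = "study_config")
}

# params for one participant x session: session schedule multiplier times
# the participant's ability factor
session_gen_params <- function(config, amp_factor, session) {
  p <- config$gen_params
  mult <- config$session_amp_schedule[session] * amp_factor
  p$target_p300_amp <- p$target_p300_amp * mult
  p
}

#' Calibrate a decoder on synthetic calibration runs
#'
#' Generates the calibration runs of one session (targets cycle through the
#' positions in balanced pseudo-random order), preprocesses them (offline
#' band-pass, epoching, amplitude rejection), and trains an SWLDA model.
#'
#' @param config A [paradigm_config()].
#' @param params An [erp_gen_params()].
#' @param seed Integer seed.
#' @return A list: `model` (`swlda_model`), `epochs` (the calibration
#'   `epoch_set` after rejection), `n_rejected`.
#' @export
calibrate_decoder <- function(config, params, seed) {
  seeds <- derive_seeds(seed, config$calib_runs + 1L)
  all_epochs <- vector("list", config$calib_runs)
  for (run in seq_len(config$calib_runs)) {
    run_seeds <- derive_seeds(seeds[run], config$calib_selections_per_run + 1L)
    withr_seed(run_seeds[1])
    targets <- as.vector(vapply(
      seq_len(ceiling(config$calib_selections_per_run / config$n_positions)),
      function(i) sample(config$positions), character(config$n_positions)
    ))[seq_len(config$calib_selections_per_run)]
    scheds <- lapply(seq_along(targets), function(i) {
      generate_selection_schedule(config, targets[i], seed = run_seeds[i + 1])
    })
    rec <- generate_run_eeg(scheds, params, config, seed = seeds[run])
    rec <- bandpass_offline(rec)
    all_epochs[[run]] <- reject_artifacts(extract_epochs(rec))
  }
  epochs <- bind_epoch_sets(all_epochs)
  model <- train_swlda(build_features(epochs))
  list(model = model, epochs = epochs,
       n_rejected = sum(epochs$info$rejected))
}

# concatenate epoch sets sharing a grid
bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  out <- sets[[1]]
  if (length(sets) == 1) return(out)
  out$epochs <- do.call(abind_epochs, lapply(sets, function(s) s$epochs))
  infos <- lapply(seq_along(sets), function(i) {
    info <- sets[[i]]$info
    info$run <- i
    info
  })
  out$info <- dplyr::bind_rows(infos)
  out$info$epoch <- seq_len(nrow(out$info))
  out
}

abind_epochs <- function(...) {
  arrays <- list(...)
  d <- dim(arrays[[1]])
  total <- sum(vapply(arrays, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, dim = c(total, d[2], d[3]))
  at <- 1L
  for (a in arrays) {
    out[at:(at + dim(a)[1] - 1L), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Simulate and classify the selection runs of one task
#'
#' Generates `n_runs` runs of cued selections (copy-task structure), scores
#' every selection with a trained model, and returns one row per selection.
#' Online selection epochs are never artifact-rejected: a live-feedback
#' system must classify every sequence. Offline ERP averages from these
#' runs (returned as `epochs`) carry the rejection mask instead.
#'
#' @param model A trained `swlda_model`.
#' @param config A [paradigm_config()].
#' @param params An [erp_gen_params()].
#' @param seed Integer seed.
#' @param n_runs Number of runs (default `config$copy_runs`).
#' @param dual If `TRUE`, target amplitudes are attenuated by
#'   `params$dual_attenuation`.
#' @return A list: `selections` (tibble with one row per classified
#'   selection), `epochs` (pooled `epoch_set` with the offline rejection
#'   mask applied).
#' @export
simulate_task_runs <- function(model, config, params, seed,
                               n_runs = config$copy_runs, dual = FALSE) {
  run_seeds <- derive_seeds(seed, n_runs)
  selections <- list()
  epoch_sets <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    seeds <- derive_seeds(run_seeds[run], config$commands_per_copy_run + 2L)
    targets <- generate_copy_target_sequence(config, seed = seeds[1])
    scheds <- lapply(seq_along(targets), function(i) {
      generate_selection_schedule(config, targets[i], seed = seeds[i + 1])
    })
    rec <- generate_run_eeg(scheds, params, config,
                            seed = seeds[length(seeds)], dual = dual)
    rec <- bandpass_offline(rec)
    epochs <- extract_epochs(rec)
    for (i in seq_along(targets)) {
      sel_epochs <- subset_epochs(epochs, epochs$info$selection == i)
      fm <- build_features(sel_epochs)
      res <- classify_selection(model, fm, true_position = targets[i])
      res$run <- run
      res$selection <- i
      selections[[length(selections) + 1]] <- res
    }
    epoch_sets[[run]] <- reject_artifacts(epochs)
  }
  list(selections = dplyr::bind_rows(selections),
       epochs = bind_epoch_sets(epoch_sets))
}

# subset an epoch_set by a logical or integer index over epochs
subset_epochs <- function(epochs, which) {
  idx <- if (is.logical(which)) which(which) else which
  epochs$epochs <- epochs$epochs[idx, , , drop = FALSE]
  epochs$info <- epochs$info[idx, ]
  epochs$info$epoch <- seq_along(idx)
  epochs
}

# simulate one NASA-TLX questionnaire from the per-session contribution
# profile: ratings are drawn around profile * 15 / weight and re-aggregated
simulate_tlx <- function(config, session) {
  w <- config$tlx_weights
  contrib_mean <- config$tlx_profile[session, ]
  rating_mean <- ifelse(w > 0, contrib_mean * 15 / w, 50)
  ratings <- pmin(pmax(stats::rnorm(6, rating_mean, config$tlx_rating_sd), 0), 100)
  names(ratings) <- tlx_subscales
  tlx_aggregate(ratings, w)
}

#' Run a full synthetic training study
#'
#' For every participant and session: generate calibration EEG and train an
#' SWLDA decoder, simulate and classify the copy runs and (in configured
#' sessions) dual runs, extract ERP window features from the offline
#' (calibration + copy) epochs, run the adaptive intensity-discrimination
#' task on the participant's simulated observer, and simulate the workload
#' questionnaire. Everything is reproducible from `master_seed`.
#'
#' This is compute-intensive at the full default scale (29 participants x
#' 5 sessions of continuous 12-channel EEG); reduced designs for quick
#' exploration are obtained by shrinking `n_participants`, the calibration
#' structure, or `copy_runs` in the embedded [paradigm_config()].
#'
#' @param config A [study_config()].
#' @param progress If `TRUE`, prints one line per participant.
#' @return An object of class `study_result`: list of tibbles `sessions`
#'   (one row per participant x session: `copy_accuracy`, `dual_accuracy`,
#'   `n_rejected_epochs`, TLX total/raw/mental contribution),
#'   `erp` (per participant x session x electrode window features, plus
#'   the 400-600 ms non-target mean and dual-task features where present),
#'   `thresholds` (per participant x assessed session: fitted and true
#'   threshold, trials used, method), and `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  p_seeds <- derive_seeds(config$master_seed, config$n_participants)
  sessions <- list(); erp <- list(); thresholds <- list()

  for (p in seq_len(config$n_participants)) {
    seeds <- derive_seeds(p_seeds[p], config$n_sessions + 2L)
    withr_seed(seeds[config$n_sessions + 1L])
    amp_factor <- exp(stats::rnorm(1, 0, config$participant_amp_sd))
    thr1 <- min(max(stats::rnorm(1, config$threshold_mean,
                                 config$threshold_sd), 8), 45)

    for (s in seq_len(config$n_sessions)) {
      s_seeds <- derive_seeds(seeds[s], 6L)
      params <- session_gen_params(config, amp_factor, s)
      cal <- calibrate_decoder(config$paradigm, params, seed = s_seeds[1])
      copy <- simulate_task_runs(cal$model, config$paradigm, params,
                                 seed = s_seeds[2])
      copy_acc <- 100 * mean(copy$selections$correct)

      dual_acc <- NA_real_
      dual_epochs <- NULL
      if (s %in% config$dual_sessions) {
        dual <- simulate_task_runs(cal$model, config$paradigm, params,
                                   seed = s_seeds[3],
                                   n_runs = config$dual_runs, dual = TRUE)
        dual_acc <- 100 * mean(dual$selections$correct)
        dual_epochs <- dual$epochs
      }

      # offline ERP features: calibration + copy epochs, rejected excluded
      offline <- bind_epoch_sets(list(cal$epochs, copy$epochs))
      curves <- average_erp(offline)
      feats <- extract_features(curves)
      nt_late <- extract_features(curves, electrodes = "Fz",
                                  window = c(400, 600))
      feats$participant <- p; feats$session <- s
      feats$nontarget_late_fz <- nt_late$mean_nontarget_amp
      if (!is.null(dual_epochs)) {
        dcurves <- tryCatch(average_erp(dual_epochs), error = function(e) NULL)
        if (!is.null(dcurves)) {
          dfeats <- extract_features(dcurves)
          feats$dual_mean_target_amp <- dfeats$mean_target_amp
          feats$dual_curve_difference <- dfeats$curve_difference
        }
      }
      erp[[length(erp) + 1]] <- feats

      if (s %in% config$discrimination_sessions) {
        pos <- match(s, sort(config$discrimination_sessions))
        true_thr <- thr1 * config$threshold_improvement^(pos - 1)
        obs <- observer_model(true_threshold = true_thr,
                              slope = config$observer_slope,
                              lapse_rate = config$observer_lapse)
        ds <- run_adaptive_procedure(obs, seed = s_seeds[4])
        fit <- fit_threshold(ds)
        thresholds[[length(thresholds) + 1]] <- tibble::tibble(
          participant = p, session = s,
          threshold = fit$midpoint, true_threshold = true_thr,
          method = fit$method, n_trials = ds$n_trials,
          converged_range = ds$converged_range)
      }

      withr_seed(s_seeds[5])
      tlx <- simulate_tlx(config, s)
      sessions[[length(sessions) + 1]] <- tibble::tibble(
        participant = p, session = s,
        copy_accuracy = copy_acc, dual_accuracy = dual_acc,
        n_selections = nrow(copy$selections),
        n_rejected_epochs = cal$n_rejected +
          sum(copy$epochs$info$rejected),
        tlx_total = tlx$total, tlx_raw = tlx$raw,
        tlx_mental = tlx$contrib_mental)
    }
    if (progress) {
      message(sprintf("participant %d/%d done", p, config$n_participants))
    }
  }

  structure(
    list(sessions = dplyr::bind_rows(sessions),
         erp = dplyr::bind_rows(erp),
         thresholds = dplyr::bind_rows(thresholds),
         config = config),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d participants x %d sessions\n",
              x$config$n_participants, x$config$n_sessions))
  acc <- x$sessions |>
    dplyr::summarise(mean_copy = mean(.data$copy_accuracy), .by = "session")
  print(acc)
  invisible(x)
}

#' Statistical battery over a study result
#'
#' Applies the BCI-efficiency screening, then runs the full analysis:
#' repeated-measures GG-corrected ANOVAs (session on copy accuracy;
#' session x electrode on target amplitudes and on curve differences),
#' pre-post one-tailed paired t tests (accuracy, per-electrode features,
#' dual vs copy per dual session, discrimination thresholds, mental-demand
#' workload, late non-target shift at Fz), the power-law learning-curve
#' fit over all session accuracies, dual-task impact factors on the
#' session-mean accuracies, ITR aggregation per session, and the
#' threshold-accuracy Pearson correlations.
#'
#' @param result A `study_result` from [run_study()].
#' @param efficiency_threshold Accuracy criterion (%) for the screening
#'   rule.
#' @return A list of tibbles: `included`, `anova`, `t_tests`,
#'   `power_fit`, `dual_impact`, `itr`, `correlations`.
#' @export
study_statistics <- function(result, efficiency_threshold = 70) {
  stopifnot(inherits(result, "study_result"))
  screen <- screen_bci_efficiency(result$sessions,
                                  threshold = efficiency_threshold)
  keep <- screen$participant[screen$efficient]
  ses <- dplyr::filter(result$sessions, .data$participant %in% keep)
  erp <- dplyr::filter(result$erp, .data$participant %in% keep)
  thr <- dplyr::filter(result$thresholds, .data$participant %in% keep)
  s_first <- min(ses$session); s_last <- max(ses$session)

  anova <- dplyr::bind_rows(
    dplyr::mutate(rm_anova_gg(ses, "copy_accuracy", "participant", "session"),
                  outcome = "copy_accuracy"),
    dplyr::mutate(rm_anova_gg(erp, "mean_target_amp", "participant",
                              c("session", "electrode")),
                  outcome = "mean_target_amp"),
    dplyr::mutate(rm_anova_gg(erp, "curve_difference", "participant",
                              c("session", "electrode")),
                  outcome = "curve_difference"))

  wide <- function(df, col, sess) {
    df <- df[df$session == sess, ]
    df[[col]][order(df$participant)]
  }
  tt <- list()
  tt$accuracy <- dplyr::mutate(
    paired_t(wide(ses, "copy_accuracy", s_last),
             wide(ses, "copy_accuracy", s_first), tail = "greater"),
    test = "copy accuracy S_last > S_first")
  for (el in unique(erp$electrode)) {
    sub <- erp[erp$electrode == el, ]
    tt[[paste0("amp_", el)]] <- dplyr::mutate(
      paired_t(wide(sub, "mean_target_amp", s_last),
               wide(sub, "mean_target_amp", s_first), tail = "greater"),
      test = paste0("target amplitude ", el, " S_last > S_first"))
    tt[[paste0("diff_", el)]] <- dplyr::mutate(
      paired_t(wide(sub, "curve_difference", s_last),
               wide(sub, "curve_difference", s_first), tail = "greater"),
      test = paste0("curve difference ", el, " S_last > S_first"))
  }
  for (s in result$config$dual_sessions) {
    sub <- ses[ses$session == s & !is.na(ses$dual_accuracy), ]
    if (nrow(sub) >= 2) {
      tt[[paste0("dual_s", s)]] <- dplyr::mutate(
        paired_t(sub$copy_accuracy, sub$dual_accuracy, tail = "greater"),
        test = paste0("copy > dual accuracy, session ", s))
    }
  }
  if (nrow(thr) > 0 && length(unique(thr$session)) == 2) {
    both <- intersect(thr$participant[thr$session == min(thr$session)],
                      thr$participant[thr$session == max(thr$session)])
    t1 <- thr[thr$session == min(thr$session) & thr$participant %in% both, ]
    t2 <- thr[thr$session == max(thr$session) & thr$participant %in% both, ]
    tt$threshold <- dplyr::mutate(
      paired_t(t1$threshold[order(t1$participant)],
               t2$threshold[order(t2$participant)], tail = "greater"),
      test = "discrimination threshold pre > post")
  }
  tt$tlx_mental <- dplyr::mutate(
    paired_t(wide(ses, "tlx_mental", s_first),
             wide(ses, "tlx_mental", s_last), tail = "greater"),
    test = "mental demand S_first > S_last")
  fz <- erp[erp$electrode == "Fz", ]
  tt$nt_shift <- dplyr::mutate(
    paired_t(wide(fz, "nontarget_late_fz", s_first),
             wide(fz, "nontarget_late_fz", s_last), tail = "greater"),
    test = "late non-target Fz shift toward negative")
  t_tests <- dplyr::bind_rows(tt)

  power_fit <- fit_power_law(
    dplyr::transmute(ses, session = .data$session,
                     accuracy = .data$copy_accuracy / 100))

  mean_acc <- ses |>
    dplyr::summarise(copy = mean(.data$copy_accuracy),
                     dual = mean(.data$dual_accuracy, na.rm = TRUE),
                     .by = "session") |>
    dplyr::filter(.data$session %in% result$config$dual_sessions)
  dual_impact <- dplyr::bind_cols(
    tibble::tibble(session = mean_acc$session),
    dual_task_impact(mean_acc$copy, mean_acc$dual))

  spm <- selections_per_minute(result$config$paradigm)
  itr_tbl <- ses |>
    dplyr::reframe(aggregate_itr(.data$copy_accuracy / 100,
                                 N = result$config$paradigm$n_positions,
                                 SPM = spm),
                   .by = "session")

  correlations <- thr |>
    dplyr::inner_join(ses, by = c("participant", "session")) |>
    dplyr::reframe(pearson_r(.data$threshold, .data$copy_accuracy),
                   .by = "session")

  list(included = screen, anova = anova, t_tests = t_tests,
       power_fit = power_fit, dual_impact = dual_impact, itr = itr_tbl,
       correlations = correlations)
}

#' Write study summary tables as TSV
#'
#' Emits the per-session ERP feature table, the dual-task table, the
#' workload table and the threshold table of a study into a directory.
#'
#' @param result A `study_result`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_tables <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(result$erp, file.path(dir, "table1_erp.tsv"))
  dual <- dplyr::filter(result$sessions, !is.na(.data$dual_accuracy))
  readr::write_tsv(dual, file.path(dir, "table2_dual.tsv"))
  readr::write_tsv(
    dplyr::select(result$sessions, "participant", "session",
                  dplyr::starts_with("tlx")),
    file.path(dir, "table3_tlx.tsv"))
  readr::write_tsv(result$thresholds, file.path(dir, "thresholds.tsv"))
  invisible(dir)
}

#' Plot session-wise accuracy of a study
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.study_result <- function(object, ...) {
  df <- object$sessions |>
    tidyr::pivot_longer(c("copy_accuracy", "dual_accuracy"),
                        names_to = "task", values_to = "accuracy") |>
    dplyr::filter(!is.na(.data$accuracy)) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     sem = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
                     .by = c("session", "task"))
  ggplot2::ggplot(df, ggplot2::aes(.data$session, .data$mean,
                                   colour = .data$task)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::geom_hline(yintercept = 25, linetype = 3) +
    ggplot2::labs(x = "Session", y = "Accuracy (%)", colour = NULL) +
    ggplot2::theme_minimal()
}
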