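# SWLDA decoding: time-binned feature construction, stepwise linear
# discriminant training (forward/backward stepwise regression on +/-1
# labels with partial-F entry/removal tests), epoch scoring, and the
# N-choice selection decision rule.

#' Build a time-binned feature matrix from epochs
#'
#' Each feature is the mean amplitude of one channel over one post-stimulus
#' time bin (default 50 ms bins over 0-800 ms: 12 channels x 16 bins = 192
#' features at the standard montage). Feature ordering is channel-major,
#' time-minor: channel 1 bins 1..K, then channel 2, and so on. Rejected
#' epochs are excluded.
#'
#' @param epochs An `epoch_set`.
#' @param bin_width Bin width in ms.
#' @param window Post-stimulus window in ms over which bins are laid out;
#'   a trailing partial bin is dropped.
#' @return An object of class `feature_matrix`: list with `x` (epochs x
#'   features), `labels` (+1 target / -1 non-target), `info` (metadata of
#'   retained epochs), `layout` (tibble: `feature`, `channel`, `bin`,
#'   `bin_start_ms`, `bin_end_ms`).
#' @export
build_features <- function(epochs, bin_width = 50, window = c(0, 800)) {
  stopifnot(inherits(epochs, "epoch_set"), bin_width > 0)
  keep <- !epochs$info$rejected
  if (!any(keep)) stop("all epochs rejected; no features to build")
  n_bins <- floor((window[2] - window[1]) / bin_width)
  if (n_bins < 1) stop("bin_width larger than the feature window")
  n_ch <- length(epochs$channel_labels)
  kept_idx <- which(keep)

  bin_of <- floor((epochs$time_ms - window[1]) / bin_width)
  sample_sel <- lapply(seq_len(n_bins) - 1L, function(b) {
    which(bin_of == b & epochs$time_ms >= window[1])
  })
  if (any(lengths(sample_sel) == 0)) stop("empty time bin; bin_width too small for the sampling rate")

  x <- matrix(NA_real_, nrow = length(kept_idx), ncol = n_ch * n_bins)
  for (i in seq_along(kept_idx)) {
    seg <- epochs$epochs[kept_idx[i], , , drop = TRUE]  # ch x sample
    binned <- vapply(sample_sel, function(s) rowMeans(seg[, s, drop = FALSE]),
                     numeric(n_ch))                     # ch x bin
    x[i, ] <- as.vector(t(binned))                      # channel-major
  }
  layout <- tibble::tibble(
    feature = seq_len(n_ch * n_bins),
    channel = rep(epochs$channel_labels, each = n_bins),
    bin = rep(seq_len(n_bins), times = n_ch),
    bin_start_ms = window[1] + (rep(seq_len(n_bins), times = n_ch) - 1) * bin_width,
    bin_end_ms = window[1] + rep(seq_len(n_bins), times = n_ch) * bin_width)
  structure(
    list(x = x,
         labels = ifelse(epochs$info$is_target[kept_idx], 1, -1),
         info = epochs$info[kept_idx, ],
         layout = layout,
         bin_width = bin_width,
         window = window),
    class = "feature_matrix")
}

# partial-F p-values for adding each candidate column to the current model.
# Q: thin Q of the current design (including intercept), res: current
# residuals, rss: current RSS, n, p_cur: current number of columns.
step_entry_pvalues <- function(x_cand, Q, res, rss, n, p_cur) {
  rx <- x_cand - Q %*% crossprod(Q, x_cand)
  denom_df <- n - p_cur - 1
  ss <- colSums(rx^2)
  gain <- drop(crossprod(rx, res))^2 / ss
  gain[ss < 1e-12] <- 0  # collinear with current model: no gain
  f <- gain / ((rss - gain) / denom_df)
  f[!is.finite(f) | f < 0] <- 0
  stats::pf(f, 1, denom_df, lower.tail = FALSE)
}

#' Train a stepwise linear discriminant (SWLDA) model
#'
#' Classic SWLDA: ordinary least-squares regression of +/-1 class labels on
#' features, with stepwise feature selection. The forward step adds the
#' candidate with the smallest partial-F p-value if it is below `p_enter`;
#' the backward step removes any included feature whose p-value exceeds
#' `p_remove`; the two alternate until the selected set is stable or
#' `max_features` is reached. Final weights are the least-squares
#' coefficients of the labels on the selected features.
#'
#' @param features A `feature_matrix` from [build_features()].
#' @param p_enter Significance level to enter a feature.
#' @param p_remove Significance level to remove a feature.
#' @param max_features Maximum number of selected features.
#' @return An object of class `swlda_model`: `selected` (ordered feature
#'   indices), `weights`, `intercept`, hyperparameters and the feature
#'   layout.
#' @examples
#' \donttest{
#' cfg <- paradigm_config(calib_runs = 1, calib_selections_per_run = 4)
#' sch <- lapply(1:4, function(i)
#'   generate_selection_schedule(cfg, "front", seed = i))
#' rec <- bandpass_offline(generate_run_eeg(sch, erp_gen_params(), cfg, seed = 1))
#' fm <- build_features(reject_artifacts(extract_epochs(rec)))
#' m <- train_swlda(fm)
#' length(m$selected)
#' }
#' @export
train_swlda <- function(features, p_enter = 0.10, p_remove = 0.15,
                        max_features = 60) {
  stopifnot(inherits(features, "feature_matrix"))
  if (p_enter > p_remove) {
    warning("p_enter > p_remove may cause cycling; proceeding anyway")
  }
  x <- features$x
  y <- features$labels
  n <- nrow(x)
  if (min(sum(y > 0), sum(y < 0)) < 2) stop("need at least 2 epochs per class")

  selected <- integer(0)
  repeat {
    changed <- FALSE
    # forward step
    if (length(selected) < max_features) {
      cand <- setdiff(seq_len(ncol(x)), selected)
      X_cur <- cbind(1, x[, selected, drop = FALSE])
      qr_cur <- qr(X_cur)
      Q <- qr.Q(qr_cur)
      res <- y - Q %*% crossprod(Q, y)
      rss <- sum(res^2)
      pvals <- step_entry_pvalues(x[, cand, drop = FALSE], Q, res, rss, n,
                                  ncol(X_cur))
      best <- which.min(pvals)
      if (length(best) && pvals[best] < p_enter) {
        selected <- c(selected, cand[best])
        changed <- TRUE
      }
    }
    # backward step: drop every included feature with p > p_remove
    if (length(selected) > 1) {
      repeat {
        X <- cbind(1, x[, selected, drop = FALSE])
        xtx <- crossprod(X)
        xtxi <- solve(xtx)
        coefs <- drop(xtxi %*% crossprod(X, y))
        rss <- sum((y - X %*% coefs)^2)
        df_res <- n - ncol(X)
        se <- sqrt(diag(xtxi) * rss / df_res)
        tv <- coefs / se
        pv <- 2 * stats::pt(abs(tv), df_res, lower.tail = FALSE)
        pv_feat <- pv[-1]
        worst <- which.max(pv_feat)
        if (length(worst) && is.finite(pv_feat[worst]) &&
            pv_feat[worst] > p_remove) {
          selected <- selected[-worst]
          changed <- TRUE
        } else break
        if (length(selected) <= 1) break
      }
    }
    if (!changed || length(selected) >= max_features) break
  }
  if (length(selected) == 0) {
    stop("no feature reached p_enter = ", p_enter,
         "; calibration data appear untrainable (consider relaxing p_enter)")
  }
  X <- cbind(1, x[, selected, drop = FALSE])
  coefs <- stats::lm.fit(X, y)$coefficients
  structure(
    list(selected = selected,
         weights = unname(coefs[-1]),
         intercept = unname(coefs[1]),
         p_enter = p_enter, p_remove = p_remove, max_features = max_features,
         n_features_total = ncol(x),
         layout = features$layout[features$layout$feature %in% selected, ]),
    class = "swlda_model")
}

#' @export
print.swlda_model <- function(x, ...) {
  cat(sprintf("<swlda_model> %d/%d features selected (p_enter %.2g, p_remove %.2g)\n",
              length(x$selected), x$n_features_total, x$p_enter, x$p_remove))
  invisible(x)
}

#' @rdname train_swlda
#' @param x An `swlda_model`.
#' @param ... Unused.
#' @export
tidy.swlda_model <- function(x, ...) {
  out <- tibble::tibble(feature = x$selected, weight = x$weights,
                        step = seq_along(x$selected))
  dplyr::left_join(out, x$layout, by = "feature")
}

#' @rdname train_swlda
#' @export
glance.swlda_model <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 n_features_total = x$n_features_total,
                 intercept = x$intercept,
                 p_enter = x$p_enter, p_remove = x$p_remove,
                 max_features = x$max_features)
}

#' Score epochs with an SWLDA model
#'
#' Linear score `intercept + x[selected] . weights`; higher means more
#' target-like.
#'
#' @param model An `swlda_model`.
#' @param feature_rows A numeric vector (one epoch) or matrix (epochs x
#'   features) in the training feature layout, or a `feature_matrix`.
#' @return Numeric score vector.
#' @export
score_epoch <- function(model, feature_rows) {
  stopifnot(inherits(model, "swlda_model"))
  if (inherits(feature_rows, "feature_matrix")) feature_rows <- feature_rows$x
  if (is.vector(feature_rows)) feature_rows <- matrix(feature_rows, nrow = 1)
  if (ncol(feature_rows) != model$n_features_total) {
    stop("feature row length ", ncol(feature_rows),
         " does not match training layout (", model$n_features_total, ")")
  }
  drop(model$intercept +
         feature_rows[, model$selected, drop = FALSE] %*% model$weights)
}

#' Classify one selection from its epochs
#'
#' Sums epoch scores per stimulus position over the sequences of one
#' selection and predicts the argmax position. Exact ties are broken by the
#' fixed position order (front, back, left, right) and flagged.
#'
#' @param model An `swlda_model`.
#' @param features A `feature_matrix` whose epochs all belong to one
#'   selection (grouped by stimulus position).
#' @param true_position The cued target position, if known.
#' @return A one-row tibble: `true_position`, `predicted`, `correct`,
#'   `tie`, plus one `score_*` column per position.
#' @export
classify_selection <- function(model, features, true_position = NA_character_) {
  stopifnot(inherits(features, "feature_matrix"))
  scores <- score_epoch(model, features)
  positions <- intersect(tactor_positions, unique(features$info$position))
  if (length(positions) == 0) stop("no position groups present")
  missing_pos <- setdiff(unique(features$info$position), positions)
  sums <- vapply(positions,
                 function(p) sum(scores[features$info$position == p]),
                 numeric(1))
  best <- max(sums)
  winners <- positions[sums == best]
  predicted <- winners[1]  # fixed-order tie-break
  out <- tibble::tibble(
    true_position = true_position,
    predicted = predicted,
    correct = if (is.na(true_position)) NA else predicted == true_position,
    tie = length(winners) > 1)
  score_cols <- tibble::as_tibble(as.list(stats::setNames(sums, paste0("score_", positions))))
  dplyr::bind_cols(out, score_cols)
}

#' Bits per selection (Wolpaw information content)
#'
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`, with the
#' `P = 0` and `P = 1` limits taken by continuity. For `P < 1/N` the
#' formula is negative; the value is returned as-is (flagged via attribute
#' `below_chance`).
#'
#' @param P Selection accuracy in \[0, 1\] (vectorized).
#' @param N Number of alternatives (>= 2).
#' @return Bits per selection.
#' @examples
#' bits_per_selection(c(0.25, 1), 4)  # 0 and 2
#' @export
bits_per_selection <- function(P, N = 4) {
  stopifnot(all(P >= 0), all(P <= 1), N >= 2)
  term_p <- ifelse(P == 0, 0, P * log2(P))
  term_q <- ifelse(P == 1, 0, (1 - P) * log2((1 - P) / (N - 1)))
  b <- log2(N) + term_p + term_q
  attr(b, "below_chance") <- P < 1 / N
  b
}

#' Information transfer rate
#'
#' ITR in bits/min: bits per selection times selections per minute.
#'
#' @param B Bits per selection.
#' @param SPM Selections per minute (> 0).
#' @return Bits per minute.
#' @export
itr <- function(B, SPM) {
  stopifnot(all(SPM > 0))
  as.numeric(B) * SPM
}

#' Aggregate ITR across participants
#'
#' Computes each participant's ITR from their own accuracy first, then
#' averages — the convention under which a group-mean ITR carries an SD.
#' (Applying the bits formula to the group-mean accuracy instead gives a
#' different, generally lower number because B is convex near the top of
#' its range.)
#'
#' @param P Vector of per-participant accuracies in \[0, 1\].
#' @param N Number of alternatives.
#' @param SPM Selections per minute.
#' @return A one-row tibble: `mean_itr`, `sd_itr`, `n`.
#' @export
aggregate_itr <- function(P, N = 4, SPM = 3) {
  itrs <- itr(bits_per_selection(P, N), SPM)
  tibble::tibble(mean_itr = mean(itrs),
                 sd_itr = stats::sd(itrs),
                 n = length(itrs))
}

#' Serialize / deserialize an SWLDA model as JSON
#'
#' @param model An `swlda_model`.
#' @param path File path.
#' @return `path` invisibly, or the model for the reader.
#' @export
write_swlda_json <- function(model, path) {
  stopifnot(inherits(model, "swlda_model"))
  obj <- list(selected = model$selected, weights = model$weights,
              intercept = model$intercept,
              p_enter = model$p_enter, p_remove = model$p_remove,
              max_features = model$max_features,
              n_features_total = model$n_features_total,
              layout = model$layout)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_swlda_json
#' @export
read_swlda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(selected = as.integer(obj$selected), weights = obj$weights,
         intercept = obj$intercept, p_enter = obj$p_enter,
         p_remove = obj$p_remove, max_features = obj$max_features,
         n_features_total = as.integer(obj$n_features_total),
         layout = tibble::as_tibble(obj$layout)),
    class = "swlda_model")
}
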