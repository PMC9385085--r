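# Adaptive two-interval forced-choice intensity discrimination and sigmoid
# threshold estimation. Stimulus pairs are a 100% reference vs. a
# comparison at 50-100%; the working variable throughout is the intensity
# DIFFERENCE in percent (0-50 in 5% steps), so a difference of 0 means
# identical stimuli.

#' Run the adaptive intensity-discrimination procedure on an observer
#'
#' Phase 1 samples every difference on the 5% grid (0-50%) a fixed number
#' of times in pseudo-random order. Phase 2 locates the mixed-response
#' range (differences where both "equal" and "unequal" occurred), re-tests
#' it more frequently, and extends in 5% steps to either side until each
#' flanking difference shows a clear consensus: a response ratio of at
#' least `consensus_ratio`:1 over at least `min_consensus_trials` trials.
#' The total number of trials is therefore data-dependent, bounded by
#' `max_trials`.
#'
#' @param observer An [observer_model()].
#' @param seed Integer seed.
#' @param grid Tested intensity differences in percent.
#' @param phase1_reps Trials per grid difference in phase 1.
#' @param consensus_ratio Required majority ratio at a flanking difference.
#' @param min_consensus_trials Minimum trials at a flank before consensus
#'   can be declared.
#' @param max_trials Trial budget; if exhausted before consensus the
#'   dataset is returned with `converged_range = FALSE`.
#' @return An object of class `psychometric_dataset`: list with `trials`
#'   (tibble: `trial`, `difference_pct`, `response`), `n_trials`,
#'   `converged_range`.
#' @examples
#' obs <- observer_model(true_threshold = 25, slope = 3)
#' ds <- run_adaptive_procedure(obs, seed = 7)
#' ds$n_trials
#' @export
run_adaptive_procedure <- function(observer, seed,
                                   grid = seq(0, 50, by = 5),
                                   phase1_reps = 2,
                                   consensus_ratio = 4,
                                   min_consensus_trials = 5,
                                   max_trials = 120) {
  stopifnot(inherits(observer, "observer_model"))
  withr_seed(seed)
  grid <- sort(grid)
  log_diff <- numeric(0)
  log_resp <- character(0)

  present <- function(d) {
    r <- simulate_observer_response(observer, d)
    log_diff <<- c(log_diff, d)
    log_resp <<- c(log_resp, r)
  }
  counts <- function() {
    tab <- table(factor(log_diff, levels = grid),
                 factor(log_resp, levels = c("equal", "unequal")))
    list(eq = tab[, "equal"], uneq = tab[, "unequal"],
         n = rowSums(tab))
  }
  has_consensus <- function(d) {
    ct <- counts()
    i <- match(d, grid)
    n <- ct$n[i]
    if (n < min_consensus_trials) return(FALSE)
    max(ct$eq[i], ct$uneq[i]) >= consensus_ratio * min(ct$eq[i], ct$uneq[i])
  }

  # phase 1: pseudo-random coverage of the whole grid
  for (d in sample(rep(grid, phase1_reps))) present(d)

  # phase 2: re-test the mixed range and consolidate its flanks
  repeat {
    if (length(log_diff) >= max_trials) break
    ct <- counts()
    mixed <- grid[ct$eq > 0 & ct$uneq > 0]
    if (length(mixed) == 0) {
      # step-like data: flanks are the boundary of the equal/unequal split
      hi_eq <- suppressWarnings(max(grid[ct$eq > 0 & ct$uneq == 0]))
      lo_un <- suppressWarnings(min(grid[ct$uneq > 0 & ct$eq == 0]))
      focus <- grid[is.finite(hi_eq) & is.finite(lo_un) &
                      grid >= hi_eq & grid <= lo_un]
      if (length(focus) == 0) focus <- grid
    } else {
      lo <- max(grid[grid < min(mixed)], min(grid))
      hi <- min(grid[grid > max(mixed)], max(grid))
      focus <- grid[grid >= lo & grid <= hi]
      flanks <- c(lo, hi)
      if (all(vapply(flanks, has_consensus, logical(1)))) break
    }
    if (length(mixed) == 0) {
      # without a mixed range, stop once the split boundary is consolidated
      if (length(focus) <= 2 && all(vapply(focus, has_consensus, logical(1)))) break
    }
    for (d in sample(focus, min(length(focus), max_trials - length(log_diff)))) {
      present(d)
      if (length(log_diff) >= max_trials) break
    }
  }

  converged <- {
    ct <- counts()
    mixed <- grid[ct$eq > 0 & ct$uneq > 0]
    if (length(mixed) == 0) TRUE
    else {
      lo <- max(grid[grid < min(mixed)], min(grid))
      hi <- min(grid[grid > max(mixed)], max(grid))
      all(vapply(c(lo, hi), has_consensus, logical(1)))
    }
  }
  structure(
    list(trials = tibble::tibble(trial = seq_along(log_diff),
                                 difference_pct = log_diff,
                                 response = log_resp),
         n_trials = length(log_diff),
         converged_range = converged),
    class = "psychometric_dataset")
}

#' @export
print.psychometric_dataset <- function(x, ...) {
  cat(sprintf("<psychometric_dataset> %d trials, range %s\n", x$n_trials,
              if (x$converged_range) "converged" else "NOT converged"))
  invisible(x)
}

#' Equal-response ratio per intensity difference
#'
#' Projects the response tallies onto a 0-1 scale: the fraction of trials
#' at each tested difference answered "equal" (1 = always equal, 0 = never).
#' Untested differences are omitted. Invariant to trial order.
#'
#' @param dataset A `psychometric_dataset`, or a data frame with columns
#'   `difference_pct` and `response` ("equal"/"unequal").
#' @return A tibble: `difference_pct`, `n_equal`, `n_unequal`, `n`,
#'   `equal_ratio`.
#' @export
equal_ratio <- function(dataset) {
  trials <- if (inherits(dataset, "psychometric_dataset")) dataset$trials
            else tibble::as_tibble(dataset)
  trials |>
    dplyr::summarise(n_equal = sum(.data$response == "equal"),
                     n_unequal = sum(.data$response == "unequal"),
                     .by = "difference_pct") |>
    dplyr::mutate(n = .data$n_equal + .data$n_unequal,
                  equal_ratio = .data$n_equal / .data$n) |>
    dplyr::arrange(.data$difference_pct)
}

#' Estimate the discrimination threshold from ratio points
#'
#' Fits a decreasing logistic
#' `ratio(d) = 1 / (1 + exp((d - midpoint) / slope))` to the equal-response
#' ratios by nonlinear least squares; the midpoint (ratio 0.5) is the
#' discrimination threshold. If the data are step-like — no ratio strictly
#' between 0 and 1, so a sigmoid has no leverage — the threshold is instead
#' placed midway between the largest all-equal and the smallest all-unequal
#' difference (`method = "manual_midpoint"`), the deterministic analogue of
#' estimating such distinct thresholds by hand.
#'
#' @param ratio_points A tibble from [equal_ratio()] (or any data frame
#'   with `difference_pct` and `equal_ratio`), or a `psychometric_dataset`.
#' @return An object of class `threshold_fit`: `midpoint` (% difference),
#'   `slope`, `method` ("sigmoid" or "manual_midpoint"), `converged`,
#'   `ratio_points`.
#' @examples
#' obs <- observer_model(true_threshold = 25, slope = 3)
#' fit <- fit_threshold(run_adaptive_procedure(obs, seed = 1))
#' fit$midpoint
#' @export
fit_threshold <- function(ratio_points) {
  if (inherits(ratio_points, "psychometric_dataset")) {
    ratio_points <- equal_ratio(ratio_points)
  }
  rp <- tibble::as_tibble(ratio_points)
  stopifnot(all(c("difference_pct", "equal_ratio") %in% names(rp)))
  rp <- dplyr::arrange(rp, .data$difference_pct)
  if (nrow(rp) < 2) stop("need at least 2 ratio points")
  if (length(unique(rp$equal_ratio)) == 1) {
    stop("all ratio points identical; threshold is undetermined")
  }

  step_like <- !any(rp$equal_ratio > 0 & rp$equal_ratio < 1)
  if (step_like) {
    hi_eq <- max(rp$difference_pct[rp$equal_ratio == 1])
    lo_un <- min(rp$difference_pct[rp$equal_ratio == 0])
    fit <- list(midpoint = (hi_eq + lo_un) / 2, slope = NA_real_,
                method = "manual_midpoint", converged = TRUE)
  } else {
    # start: interpolated 0.5 crossing
    below <- rp$difference_pct[rp$equal_ratio <= 0.5]
    start_mid <- if (length(below)) min(below) else max(rp$difference_pct)
    d <- rp$difference_pct
    r <- rp$equal_ratio
    w <- rp$n %||% rep(1, nrow(rp))
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(r ~ 1 / (1 + exp((d - midpoint) / slope)),
                        start = list(midpoint = start_mid, slope = 3),
                        weights = w,
                        lower = c(midpoint = min(d), slope = 0.1),
                        upper = c(midpoint = max(d), slope = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(nls_fit)) {
      # fall back to the interpolated crossing, flagged as non-converged
      fit <- list(midpoint = start_mid, slope = NA_real_,
                  method = "sigmoid", converged = FALSE)
    } else {
      cf <- stats::coef(nls_fit)
      fit <- list(midpoint = unname(cf["midpoint"]),
                  slope = unname(cf["slope"]),
                  method = "sigmoid", converged = TRUE)
    }
  }
  structure(c(fit, list(ratio_points = rp)), class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> midpoint %.2f%% (%s%s)\n", x$midpoint,
              x$method, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @rdname fit_threshold
#' @param x A `threshold_fit`.
#' @param ... Unused.
#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(midpoint = x$midpoint, slope = x$slope, method = x$method,
                 converged = x$converged,
                 n_points = nrow(x$ratio_points))
}

#' @rdname fit_threshold
#' @param object A `threshold_fit`.
#' @export
autoplot.threshold_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$ratio_points,
                       ggplot2::aes(.data$difference_pct, .data$equal_ratio)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$midpoint, linetype = 2,
                        colour = "steelblue") +
    ggplot2::labs(x = "Intensity difference (%)",
                  y = "P(equal)", size = "Trials") +
    ggplot2::theme_minimal()
  if (object$method == "sigmoid" && is.finite(object$slope)) {
    grid <- tibble::tibble(
      difference_pct = seq(min(object$ratio_points$difference_pct),
                           max(object$ratio_points$difference_pct),
                           length.out = 200))
    grid$equal_ratio <- 1 / (1 + exp((grid$difference_pct - object$midpoint) /
                                       object$slope))
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Write a psychometric trial log as TSV
#'
#' @param dataset A `psychometric_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "psychometric_dataset"))
  readr::write_tsv(dataset$trials, path)
  invisible(path)
}
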