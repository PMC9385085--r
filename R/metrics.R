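# Study-level derived metrics: dual-task impact factors, absolute
# physiological differences, the power-law learning curve, and NASA-TLX
# workload aggregation.

#' Relative dual-task impact on accuracy
#'
#' The relative accuracy difference between dual and copy task,
#' `(P_dual - P_copy) / P_copy`: a factor of -0.12 means the dual task cost
#' 12% of the copy-task accuracy. Scale-invariant, so percentages and
#' proportions give the same factor.
#'
#' @param P_copy Copy-task accuracy (> 0), in % or proportion (vectorized).
#' @param P_dual Dual-task accuracy on the same scale.
#' @param digits Decimals for the reported factor (default 2, the
#'   conventional print precision).
#' @return A tibble: `P_copy`, `P_dual`, `delta_relative` (rounded) and
#'   `delta_relative_raw`.
#' @examples
#' dual_task_impact(79.2, 69.5)$delta_relative  # -0.12
#' @export
dual_task_impact <- function(P_copy, P_dual, digits = 2) {
  if (any(P_copy <= 0)) stop("P_copy must be positive")
  delta <- (P_dual - P_copy) / P_copy
  tibble::tibble(P_copy = P_copy, P_dual = P_dual,
                 delta_relative = round(delta, digits),
                 delta_relative_raw = delta)
}

#' Absolute dual-task impact on a physiological measure
#'
#' Physiological ERP measures (amplitudes, curve differences) can be
#' negative, which makes a relative factor misleading; the impact is
#' therefore the simple subtraction `dual - copy` in microvolts.
#'
#' @param metric_copy,metric_dual Measures (microvolts) from copy and dual
#'   runs (vectorized).
#' @return A tibble: `metric_copy`, `metric_dual`, `delta_absolute`.
#' @examples
#' physio_impact(3.03, 3.98)$delta_absolute  # +0.95
#' @export
physio_impact <- function(metric_copy, metric_dual) {
  tibble::tibble(metric_copy = metric_copy, metric_dual = metric_dual,
                 delta_absolute = metric_dual - metric_copy)
}

#' Fit a power-law learning curve
#'
#' Fits `accuracy = a * session^b` by nonlinear least squares (initialized
#' from the log-log OLS solution), the standard power-law-of-practice model
#' for training data. The F statistic tests the model against the
#' constant-mean model with (1, n-2) degrees of freedom; with 145
#' session-accuracy observations this gives the familiar (1, 143) pattern.
#' On non-convergence the log-log closed form is returned, flagged.
#'
#' @param data Data frame with the observation columns.
#' @param session,accuracy Column names (strings) of session index and
#'   accuracy; accuracies must be positive.
#' @param asymptote If `TRUE`, fits the 3-parameter variant
#'   `c + a * session^b`. Not the default: five sessions constrain three
#'   parameters poorly.
#' @return An object of class `learning_curve_fit` with `tidy()` /
#'   `glance()` methods; `glance()` reports `a`, `b`, `r_squared`,
#'   `statistic` (F), `df`, `df_residual`, `p_value`, `converged`.
#' @examples
#' d <- data.frame(session = 1:5, accuracy = 0.8 * (1:5)^0.1)
#' glance(fit_power_law(d))
#' @export
fit_power_law <- function(data, session = "session", accuracy = "accuracy",
                          asymptote = FALSE) {
  x <- data[[session]]
  y <- data[[accuracy]]
  if (length(unique(x)) < 2) stop("need >= 2 distinct sessions")
  if (any(y <= 0)) stop("accuracies must be positive to fit a power model")
  n <- length(y)

  loglog <- stats::lm(log(y) ~ log(x))
  start <- list(a = exp(stats::coef(loglog)[[1]]), b = stats::coef(loglog)[[2]])
  converged <- TRUE
  if (asymptote) start <- c(list(c = 0), start)
  form <- if (asymptote) y ~ c + a * x^b else y ~ a * x^b
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(x = x, y = y), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    converged <- FALSE
    coefs <- c(a = start$a, b = start$b)
    if (asymptote) coefs <- c(c = 0, coefs)
    fitted_y <- if (asymptote) coefs[["c"]] + coefs[["a"]] * x^coefs[["b"]]
                else coefs[["a"]] * x^coefs[["b"]]
  } else {
    coefs <- stats::coef(fit)
    fitted_y <- stats::fitted(fit)
  }
  rss <- sum((y - fitted_y)^2)
  tss <- sum((y - mean(y))^2)
  n_par <- length(coefs)
  df1 <- n_par - 1
  df2 <- n - n_par
  f_stat <- if (rss == 0) Inf else ((tss - rss) / df1) / (rss / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  structure(
    list(coefficients = coefs,
         data = tibble::tibble(session = x, accuracy = y, fitted = fitted_y),
         r_squared = if (tss == 0) NA_real_ else 1 - rss / tss,
         statistic = f_stat, df = df1, df_residual = df2, p_value = p,
         converged = converged, asymptote = asymptote),
    class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat("<learning_curve_fit> accuracy ~ ",
      if (x$asymptote) "c + a * session^b" else "a * session^b", "\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g, R2 = %.3f%s\n",
              x$df, x$df_residual, x$statistic, x$p_value, x$r_squared,
              if (x$converged) "" else " [log-log fallback]"))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x A `learning_curve_fit`.
#' @param ... Unused.
#' @export
tidy.learning_curve_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_power_law
#' @export
glance.learning_curve_fit <- function(x, ...) {
  tibble::tibble(a = x$coefficients[["a"]], b = x$coefficients[["b"]],
                 r_squared = x$r_squared, statistic = x$statistic,
                 df = x$df, df_residual = x$df_residual,
                 p_value = x$p_value, converged = x$converged)
}

#' @rdname fit_power_law
#' @param object A `learning_curve_fit`.
#' @export
autoplot.learning_curve_fit <- function(object, ...) {
  grid <- tibble::tibble(
    session = seq(min(object$data$session), max(object$data$session),
                  length.out = 100))
  cf <- object$coefficients
  grid$fitted <- if (object$asymptote) {
    cf[["c"]] + cf[["a"]] * grid$session^cf[["b"]]
  } else cf[["a"]] * grid$session^cf[["b"]]
  ggplot2::ggplot(object$data, ggplot2::aes(.data$session, .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.05, height = 0, alpha = 0.4) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "Session", y = "Accuracy") +
    ggplot2::theme_minimal()
}

tlx_subscales <- c("mental", "physical", "temporal", "performance",
                   "effort", "frustration")

#' Aggregate a NASA-TLX questionnaire
#'
#' Computes the weighted global workload score from six subscale ratings
#' (0-100) and six pairwise-comparison weights (0-5, summing to 15): each
#' subscale contributes `rating * weight / 15`, the total is the sum of
#' contributions, and the raw score is the unweighted mean of ratings.
#'
#' @param ratings Numeric vector of six subscale ratings in \[0, 100\], in
#'   the order mental, physical, temporal, performance, effort,
#'   frustration (names, if present, are honored).
#' @param weights Six pairwise-comparison tallies in \[0, 5\] summing
#'   to 15, same order.
#' @return A one-row tibble: one `contrib_*` column per subscale, `total`,
#'   `raw`.
#' @examples
#' tlx_aggregate(rep(50, 6), c(5, 1, 2, 2, 3, 2))
#' @export
tlx_aggregate <- function(ratings, weights) {
  stopifnot(length(ratings) == 6, length(weights) == 6)
  if (!is.null(names(ratings))) ratings <- ratings[tlx_subscales]
  if (!is.null(names(weights))) weights <- weights[tlx_subscales]
  if (any(ratings < 0 | ratings > 100)) stop("ratings must lie in [0, 100]")
  if (any(weights < 0 | weights > 5) || sum(weights) != 15) {
    stop("weights must lie in [0, 5] and sum to 15")
  }
  contributions <- ratings * weights / 15
  out <- tibble::as_tibble(as.list(stats::setNames(
    contributions, paste0("contrib_", tlx_subscales))))
  out$total <- sum(contributions)
  out$raw <- mean(ratings)
  out
}
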