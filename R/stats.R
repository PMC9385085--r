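# The within-subject statistical battery: repeated-measures ANOVA with
# Greenhouse-Geisser correction and partial eta squared, one- and
# two-tailed paired t tests with Cohen's d_z, Pearson correlations, and
# the BCI-efficiency screening rule.

# orthonormal polynomial-free contrast matrix (k x (k-1)) spanning the
# effect space of a k-level within factor
orth_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  qr.Q(qr(cm))
}

# one within-subject effect: Y (n x p) condition scores, M (p x q)
# orthonormal contrast for that effect
gg_effect <- function(Y, M, effect) {
  n <- nrow(Y)
  Z <- Y %*% M                    # n x q effect scores
  q <- ncol(Z)
  zbar <- colMeans(Z)
  ss_eff <- n * sum(zbar^2)
  ss_err <- sum(sweep(Z, 2, zbar)^2)
  df1 <- q
  df2 <- q * (n - 1)
  f <- (ss_eff / df1) / (ss_err / df2)
  S <- stats::cov(Z)
  eps <- if (q == 1) 1 else sum(diag(S))^2 / (q * sum(S^2))
  eps <- min(max(eps, 1 / q), 1)
  df1_gg <- eps * df1
  df2_gg <- eps * df2
  tibble::tibble(
    effect = effect,
    F = f,
    df1 = df1_gg,
    df2 = df2_gg,
    df1_uncorrected = df1,
    df2_uncorrected = df2,
    epsilon = eps,
    p_value = stats::pf(f, df1_gg, df2_gg, lower.tail = FALSE),
    eta_p2 = ss_eff / (ss_eff + ss_err))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA for one or two repeated factors on a long
#' data frame. Each effect is tested on its orthonormal contrast scores;
#' the Greenhouse-Geisser epsilon is the box estimator on the covariance of
#' those scores, computed per effect, and both degrees of freedom are
#' multiplied by epsilon. Effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`. The design must be complete and
#' balanced (one observation per participant x condition cell); unbalanced
#' data raise an error rather than being imputed.
#'
#' @param data Long data frame.
#' @param value Column name (string) of the dependent variable.
#' @param participant Column identifying participants.
#' @param within Character vector of one or two within-factor column names
#'   (e.g. `c("session", "electrode")`).
#' @return A tibble of class `rm_anova_gg` with one row per effect
#'   (main effects and, for two factors, their interaction): `effect`,
#'   `F`, corrected `df1`/`df2`, uncorrected df, `epsilon`, `p_value`,
#'   `eta_p2`.
#' @examples
#' d <- expand.grid(id = 1:8, session = 1:5)
#' d$y <- rnorm(nrow(d)) + 0.3 * d$session
#' rm_anova_gg(d, "y", "id", "session")
#' @export
rm_anova_gg <- function(data, value, participant, within) {
  stopifnot(length(within) %in% 1:2)
  df <- tibble::as_tibble(data)
  for (w in within) df[[w]] <- factor(df[[w]])
  df[[participant]] <- factor(df[[participant]])

  cells <- table(df[[participant]], interaction(df[, within, drop = FALSE]))
  if (any(cells != 1)) {
    stop("design must be complete and balanced: exactly one observation per ",
         "participant x condition cell")
  }
  n <- nlevels(df[[participant]])
  if (n < 2) stop("need at least 2 participants")

  # wide matrix of condition scores, columns ordered by the factor levels
  # (first factor varying slowest)
  if (length(within) == 1) {
    lv <- levels(df[[within[1]]])
    key <- df[[within[1]]]
    cond_levels <- lv
  } else {
    lv1 <- levels(df[[within[1]]]); lv2 <- levels(df[[within[2]]])
    key <- interaction(df[[within[1]]], df[[within[2]]], lex.order = TRUE)
    cond_levels <- levels(key)
  }
  Y <- matrix(NA_real_, nrow = n, ncol = length(cond_levels),
              dimnames = list(levels(df[[participant]]), cond_levels))
  Y[cbind(as.integer(df[[participant]]), match(key, cond_levels))] <- df[[value]]

  if (length(within) == 1) {
    k <- length(cond_levels)
    out <- gg_effect(Y, orth_contrasts(k), within[1])
  } else {
    k1 <- nlevels(df[[within[1]]]); k2 <- nlevels(df[[within[2]]])
    C1 <- orth_contrasts(k1); C2 <- orth_contrasts(k2)
    one1 <- matrix(1 / sqrt(k1), k1, 1); one2 <- matrix(1 / sqrt(k2), k2, 1)
    out <- dplyr::bind_rows(
      gg_effect(Y, kronecker(C1, one2), within[1]),
      gg_effect(Y, kronecker(one1, C2), within[2]),
      gg_effect(Y, kronecker(C1, C2), paste(within, collapse = " x ")))
  }
  class(out) <- c("rm_anova_gg", class(out))
  out
}

#' Paired t test with Cohen's d_z
#'
#' Classic paired t test on the differences `x - y`, reporting Cohen's
#' `d_z = mean(diff) / sd(diff)` (equivalently `t / sqrt(n)`). One-tailed
#' tests halve the two-tailed p when the observed effect lies in the
#' hypothesized direction.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2).
#' @param tail `"two"`, `"greater"` (x > y hypothesized) or `"less"`.
#' @return A one-row tibble: `t`, `df`, `p_value`, `d_z`, `mean_diff`,
#'   `tail`.
#' @export
paired_t <- function(x, y, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("all paired differences are identical (zero variance); t undefined")
  }
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    d_z = mean(d) / stats::sd(d),
    mean_diff = mean(d),
    tail = tail)
}

#' Pearson correlation with two-tailed p
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-degenerate
#'   variance.
#' @return A one-row tibble: `r`, `df`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate),
                 df = unname(ct$parameter),
                 p_value = ct$p.value,
                 n = length(x))
}

#' BCI-efficiency screening
#'
#' Flags participants as BCI-efficient when their copy-task accuracy
#' exceeds `threshold` (default 70%) in the final session, or in at least
#' `min_sessions` (default 3) sessions; others are excluded from analysis
#' as BCI-inefficient.
#'
#' @param data Long data frame of per-session accuracies.
#' @param accuracy,participant,session Column names.
#' @param threshold Accuracy criterion in the same units as `accuracy`.
#' @param min_sessions Number of above-threshold sessions that also
#'   qualifies.
#' @return A tibble with one row per participant: `participant`,
#'   `efficient`, `final_session_accuracy`, `n_sessions_above`.
#' @export
screen_bci_efficiency <- function(data, accuracy = "copy_accuracy",
                                  participant = "participant",
                                  session = "session",
                                  threshold = 70, min_sessions = 3) {
  df <- tibble::as_tibble(data)
  last_session <- max(df[[session]])
  df |>
    dplyr::summarise(
      final_session_accuracy =
        mean(.data[[accuracy]][.data[[session]] == last_session]),
      n_sessions_above = sum(.data[[accuracy]] > threshold),
      .by = dplyr::all_of(participant)) |>
    dplyr::mutate(
      efficient = (!is.na(.data$final_session_accuracy) &
                     .data$final_session_accuracy > threshold) |
        .data$n_sessions_above >= min_sessions) |>
    dplyr::relocate(dplyr::all_of(participant), "efficient")
}
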