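# independent exhaustive stepwise reference: re-runs a full OLS for every
# candidate at every forward/backward step
oracle_stepwise <- function(x, y, p_enter, p_remove, max_features = ncol(x)) {
  selected <- integer(0)
  pval_add <- function(j) {
    f_full <- stats::lm(y ~ x[, c(selected, j), drop = FALSE])
    f_red <- if (length(selected) == 0) stats::lm(y ~ 1)
             else stats::lm(y ~ x[, selected, drop = FALSE])
    stats::anova(f_red, f_full)$`Pr(>F)`[2]
  }
  pvals_current <- function() {
    fit <- stats::lm(y ~ x[, selected, drop = FALSE])
    summary(fit)$coefficients[-1, 4]
  }
  repeat {
    changed <- FALSE
    if (length(selected) < max_features) {
      cand <- setdiff(seq_len(ncol(x)), selected)
      pv <- vapply(cand, pval_add, numeric(1))
      if (min(pv) < p_enter) {
        selected <- c(selected, cand[which.min(pv)])
        changed <- TRUE
      }
    }
    while (length(selected) > 1) {
      pv <- pvals_current()
      if (max(pv) > p_remove) {
        selected <- selected[-which.max(pv)]
        changed <- TRUE
      } else break
    }
    if (!changed || length(selected) >= max_features) break
  }
  selected
}

test_that("time-binned features follow the channel-major layout", {
  sig <- matrix(2, nrow = 12, ncol = 512 * 4)
  ep <- extract_epochs(make_recording(sig, flat_events(2, soa_ms = 1500),
                                      labels = paste0("c", 1:12)))
  # constant recording baseline-corrects to zero everywhere
  fm0 <- build_features(ep)
  expect_equal(ncol(fm0$x), 192)
  expect_true(all(fm0$x == 0))
  # put a known value into one epoch post-stimulus
  ep$epochs[1, , ] <- 2
  fm <- build_features(ep)
  expect_true(all(abs(fm$x[1, ] - 2) < 1e-12))
  expect_equal(fm$layout$channel[1:16], rep("c1", 16))
  fm1 <- build_features(ep, bin_width = 800)
  expect_equal(ncol(fm1$x), 12)
})

test_that("swlda selects a perfectly separating feature and fits it", {
  set.seed(1)
  n <- 60
  y <- rep(c(1, -1), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 3] <- y + rnorm(n, 0, 0.05)
  fm <- make_feature_matrix(x, y, rep(tactor_positions, length.out = n))
  m <- train_swlda(fm)
  expect_equal(m$selected[1], 3)
  scores <- score_epoch(m, fm)
  expect_true(all((scores > 0) == (y > 0)))  # 100% training accuracy
  # mean target score exceeds mean non-target score (LS on +/-1 labels)
  expect_gt(mean(scores[y > 0]), mean(scores[y < 0]))
})

test_that("entry test controls type-I error on permuted labels", {
  errors <- 0
  for (seed in 1:100) {
    set.seed(seed)
    n <- 40
    x <- matrix(rnorm(n * 20), n, 20)
    y <- sample(rep(c(1, -1), each = n / 2))
    fm <- make_feature_matrix(x, y, rep(tactor_positions, length.out = n))
    res <- tryCatch(train_swlda(fm, p_enter = 1e-6), error = function(e) "err")
    if (identical(res, "err")) errors <- errors + 1
  }
  expect_gte(errors, 95)
})

test_that("swlda matches the exhaustive stepwise oracle on small problems", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 50
    x <- matrix(rnorm(n * 5), n, 5)
    beta <- c(1.2, 0, 0.8, 0, 0.3)
    y <- sign(x %*% beta + rnorm(n, 0, 0.8))
    y[y == 0] <- 1
    fm <- make_feature_matrix(x, drop(y), rep(tactor_positions, length.out = n))
    m <- tryCatch(train_swlda(fm, p_enter = 0.10, p_remove = 0.15),
                  error = function(e) NULL)
    ref <- oracle_stepwise(x, drop(y), 0.10, 0.15)
    if (is.null(m)) {
      expect_length(ref, 0)
    } else {
      expect_equal(m$selected, ref)
    }
  }
})

test_that("swlda with open thresholds equals the full least-squares fit", {
  set.seed(3)
  n <- 80
  x <- matrix(rnorm(n * 6), n, 6)
  y <- sample(rep(c(1, -1), each = n / 2))
  fm <- make_feature_matrix(x, y, rep(tactor_positions, length.out = n))
  m <- train_swlda(fm, p_enter = 1, p_remove = 1, max_features = 10)
  expect_setequal(m$selected, 1:6)
  full <- stats::lm(y ~ x)
  expect_equal(m$weights[order(m$selected)],
               unname(coef(full)[-1]), tolerance = 1e-8)
  expect_equal(m$intercept, unname(coef(full)[1]), tolerance = 1e-8)
})

test_that("epoch scoring is the stated affine form", {
  m <- structure(list(selected = c(2L, 4L), weights = c(0.5, -1),
                      intercept = 0.3, n_features_total = 5,
                      layout = tibble::tibble()),
                 class = "swlda_model")
  expect_equal(score_epoch(m, rep(0, 5)), 0.3)
  expect_equal(score_epoch(m, c(0, 2, 0, 1, 0)), 0.3 + 1 - 1)
  m2 <- m; m2$weights <- m$weights * 3
  x <- c(1, 2, 3, 4, 5)
  expect_equal(score_epoch(m2, x) - m2$intercept,
               3 * (score_epoch(m, x) - m$intercept))
  expect_error(score_epoch(m, rep(0, 4)), "layout")
})

test_that("selection rule sums scores, argmaxes, and tie-breaks by order", {
  m <- structure(list(selected = 1L, weights = 1, intercept = 0,
                      n_features_total = 1, layout = tibble::tibble()),
                 class = "swlda_model")
  pos <- rep(tactor_positions, each = 2)
  # target 'left' scores +1, others -1
  x <- matrix(ifelse(pos == "left", 1, -1), ncol = 1)
  fm <- make_feature_matrix(x, ifelse(pos == "left", 1, -1), pos)
  res <- classify_selection(m, fm, true_position = "left")
  expect_true(res$correct)
  expect_false(res$tie)
  # all-equal scores: front wins, tie flagged
  fm0 <- make_feature_matrix(matrix(0, 8, 1), rep(c(1, -1), 4), pos)
  res0 <- classify_selection(m, fm0, true_position = "right")
  expect_equal(res0$predicted, "front")
  expect_true(res0$tie)
  expect_false(res0$correct)
})

test_that("a zero-information model decodes at chance", {
  m <- structure(list(selected = 1L, weights = 1, intercept = 0,
                      n_features_total = 1, layout = tibble::tibble()),
                 class = "swlda_model")
  set.seed(42)
  pos <- rep(tactor_positions, each = 8)
  correct <- vapply(1:1000, function(i) {
    fm <- make_feature_matrix(matrix(rnorm(32), ncol = 1),
                              ifelse(pos == "front", 1, -1), pos)
    classify_selection(m, fm, true_position = "front")$correct
  }, logical(1))
  expect_lt(abs(mean(correct) - 0.25), 0.041)  # binomial 3 sigma at n=1000
})

test_that("bits per selection follows the N-choice information formula", {
  expect_equal(as.numeric(bits_per_selection(0.25, 4)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(bits_per_selection(1, 4)), 2)
  expect_equal(as.numeric(bits_per_selection(0, 4)), log2(4) + log2(1 / 3))
  expect_equal(as.numeric(bits_per_selection(0.92, 4)), 1.471, tolerance = 5e-4)
  # strictly increasing on [1/N, 1]
  p <- seq(0.25, 1, by = 0.01)
  expect_true(all(diff(as.numeric(bits_per_selection(p, 4))) > 0))
  expect_true(attr(bits_per_selection(0.1, 4), "below_chance"))
})

test_that("ITR is per-participant-then-mean", {
  expect_equal(itr(2, 3), 6)
  agg0 <- aggregate_itr(rep(0.25, 5), N = 4, SPM = 3)
  expect_equal(agg0$mean_itr, 0, tolerance = 1e-12)
  agg <- aggregate_itr(c(0.75, 1), N = 4, SPM = 3)
  hand <- (as.numeric(bits_per_selection(0.75, 4)) + 2) / 2 * 3
  expect_equal(agg$mean_itr, hand)
  expect_equal(agg$n, 2)
})

test_that("swlda models survive a JSON round-trip", {
  set.seed(4)
  x <- matrix(rnorm(200), 40, 5)
  y <- sign(x[, 2] + rnorm(40, 0, 0.4)); y[y == 0] <- 1
  fm <- make_feature_matrix(x, y, rep(tactor_positions, 10))
  m <- train_swlda(fm, p_enter = 0.2, p_remove = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_swlda_json(m, path)
  back <- read_swlda_json(path)
  expect_equal(back$selected, m$selected)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(score_epoch(back, x), score_epoch(m, x), tolerance = 1e-9)
})
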