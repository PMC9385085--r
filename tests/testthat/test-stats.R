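# long-format helper: participant x condition scores from a wide matrix
long_1w <- function(Y) {
  tibble::tibble(id = rep(seq_len(nrow(Y)), times = ncol(Y)),
                 session = rep(seq_len(ncol(Y)), each = nrow(Y)),
                 y = as.vector(Y))
}

test_that("GG ANOVA matches the car oracle on a two-factor worked dataset", {
  skip_if_not_installed("car")
  set.seed(10)
  n <- 12
  # 5 sessions x 3 electrodes with a session trend and non-spherical noise
  subj <- matrix(rnorm(n * 15), n, 15)
  trend <- rep(seq(0, 1, length.out = 5), each = 3)
  Y <- sweep(subj %*% chol(0.5 + 0.5 * diag(15)), 2, trend, "+")
  df <- tibble::tibble(
    id = rep(seq_len(n), times = 15),
    session = rep(rep(1:5, each = 3), each = n),
    electrode = rep(rep(c("Fz", "Cz", "Pz"), times = 5), each = n),
    y = as.vector(Y))
  res <- rm_anova_gg(df, "y", "id", c("session", "electrode"))

  idata <- expand.grid(electrode = factor(c("Fz", "Cz", "Pz"),
                                          levels = c("Fz", "Cz", "Pz")),
                       session = factor(1:5))[, c("session", "electrode")]
  mlm <- stats::lm(Y ~ 1)
  aov_car <- car::Anova(mlm, idata = idata, idesign = ~ session * electrode,
                        type = 3)
  s <- summary(aov_car, multivariate = FALSE)
  uni <- s$univariate.tests
  adj <- s$pval.adjustments
  for (eff in c("session", "electrode", "session:electrode")) {
    mine <- res[res$effect == sub(":", " x ", eff), ]
    expect_equal(mine$F, uni[eff, "F value"], tolerance = 1e-8)
    expect_equal(mine$epsilon, adj[eff, "GG eps"], tolerance = 1e-8)
    expect_equal(mine$p_value, adj[eff, "Pr(>F[GG])"], tolerance = 1e-8)
  }
})

test_that("GG ANOVA matches the car oracle on a one-factor design", {
  skip_if_not_installed("car")
  set.seed(21)
  Y <- matrix(rnorm(8 * 5), 8, 5) %*% chol(diag(5) * 0.4 + 0.6)
  res <- rm_anova_gg(long_1w(Y), "y", "id", "session")
  idata <- data.frame(session = factor(1:5))
  s <- summary(car::Anova(stats::lm(Y ~ 1), idata = idata,
                          idesign = ~ session, type = 3),
               multivariate = FALSE)
  expect_equal(res$F, s$univariate.tests["session", "F value"],
               tolerance = 1e-8)
  expect_equal(res$epsilon, s$pval.adjustments["session", "GG eps"],
               tolerance = 1e-8)
  expect_equal(res$p_value, s$pval.adjustments["session", "Pr(>F[GG])"],
               tolerance = 1e-8)
})

test_that("epsilon behaves at its structural boundaries", {
  set.seed(3)
  # two-level factor: epsilon exactly 1
  Y2 <- matrix(rnorm(20 * 2), 20, 2)
  res2 <- rm_anova_gg(long_1w(Y2), "y", "id", "session")
  expect_equal(res2$epsilon, 1)
  expect_equal(res2$df1, res2$df1_uncorrected)
  # exchangeable (compound-symmetric) errors: epsilon near 1
  n <- 200
  subj <- rnorm(n, 0, 2)
  Y <- sapply(1:4, function(k) subj + rnorm(n))
  res <- rm_anova_gg(long_1w(Y), "y", "id", "session")
  expect_gt(res$epsilon, 0.95)
  # correction never increases df
  expect_lte(res$df2, res$df2_uncorrected)
  expect_gte(res$epsilon, 1 / 3)
})

test_that("GG ANOVA demands a complete balanced design", {
  df <- long_1w(matrix(rnorm(12), 4, 3))
  expect_error(rm_anova_gg(df[-1, ], "y", "id", "session"), "balanced")
  expect_silent(rm_anova_gg(df, "y", "id", "session"))
})

test_that("within-subject statistics ignore participant-level offsets", {
  set.seed(5)
  Y <- matrix(rnorm(10 * 4), 10, 4)
  res1 <- rm_anova_gg(long_1w(Y), "y", "id", "session")
  res2 <- rm_anova_gg(long_1w(Y + rnorm(10) * 100), "y", "id", "session")
  expect_equal(res1$F, res2$F, tolerance = 1e-9)
  expect_equal(res1$epsilon, res2$epsilon, tolerance = 1e-9)
})

test_that("GG ANOVA holds its nominal type-I error on null data", {
  set.seed(8)
  rejections <- vapply(1:2000, function(i) {
    Y <- matrix(rnorm(29 * 5), 29, 5)
    rm_anova_gg(long_1w(Y), "y", "id", "session")$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("paired t reports the classic statistic and d_z", {
  x <- c(5.1, 6.2, 5.9, 7.3, 6.8, 5.5)
  y <- c(4.8, 5.9, 6.1, 6.9, 6.2, 5.1)
  res <- paired_t(x, y, tail = "greater")
  ref <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$d_z, res$t / sqrt(6), tolerance = 1e-9)
  # one-tailed p is half the two-tailed p in the hypothesized direction
  res2 <- paired_t(x, y, tail = "two")
  expect_equal(res$p_value, res2$p_value / 2)
  expect_error(paired_t(x, x), "zero variance|identical")
})

test_that("paired t power matches the noncentral-t closed form", {
  set.seed(9)
  n <- 29
  rejections <- vapply(1:2000, function(i) {
    d <- rnorm(n, 0.5, 1)
    paired_t(d, rep(0, n), tail = "greater")$p_value < 0.05
  }, logical(1))
  power_analytic <- 1 - stats::pt(stats::qt(0.95, n - 1), n - 1,
                                  ncp = 0.5 * sqrt(n))
  expect_lt(abs(mean(rejections) - power_analytic), 0.03)
})

test_that("pearson correlation handles exact and null cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(3, 10)), "degenerate")
  # critical value control: |r| > r_crit in ~5% of null replicates
  set.seed(12)
  n <- 28
  r_crit <- sqrt(stats::qf(0.95, 1, n - 2) / (stats::qf(0.95, 1, n - 2) + n - 2))
  hits <- vapply(1:2000, function(i) {
    abs(pearson_r(rnorm(n), rnorm(n))$r) > r_crit
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("BCI-efficiency screening applies the 70% rule", {
  acc <- tibble::tibble(
    participant = rep(1:4, each = 5),
    session = rep(1:5, 4),
    copy_accuracy = c(80, 85, 90, 88, 92,    # efficient: final > 70
                      60, 65, 50, 55, 45,    # inefficient
                      75, 80, 72, 60, 65,    # efficient: 3 sessions > 70
                      50, 60, 72, 65, 70))   # inefficient: 70 not > 70
  res <- screen_bci_efficiency(acc)
  expect_equal(res$efficient[match(1:4, res$participant)],
               c(TRUE, FALSE, TRUE, FALSE))
})
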