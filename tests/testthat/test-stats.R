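test_that("Pearson correlation against the hand covariance formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  # independent oracle: raw product-moment formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate(x, y)
  expect_equal(res$estimate, r_hand)
  expect_equal(res$r_squared, r_hand^2)
  expect_equal(res$df, 2)
  # t from r
  expect_equal(res$statistic, r_hand * sqrt(2) / sqrt(1 - r_hand^2))

  expect_equal(correlate(x, x)$estimate, 1)
  # orthogonal by balanced construction
  expect_equal(correlate(c(-1, 1, -1, 1), c(-1, -1, 1, 1))$estimate, 0)
  expect_error(correlate(x, rep(3, 4)), "zero variance")
  expect_error(correlate(1:2, 2:3))  # n < 3
})

test_that("correlation is affine-invariant up to sign", {
  set.seed(21)
  x <- rnorm(40); y <- x + rnorm(40)
  r <- correlate(x, y)$estimate
  expect_equal(correlate(3 * x + 7, y)$estimate, r)
  expect_equal(correlate(x, -2 * y + 1)$estimate, -r)
})

test_that("start-price binning partitions at the $100 boundary", {
  rec <- data.frame(start_price = c(60, 99.9, 100, 140),
                    winning_price = c(30, 50, 55, 70))
  bins <- split_by_start_price(rec)
  expect_equal(bins$low, c(30, 50))
  expect_equal(bins$high, c(55, 70))       # boundary 100 goes high
  expect_equal(sort(c(bins$low, bins$high)), sort(rec$winning_price))

  # censored records are excluded; empty bin warns
  rec$winning_price[2] <- NA
  expect_equal(split_by_start_price(rec)$low, 30)
  expect_warning(split_by_start_price(rec[3:4, ]), "empty")

  # uniform start prices split evenly
  set.seed(3)
  big <- data.frame(start_price = runif(1e4, 50, 150),
                    winning_price = runif(1e4, 0, 50))
  b <- split_by_start_price(big)
  se <- sqrt(0.25 * 1e4)
  expect_lt(abs(length(b$low) - 5000), 3 * se)
})

test_that("pooled two-sample t against the textbook formula", {
  set.seed(31)
  a <- rnorm(12, 50, 5); b <- rnorm(9, 55, 5)
  # independent oracle: pooled-variance formula by hand
  sp2 <- ((11 * var(a)) + (8 * var(b))) / (12 + 9 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 12 + 1 / 9))
  res <- two_sample_t(a, b)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 19)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 19))

  expect_equal(two_sample_t(a, a)$statistic, 0)
  shift <- two_sample_t(a, a + 3)
  expect_lt(shift$statistic, 0)            # sign(t) = -sign(shift)
  expect_gt(two_sample_t(a + 3, a)$statistic, 0)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("JZS Bayes factor: null behaviour, monotonicity, sign invariance", {
  expect_lt(jzs_bf_ttest(0, 330, 330)$bf10, 1)
  bfs <- vapply(c(0, 1, 2, 3, 5, 8, 12),
                function(t) jzs_bf_ttest(t, 50, 50)$log_bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bf_ttest(-4.85, 330, 330)$log_bf10,
               jzs_bf_ttest(4.85, 330, 330)$log_bf10)
  b <- jzs_bf_ttest(7.3, 40, 60)
  expect_equal(b$log_bf10, log(b$bf10), tolerance = 1e-12)
})

test_that("JZS log BF sits in the BIC sanity corridor for large |t|", {
  n <- 1000
  for (t in c(10.5, 12, 15, 17)) {
    ln_bf <- jzs_bf_ttest(t, n / 2, n / 2)$log_bf10
    bic <- (n / 2) * log(1 + t^2 / (n - 2)) - 0.5 * log(n)
    expect_lt(abs(ln_bf - bic) / bic, 0.02)
  }
})

test_that("paired comparison: t and signed-rank routes", {
  set.seed(41)
  a <- rnorm(20, 50, 5)

  # constant shift gives the extreme signed-rank statistics
  up <- compare_paired_conditions(a, a + 5, method = "wilcoxon")
  expect_identical(unname(up$statistic), 0)          # all differences negative
  dn <- compare_paired_conditions(a + 5, a, method = "wilcoxon")
  expect_identical(unname(dn$statistic), 20 * 21 / 2)

  # exhaustive enumeration oracle for the exact signed-rank p value
  d <- c(1.2, -0.4, 2.5, -3.1, 0.7, 1.9)
  b <- rep(0, 6)
  res <- compare_paired_conditions(d, b, method = "wilcoxon")
  rk <- rank(abs(d))
  V_obs <- sum(rk[d > 0])
  expect_identical(unname(res$statistic), V_obs)
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  V_null <- as.matrix(signs) %*% rk
  p_exact <- min(1, 2 * min(mean(V_null >= V_obs), mean(V_null <= V_obs)))
  expect_equal(res$p_value, p_exact)

  # t route reports the paired t and a one-sample JZS BF
  res_t <- compare_paired_conditions(a, a + rnorm(20, 1, 1), method = "t")
  expect_identical(res_t$method, "Paired t")
  expect_equal(res_t$df, 19)
  expect_gt(res_t$bf10, 0)

  # auto route: heavy-tailed differences fail Shapiro-Wilk -> signed rank
  skew <- a + c(rep(0.1, 19), 40)
  res_auto <- compare_paired_conditions(skew, a, method = "auto")
  expect_identical(res_auto$method, "Wilcoxon signed rank")
  expect_lt(res_auto$shapiro_p, 0.05)

  expect_error(compare_paired_conditions(a, a), "degenerate")
})

test_that("ECDF is right-continuous with unit mass at the maximum", {
  f1 <- ecdf_step(5)
  expect_equal(f1(4.999), 0)
  expect_equal(f1(5), 1)
  f <- ecdf_step(c(1, 2, 3, 4))
  expect_equal(f(2.5), 0.5)
  expect_equal(f(4), 1)

  # independent sorted-rank construction
  set.seed(51)
  v <- rnorm(200)
  fe <- ecdf_step(v)
  sv <- sort(v)
  expect_equal(fe(sv), seq_along(sv) / length(sv))
})

test_that("repeated-measures ANOVA wrapper agrees with aov and bounds epsilon", {
  set.seed(61)
  wide <- matrix(rnorm(11 * 5, mean = rep(c(50, 52, 51, 53, 50), each = 11)),
                 nrow = 11)
  res <- rm_anova_gg(wide)

  # oracle: stats::aov with subject error stratum
  long <- data.frame(y = as.vector(wide),
                     subj = factor(rep(1:11, 5)),
                     lvl = factor(rep(1:5, each = 11)))
  av <- summary(stats::aov(y ~ lvl + Error(subj), data = long))
  tab <- av[["Error: Within"]][[1]]
  expect_equal(res$F, tab[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, tab[1, "Pr(>F)"], tolerance = 1e-10)
  expect_gte(res$epsilon, 1 / 4)
  expect_lte(res$epsilon, 1)
  expect_gte(res$p_gg, res$p_value)  # the correction never sharpens p

  # two levels: sphericity is trivial, epsilon = 1
  expect_equal(rm_anova_gg(wide[, 1:2])$epsilon, 1)
})

test_that("stat_result carries a consistent Bayes factor pair", {
  set.seed(71)
  res <- two_sample_t(rnorm(30), rnorm(30, 1))
  expect_gt(res$bf10, 0)
  expect_equal(res$log_bf10, log(res$bf10), tolerance = 1e-12)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_output(print(res), "Two-sample t")
})
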