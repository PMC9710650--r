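test_that("independent t-test matches the closed-form pooled formula", {
  res <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # pooled variance = (2 + 2) / 4 = 1; se = sqrt(1 * (1/3 + 1/3))
  t_expected <- (2 - 5) / sqrt(2 / 3)
  p_expected <- 2 * pt(-abs(t_expected), df = 4)
  res <- independent_t_test(a, b)
  expect_equal(res$t, t_expected, tolerance = 1e-12)
  expect_equal(res$p, p_expected, tolerance = 1e-12)
  expect_equal(res$df, 4)

  expect_error(independent_t_test(1, c(1, 2)),
               class = "insufficient_data_error")
  expect_error(independent_t_test(c(1, 2, NA), c(3, NA, NA)),
               class = "insufficient_data_error")
})

test_that("Benjamini-Hochberg matches the hand-computed step-up", {
  # 0.01*3/1 = 0.03, 0.02*3/2 = 0.03, 0.03*3/3 = 0.03
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.4, 5)), rep(0.4, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, -0.1)), "\\[0, 1\\]")

  set.seed(10)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_equal(adj, naive_bh(p), tolerance = 1e-12)
  expect_true(all(adj >= p & adj <= 1))
})

test_that("one-tailed Fisher p equals combinatorial enumeration", {
  # 2 of 4 proteins in term, both among the 2 detected: only 1 of C(4,2)=6
  # detected-set draws achieves >= 2 in-term hits
  expect_equal(fisher_one_tailed(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  # nothing in-term detected: upper tail includes everything
  expect_equal(fisher_one_tailed(0, 3, 5, 2), 1)
  expect_error(fisher_one_tailed(-1, 2, 3, 4), "non-negative")

  set.seed(11)
  for (i in 1:200) {
    m <- sample(0:12, 1); n <- sample(0:12, 1)
    if (m + n == 0) next
    k <- sample(0:(m + n), 1)
    supp <- max(0, k - n):min(k, m)
    x <- supp[sample.int(length(supp), 1)]
    expect_equal(fisher_one_tailed(x, m - x, k - x, n - (k - x)),
                 brute_hyper_upper(x, m, n, k), tolerance = 1e-12)
  }
})

test_that("pearson_r2 matches the textbook formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r2(x, x), 1)
  expect_equal(pearson_r2(x, -x), 1)

  set.seed(12)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r2(x, y), r_manual^2, tolerance = 1e-12)

  # pairwise-complete filtering
  x2 <- c(x, NA); y2 <- c(y, 5)
  expect_equal(pearson_r2(x2, y2), r_manual^2, tolerance = 1e-12)

  expect_error(pearson_r2(c(1, 1, 1), c(1, 2, 3)),
               class = "undefined_correlation_error")
  expect_error(pearson_r2(1, c(1, 2)), "equal length")
})

test_that("moderated t reduces to the ordinary t as the prior df vanishes", {
  set.seed(13)
  a <- matrix(rnorm(200, 20, 1), 50, 4)
  b <- matrix(rnorm(200, 20, 1), 50, 4)
  rownames(a) <- rownames(b) <- paste0("G", 1:50)
  fit0 <- moderated_t_fit(a, b, trend = FALSE, prior_df = 0)
  for (g in c(1, 17, 50)) {
    ord <- independent_t_test(a[g, ], b[g, ])
    expect_equal(fit0$t[g], ord$t, tolerance = 1e-9)
    expect_equal(fit0$p[g], ord$p, tolerance = 1e-9)
  }
  fit_inf <- moderated_t_fit(a, b, trend = FALSE, prior_df = Inf)
  expect_equal(fit_inf$s2_post, fit_inf$s2_prior, tolerance = 1e-12)
})

test_that("posterior variances interpolate prior and sample variances", {
  set.seed(14)
  a <- matrix(rnorm(320, 25, 1), 80, 4)
  b <- matrix(rnorm(320, 25, 1), 80, 4)
  fit <- moderated_t_fit(a, b, trend = TRUE)
  d0 <- attr(fit, "prior_df")
  expect_true(d0 > 0)
  expect_equal(fit$s2_post,
               (d0 * fit$s2_prior + fit$df_resid * fit$s2) /
                 (d0 + fit$df_resid),
               tolerance = 1e-12)
  expect_true(all(fit$s2_post >= pmin(fit$s2_prior, fit$s2) - 1e-12))
  expect_true(all(fit$s2_post <= pmax(fit$s2_prior, fit$s2) + 1e-12))
  expect_true(all(fit$p > 0 & fit$p <= 1))
})

test_that("the empirical-Bayes fit agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(15)
  n <- 300
  a <- matrix(rnorm(n * 4, 22, 1), n, 4)
  b <- matrix(rnorm(n * 4, 22, 1), n, 4)
  fit <- moderated_t_fit(a, b, trend = FALSE)

  design <- cbind(mean_a = 1, b_vs_a = rep(c(0, 1), each = 4))
  lfit <- limma::eBayes(limma::lmFit(cbind(a, b), design), trend = FALSE)
  expect_equal(attr(fit, "prior_df"), lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$s2_prior, rep(lfit$s2.prior, n), tolerance = 1e-6)
  # our fold change is A - B, limma's coefficient is B - A
  expect_equal(fit$t, -lfit$t[, 2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$p, lfit$p.value[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("type-I error of the moderated test is nominal on null data", {
  set.seed(16)
  n <- 500
  a <- matrix(rnorm(n * 4, 25, 0.5), n, 4)
  b <- matrix(rnorm(n * 4, 25, 0.5), n, 4)
  fit <- moderated_t_fit(a, b, trend = TRUE)
  frac <- mean(fit$p < 0.05)
  ci_half <- qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_gt(frac, 0.05 - ci_half)
  expect_lt(frac, 0.05 + ci_half)
})

test_that("insufficient observations per group are rejected up front", {
  a <- matrix(c(1, NA, 2, 3), 1, 4)
  b <- matrix(rnorm(4), 1, 4)
  expect_silent(moderated_t_fit(a, b, trend = FALSE))
  a2 <- matrix(c(1, NA, NA, NA), 1, 4)
  expect_error(moderated_t_fit(a2, b, trend = FALSE), "fewer than 2")
})
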