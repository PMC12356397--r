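test_that("repeated-measures ANOVA matches the sum-of-squares oracle", {
  # hand-worked 3x3 case
  m <- matrix(c(1, 2, 3,
                2, 4, 5,
                4, 5, 9), nrow = 3, byrow = TRUE)
  res <- rm_anova_oneway(m)
  expect_equal(res$value, rm_anova_ss_oracle(m), tolerance = 1e-10)
  expect_identical(res$df, c(2L, 4L))
  expect_equal(res$p_raw, pf(res$value, 2, 4, lower.tail = FALSE))

  # subject offsets only (constant rows): no level effect
  flat <- rbind(rep(1, 3), rep(5, 3), rep(9, 3), rep(2, 3))
  expect_equal(rm_anova_oneway(flat)$value, 0)

  # location invariance
  set.seed(21)
  m2 <- matrix(rnorm(20), 4, 5)
  expect_equal(rm_anova_oneway(m2)$value,
               rm_anova_oneway(m2 + 100)$value, tolerance = 1e-8)

  # property: random matrices up to 6x6
  for (i in 1:20) {
    n <- sample(2:6, 1); k <- sample(2:6, 1)
    mm <- matrix(rnorm(n * k, sd = sample(1:3, 1)), n, k)
    expect_equal(rm_anova_oneway(mm)$value, rm_anova_ss_oracle(mm),
                 tolerance = 1e-8)
  }
  expect_error(rm_anova_oneway(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  expect_error(rm_anova_oneway(matrix(1:3, 1, 3)), ">= 2")
})

test_that("baseline post-hocs are one-tailed, paired and FDR-corrected", {
  set.seed(5)
  base <- rnorm(12)
  m <- cbind(baseline = base,
             up = base + 0.8 + rnorm(12, sd = 0.3),
             same = base + rnorm(12, sd = 0.3),
             down = base - 0.8 + rnorm(12, sd = 0.3))
  res <- posthoc_vs_baseline(m, "baseline", "greater")
  expect_identical(res$level, c("up", "same", "down"))
  up <- res[res$level == "up", ]
  diffs <- m[, "up"] - base
  expect_equal(up$t, mean(diffs) / (sd(diffs) / sqrt(12)), tolerance = 1e-10)
  expect_equal(up$cohens_d, mean(diffs) / sd(diffs), tolerance = 1e-12)
  expect_equal(res$p_corr, fdr_bh(res$p_raw))
  expect_lt(up$p_corr, 0.05)
  # the decreasing level is significant only in the "less" direction
  res_less <- posthoc_vs_baseline(m, "baseline", "less")
  expect_lt(res_less$p_raw[res_less$level == "down"], 0.05)
  expect_gt(res$p_raw[res$level == "down"], 0.5)

  # a level identical to baseline: t = 0, one-tailed p = 0.5
  m2 <- cbind(b = base, ident = base, up = base + 1 + rnorm(12, sd = 0.1))
  r2 <- posthoc_vs_baseline(m2, "b", "greater")
  expect_equal(r2$t[r2$level == "ident"], 0)
  expect_equal(r2$p_raw[r2$level == "ident"], 0.5)
  # constant nonzero differences are degenerate
  m3 <- cbind(b = base, shift = base + 1)
  expect_error(posthoc_vs_baseline(m3, "b", "greater"), "degenerate")
  expect_error(posthoc_vs_baseline(m[1, , drop = FALSE], "baseline",
                                   "greater"), ">= 2")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1)) ^ sample(1:3, 1)
    adj <- fdr_bh(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # order invariance
    ord <- sample(length(p))
    expect_equal(fdr_bh(p[ord]), adj[ord], tolerance = 1e-12)
  }
  expect_error(fdr_bh(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("one-sample t and Cohen's d follow their definitions", {
  expect_equal(one_sample_t(c(-2, -1, 1, 2))$value, 0)
  # a sample with mean 0.52 and SD 0.40 at n = 22 implies t ~ 6.10
  set.seed(2)
  x <- as.numeric(scale(rnorm(22))) * 0.40 + 0.52
  res <- one_sample_t(x, 0, tails = 1L)
  expect_equal(res$value, 0.52 / (0.40 / sqrt(22)), tolerance = 1e-9)
  expect_equal(res$value, 6.0978, tolerance = 1e-3)
  expect_identical(res$df, 21)
  expect_equal(res$cohens_d, 0.52 / 0.40, tolerance = 1e-9)
  # shifting the sample by its own displacement from mu0 doubles d
  y <- x + (mean(x) - 0)
  expect_equal(one_sample_t(y)$cohens_d, 2 * res$cohens_d,
               tolerance = 1e-9)
  expect_error(one_sample_t(rep(1, 5)), "degenerate")
})

test_that("JZS one-sample Bayes factors behave and match a Monte-Carlo oracle", {
  expect_lt(jzs_bf_one_sample(0, 22)$ln_bf10, 0)
  mc <- jzs_mc_oracle(2, 20)
  expect_equal(jzs_bf_one_sample(2, 20)$ln_bf10, mc, tolerance = 0.02)
  # monotone increasing in |t| at fixed n
  lnbf <- vapply(seq(0, 6, by = 0.5),
                 function(t) jzs_bf_one_sample(t, 20)$ln_bf10, numeric(1))
  expect_true(all(diff(lnbf) > 0))
})

test_that("correlation Bayes factors separate signal from noise", {
  strong <- jzs_bf_correlation(1:20, (1:20) * 3 + 2)
  expect_true(is.finite(strong$ln_bf10))
  expect_gt(strong$ln_bf10, 3)
  # independent noise rarely earns evidence
  frac_null <- mean(vapply(1:20, function(s) {
    set.seed(s)
    jzs_bf_correlation(rnorm(22), rnorm(22))$ln_bf10 < 1
  }, logical(1)))
  expect_gte(frac_null, 0.7)
  # invariance under positively scaled affine maps of either variable
  set.seed(31)
  x <- rnorm(15); y <- x + rnorm(15)
  expect_equal(jzs_bf_correlation(x, y)$ln_bf10,
               jzs_bf_correlation(5 * x - 2, 0.1 * y + 7)$ln_bf10,
               tolerance = 1e-6)
  expect_error(jzs_bf_correlation(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("power analysis scans the noncentral t to the minimal n", {
  one <- power_sample_size(0.6, 0.05, 0.80, tails = 1)
  expect_identical(one$required_n, 19L)
  two <- power_sample_size(0.6, 0.05, 0.80, tails = 2)
  expect_identical(two$required_n, 24L)
  # cross-check against the base power calculator
  expect_identical(one$required_n,
                   as.integer(ceiling(power.t.test(
                     delta = 0.6, sd = 1, sig.level = 0.05, power = 0.8,
                     type = "one.sample",
                     alternative = "one.sided")$n)))
  # minimality: target met at n, not at n - 1
  pow_at <- function(n, tails) {
    crit <- qt(1 - 0.05 / tails, n - 1)
    pt(crit, n - 1, ncp = 0.6 * sqrt(n), lower.tail = FALSE)
  }
  expect_gte(one$achieved_power, 0.80)
  expect_lt(pow_at(one$required_n - 1, 1), 0.80)
  expect_error(power_sample_size(-1, 0.05, 0.8), "d > 0")
})
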