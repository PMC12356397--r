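# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# standard-normal quantile by bisection on the error function (pracma::erf)
qnorm_bisect <- function(p, tol = 1e-12) {
  stopifnot(p > 0, p < 1)
  f <- function(z) (1 + pracma::erf(z / sqrt(2))) / 2 - p
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# brute-force within-subject sum-of-squares decomposition
rm_anova_ss_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ss_lev <- n * sum((colm - gm) ^ 2)
  ss_err <- sum((m - outer(rowm, colm, "+") + gm) ^ 2)
  ms_lev <- ss_lev / (k - 1)
  ms_err <- ss_err / ((k - 1) * (n - 1))
  if (ms_err == 0) return(if (ms_lev == 0) 0 else Inf)
  ms_lev / ms_err
}

# brute-force Benjamini-Hochberg step-up adjustment
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Monte-Carlo JZS marginal likelihood: g drawn from its inverse-chi-square(1)
# prior, likelihood ratio averaged
jzs_mc_oracle <- function(t, n, r = sqrt(2) / 2, m = 2e5, seed = 99) {
  set.seed(seed)
  nu <- n - 1
  g <- 1 / stats::rchisq(m, df = 1)
  c2 <- 1 + n * g * r ^ 2
  log_ratio <- -0.5 * log(c2) -
    (nu + 1) / 2 * (log1p(t ^ 2 / (c2 * nu)) - log1p(t ^ 2 / nu))
  log(mean(exp(log_ratio)))
}

# small balanced schedule builder for observer tests
balanced_schedule <- function(n = 60, sigma = 0, seed = 1) {
  set.seed(seed)
  l <- rep(letter_set(), each = n / 6)
  data.frame(block = "block4", trial_index = seq_len(n), sigma = sigma,
             letter_shown = sample(l), stringsAsFactors = FALSE)
}

# 80/20 schedule (frequent = consonant), n divisible by 15
biased_schedule <- function(n = 60, sigma = 0, seed = 1) {
  set.seed(seed)
  l <- c(rep(c("C", "B", "H"), each = n * 4 / 15),
         rep(c("O", "E", "U"), each = n / 15))
  data.frame(block = "block4", trial_index = seq_len(n), sigma = sigma,
             letter_shown = sample(l), stringsAsFactors = FALSE)
}
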