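#' One-way repeated-measures ANOVA over noise levels
#'
#' Classical within-subject decomposition on a complete participants x
#' levels matrix: `F = MS_levels / MS_(levels x subjects)` with
#' `df = (k - 1, (k - 1)(n - 1))`; no sphericity correction.  The fit is
#' performed with [stats::aov()] using an `Error(subject)` stratum.
#'
#' @param data numeric matrix, rows = participants, columns = levels
#'   (column names become level labels).
#' @return List (class `stat_result`) with `statistic = "F"`, `value`, `df`
#'   (length-2), `p_raw`.
#' @export
rm_anova_oneway <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells: the design must be complete")
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L) stop("need >= 2 participants and >= 2 levels")
  d <- data.frame(
    y = as.vector(data),
    subject = factor(rep(seq_len(n), times = k)),
    level = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ level + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  ss <- tab[, "Sum Sq"]  # row 1: level, row 2: residuals
  # guard numerically-zero level variance (e.g. constant rows)
  tol <- 1e-12 * (sum((data - mean(data)) ^ 2) + .Machine$double.xmin)
  fval <- if (ss[1L] <= tol) 0
          else (ss[1L] / (k - 1L)) / (ss[2L] / ((k - 1L) * (n - 1L)))
  structure(
    list(statistic = "F", value = unname(fval),
         df = c(k - 1L, (k - 1L) * (n - 1L)),
         p_raw = unname(stats::pf(fval, k - 1L, (k - 1L) * (n - 1L),
                                  lower.tail = FALSE)),
         direction = "two-tailed"),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  df <- paste(round(x$df, 2), collapse = ", ")
  cat(sprintf("%s(%s) = %.4g, p = %.4g", x$statistic, df, x$value,
              x$p_raw))
  if (!is.null(x$p_corr)) cat(sprintf(", p_corr = %.4g", x$p_corr))
  if (!is.null(x$cohens_d)) cat(sprintf(", d = %.3g", x$cohens_d))
  cat("\n")
  invisible(x)
}

#' Baseline-referenced one-tailed post-hoc t-tests with FDR correction
#'
#' Paired one-tailed t-test of each non-baseline level against the baseline
#' level, with Cohen's d for paired contrasts (`mean(diff) / sd(diff)`) and
#' Benjamini-Hochberg adjusted p values.  Direction `"greater"` tests for
#' increases over baseline (accuracy, d'), `"less"` for decreases
#' (criterion).
#'
#' @param data participants x levels matrix; column names label the levels.
#' @param baseline_level column name or index of the baseline.
#' @param direction `"greater"` or `"less"` (alternative for level vs
#'   baseline).
#' @param on_degenerate what to do when a level's differences from baseline
#'   are constant but nonzero: `"error"` (default) or `"na"` (emit an NA
#'   row, used by [run_analyze()] so one degenerate level cannot abort a
#'   whole analysis).
#' @return Data frame: `level`, `t`, `df`, `p_raw`, `p_corr`, `cohens_d`,
#'   `direction`.
#' @export
posthoc_vs_baseline <- function(data, baseline_level = 1L,
                                direction = c("greater", "less"),
                                on_degenerate = c("error", "na")) {
  direction <- match.arg(direction)
  on_degenerate <- match.arg(on_degenerate)
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need >= 2 paired observations")
  if (is.character(baseline_level)) {
    baseline_level <- match(baseline_level, colnames(data))
  }
  if (is.na(baseline_level) || baseline_level < 1L ||
      baseline_level > ncol(data)) {
    stop("baseline level not present")
  }
  base <- data[, baseline_level]
  others <- setdiff(seq_len(ncol(data)), baseline_level)
  rows <- lapply(others, function(j) {
    lvl <- colnames(data)[j] %||% as.character(j)
    diffs <- data[, j] - base
    m_abs <- max(abs(diffs))
    if (stats::sd(diffs) <= 1e-10 * max(m_abs, .Machine$double.xmin)) {
      if (m_abs <= 1e-12 * max(1, max(abs(base)))) {
        # level identical to baseline: no effect, one-tailed p = 0.5
        return(data.frame(level = lvl, t = 0, df = nrow(data) - 1L,
                          p_raw = 0.5, cohens_d = 0,
                          direction = direction, stringsAsFactors = FALSE))
      }
      if (on_degenerate == "error") {
        stop("degenerate variance: differences for level '", lvl,
             "' are constant and nonzero")
      }
      return(data.frame(level = lvl, t = NA_real_,
                        df = nrow(data) - 1L, p_raw = NA_real_,
                        cohens_d = NA_real_, direction = direction,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(data[, j], base, paired = TRUE,
                        alternative = direction)
    data.frame(
      level = lvl,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value,
      cohens_d = mean(diffs) / stats::sd(diffs),
      direction = direction,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corr <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_corr[ok] <- fdr_bh(out$p_raw[ok])
  out[, c("level", "t", "df", "p_raw", "p_corr", "cohens_d", "direction")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone-enforced, capped at 1), delegated to
#' [stats::p.adjust()] after validation.
#'
#' @param p_values numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, `>=` the input elementwise.
#' @export
fdr_bh <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' One-sample t-test with Cohen's d
#'
#' @param values numeric sample (n >= 2, nonzero variance).
#' @param mu0 null value (default 0).
#' @param tails 1 (alternative: mean > mu0) or 2.
#' @return `stat_result` list: `statistic = "t"`, `value`, `df`, `p_raw`,
#'   `cohens_d = (mean - mu0) / sd`, `direction`.
#' @export
one_sample_t <- function(values, mu0 = 0, tails = 2L) {
  stopifnot(length(values) >= 2L, tails %in% c(1L, 2L))
  if (stats::sd(values) == 0) {
    stop("degenerate variance: all values identical")
  }
  alt <- if (tails == 1L) "greater" else "two.sided"
  tt <- stats::t.test(values, mu = mu0, alternative = alt)
  structure(
    list(statistic = "t", value = unname(tt$statistic),
         df = unname(tt$parameter), p_raw = tt$p.value,
         cohens_d = (mean(values) - mu0) / stats::sd(values),
         direction = if (tails == 1L) "greater" else "two-tailed"),
    class = "stat_result"
  )
}

#' JZS Bayes factor for a one-sample t statistic
#'
#' Default Bayesian t-test: the alternative places a Cauchy(0, r) prior on
#' the standardised effect, equivalent to a mixture over the variance ratio
#' g with an inverse-chi-squared(1) weight scaled by `r^2`.  BF10 is the
#' ratio of the marginal likelihood under the alternative, obtained by
#' numerical integration over g, to the point-null likelihood.
#'
#' @param t observed t statistic.
#' @param n sample size (df = n - 1).
#' @param prior_scale Cauchy scale r (default `sqrt(2)/2` ~ 0.707).
#' @return Object of class `bayes_result`: list with `ln_bf10`,
#'   `prior_scale`, `model = "one-sample-t"`.
#' @examples
#' jzs_bf_one_sample(6.46, 22)$ln_bf10  # ~ 9.11
#' @export
jzs_bf_one_sample <- function(t, n, prior_scale = sqrt(2) / 2) {
  stopifnot(is.finite(t), n >= 2, prior_scale > 0)
  nu <- n - 1
  r2 <- prior_scale ^ 2
  log_null <- -(nu + 1) / 2 * log1p(t ^ 2 / nu)
  integrand <- function(g) {
    c2 <- 1 + n * g * r2
    exp(-0.5 * log(c2) - (nu + 1) / 2 * log1p(t ^ 2 / (c2 * nu)) -
          log_null) *
      (2 * pi) ^ (-0.5) * g ^ (-1.5) * exp(-1 / (2 * g))
  }
  int <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                     subdivisions = 500L),
    error = function(e) stop("JZS integration failed: ",
                             conditionMessage(e)))
  structure(
    list(ln_bf10 = log(int$value), prior_scale = prior_scale,
         model = "one-sample-t"),
    class = "bayes_result"
  )
}

#' @export
print.bayes_result <- function(x, ...) {
  cat(sprintf("<bayes_result %s: lnBF10 = %.4g (prior scale %.3g)>\n",
              x$model, x$ln_bf10, x$prior_scale))
  invisible(x)
}

#' Jeffreys-style Bayes factor for a Pearson correlation
#'
#' Tests a correlation against the point null using Jeffreys's
#' approximation to the sampling density of r and a stretched-beta prior of
#' width `kappa = 1` on rho (uniform on (-1, 1)):
#' `BF10 = integral over rho of
#'  (1 - rho^2)^((n-1)/2) (1 - rho * r)^(-(n - 3/2)) / 2 d rho`.
#' Depends on the data only through r, hence invariant under affine
#' rescaling of either variable.
#'
#' @param x,y paired numeric samples (n >= 3, non-constant).
#' @param kappa stretched-beta prior width (default 1).
#' @return `bayes_result` with `ln_bf10`, `prior_scale = kappa`,
#'   `model = "correlation"` and the sample correlation `r`.
#' @export
jzs_bf_correlation <- function(x, y, kappa = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3L, kappa > 0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant sample")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  # guard |r| -> 1, where the Jeffreys integrand develops a near-singular
  # spike at rho = r that defeats the quadrature
  r <- sign(r) * min(abs(r), 0.999)
  a <- 1 / kappa  # stretched beta(1/kappa, 1/kappa) on (-1, 1)
  logf <- function(rho) {
    (n - 1) / 2 * log1p(-rho ^ 2) - (n - 1.5) * log1p(-rho * r) +
      (a - 1) * (log1p(rho) + log1p(-rho))
  }
  norm <- stats::integrate(function(rho) exp((a - 1) *
             (log1p(rho) + log1p(-rho))), -1, 1, rel.tol = 1e-9)$value
  # split at the likelihood peak (rho = r) so narrow modes are resolved
  int1 <- stats::integrate(function(rho) exp(logf(rho)), -1, r,
                           rel.tol = 1e-9, subdivisions = 500L)
  int2 <- stats::integrate(function(rho) exp(logf(rho)), r, 1,
                           rel.tol = 1e-9, subdivisions = 500L)
  int <- list(value = int1$value + int2$value)
  structure(
    list(ln_bf10 = log(int$value / norm), prior_scale = kappa,
         model = "correlation", r = r),
    class = "bayes_result"
  )
}

#' A priori sample size from the noncentral t distribution
#'
#' Smallest n for which a one-sample (equivalently paired) t-test with
#' noncentrality `d * sqrt(n)` reaches the target power, found by scanning
#' n with exact noncentral-t tail probabilities.
#'
#' @param d standardised effect size (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param tails 1 or 2.
#' @param n_max scan ceiling.
#' @return List (class `power_spec`): `effect_size`, `alpha`, `power`
#'   (target), `tails`, `required_n`, `achieved_power`.
#' @examples
#' power_sample_size(0.6, 0.05, 0.80, tails = 1)$required_n  # 19
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.80, tails = 1L,
                              n_max = 10000L) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            tails %in% c(1L, 2L))
  achieved <- function(n) {
    df <- n - 1
    crit <- stats::qt(1 - alpha / tails, df)
    p <- stats::pt(crit, df, ncp = d * sqrt(n), lower.tail = FALSE)
    if (tails == 2L) p <- p + stats::pt(-crit, df, ncp = d * sqrt(n))
    p
  }
  for (n in 2:n_max) {
    if (achieved(n) >= power) {
      return(structure(
        list(effect_size = d, alpha = alpha, power = power, tails = tails,
             required_n = n, achieved_power = achieved(n)),
        class = "power_spec"))
    }
  }
  stop("target power not reachable with n <= ", n_max)
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf(
    "<power_spec: d = %.3g, alpha = %.3g, %d-tailed -> N = %d (power %.3f)>\n",
    x$effect_size, x$alpha, x$tails, x$required_n, x$achieved_power))
  invisible(x)
}
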