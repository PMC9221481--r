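# Statistical comparison layer: paired tests, effect sizes, repeated
# measures ANOVA with Greenhouse-Geisser correction, and the Shapiro-Wilk
# routing between parametric and non-parametric tests.

new_stat_result <- function(test, statistic, df, p, effect, effect_value,
                            normality_route, n) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 effect = effect, effect_value = effect_value,
                 normality_route = normality_route, n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  df <- if (length(x$df) == 2) sprintf("(%.2f, %.2f)", x$df[1], x$df[2])
        else format(round(x$df, 3))
  cat(sprintf("<stat_result> %s: statistic = %.3f, df = %s, p = %.4g, %s = %.3f (n = %d, %s)\n",
              x$test, x$statistic, df, x$p, x$effect, x$effect_value, x$n,
              x$normality_route))
  invisible(x)
}

#' Two-tailed p value of a t statistic
#'
#' @param t t statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Two-tailed tail probability of the central t distribution.
#' @export
p_from_t <- function(t, df) {
  if (any(df < 1)) stop_config("p_from_t: df must be >= 1")
  2 * pt(-abs(t), df)
}

#' Cohen's dz from a paired t statistic
#'
#' For a paired design `dz = |MD| / SD_MD = |t| / sqrt(n)`.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @return Effect size dz (non-negative).
#' @export
dz_from_t <- function(t, n) abs(t) / sqrt(n)

#' Paired t test with Cohen's dz
#'
#' `t = MD / (SD_MD / sqrt(n))` with `df = n - 1`, two-tailed p, and effect
#' size `dz = |MD| / SD_MD` where MD is the mean of the paired differences.
#'
#' @param a,b Paired samples of equal length (n >= 2).
#' @return A `stat_result`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop_config("paired_t: need two equal-length samples with n >= 2")
  d <- a - b
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d == 0)
    stop_config("paired_t: degenerate input, differences have zero variance")
  t <- mean(d) / (sd_d / sqrt(n))
  new_stat_result("paired_t", t, n - 1, p_from_t(t, n - 1),
                  "dz", abs(mean(d)) / sd_d, "parametric", n)
}

#' Wilcoxon signed-rank test with effect size r
#'
#' Signed-rank statistic on the paired differences (zeros dropped), exact
#' null distribution when there are no ties and few pairs, otherwise the
#' normal approximation with tie correction. The effect size is
#' the ratio `|z| / sqrt(n)` with n the number of pairs entered.
#'
#' @param a,b Paired samples.
#' @param exact_max Largest tie-free sample size for which the exact null
#'   distribution is used.
#' @return A `stat_result` with `statistic` the signed-rank sum V of the
#'   positive differences and `df = NA`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0)
    stop_config("wilcoxon_signed_rank: degenerate input, all differences zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)
  mu <- m * (m + 1) / 4
  sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu) / sqrt(sig2)
  has_ties <- any(ties > 1)
  if (!has_ties && m <= exact_max) {
    p <- if (V > mu) 2 * psignrank(V - 1, m, lower.tail = FALSE)
         else 2 * psignrank(V, m)
    p <- min(1, p)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  n <- length(a)
  new_stat_result("wilcoxon", V, NA_real_, p, "r", abs(z) / sqrt(n),
                  "nonparametric", n)
}

# z value of the signed-rank statistic (exposed for effect-size checks)
wilcoxon_z <- function(a, b) {
  d <- (a - b); d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)
  (V - m * (m + 1) / 4) /
    sqrt(m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Decomposes the units x conditions matrix into condition, subject and
#' error sums of squares. Sphericity is checked with Mauchly's test on the
#' orthonormal contrasts; when rejected (p <= 0.05, estimable only for
#' enough units) the Greenhouse-Geisser epsilon rescales both degrees of
#' freedom. The effect size is partial eta squared
#' `SS_cond / (SS_cond + SS_err)`.
#'
#' @param m Numeric matrix, one row per unit (subject), one column per
#'   condition; at least 2 conditions and 3 units, no missing cells.
#' @return A `stat_result` with `df` a length-2 vector (possibly
#'   epsilon-corrected) and extra fields `epsilon`, `mauchly_p`, `sphericity`.
#' @export
rm_anova_gg <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop_config("rm_anova_gg: missing cells are not supported")
  n <- nrow(m); k <- ncol(m)
  if (k < 2 || n < 3)
    stop_config("rm_anova_gg: need >= 2 conditions and >= 3 units")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_cond <= 1e-12 * max(ss_tot, 1)) {   # identical condition means
    res <- new_stat_result("rm_anova", 0, c(df1, df2), 1, "eta_sq", 0,
                           "parametric", n)
    res$epsilon <- 1; res$mauchly_p <- NA_real_; res$sphericity <- TRUE
    res$ss <- c(cond = ss_cond, subj = ss_subj, err = ss_err)
    return(res)
  }
  F <- (ss_cond / df1) / (ss_err / df2)
  # sphericity on orthonormal contrasts of the condition covariance
  ctr <- stats::contr.helmert(k)
  ctr <- qr.Q(qr(ctr))                        # orthonormal k x (k-1)
  S <- stats::cov(m)
  Tm <- t(ctr) %*% S %*% ctr
  ev <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(ev)^2 / (df1 * sum(ev^2))
  mauchly_p <- NA_real_
  sphericity <- TRUE
  if (k > 2 && n > k - 1 && all(ev > 1e-12)) {
    W <- prod(ev) / (mean(ev)^(k - 1))
    f <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
    chi2 <- -(n - 1) * f * log(W)
    dfm <- k * (k - 1) / 2 - 1
    mauchly_p <- stats::pchisq(chi2, dfm, lower.tail = FALSE)
    sphericity <- mauchly_p > 0.05
  }
  if (!sphericity) {
    df1 <- eps * df1; df2 <- eps * df2
  }
  res <- new_stat_result("rm_anova", F, c(df1, df2),
                         pf(F, df1, df2, lower.tail = FALSE),
                         "eta_sq", ss_cond / (ss_cond + ss_err),
                         "parametric", n)
  res$epsilon <- eps; res$mauchly_p <- mauchly_p; res$sphericity <- sphericity
  res$ss <- c(cond = ss_cond, subj = ss_subj, err = ss_err)
  res
}

#' Shapiro-Wilk routing between parametric and non-parametric tests
#'
#' Paired comparisons run the t test when the Shapiro-Wilk test on the
#' paired differences does not reject normality (p > 0.05), and the Wilcoxon
#' signed-rank test otherwise.
#'
#' @param values Numeric sample (normally the paired differences), n >= 3.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(values) {
  if (length(values) < 3)
    stop_config("normality_gate: need n >= 3")
  if (sd(values) == 0)
    stop_config("normality_gate: degenerate input, constant values")
  if (shapiro.test(values)$p.value > 0.05) "parametric" else "nonparametric"
}

#' Coefficient of variation
#'
#' `sd(values) / mean(values)`; undefined (NA) for zero mean, 0 for a
#' constant sample.
#'
#' @param values Numeric sample.
#' @return The CV, or `NA_real_` when the mean is zero.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) return(NA_real_)
  sd(values) / m
}
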