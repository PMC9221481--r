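# Pair enumeration, aggregation tree and the statistical comparison suite.

test_that("pair enumeration counts unordered pairs", {
  expect_equal(nrow(enumerate_signal_pairs()), 378)   # 28 signals
  expect_equal(nrow(enumerate_signal_pairs(c("a", "b"))), 1)
  expect_equal(nrow(enumerate_signal_pairs(letters[1:5])), 10)
  expect_error(enumerate_signal_pairs(c("a", "a")), "duplicate")
})

test_that("pair classification reproduces the region-combination layout", {
  pairs <- classify_pairs(enumerate_signal_pairs())
  intra <- pairs[pairs$scope == "intrapersonal", ]
  inter <- pairs[pairs$scope == "interpersonal", ]
  expect_setequal(unique(intra$combo),
                  paste0("intra-", c("MMGs", "EEGcen", "EEGle", "EEGri",
                                     "EEGcen-EEGle", "EEGcen-EEGri",
                                     "EEGle-EEGri", "MMGs-EEGcen",
                                     "MMGs-EEGle", "MMGs-EEGri")))
  expect_setequal(unique(inter$combo),
                  paste0("inter-", c("MMGs", "EEGcen", "EEGle", "EEGri",
                                     "EEGcen-EEGle", "EEGcen-EEGri",
                                     "EEGle-EEGri", "MMGs-EEGcen",
                                     "MMGs-EEGle", "MMGs-EEGri")))
  # aggregation units per combo match the published sample sizes
  units_of <- function(d, combo) length(unique(d$unit[d$combo == combo]))
  expect_equal(units_of(intra, "intra-MMGs"), 3)
  expect_equal(units_of(intra, "intra-MMGs-EEGcen"), 12)
  expect_equal(units_of(intra, "intra-MMGs-EEGle"), 9)
  expect_equal(units_of(intra, "intra-EEGcen"), 6)
  expect_equal(units_of(intra, "intra-EEGle"), 3)
  expect_equal(units_of(intra, "intra-EEGcen-EEGle"), 12)
  expect_equal(units_of(inter, "inter-MMGs"), 6)
  expect_equal(units_of(inter, "inter-EEGcen"), 10)
  expect_equal(units_of(inter, "inter-EEGri"), 6)
  expect_equal(units_of(inter, "inter-MMGs-EEGcen"), 12)
  expect_equal(units_of(inter, "inter-EEGle-EEGri"), 9)
  # force/ACC scope keeps per-subject units
  fa <- pairs[pairs$scope == "force_acc", ]
  expect_equal(units_of(fa, "force-EEGle"), 6)
  expect_equal(units_of(fa, "ACC-MMGs"), 6)
})

test_that("random pairing always crosses trials and is reproducible", {
  pairs <- enumerate_signal_pairs()
  rnd <- build_random_pairs(pairs, paste0("trial", 1:6), seed = 4)
  expect_equal(nrow(rnd), 378)
  expect_true(all(rnd$trial_a != rnd$trial_b))
  rnd2 <- build_random_pairs(pairs, paste0("trial", 1:6), seed = 4)
  expect_identical(rnd, rnd2)
  expect_error(build_random_pairs(pairs, "trial1", seed = 1), "single trial")
  two <- build_random_pairs(pairs, c("t1", "t2"), seed = 2)
  expect_true(all(two$trial_a != two$trial_b))
})

make_values <- function(scope_filter, value_fun) {
  pairs <- classify_pairs(enumerate_signal_pairs())
  pairs <- pairs[pairs$scope == scope_filter, ]
  grid <- expand.grid(i = seq_len(nrow(pairs)),
                      trial = 1:6, stringsAsFactors = FALSE)
  df <- data.frame(pairs[grid$i, ], trial_id = paste0("trial", grid$trial))
  df$configuration <- ifelse(grid$trial %% 2 == 1, "A-PIMA_B-HIMA",
                             "B-PIMA_A-HIMA")
  subj <- wavecoh:::signal_subject(df$side_a)
  nb <- is.na(subj)
  subj[nb] <- wavecoh:::signal_subject(df$side_b)[nb]
  df$subject <- if (scope_filter == "interpersonal") NA else subj
  df$task <- ifelse(df$configuration == "A-PIMA_B-HIMA",
                    ifelse(df$subject == "A", "PIMA", "HIMA"),
                    ifelse(df$subject == "A", "HIMA", "PIMA"))
  df$parameter <- "Sum5PaD"
  df$value <- value_fun(df)
  df
}

test_that("aggregation is idempotent on constant inputs", {
  for (scope in c("intrapersonal", "interpersonal", "force_acc")) {
    vals <- make_values(scope, function(df) rep(7.5, nrow(df)))
    agg <- aggregate_pairs(vals, scope)
    expect_true(all(abs(agg$value - 7.5) < 1e-12))
  }
})

test_that("intrapersonal aggregation averages subjects after configurations", {
  vals <- make_values("intrapersonal", function(df) {
    # subject A always 10 within config 1, 20 within config 2; B 30 and 50
    ifelse(df$subject == "A",
           ifelse(df$configuration == "A-PIMA_B-HIMA", 10, 20),
           ifelse(df$configuration == "A-PIMA_B-HIMA", 30, 50))
  })
  agg <- aggregate_pairs(vals, "intrapersonal")
  # AB_IMA = mean(mean(config means of A), mean(config means of B))
  expect_true(all(abs(agg$value - mean(c(mean(c(10, 20)),
                                         mean(c(30, 50))))) < 1e-12))
  expect_equal(sum(agg$combo == "intra-MMGs"), 3)
  expect_equal(nrow(agg), 3 + 6 + 3 + 3 + 12 + 12 + 9 + 12 + 9 + 9)
})

test_that("interpersonal aggregation averages the two configuration means", {
  vals <- make_values("interpersonal", function(df)
    ifelse(df$configuration == "A-PIMA_B-HIMA", 12, 24))
  agg <- aggregate_pairs(vals, "interpersonal")
  expect_true(all(abs(agg$value - 18) < 1e-12))
  expect_equal(sum(agg$combo == "inter-MMGs"), 6)
  expect_equal(sum(agg$combo == "inter-EEGcen"), 10)
})

test_that("task grouping follows the acting subject's task", {
  vals <- make_values("intrapersonal", function(df)
    ifelse(df$task == "HIMA", 100, 50))
  tg <- aggregate_pairs(vals, "task_grouped")
  expect_true(all(tg$value[tg$task == "HIMA"] == 100))
  expect_true(all(tg$value[tg$task == "PIMA"] == 50))
  # one row per unit, subject and task
  expect_equal(nrow(tg[tg$combo == "intra-MMGs", ]), 3 * 2 * 2)
})

test_that("coefficient of variation reproduces published ratios", {
  # mean 97.097, sd 4.895 -> 0.050; mean 20.556, sd 3.481 -> 0.169
  expect_equal(round(4.895 / 97.097, 3), 0.050)
  v1 <- c(92.202, 97.097, 101.992)       # mean 97.097, sd 4.895
  expect_equal(mean(v1), 97.097, tolerance = 1e-12)
  expect_equal(sd(v1), 4.895, tolerance = 1e-12)
  expect_equal(round(coefficient_of_variation(v1), 3), 0.050)
  v2 <- c(17.075, 20.556, 24.037)        # mean 20.556, sd 3.481
  expect_equal(round(coefficient_of_variation(v2), 3), 0.169)
  expect_equal(coefficient_of_variation(rep(5, 4)), 0)
  expect_true(is.na(coefficient_of_variation(c(-1, 1))))
})

test_that("paired t follows its closed form and the dz identity", {
  d <- c(2 - sqrt(6), 2, 2, 2 + sqrt(6))   # mean 2, sd 2, n 4
  res <- paired_t(d, rep(0, 4))
  expect_equal(res$statistic, 2, tolerance = 1e-12)
  expect_equal(res$effect_value, 1, tolerance = 1e-12)
  expect_equal(res$df, 3)
  # matches stats::t.test
  tt <- t.test(d, rep(0, 4), paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_error(paired_t(1:4, 1:4), "zero variance")
  set.seed(10)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    r <- paired_t(a, b)
    expect_equal(r$effect_value, abs(r$statistic) / sqrt(n),
                 tolerance = 1e-12)
  }
})

test_that("t tail probabilities are invariant under sign flips", {
  expect_equal(p_from_t(0, 5), 1)
  expect_equal(p_from_t(2.5, 7), p_from_t(-2.5, 7))
  expect_error(p_from_t(1, 0.5), "df")
})

test_that("wilcoxon handles balanced ranks, matches enumeration, reports r", {
  res <- wilcoxon_signed_rank(c(-1, 1, -2, 2, -3, 3), rep(0, 6))
  expect_gt(res$p, 0.9)
  set.seed(11)
  for (n in c(6, 8, 10)) {
    repeat {
      a <- round(rnorm(n), 3); b <- round(rnorm(n), 3)
      d <- a - b
      if (all(d != 0) && !anyDuplicated(abs(d))) break
    }
    r <- wilcoxon_signed_rank(a, b)
    expect_equal(r$p, wilcoxon_enum_p(d), tolerance = 1e-12)
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = TRUE))
    expect_equal(r$p, wt$p.value, tolerance = 1e-12)
  }
  # effect size is |z|/sqrt(n) with the tie-corrected z
  a <- c(5, 3, 8, 9, 1, 2, 6, 7, 4, 10); b <- rep(2.5, 10)
  r <- wilcoxon_signed_rank(a, b)
  z <- wavecoh:::wilcoxon_z(a, b)
  expect_equal(r$effect_value, abs(z) / sqrt(10), tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  m <- matrix(rep(c(3, 5, 9), each = 4), 4)
  same <- rm_anova_gg(cbind(m[, 1], m[, 1], m[, 1]))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # two conditions: F equals the squared paired t
  set.seed(12)
  a <- rnorm(8); b <- rnorm(8)
  f2 <- rm_anova_gg(cbind(a, b))
  expect_equal(f2$statistic, paired_t(a, b)$statistic^2, tolerance = 1e-10)
  # random three-condition data against the from-scratch decomposition
  for (i in 1:10) {
    y <- matrix(rnorm(18), 6, 3)
    res <- rm_anova_gg(y)
    ss <- rm_ss_oracle(y)
    expect_equal(unname(res$ss), unname(ss), tolerance = 1e-10)
    expect_equal(res$effect_value, ss["cond"] / (ss["cond"] + ss["err"]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_gte(res$epsilon, 1 / 2 - 1e-9)  # lower bound 1/(k-1)
    expect_lte(res$epsilon, 1 + 1e-9)
  }
  expect_error(rm_anova_gg(matrix(1:4, 2)), "units")
  expect_error(rm_anova_gg(matrix(c(1, NA, 3, 4, 5, 6), 3)), "missing")
})

test_that("normality gate routes by the Shapiro-Wilk test", {
  routes <- vapply(1:20, function(seed) {
    set.seed(seed)
    normality_gate(rnorm(50))
  }, character(1))
  expect_gte(mean(routes == "parametric"), 0.9)
  set.seed(13)
  heavy <- c(rnorm(9), 50)
  expect_equal(normality_gate(heavy), "nonparametric")
  expect_error(normality_gate(rep(1, 5)), "constant")
  expect_error(normality_gate(c(1, 2)), "n >= 3")
})

test_that("real-vs-random comparison builds one row per region combination", {
  set.seed(14)
  pairs <- classify_pairs(enumerate_signal_pairs())
  intra <- unique(pairs[pairs$scope == "intrapersonal", c("combo", "unit")])
  real <- data.frame(intra, value = rnorm(nrow(intra), 90, 5))
  random <- data.frame(intra, value = rnorm(nrow(intra), 20, 5))
  cmp <- compare_real_vs_random(real, random)
  expect_equal(nrow(cmp), 10)
  expect_setequal(cmp$combo, unique(intra$combo))
  big <- cmp[cmp$n >= 3, ]
  expect_true(all(big$p < 0.05))
  expect_true(all(big$mean_real > big$mean_rand))
  expect_true(all(big$test %in% c("paired_t", "wilcoxon")))
  # identical inputs are degenerate, not significant
  cmp0 <- compare_real_vs_random(real, real)
  expect_true(all(is.na(cmp0$p)))
  # unmatched units are reported
  expect_error(compare_real_vs_random(real[-1, ], random), "unmatched")
})
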