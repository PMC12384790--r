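make_table <- function(s = 10, c = 3, effect = 0, seed = 1) {
  set.seed(seed)
  subj <- rnorm(s, sd = 1)
  vals <- outer(subj, rep(0, c), "+") + matrix(rnorm(s * c), s, c) +
    matrix(rep(seq(0, effect, length.out = c), each = s), s, c)
  subject_condition_table(vals)
}

test_that("assumption checks report normality and homogeneity", {
  tab <- make_table(s = 40, seed = 2)
  rep_ <- check_assumptions(tab)
  expect_named(rep_, c("normality", "homogeneity"))
  expect_equal(nrow(rep_$normality), 3)
  expect_true(all(rep_$normality$p >= 0 & rep_$normality$p <= 1))

  # heavy-tailed samples are flagged most of the time
  set.seed(3)
  hits <- 0
  for (i in 1:30) {
    vals <- cbind(rcauchy(100), rcauchy(100))
    r <- suppressWarnings(check_assumptions(subject_condition_table(vals)))
    if (any(!r$normality$ok)) hits <- hits + 1
  }
  expect_gte(hits, 27)  # >= 90% detection
})

test_that("RM-ANOVA matches brute-force sums of squares", {
  tab <- subject_condition_table(matrix(c(3, 5, 2, 4, 8, 3), 3, 2))
  an <- rm_anova_oneway(tab)
  expect_equal(an$F, oracle_rm_anova_F(unclass(tab)), tolerance = 1e-10)
  expect_equal(an$df, c(1, 2))

  set.seed(4)
  for (i in 1:10) {
    tab <- make_table(s = sample(4:12, 1), c = sample(2:4, 1), seed = i)
    an <- rm_anova_oneway(tab)
    expect_equal(an$F, oracle_rm_anova_F(unclass(tab)), tolerance = 1e-8)
  }
})

test_that("RM-ANOVA F collapses when condition means are identical", {
  set.seed(5)
  subj <- rnorm(12)
  tab <- subject_condition_table(outer(subj, rep(1, 3)))
  # condition variance is exactly zero; F is 0/0 -> NaN guarded by data
  tab2 <- subject_condition_table(outer(subj, rep(1, 3)) +
                                    matrix(rnorm(36, sd = 1e-8), 12, 3))
  an <- rm_anova_oneway(tab2)
  expect_lt(an$F, 5)  # no spurious condition effect
  expect_error(rm_anova_oneway(
    subject_condition_table(matrix(c(1, NA, 2, 3), 2, 2))), "complete")
})

test_that("null RM-ANOVA p-values are calibrated", {
  set.seed(6)
  p <- replicate(400, rm_anova_oneway(make_table(s = 10, c = 3,
                                                 seed = sample.int(1e6, 1)))$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment is standard step-up", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.2, 0.04, 0.9)
  adj <- fdr_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  expect_equal(fdr_bh(p[perm]), adj[perm])
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Scheffe contrasts find separated conditions with direction", {
  set.seed(7)
  hits <- 0
  for (i in 1:20) {
    base <- rnorm(30)
    tab <- subject_condition_table(cbind(A = base + rnorm(30),
                                         B = base + rnorm(30) + 5))
    ph <- scheffe_posthoc(tab)
    if (ph$p < 0.05 && ph$direction == "B > A") hits <- hits + 1
  }
  expect_gte(hits, 20 * 0.99)

  # identical conditions: no direction claimed
  base <- rnorm(20)
  tab0 <- subject_condition_table(cbind(base + rnorm(20, sd = 0.1),
                                        base + rnorm(20, sd = 0.1)))
  ph0 <- scheffe_posthoc(tab0)
  if (ph0$p >= 0.05) expect_equal(ph0$direction, "")
})

test_that("Scheffe is conservative relative to the per-pair t test", {
  set.seed(8)
  for (i in 1:20) {
    tab <- make_table(s = sample(6:15, 1), c = sample(3:4, 1),
                      effect = runif(1, 0, 2), seed = i * 11)
    an <- rm_anova_oneway(tab)
    ph <- scheffe_posthoc(tab, an)
    cn <- colnames(tab)
    for (r in seq_len(nrow(ph))) {
      pr <- strsplit(ph$pair[r], " vs ")[[1]]
      d <- an$means[pr[1]] - an$means[pr[2]]
      t2 <- d^2 / (2 * an$ms_error / nrow(tab))
      p_t <- pf(t2, 1, an$df_error, lower.tail = FALSE)
      expect_gte(ph$p[r] + 1e-12, p_t)
    }
  }
})

test_that("Cohen's d bands follow the stated cutpoints", {
  set.seed(9)
  x <- rnorm(50)
  same <- cohens_d(x, x + rnorm(50, sd = 1e-12))
  expect_lt(abs(same$d), 0.05)
  expect_equal(same$band, "small")
  expect_equal(cohens_d(rep(c(0, 1), 10), rep(c(0.28, 1.28), 10))$band,
               "moderate")
  expect_equal(cohens_d(rep(c(0, 1), 10), rep(c(0.9, 1.9), 10))$band,
               "large")
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled SD")
})

test_that("correlation bands and reporting filter behave", {
  x <- 1:20
  perfect <- correlate_behavior(x, x)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$band, "strong")
  expect_true(perfect$reportable)

  set.seed(10)
  low_hits <- 0
  for (i in 1:200) {
    r <- correlate_behavior(rnorm(30), rnorm(30))
    if (abs(r$r) < 0.3) low_hits <- low_hits + 1
  }
  expect_gt(low_hits / 200, 0.80)
  expect_lt(low_hits / 200, 0.97)

  set.seed(11)
  x <- rnorm(60)
  y <- -x + rnorm(60, sd = 1.1)
  r <- correlate_behavior(x, y)
  expect_lt(r$r, 0)
  expect_error(correlate_behavior(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("sample-size search reproduces the printed design and is monotone", {
  n <- rm_anova_sample_size(0.25, 0.05, 0.8, 1, 3, 0.5, 1)
  expect_identical(as.integer(n), 28L)
  expect_gte(attr(n, "power"), 0.8)
  n_big <- rm_anova_sample_size(0.5, 0.05, 0.8, 1, 3, 0.5, 1)
  expect_lt(n_big, n)
  expect_error(rm_anova_sample_size(1e-4, target_power = 0.999,
                                    n_cap = 1e4), "cap")
  expect_error(rm_anova_sample_size(-1), "effect_size_f")
})

test_that("the metric-wise ANOVA report corrects across metrics", {
  des <- study_design(n_subjects = 8,
                      conditions = list(a = list(dwell = 0.95),
                                        b = list(dwell = 0.75)),
                      trials_per_condition = 2,
                      base_config = synth_config(duration = 3, seed = 1),
                      include_eeg = FALSE, seed = 12)
  m <- study_sequence_metrics(generate_study(des), seed = 12)
  res <- rm_anova_by_metric(m)
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_fdr >= res$p))
  # a strong dwell shift must surface in the transition-sensitive metrics
  expect_true(res$significant[res$metric == "ms_lzc"])
})

test_that("transition-structure shifts flag Ms-LZC more than Ms-SE", {
  set.seed(13)
  lzc_hits <- se_hits <- 0
  for (i in 1:15) {
    des <- study_design(n_subjects = 10,
                        conditions = list(a = list(dwell = 0.95),
                                          b = list(dwell = 0.85)),
                        trials_per_condition = 1,
                        base_config = synth_config(duration = 3, seed = 1),
                        include_eeg = FALSE, seed = 1000 + i)
    m <- study_sequence_metrics(generate_study(des),
                                metrics = c("ms_lzc", "ms_se"),
                                seed = 1000 + i)
    res <- rm_anova_by_metric(m)
    if (res$p[res$metric == "ms_lzc"] < 0.05) lzc_hits <- lzc_hits + 1
    if (res$p[res$metric == "ms_se"] < 0.05) se_hits <- se_hits + 1
  }
  expect_gt(lzc_hits, se_hits)
})
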