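test_that("generated templates are zero-mean, unit-norm and decorrelated", {
  ts <- generate_templates(30, 5, seed = 1)
  expect_equal(rowMeans(ts$maps), rep(0, 5), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(ts$maps^2)), rep(1, 5), tolerance = 1e-12)
  r <- cor(t(ts$maps))
  expect_true(max(abs(r[upper.tri(r)])) <= 0.5)
})

test_that("template generation is deterministic and rejects infeasible K", {
  a <- generate_templates(30, 5, seed = 42)
  b <- generate_templates(30, 5, seed = 42)
  expect_identical(a$maps, b$maps)
  expect_false(identical(a$maps, generate_templates(30, 5, seed = 43)$maps))
  expect_error(generate_templates(2, 3), "orthogonal")
})

test_that("label chains follow their transition matrices", {
  # absorbing identity chain stays constant
  cfg <- synth_config(K = 3, transition_matrix = diag(3), duration = 1,
                      seed = 1)
  s <- generate_label_sequence(cfg, init_state = 2)
  expect_true(all(s$labels == 2L))

  # cyclic permutation chain is exactly periodic
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  cfg <- synth_config(K = 3, transition_matrix = P, duration = 1, seed = 1)
  s <- generate_label_sequence(cfg, init_state = 1)
  expect_equal(s$labels, rep(c(1L, 2L, 3L), length.out = 250))

  # i.i.d. uniform rows give near-uniform occupancy (3 Monte-Carlo SE)
  K <- 4
  cfg <- synth_config(K = K, transition_matrix = matrix(1 / K, K, K),
                      fs = 1000, duration = 50, seed = 7)
  s <- generate_label_sequence(cfg)
  n <- length(s$labels)
  p_hat <- tabulate(s$labels, K) / n
  se <- sqrt((1 / K) * (1 - 1 / K) / n)
  expect_true(all(abs(p_hat - 1 / K) <= 3 * se))
})

test_that("empirical transition frequencies converge to the configured matrix", {
  cfg <- synth_config(K = 4, fs = 1000, duration = 100, dwell = 0.9,
                      seed = 11)
  s <- generate_label_sequence(cfg)  # 1e5 samples
  m <- transition_model(s)
  expect_lt(max(abs(m$p_cond - cfg$transition_matrix)), 0.02)
})

test_that("non-stochastic transition matrices are rejected", {
  P <- matrix(c(0.5, 0.6, 0.4, 0.5), 2, 2)
  expect_error(synth_config(K = 2, transition_matrix = P), "sum to 1")
})

test_that("synthetic EEG hits the requested SNR exactly and reproducibly", {
  cfg <- synth_config(n_channels = 20, K = 4, duration = 4, snr_db = 13,
                      seed = 5)
  tpl <- generate_templates(20, 4, seed = 5)
  lab <- generate_label_sequence(cfg)
  rec <- generate_eeg(tpl, lab, cfg)
  gt <- attr(rec, "ground_truth")
  S <- t(tpl$maps)[, gt$labels] * rep(gt$amplitudes, each = 20)
  noise <- rec$data - S
  realized_db <- 10 * log10(mean(S^2) / mean(noise^2))
  expect_lt(abs(realized_db - 13), 0.5)
  # bitwise determinism
  rec2 <- generate_eeg(tpl, lab, cfg)
  expect_identical(rec$data, rec2$data)
})

test_that("back-fit recovery tracks the SNR regime", {
  cfg <- synth_config(n_channels = 30, K = 5, duration = 4, snr_db = 60,
                      seed = 2)
  tpl <- generate_templates(30, 5, seed = 2)
  lab <- generate_label_sequence(cfg)
  rec <- generate_eeg(tpl, lab, cfg)
  bf <- backfit(tpl, rec)
  expect_gte(mean(bf$labels == lab$labels), 0.99)

  cfg_lo <- synth_config(n_channels = 30, K = 5, duration = 4,
                         snr_db = -60, seed = 2)
  rec_lo <- generate_eeg(tpl, lab, cfg_lo)
  bf_lo <- backfit(tpl, rec_lo)
  acc <- mean(bf_lo$labels == lab$labels)
  expect_lt(acc, 0.35)  # chance is 1/5
})

test_that("generate_eeg validates labels and channel counts", {
  cfg <- synth_config(n_channels = 10, K = 3, duration = 1, seed = 1)
  tpl <- generate_templates(10, 3, seed = 1)
  expect_error(generate_eeg(tpl, label_sequence(c(1, 4), fs = 250, K = 4),
                            cfg), "outside")
  tpl_bad <- generate_templates(12, 3, seed = 1)
  lab <- generate_label_sequence(cfg)
  expect_error(generate_eeg(tpl_bad, lab, cfg), "channel count")
})

test_that("a synthetic study has the declared shape and ground truth", {
  des <- study_design(n_subjects = 3,
                      conditions = list(normal = list(),
                                        lowlight = list(dwell = 0.9)),
                      trials_per_condition = 2,
                      base_config = synth_config(duration = 1, seed = 1),
                      include_eeg = FALSE, seed = 3)
  st <- generate_study(des)
  expect_equal(nrow(st$trials), 3 * 2 * 2)
  expect_setequal(unique(st$trials$condition), c("normal", "lowlight"))
  expect_equal(st$ground_truth$dwell,
               c(0.95, 0.9))
  expect_true(all(vapply(st$trials$labels, inherits, TRUE,
                         "label_sequence")))
})

test_that("a more random condition yields higher mean Ms-LZC", {
  des <- study_design(n_subjects = 8,
                      conditions = list(calm = list(dwell = 0.95),
                                        jumpy = list(dwell = 0.7)),
                      trials_per_condition = 2,
                      base_config = synth_config(duration = 3, seed = 1),
                      subject_dwell_sd = 0.1,
                      include_eeg = FALSE, seed = 9)
  st <- generate_study(des)
  m <- study_sequence_metrics(st, metrics = "ms_lzc", seed = 9)
  means <- tapply(m$value, m$condition, mean)
  expect_gt(means[["jumpy"]], means[["calm"]])
})

test_that("single-subject designs are refused by the RM-ANOVA layer", {
  des <- study_design(n_subjects = 1,
                      conditions = list(a = list(), b = list()),
                      trials_per_condition = 1,
                      base_config = synth_config(duration = 1, seed = 1),
                      include_eeg = FALSE, seed = 1)
  st <- generate_study(des)
  m <- study_sequence_metrics(st, metrics = "ms_se", seed = 1)
  expect_error(subject_condition_table(m), ">= 2 subjects")
})
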