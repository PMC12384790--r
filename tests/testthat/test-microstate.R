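test_that("GFP matches its closed forms", {
  expect_equal(gfp(matrix(5, 4, 1)), 0)
  expect_equal(gfp(matrix(c(1, -1), 2, 1)), 1)
  expect_equal(gfp(matrix(c(2, 0, -2, 0), 4, 1)), sqrt(8 / 4))
  expect_error(gfp(matrix(1, 1, 10)), "2 channels")
})

test_that("GFP peaks are strict interior maxima", {
  expect_length(gfp_peaks(1:10), 0)
  expect_equal(gfp_peaks(c(0, 1, 0, 1, 0)), c(2L, 4L))
  # 5 full cycles of a sinusoid have exactly 5 maxima
  g <- sin(2 * pi * 5 * seq(0, 1 - 1e-4, by = 1e-4)) + 2
  expect_length(gfp_peaks(g), 5)
  expect_error(gfp_peaks(c(1, 2)), "length >= 3")
})

test_that("GEV evaluates the explained-variance formula", {
  tpl <- generate_templates(12, 3, seed = 1)
  # maps exactly equal to their templates -> GEV = 1
  maps <- t(tpl$maps)[, c(1, 2, 3, 1, 2, 3)] * 5
  expect_equal(as.numeric(gev(tpl, maps)), 1, tolerance = 1e-10)
  # maps orthogonal to every template -> GEV = 0
  ortho <- generate_templates(12, 3, seed = 99)$maps
  proj <- ortho - ortho %*% t(tpl$maps) %*% tpl$maps
  proj <- proj - rowMeans(proj)
  expect_lt(as.numeric(gev(tpl, t(proj))), 1e-10)
  # half perfectly fitted, half orthogonal, equal GFP -> 0.5
  half <- cbind(t(tpl$maps), t(proj / sqrt(rowSums(proj^2))))
  expect_equal(as.numeric(gev(tpl, half)), 0.5, tolerance = 1e-10)
})

test_that("SSE is zero on exact template data and matches brute force", {
  tpl <- generate_templates(8, 2, seed = 3)
  exact <- t(tpl$maps)[, rep(1:2, 10)] * rep(runif(20, 0.5, 2), each = 8)
  expect_lt(sse(tpl, exact), 1e-18)

  # hand-checkable 3-channel case against direct arithmetic:
  # template (1, 0, -1) normalizes to t = (1, 0, -1)/sqrt(2)
  templates <- template_set(matrix(c(1, 0, -1), 1, 3))
  data2 <- matrix(c(2, 0, 1,
                    0, 3, 0), 3, 2)
  # col 1 centered: (1, -1, 0), a = 1/sqrt(2), residual 2 - 1/2 = 3/2
  # col 2 centered: (-1, 2, -1), a = 0, residual 6
  expect_equal(sse(templates, data2), 1.5 + 6, tolerance = 1e-12)
})

test_that("SSE is non-increasing in K on the same data", {
  set.seed(4)
  pm <- matrix(rnorm(20 * 300), 20, 300)
  by_k <- aahc_cluster(pm, 1:8)
  sse_k <- vapply(by_k, function(t) t$sse, 0)
  expect_true(all(diff(sse_k) <= 1e-8))
})

test_that("AAHC recovers separable clusters and ignores polarity", {
  tpl <- generate_templates(16, 3, seed = 6)
  pm <- t(tpl$maps)[, rep(1:3, each = 40)] *
    rep(abs(rnorm(120, 1, 0.1)), each = 16)
  got <- aahc_cluster(pm, 3)$K3
  r <- abs(got$maps %*% t(tpl$maps))
  expect_equal(unname(apply(r, 2, max)), rep(1, 3), tolerance = 1e-8)

  flip <- pm
  flip[, seq(1, 120, by = 2)] <- -flip[, seq(1, 120, by = 2)]
  got_flip <- aahc_cluster(flip, 3)$K3
  match_up_to_sign <- apply(abs(got_flip$maps %*% t(got$maps)), 1, max)
  expect_equal(unname(match_up_to_sign), rep(1, 3), tolerance = 1e-8)
  expect_error(aahc_cluster(pm[, 1:2], 3), "usable maps")
})

test_that("AAHC recovers generating maps from noisy peak data", {
  set.seed(8)
  tpl <- generate_templates(30, 5, seed = 8)
  # 400 maps drawn from the 5 templates with map-level noise at 20 dB
  lab <- sample.int(5, 400, replace = TRUE)
  sig <- t(tpl$maps)[, lab] * rep(abs(rnorm(400, 1, 0.1)), each = 30)
  noise <- matrix(rnorm(30 * 400), 30, 400)
  noise <- noise * sqrt(mean(sig^2) / (mean(noise^2) * 10^(20 / 10)))
  got <- aahc_cluster(sig + noise, 5)$K5
  r <- abs(got$maps %*% t(tpl$maps))
  expect_gte(mean(apply(r, 2, max)), 0.9)
})

test_that("AAHC is deterministic and stable under input permutation", {
  set.seed(10)
  tpl <- generate_templates(20, 4, seed = 10)
  pm <- t(tpl$maps)[, rep(1:4, each = 60)] + rnorm(20 * 240, sd = 0.15)
  a <- aahc_cluster(pm, 4)$K4
  b <- aahc_cluster(pm, 4)$K4
  expect_identical(a$maps, b$maps)
  perm <- sample(ncol(pm))
  c_ <- aahc_cluster(pm[, perm], 4)$K4
  expect_lt(abs(a$gev_total - c_$gev_total), 0.01)
})

test_that("elbow selection finds the generating template count", {
  tpl <- generate_templates(24, 5, seed = 12)
  set.seed(12)
  pm <- t(tpl$maps)[, rep(1:5, each = 60)] *
    rep(abs(rnorm(300, 1, 0.1)), each = 24)
  by_k <- aahc_cluster(pm, 1:10)
  sse_k <- vapply(by_k, function(t) t$sse, 0)
  gev_k <- vapply(by_k, function(t) t$gev_total, 0)
  expect_equal(select_k_elbow(sse_k, gev_k, 1:10), 5)

  # two orthogonal templates
  tpl2 <- generate_templates(24, 2, seed = 13)
  pm2 <- t(tpl2$maps)[, rep(1:2, each = 50)] *
    rep(abs(rnorm(100, 1, 0.1)), each = 24)
  by_k2 <- aahc_cluster(pm2, 1:6)
  expect_equal(select_k_elbow(vapply(by_k2, function(t) t$sse, 0),
                              vapply(by_k2, function(t) t$gev_total, 0),
                              1:6), 2)
})

test_that("elbow selection degrades gracefully", {
  # geometric (curvature-free in log) decay falls back with a warning
  sse_lin <- 100 * 0.5^(1:8)
  expect_warning(k <- select_k_elbow(sse_lin, rep(0.9, 8), 1:8),
                 "no elbow")
  expect_equal(k, 1)
  # no K passing the threshold is an error listing the attained GEVs
  expect_error(select_k_elbow(sse_lin, seq(0.1, 0.45, length.out = 8), 1:8),
               "no K reaches")
})

test_that("back-fitting labels noiseless data exactly and is polarity-blind", {
  tpl <- generate_templates(15, 4, seed = 14)
  truth <- rep(c(1L, 3L, 2L, 4L, 2L), each = 20)
  x <- t(tpl$maps)[, truth] * rep(abs(rnorm(100, 1, 0.1)), each = 15)
  bf <- backfit(tpl, x, fs = 250)
  expect_equal(bf$labels, truth)
  bf_neg <- backfit(tpl, -x, fs = 250)
  expect_equal(bf_neg$labels, truth)
})

test_that("back-fitting carries the previous label over flat samples", {
  tpl <- generate_templates(6, 2, seed = 15)
  x <- cbind(t(tpl$maps)[, c(2, 2)], 0, t(tpl$maps)[, 1])
  expect_message(bf <- backfit(tpl, x, fs = 100), "zero-variance")
  expect_equal(bf$labels, c(2L, 2L, 2L, 1L))
  # a flat first sample falls back to label 1
  x2 <- cbind(0, t(tpl$maps)[, 2, drop = FALSE])
  expect_message(bf2 <- backfit(tpl, x2, fs = 100))
  expect_equal(bf2$labels, c(1L, 2L))
})

test_that("microstate parameters match the hand-counted example", {
  p <- microstate_params(label_sequence(c(1, 1, 2, 2, 2), fs = 5))
  expect_equal(unname(p$coverage), c(0.4, 0.6))
  expect_equal(unname(p$mean_duration_ms), c(400, 600))
  expect_equal(unname(p$occurrence_per_s), c(1, 1))
  expect_equal(p$transition_matrix["Ms1", "Ms2"], 1)

  const <- microstate_params(label_sequence(rep(2L, 50), fs = 10, K = 3))
  expect_equal(unname(const$coverage), c(0, 1, 0))
  expect_true(all(const$transition_matrix == 0))
})

test_that("coverages always partition the sequence", {
  set.seed(16)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    s <- label_sequence(sample.int(K, 200, TRUE), fs = 250, K = K)
    expect_equal(sum(microstate_params(s)$coverage), 1, tolerance = 1e-10)
  }
})

test_that("the full pipeline recovers the configured dwell time", {
  cfg <- synth_config(n_channels = 30, K = 5, duration = 40, snr_db = 20,
                      dwell = 0.95, seed = 17)  # 1e4 samples, ~80 ms dwell
  tpl <- generate_templates(30, 5, seed = 17)
  lab <- generate_label_sequence(cfg)
  rec <- generate_eeg(tpl, lab, cfg)
  bf <- backfit(tpl, rec)
  true_dwell_ms <- mean(rle(lab$labels)$lengths) / 250 * 1000
  est_dwell_ms <- mean(rle(bf$labels)$lengths) / 250 * 1000
  expect_lt(abs(est_dwell_ms - true_dwell_ms) / true_dwell_ms, 0.10)
})

test_that("fit_microstates meets the GEV threshold on default synthetic data", {
  cfg <- synth_config(n_channels = 30, K = 5, duration = 40, snr_db = 20,
                      seed = 18)
  tpl <- generate_templates(30, 5, seed = 18)
  rec <- generate_eeg(tpl, generate_label_sequence(cfg), cfg)
  rec <- preprocess_chain(rec, band = c(2, 20))
  fit <- fit_microstates(rec, k_range = 1:10)
  expect_equal(fit$K, 5)
  expect_gte(fit$templates$gev_total, 0.65)
  expect_length(fit$sequences, 1)
  expect_equal(fit$sequences[[1]]$K, fit$K)
})
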