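#' Empirical transition model of a symbolic sequence
#'
#' Estimates the stationary probabilities `p_i` (symbol frequencies), the
#' joint pair probabilities `p_ij` (consecutive-pair frequencies) and the
#' conditional transition probabilities `p_{i->j}` (row-normalized pair
#' counts, so that visited rows sum to exactly 1). With
#' `include_self = FALSE` the sequence is first run-length compressed, so
#' only segment-to-segment transitions are counted.
#'
#' @param seq A [label_sequence()] or integer vector (length >= 2).
#' @param include_self Count self-transitions at the sample level
#'   (default TRUE); FALSE switches to run-level counting.
#' @param n_states Alphabet size; taken from the sequence when missing.
#' @return An object of class `transition_model` with elements `p_i`,
#'   `p_ij`, `p_cond`, `n_states`, `n_pairs`.
#' @examples
#' m <- transition_model(c(1, 1, 2, 2))
#' m$p_i    # 0.5 0.5
#' m$p_ij   # pairs (1,1), (1,2), (2,2): 1/3 each
#' @export
transition_model <- function(seq, include_self = TRUE, n_states = NULL) {
  K <- n_states %||% (if (inherits(seq, "label_sequence")) seq$K else NULL)
  lab <- as_labels(seq)
  if (!isTRUE(include_self)) {
    lab <- rle(lab)$values
  }
  if (length(lab) < 2L)
    stopf("need at least 2 symbols to form transitions")
  K <- as.integer(K %||% max(lab))
  from <- lab[-length(lab)]
  to <- lab[-1]
  counts <- matrix(tabulate((from - 1L) * K + to, K * K), K, K,
                   byrow = TRUE)
  p_ij <- counts / sum(counts)
  p_i <- tabulate(lab, K) / length(lab)
  p_cond <- matrix(0, K, K)
  rs <- rowSums(counts)
  p_cond[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(list(p_i = p_i, p_ij = p_ij, p_cond = p_cond,
                 n_states = K, n_pairs = length(from)),
            class = "transition_model")
}

#' Microstate Lempel-Ziv complexity of a label sequence
#'
#' LZ76 phrase-dictionary size of the sequence over its native K-letter
#' alphabet (no binarization), normalized by the mean dictionary size of
#' `n_shuffles` uniformly random reorderings of the same sequence. Values
#' below 1 indicate temporal structure that shuffling destroys.
#'
#' @param seq A [label_sequence()] or integer vector (length >= 2).
#' @param n_shuffles Number of random permutations (default 20).
#' @param seed Seed of the shuffle stream.
#' @return Scalar ratio; the shuffle-dictionary SD is attached as attribute
#'   `"shuffle_sd"`.
#' @export
ms_lzc <- function(seq, n_shuffles = 20, seed = 1) {
  lab <- as_labels(seq)
  if (length(lab) < 2L) stopf("sequence too short")
  if (n_shuffles < 1L) stopf("n_shuffles must be >= 1")
  c_obs <- lz76_phrase_count(lab)
  c_sh <- with_seed(stream_seed(seed, "ms-lzc-shuffles"),
                    vapply(seq_len(n_shuffles),
                           function(i) lz76_phrase_count(sample(lab)),
                           0L))
  structure(c_obs / mean(c_sh), shuffle_sd = sd(as.numeric(c_sh)))
}

# -sum p log2 p with the 0 log 0 := 0 convention; + 0 avoids IEEE -0
neg_sum_plog2 <- function(p, q = p) {
  nz <- p > 0
  -sum(p[nz] * log2(q[nz])) + 0
}

#' Microstate mean information gain
#'
#' Expected surprisal of the next microstate given the current one:
#' `MIG = -sum_ij p_ij log2 p_{i->j}` (0 log 0 := 0). Zero for
#' deterministic dynamics; approaches `log2 N` for i.i.d. uniform
#' sequences.
#'
#' @param model A [transition_model()] (or a sequence, converted with
#'   defaults).
#' @return Scalar in `[0, log2 N]`, bits.
#' @export
ms_mig <- function(model) {
  model <- as_transition_model(model)
  neg_sum_plog2(model$p_ij, model$p_cond)
}

#' Microstate fluctuation complexity
#'
#' Mean squared net information gain across transitions:
#' `FC = sum_ij p_ij (log2(p_i / p_j))^2`. Zero whenever the stationary
#' distribution is uniform; large when transitions keep moving probability
#' between rare and common states.
#'
#' @inheritParams ms_mig
#' @return Non-negative scalar, bits^2.
#' @export
ms_fc <- function(model) {
  model <- as_transition_model(model)
  p_i <- model$p_i
  K <- model$n_states
  out <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    pij <- model$p_ij[i, j]
    if (pij > 0 && p_i[i] > 0 && p_i[j] > 0)
      out <- out + pij * (log2(p_i[i] / p_i[j]))^2
  }
  out
}

as_transition_model <- function(x) {
  if (inherits(x, "transition_model")) x else transition_model(x)
}

#' Microstate Shannon entropy
#'
#' Entropy of the empirical state distribution:
#' `SE = -sum_i p_i log2 p_i`.
#'
#' @param seq A [label_sequence()] or integer vector.
#' @return Scalar in `[0, log2 K]`, bits.
#' @export
ms_se <- function(seq) {
  lab <- as_labels(seq)
  K <- if (inherits(seq, "label_sequence")) seq$K else max(lab)
  p <- tabulate(lab, K) / length(lab)
  neg_sum_plog2(p)
}

#' Microstate entropy rate and excess entropy
#'
#' Estimates the block-entropy curve `H_k` for `k = 1..k_max` by the
#' plug-in estimator on overlapping blocks and fits the asymptote
#' `H_k ~ h k + E` by ordinary least squares. The slope `h` is the entropy
#' rate (per-symbol unpredictability, bits/symbol) and the intercept `E`
#' the excess entropy (stored structure, bits). `k_max` is capped
#' adaptively so that the number of blocks stays at least 10 times the
#' number of distinct observed blocks; a cap triggers a warning.
#'
#' @param seq A [label_sequence()] or integer vector, length >= 10 * k_max.
#' @param k_max Largest block length for the fit (default 6).
#' @return Named numeric `c(entropy_rate, excess_entropy)` with the fitted
#'   curve in attribute `"H_k"`.
#' @export
ms_entropy_rate_excess <- function(seq, k_max = 6) {
  lab <- as_labels(seq)
  K <- if (inherits(seq, "label_sequence")) seq$K else max(lab)
  n <- length(lab)
  if (n < 10 * k_max)
    stopf("sequence length %d too short for k_max = %d (need >= %d)",
          n, k_max, 10 * k_max)
  H <- numeric(0)
  ks <- integer(0)
  for (k in seq_len(k_max)) {
    nb <- n - k + 1L
    code <- numeric(nb)
    for (j in seq_len(k)) code <- code * K + (lab[j:(j + nb - 1L)] - 1)
    distinct <- length(unique(code))
    if (k > 1L && nb < 10 * distinct) {
      warnf("block length capped at k = %d (support too thin beyond)", k - 1L)
      break
    }
    p <- tabulate(match(code, unique(code))) / nb
    H <- c(H, neg_sum_plog2(p))
    ks <- c(ks, k)
  }
  if (length(ks) < 2L) {
    # a single usable block length: slope falls back to H_1 per symbol
    h <- H[1]
    E <- 0
  } else {
    fit <- coef(lm(H ~ ks))
    h <- max(0, unname(fit[2]))
    E <- unname(fit[1])
  }
  structure(c(entropy_rate = h, excess_entropy = E), H_k = setNames(H, ks))
}

#' All six microstate-sequence complexity metrics
#'
#' @param seq A [label_sequence()] or integer vector.
#' @param metrics Subset of
#'   `c("ms_lzc", "ms_mig", "ms_fc", "ms_se", "ms_er", "ms_ee")`.
#' @param include_self Sample-level transition counting (default TRUE);
#'   see [transition_model()].
#' @param n_shuffles,seed Passed to [ms_lzc()].
#' @param k_max Passed to [ms_entropy_rate_excess()].
#' @return Named numeric vector over `metrics`.
#' @examples
#' cfg <- synth_config(duration = 3, seed = 2)
#' sequence_complexity(generate_label_sequence(cfg), seed = 7)
#' @export
sequence_complexity <- function(seq,
                                metrics = c("ms_lzc", "ms_mig", "ms_fc",
                                            "ms_se", "ms_er", "ms_ee"),
                                include_self = TRUE, n_shuffles = 20,
                                seed = 1, k_max = 6) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  need_model <- any(metrics %in% c("ms_mig", "ms_fc"))
  model <- if (need_model) transition_model(seq, include_self = include_self)
  need_er <- any(metrics %in% c("ms_er", "ms_ee"))
  er <- if (need_er)
    suppressWarnings(ms_entropy_rate_excess(seq, k_max = k_max))
  out <- vapply(metrics, function(m) {
    switch(m,
           ms_lzc = as.numeric(ms_lzc(seq, n_shuffles, seed)),
           ms_mig = ms_mig(model),
           ms_fc = ms_fc(model),
           ms_se = ms_se(seq),
           ms_er = unname(er["entropy_rate"]),
           ms_ee = unname(er["excess_entropy"]))
  }, 0)
  setNames(out, metrics)
}
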