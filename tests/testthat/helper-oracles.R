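# Independent direct-from-definition implementations used as oracles.
# Deliberately naive (loops, string tables); they share no code with the
# package internals they check.

# LZ76 exhaustive-history parsing: each phrase is the shortest prefix of
# the remainder that cannot be copied (overlap allowed) from everything
# before its end.
oracle_lz76 <- function(s) {
  n <- length(s)
  if (n == 0L) return(0L)
  count <- 0L
  h <- 0L
  while (h < n) {
    j <- h + 1L
    repeat {
      if (j > n) break
      pat <- s[(h + 1L):j]
      L <- j - h
      found <- FALSE
      if (j - 1L >= L) {
        for (st in 1:(j - L)) {
          if (all(s[st:(st + L - 1L)] == pat)) { found <- TRUE; break }
        }
      }
      if (!found) break
      j <- j + 1L
    }
    count <- count + 1L
    h <- min(j, n)
  }
  count
}

oracle_pair_table <- function(s, K) {
  tab <- table(factor(s[-length(s)], levels = 1:K),
               factor(s[-1], levels = 1:K))
  matrix(as.numeric(tab), K, K)
}

oracle_mig <- function(s, K = max(s)) {
  cnt <- oracle_pair_table(s, K)
  pij <- cnt / sum(cnt)
  out <- 0
  for (i in 1:K) for (j in 1:K) {
    if (pij[i, j] > 0) {
      pc <- cnt[i, j] / sum(cnt[i, ])
      out <- out - pij[i, j] * log2(pc)
    }
  }
  out
}

oracle_fc <- function(s, K = max(s)) {
  cnt <- oracle_pair_table(s, K)
  pij <- cnt / sum(cnt)
  p <- as.numeric(table(factor(s, levels = 1:K))) / length(s)
  out <- 0
  for (i in 1:K) for (j in 1:K)
    if (pij[i, j] > 0) out <- out + pij[i, j] * (log2(p[i] / p[j]))^2
  out
}

oracle_se <- function(s, K = max(s)) {
  p <- as.numeric(table(factor(s, levels = 1:K))) / length(s)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_block_H <- function(s, k) {
  n <- length(s) - k + 1
  blocks <- vapply(seq_len(n),
                   function(i) paste(s[i:(i + k - 1)], collapse = "-"), "")
  p <- as.numeric(table(blocks)) / n
  -sum(p * log2(p))
}

oracle_er_ee <- function(s, k_values) {
  H <- vapply(k_values, function(k) oracle_block_H(s, k), 0)
  if (length(k_values) == 1L)            # degenerate: slope convention
    return(c(h = max(0, H), E = 0))
  fit <- stats::lm(H ~ k_values)
  c(h = max(0, unname(coef(fit)[2])), E = unname(coef(fit)[1]))
}

oracle_lzc_signal <- function(x) {
  b <- as.integer(x > stats::median(x))
  oracle_lz76(b) * log2(length(x)) / length(x)
}

oracle_sampen <- function(x, m = 2, r = 0.15 * stats::sd(x)) {
  n <- length(x)
  B <- 0; A <- 0
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (j <= i) next
      db <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (db <= r) {
        B <- B + 1
        if (max(db, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_peen <- function(x, m = 5, tau = 1) {
  n_pat <- length(x) - (m - 1) * tau
  pats <- vapply(seq_len(n_pat), function(i) {
    idx <- i + seq(0, (m - 1) * tau, by = tau)
    paste(order(x[idx]), collapse = "-")
  }, "")
  p <- as.numeric(table(pats)) / n_pat
  -sum(p * log2(p)) / log2(factorial(m))
}

oracle_higuchi <- function(x, kmax = 10) {
  n <- length(x)
  L <- numeric(kmax)
  for (k in 1:kmax) {
    Lm <- numeric(k)
    for (m in 1:k) {
      idx <- seq(m, n, by = k)
      s <- 0
      for (q in 2:length(idx)) s <- s + abs(x[idx[q]] - x[idx[q - 1]])
      Lm[m] <- s * (n - 1) / (floor((n - m) / k) * k) / k
    }
    L[k] <- mean(Lm)
  }
  D <- unname(coef(stats::lm(log(L) ~ log(1 / (1:kmax))))[2])
  min(2, max(1, D))   # same admissible range as the estimator under test
}

oracle_we <- function(x, n_segments = 8) {
  n <- length(x)
  L <- max(1, min(n_segments, floor(n / 8)))
  seg_len <- floor(n / L)
  nf <- floor(seg_len / 2)
  Psum <- numeric(nf)
  for (s in 1:L) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    for (f in 1:nf) {
      # direct DFT ordinate at bin f
      w <- 2 * pi * f * (0:(seg_len - 1)) / seg_len
      re <- sum(seg * cos(w)); im <- sum(seg * sin(w))
      Psum[f] <- Psum[f] + (re^2 + im^2) / seg_len
    }
  }
  P <- pmax(Psum / L, 1e-300)
  exp(mean(log(P))) / mean(P)
}

oracle_ssv <- function(x, fs, subwindow_s = 0.5, overlap = 0.5) {
  wlen <- round(subwindow_s * fs)
  step <- max(1, round(wlen * (1 - overlap)))
  starts <- seq(1, length(x) - wlen + 1, by = step)
  v <- vapply(starts, function(s) oracle_we(x[s:(s + wlen - 1)]), 0)
  mean((v - mean(v))^2)
}

# Brute-force repeated-measures sums of squares (subjects x conditions).
oracle_rm_anova_F <- function(tab) {
  s <- nrow(tab); c <- ncol(tab)
  grand <- mean(tab)
  ss_cond <- s * sum((colMeans(tab) - grand)^2)
  ss_subj <- c * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  (ss_cond / (c - 1)) / (ss_err / ((c - 1) * (s - 1)))
}

random_label_seq <- function(n, K) sample.int(K, n, replace = TRUE)
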