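#' Lempel-Ziv complexity of a continuous signal
#'
#' Binarizes the signal at its median (`x > median(x)`), counts LZ76
#' phrases `C(N)` and returns the normalized value `C(N) log2(N) / N`,
#' which approaches 1 for i.i.d. random binary strings. A constant signal
#' degenerates to the all-zeros string (two phrases) and triggers a
#' warning.
#'
#' @param x Numeric vector, length >= 2.
#' @return Scalar normalized complexity.
#' @export
lzc <- function(x) {
  n <- length(x)
  if (n < 2L) stopf("signal too short for LZC")
  med <- median(x)
  b <- as.integer(x > med)
  if (all(b == b[1]) && any(x != x[1]))
    b <- as.integer(x >= med)   # discrete signals where > collapses a level
  if (all(b == b[1]))
    warnf("degenerate binarization (constant signal): LZC of a constant string")
  lz76_phrase_count(b) * log2(n) / n
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts template pairs matching
#' over `m` points and `A` those still matching over `m + 1` points, under
#' the Chebyshev distance with tolerance `r` (by default a fraction of the
#' signal SD). Self-matches are excluded. When no pair matches at either
#' length the statistic is undefined and `NA` is returned (never coerced
#' to a number), with attribute `"undefined" = TRUE`.
#'
#' @param x Numeric vector, length >= m + 2.
#' @param m Template length (default 2).
#' @param r Tolerance (default 0.15).
#' @param r_mode `"sd"` (tolerance = `r * sd(x)`, the field convention) or
#'   `"absolute"`.
#' @return Scalar in nats, or `NA` when undefined.
#' @export
sampen <- function(x, m = 2, r = 0.15, r_mode = c("sd", "absolute")) {
  r_mode <- match.arg(r_mode)
  n <- length(x)
  if (n < m + 2L) stopf("need at least m + 2 = %d samples", m + 2L)
  if (r <= 0) stopf("r must be positive")
  tol <- if (r_mode == "sd") r * sd(x) else r
  # constant signals have SD 0; the tolerance floor makes every pair match
  # so the entropy is 0 rather than an error
  tol <- max(tol, 1e-12)
  counts <- sampen_match_counts(as.numeric(x), as.integer(m), tol)
  B <- counts[["B"]]; A <- counts[["A"]]
  if (B == 0 || A == 0) {
    warnf("sample entropy undefined (no template matches at %s length)",
          if (B == 0) "m" else "m+1")
    return(structure(NA_real_, undefined = TRUE))
  }
  -log(A / B)
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal patterns of `m`
#' successive values (delay `tau`), normalized by `log2(m!)` so the result
#' lies in `[0, 1]`. Ties are broken by temporal order of occurrence.
#'
#' @param x Numeric vector, length >= m * tau + 1.
#' @param m Pattern dimension (default 5).
#' @param tau Time delay in samples (default 1).
#' @return Scalar in `[0, 1]`.
#' @export
peen <- function(x, m = 5, tau = 1) {
  n <- length(x)
  span <- (m - 1L) * tau
  if (n < m * tau + 1L) stopf("need at least m * tau + 1 = %d samples",
                              m * tau + 1L)
  n_pat <- n - span
  idx <- seq(0L, span, by = tau)
  # pattern code: factorial number system over the ranks
  codes <- vapply(seq_len(n_pat), function(i) {
    o <- order(x[i + idx])          # stable: ties broken by position
    sum(o * m^(seq_len(m) - 1))
  }, 0)
  p <- tabulate(match(codes, unique(codes))) / n_pat
  neg_sum_plog2(p) / log2(factorial(m))
}

#' Higuchi fractal dimension
#'
#' Builds Higuchi's normalized curve lengths `L(k)` for `k = 1..kmax`
#' (averaged over the k offsets) and returns the slope of
#' `ln L(k)` versus `ln(1/k)`. Near 1 for smooth curves, near 2 for
#' noise-like series; values are clipped to `[1, 2]` with a warning.
#'
#' @param x Numeric vector, length >= 2 * kmax.
#' @param kmax Largest scale (default 10).
#' @return Scalar dimension in `[1, 2]`.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  n <- length(x)
  if (kmax >= n / 2) stopf("kmax (%d) must be < length/2 (%g)", kmax, n / 2)
  Lk <- vapply(seq_len(kmax), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      norm <- (n - 1) / (floor((n - m) / k) * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, 0)
    mean(Lm, na.rm = TRUE)
  }, 0)
  D <- unname(coef(lm(log(Lk) ~ log(1 / seq_len(kmax))))[2])
  if (D < 1 || D > 2) {
    warnf("Higuchi dimension %.3f outside [1, 2]; clipped", D)
    D <- min(2, max(1, D))
  }
  D
}

#' Scale selection for the Higuchi dimension
#'
#' Computes the dimension at each candidate `kmax` and returns the first
#' `k` for which `|D(k+2) - D(k)| < tol`; when no candidate stabilizes,
#' 10 is returned with a warning.
#'
#' @param x Numeric vector.
#' @param candidates Ascending candidate scales (default
#'   `c(6, 8, 10, 12, 14, 16)`).
#' @param tol Stabilization tolerance on the dimension (default 0.02).
#' @return Selected `kmax`.
#' @export
select_kmax <- function(x, candidates = c(6, 8, 10, 12, 14, 16),
                        tol = 0.02) {
  D <- vapply(candidates, function(k) higuchi_fd(x, k), 0)
  for (i in seq_len(length(candidates) - 1L)) {
    if (candidates[i + 1L] - candidates[i] != 2)
      stopf("candidates must step by 2 for the |D(k+2) - D(k)| rule")
    if (abs(D[i + 1L] - D[i]) < tol) return(candidates[i])
  }
  warnf("Higuchi dimension never stabilized within %.3g; defaulting to kmax = 10",
        tol)
  10
}

#' Wiener entropy (spectral flatness measure)
#'
#' Ratio of the geometric to the arithmetic mean of the power spectral
#' density over positive frequencies (DC excluded):
#' `SFM = exp(mean(ln P_f)) / mean(P_f)`. The PSD is a Bartlett-averaged
#' periodogram (up to `n_segments` non-overlapping segments): a raw
#' single periodogram has exponentially distributed ordinates whose
#' flatness saturates at `exp(-gamma) ~ 0.56` even for white noise, while
#' segment averaging restores values near 1 for flat spectra. Near 0 for
#' line spectra. Zero-power bins are floored at 1e-300 before the
#' logarithm.
#'
#' @param x Numeric vector, length >= 8, not all zero.
#' @param n_segments Segments to average (default 8; reduced so that each
#'   segment keeps at least 8 samples).
#' @return Scalar in `[0, 1]`.
#' @export
wiener_entropy <- function(x, n_segments = 8) {
  n <- length(x)
  if (n < 8L) stopf("need at least 8 samples")
  if (all(x == 0)) stopf("all-zero signal: spectrum undefined")
  L <- max(1L, min(as.integer(n_segments), floor(n / 8)))
  seg_len <- floor(n / L)
  acc <- NULL
  for (s in seq_len(L)) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    P <- Mod(fft(seg))^2 / seg_len
    P <- P[2:(floor(seg_len / 2) + 1L)]  # positive frequencies, DC dropped
    acc <- if (is.null(acc)) P else acc + P
  }
  P <- pmax(acc / L, 1e-300)
  exp(mean(log(P))) / mean(P)
}

#' Spectral structure variability
#'
#' Population variance of the Wiener entropy across overlapping
#' subwindows: low when the spectral shape is stable over time, high when
#' the signal keeps switching spectral regimes.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param subwindow_s Subwindow length in seconds (default 0.5).
#' @param overlap Fractional overlap between consecutive subwindows
#'   (default 0.5).
#' @return Non-negative scalar.
#' @export
ssv <- function(x, fs, subwindow_s = 0.5, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  wlen <- round(subwindow_s * fs)
  if (wlen < 8L) stopf("subwindow too short (%d samples)", wlen)
  step <- max(1L, round(wlen * (1 - overlap)))
  if (length(x) < wlen + step)
    stopf("signal spans fewer than 2 subwindows")
  starts <- seq(1L, length(x) - wlen + 1L, by = step)
  sfm <- vapply(starts, function(s) wiener_entropy(x[s:(s + wlen - 1L)]), 0)
  mean((sfm - mean(sfm))^2)
}

# registry: minimal admissible length per metric (samples), and whether fs
# is needed
sig_metric_registry <- function() {
  list(
    lzc = list(fn = function(x, fs, ...) lzc(x), min_len = 2L),
    sampen = list(fn = function(x, fs, ...) sampen(x, ...), min_len = 100L),
    peen = list(fn = function(x, fs, ...) peen(x, ...), min_len = 6L),
    fd = list(fn = function(x, fs, ...) higuchi_fd(x, ...), min_len = 21L),
    we = list(fn = function(x, fs, ...) wiener_entropy(x), min_len = 8L),
    ssv = list(fn = function(x, fs, ...) ssv(x, fs, ...), min_len = 8L)
  )
}

#' Sliding-window complexity profile of a single signal
#'
#' Evaluates one complexity metric on every sliding window of a signal (or
#' of a symbolic label sequence for the sequence metrics), plus the
#' whole-series value.
#'
#' @param x Numeric vector, [eeg_epoch()] single channel (give `channel`),
#'   or [label_sequence()] for metrics `ms_*`.
#' @param metric One of `"lzc"`, `"sampen"`, `"peen"`, `"fd"`, `"we"`,
#'   `"ssv"` (continuous) or `"ms_lzc"`, `"ms_mig"`, `"ms_fc"`, `"ms_se"`
#'   (symbolic).
#' @param spec A [window_spec()] (default 1 s / 0.2 s).
#' @param fs Sampling rate; taken from `x` when it carries one.
#' @param channel Channel index when `x` is an epoch/recording
#'   (default 1).
#' @param ... Extra arguments for the metric (e.g. `m`, `r`, `kmax`,
#'   `seed`).
#' @return A list of class `complexity_result`: `metric`, `value`
#'   (whole-series), `windows` (data.frame `start_s`, `end_s`, `value`).
#' @export
windowed_complexity <- function(x, metric, spec = window_spec(), fs = NULL,
                                channel = 1L, ...) {
  stopifnot(inherits(spec, "window_spec"))
  symbolic <- grepl("^ms_", metric)
  if (inherits(x, c("eeg_epoch", "eeg_recording"))) {
    fs <- fs %||% x$fs
    x <- as_data_matrix(x)[channel, ]
  } else if (inherits(x, "label_sequence")) {
    fs <- fs %||% x$fs
  }
  if (is.null(fs)) stopf("`fs` required")
  if (symbolic) {
    fn <- switch(metric,
                 ms_lzc = function(s, ...) as.numeric(ms_lzc(s, ...)),
                 ms_mig = function(s, ...) ms_mig(transition_model(s)),
                 ms_fc = function(s, ...) ms_fc(transition_model(s)),
                 ms_se = function(s, ...) ms_se(s),
                 stopf("unknown symbolic metric '%s'", metric))
    series <- as_labels(x)
    min_len <- 2L
  } else {
    reg <- sig_metric_registry()
    if (!metric %in% names(reg)) stopf("unknown metric '%s'", metric)
    fn <- function(s, ...) reg[[metric]]$fn(s, fs, ...)
    series <- as.numeric(x)
    min_len <- reg[[metric]]$min_len
  }
  n <- length(series)
  dur <- n / fs
  wlen <- round(spec$length * fs)
  if (wlen < min_len)
    stopf("window of %d samples too short for metric '%s' (needs >= %d)",
          wlen, metric, min_len)
  n_win <- floor((dur - spec$length) / spec$step + 1e-9) + 1L
  win <- lapply(seq_len(n_win), function(i) {
    s0 <- round((i - 1L) * spec$step * fs)
    seg <- series[(s0 + 1):(s0 + wlen)]
    list(start_s = (i - 1L) * spec$step,
         end_s = (i - 1L) * spec$step + spec$length,
         value = as.numeric(fn(seg, ...)))
  })
  structure(list(metric = metric,
                 value = as.numeric(fn(series, ...)),
                 windows = data.frame(
                   start_s = vapply(win, `[[`, 0, "start_s"),
                   end_s = vapply(win, `[[`, 0, "end_s"),
                   value = vapply(win, `[[`, 0, "value"))),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("<complexity_result> %s = %.4f over %d windows\n",
              x$metric, x$value, nrow(x$windows)))
  invisible(x)
}

#' All six continuous-signal complexity metrics
#'
#' @param x Numeric vector (one channel or region time series).
#' @param fs Sampling rate (needed for `ssv`).
#' @param metrics Subset of `c("lzc", "sampen", "peen", "fd", "we",
#'   "ssv")`.
#' @param sampen_m,sampen_r Sample-entropy parameters (defaults 2, 0.15).
#' @param peen_m,peen_tau Permutation-entropy parameters (defaults 5, 1).
#' @param kmax Higuchi scale (default 10).
#' @return Named numeric vector (NA where a metric is undefined).
#' @export
signal_complexity <- function(x, fs,
                              metrics = c("lzc", "sampen", "peen", "fd",
                                          "we", "ssv"),
                              sampen_m = 2, sampen_r = 0.15,
                              peen_m = 5, peen_tau = 1, kmax = 10) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- vapply(metrics, function(m) {
    switch(m,
           lzc = lzc(x),
           sampen = as.numeric(sampen(x, sampen_m, sampen_r)),
           peen = peen(x, peen_m, peen_tau),
           fd = higuchi_fd(x, kmax),
           we = wiener_entropy(x),
           ssv = ssv(x, fs))
  }, 0)
  setNames(out, metrics)
}
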