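#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of every channel.
#' The response contract is stated in terms of gain, not realization: a
#' mid-band sinusoid passes with gain in `[0.95, 1.05]` and a tone at twice
#' the upper edge is attenuated by at least 20 dB.
#'
#' @param rec An [eeg_recording()] (or epoch/matrix; `fs` then required).
#' @param lo_hz Lower edge in Hz; `0` gives a pure low-pass.
#' @param hi_hz Upper edge in Hz; must be below Nyquist.
#' @param order Butterworth prototype order per edge (default 2, i.e. a
#'   4th-order band-pass before the forward-backward doubling).
#' @param fs Sampling rate when `rec` is a bare matrix.
#' @return Filtered object of the same class as `rec`.
#' @examples
#' cfg <- synth_config(duration = 2, seed = 1)
#' rec <- generate_eeg(generate_templates(30, 5, 1),
#'                     generate_label_sequence(cfg), cfg)
#' filt <- bandpass_filter(rec, 2, 20)
#' @export
bandpass_filter <- function(rec, lo_hz, hi_hz, order = 2, fs = NULL) {
  fs <- fs %||% get_fs(rec)
  if (is.null(fs)) stopf("`fs` required when filtering a bare matrix")
  if (lo_hz < 0 || hi_hz <= lo_hz) stopf("need 0 <= lo_hz < hi_hz")
  if (hi_hz >= fs / 2)
    stopf("hi_hz (%g) must be below the Nyquist frequency (%g)", hi_hz, fs / 2)
  bf <- if (lo_hz == 0)
    signal::butter(order, hi_hz / (fs / 2), type = "low")
  else
    signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  x <- as_data_matrix(rec)
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  replace_data(rec, out, fs)
}

#' Integer-factor downsampling with anti-aliasing
#'
#' Applies a zero-phase low-pass at 80% of the target Nyquist frequency,
#' then keeps every `factor`-th sample (phase 1), yielding
#' `floor(n / factor)` samples.
#'
#' @param rec An [eeg_recording()] or [eeg_epoch()].
#' @param factor Positive integer decimation factor; `1` is the identity.
#' @return Object of the same class with `fs / factor`.
#' @export
downsample <- function(rec, factor) {
  if (length(factor) != 1L || factor < 1 || factor != round(factor))
    stopf("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  fs <- rec$fs
  x <- as_data_matrix(rec)
  new_fs <- fs / factor
  bf <- signal::butter(4, 0.8 * (new_fs / 2) / (fs / 2), type = "low")
  lp <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  keep <- seq(1L, by = factor, length.out = floor(ncol(x) / factor))
  replace_data(rec, lp[, keep, drop = FALSE], new_fs)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every sample, so
#' that each column of the data matrix sums to zero.
#'
#' @param rec An [eeg_recording()] or [eeg_epoch()] with >= 2 channels.
#' @return Re-referenced object; for recordings, `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  x <- as_data_matrix(rec)
  if (nrow(x) < 2L) stopf("average reference needs >= 2 channels")
  out <- sweep(x, 2, colMeans(x))
  res <- replace_data(rec, out, get_fs(rec))
  if (inherits(res, "eeg_recording")) res$reference <- "average"
  res
}

get_fs <- function(rec) if (is.list(rec)) rec$fs else NULL

replace_data <- function(rec, newdata, fs) {
  if (inherits(rec, "eeg_recording")) {
    out <- eeg_recording(newdata, fs, rec$channel_labels, rec$reference)
  } else if (inherits(rec, "eeg_epoch")) {
    out <- eeg_epoch(newdata, fs, rec$t0_offset, rec$channel_labels)
  } else {
    out <- newdata
  }
  out
}

#' Apply the standard preprocessing chain
#'
#' Fixed order: band-pass filter, downsample, common average reference.
#' The applied steps are recorded in the `"preprocessing"` attribute of the
#' result.
#'
#' @param rec An [eeg_recording()].
#' @param band Length-2 numeric `c(lo, hi)` in Hz, or NULL to skip.
#' @param ds_factor Integer decimation factor, or 1/NULL to skip.
#' @param reref Apply the average reference (default TRUE).
#' @return Preprocessed [eeg_recording()].
#' @export
preprocess_chain <- function(rec, band = c(2, 20), ds_factor = 1,
                             reref = TRUE) {
  log <- character()
  if (!is.null(band)) {
    rec <- bandpass_filter(rec, band[1], band[2])
    log <- c(log, sprintf("bandpass %g-%g Hz", band[1], band[2]))
  }
  if (!is.null(ds_factor) && ds_factor > 1) {
    rec <- downsample(rec, ds_factor)
    log <- c(log, sprintf("downsample x%d -> %g Hz", ds_factor, rec$fs))
  }
  if (isTRUE(reref)) {
    rec <- rereference_average(rec)
    log <- c(log, "average reference")
  }
  attr(rec, "preprocessing") <- log
  rec
}

#' Extract fixed pre-trigger epochs
#'
#' Cuts one epoch per trigger over the half-open span
#' `[trigger + span[1], trigger + span[2])` seconds (default the 3 s
#' before the trigger). Triggers whose span does not fit inside the
#' recording are dropped with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param trigger_times Numeric vector of trigger times in seconds from
#'   recording start; an empty vector yields an empty list.
#' @param span Length-2 numeric, seconds relative to the trigger
#'   (default `c(-3, 0)`).
#' @return List of [eeg_epoch()] objects.
#' @export
epoch_prefire <- function(rec, trigger_times, span = c(-3, 0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (span[2] <= span[1]) stopf("`span` must have positive length")
  n <- ncol(rec$data)
  n_epoch <- round((span[2] - span[1]) * rec$fs)
  out <- list()
  for (t in trigger_times) {
    start0 <- round((t + span[1]) * rec$fs)       # 0-based first sample
    if (start0 < 0 || start0 + n_epoch > n) {
      warnf("trigger at %.3f s: span [%+g, %+g) s outside recording; dropped",
            t, span[1], span[2])
      next
    }
    idx <- (start0 + 1):(start0 + n_epoch)
    out[[length(out) + 1L]] <- eeg_epoch(rec$data[, idx, drop = FALSE],
                                         rec$fs, t0_offset = span[1],
                                         channel_labels = rec$channel_labels)
  }
  out
}

#' Sliding-window specification
#'
#' @param length Window length in seconds (default 1).
#' @param step Step between window starts in seconds (default 0.2).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length = 1, step = 0.2) {
  if (step <= 0 || length <= 0 || step > length + 1e-12)
    stopf("need 0 < step <= length")
  structure(list(length = length, step = step), class = "window_spec")
}

#' Cut an epoch into sliding windows
#'
#' Window `i` (1-based) spans `[(i-1)*step, (i-1)*step + length]` seconds
#' relative to the epoch start; only windows ending within the epoch are
#' returned. With the defaults (1 s window, 0.2 s step) a 3 s epoch yields
#' 11 windows; window 5 spans 0.8-1.8 s.
#'
#' @param epoch An [eeg_epoch()] (or [eeg_recording()]).
#' @param spec A [window_spec()].
#' @return List of elements `list(start_s, end_s, data)` where `data` is an
#'   [eeg_epoch()] restricted to the window.
#' @export
sliding_windows <- function(epoch, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  x <- as_data_matrix(epoch)
  fs <- epoch$fs
  dur <- ncol(x) / fs
  if (spec$length > dur + 1e-12)
    stopf("window length (%g s) exceeds epoch duration (%g s)",
          spec$length, dur)
  n_win <- floor((dur - spec$length) / spec$step + 1e-9) + 1L
  wlen <- round(spec$length * fs)
  t0 <- if (inherits(epoch, "eeg_epoch")) epoch$t0_offset else 0
  lapply(seq_len(n_win), function(i) {
    start_s <- (i - 1L) * spec$step
    s0 <- round(start_s * fs)                  # 0-based
    idx <- (s0 + 1):(s0 + wlen)
    list(start_s = start_s, end_s = start_s + spec$length,
         data = eeg_epoch(x[, idx, drop = FALSE], fs,
                          t0_offset = t0 + start_s,
                          channel_labels = epoch$channel_labels %||% NULL))
  })
}
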