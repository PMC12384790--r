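#' Multichannel EEG recording
#'
#' Container for a channels-by-samples potential matrix with its sampling
#' rate, channel labels and reference state. All user-facing functions in
#' the package accept and return this class for continuous data.
#'
#' @param data Numeric matrix, channels x samples (microvolts). Must be
#'   finite throughout.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector of unique labels, one per row of
#'   `data`. Defaults to `Ch01`, `Ch02`, ...
#' @param reference Reference state, `"raw"` or `"average"`.
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels`, `reference`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 4, 50), fs = 50)
#' rec
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          reference = c("raw", "average")) {
  reference <- match.arg(reference)
  if (!is.matrix(data) || !is.numeric(data))
    stopf("`data` must be a numeric channels x samples matrix")
  if (any(!is.finite(data)))
    stopf("`data` contains NaN/Inf or missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stopf("channel label count (%d) does not match channel count (%d)",
          length(channel_labels), nrow(data))
  if (anyDuplicated(channel_labels))
    stopf("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.3f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' Fixed-length epoch extracted around a trigger
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate (Hz).
#' @param t0_offset Start of the epoch in seconds relative to the trigger
#'   (negative = pre-trigger; default -3).
#' @param channel_labels Optional labels; defaults as in [eeg_recording()].
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, t0_offset = -3, channel_labels = NULL) {
  rec <- eeg_recording(data, fs, channel_labels)
  structure(list(data = rec$data, fs = fs, t0_offset = t0_offset,
                 channel_labels = rec$channel_labels),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz, span [%+.2f, %+.2f) s\n",
              nrow(x$data), ncol(x$data), x$fs, x$t0_offset,
              x$t0_offset + dur))
  invisible(x)
}

# Accept either container where a channels x samples matrix is expected.
as_data_matrix <- function(x) {
  if (inherits(x, c("eeg_recording", "eeg_epoch"))) return(x$data)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stopf("expected an eeg_recording, eeg_epoch or numeric matrix")
}

#' Per-sample microstate label sequence
#'
#' Symbolic representation of an EEG segment: one label per sample drawn
#' from the alphabet `1..K`.
#'
#' @param labels Integer vector of labels in `1..K`.
#' @param fs Sampling rate of the underlying signal (Hz).
#' @param K Alphabet size; defaults to `max(labels)`.
#' @return An object of class `label_sequence`.
#' @export
label_sequence <- function(labels, fs, K = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stopf("label sequence must be non-empty")
  if (anyNA(labels)) stopf("labels contain missing values")
  K <- as.integer(K %||% max(labels))
  if (any(labels < 1L | labels > K))
    stopf("labels outside alphabet 1..%d", K)
  if (!is.numeric(fs) || fs <= 0) stopf("`fs` must be positive (Hz)")
  structure(list(labels = labels, fs = fs, K = K),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, alphabet 1..%d\n",
              length(x$labels), x$fs, x$K))
  invisible(x)
}

as_labels <- function(x) {
  if (inherits(x, "label_sequence")) x$labels
  else if (is.numeric(x)) as.integer(x)
  else stopf("expected a label_sequence or integer vector")
}

#' Microstate template set
#'
#' A set of K topographic maps (each zero-mean across channels and unit
#' norm) together with the explained-variance and error summaries of the
#' clustering that produced them.
#'
#' @param maps Numeric matrix, K x channels; each row is normalized to zero
#'   mean and unit norm.
#' @param gev_total Total global explained variance in `[0, 1]` (NA when not
#'   yet evaluated).
#' @param gev_per_template Per-template GEV contributions.
#' @param sse Sum of squared errors of the fitted maps (NA when not yet
#'   evaluated).
#' @return An object of class `template_set`.
#' @export
template_set <- function(maps, gev_total = NA_real_,
                         gev_per_template = NULL, sse = NA_real_) {
  if (!is.matrix(maps) || !is.numeric(maps))
    stopf("`maps` must be a K x channels numeric matrix")
  maps <- normalize_maps(maps)
  K <- nrow(maps)
  if (!is.na(gev_total) && (gev_total < -1e-12 || gev_total > 1 + 1e-12))
    stopf("gev_total outside [0, 1]")
  if (!is.na(sse) && sse < 0) stopf("sse must be non-negative")
  structure(list(maps = maps, K = K, gev_total = gev_total,
                 gev_per_template = gev_per_template, sse = sse),
            class = "template_set")
}

# Zero-mean each row across channels and scale to unit norm.
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stopf("degenerate (constant) template map")
  maps / nrm
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> K = %d templates, %d channels", x$K,
              ncol(x$maps)))
  if (!is.na(x$gev_total)) cat(sprintf(", GEV = %.3f", x$gev_total))
  if (!is.na(x$sse)) cat(sprintf(", SSE = %.4g", x$sse))
  cat("\n")
  invisible(x)
}
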