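#' Read a recording from disk
#'
#' Supports two on-disk forms: a CSV channel matrix (one row per channel,
#' first column `channel`, a `# fs=<Hz>` comment line carrying the sampling
#' rate) and 16-bit EDF.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param fs Sampling rate override for CSV files lacking the `# fs=` line.
#' @return An [eeg_recording()] with `reference = "raw"`.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format,
         csv = read_csv_recording(path, fs),
         edf = read_edf_recording(path))
}

#' Write a recording to disk
#'
#' @param rec An [eeg_recording()].
#' @param path Destination path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(format,
         csv = write_csv_recording(rec, path),
         edf = write_edf_recording(rec, path))
  invisible(path)
}

read_csv_recording <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*fs\\s*=", first)) {
    fs_file <- suppressWarnings(as.numeric(sub("^#\\s*fs\\s*=\\s*", "", first)))
    if (is.na(fs_file)) stopf("malformed fs comment line in %s", path)
    fs <- fs %||% fs_file
  }
  if (is.null(fs))
    stopf("sampling rate unknown: no '# fs=' line in %s and no `fs` given", path)
  df <- read.csv(path, comment.char = "#", check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!"channel" %in% names(df))
    stopf("CSV recording must have a 'channel' column: %s", path)
  labels <- as.character(df$channel)
  num <- df[setdiff(names(df), "channel")]
  mat <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(df))))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(df))
  if (anyNA(mat))
    stopf("non-numeric or missing cell in data columns of %s", path)
  # vapply over columns yields channels x samples already
  rownames(mat) <- labels
  eeg_recording(mat, fs = fs, channel_labels = labels)
}

write_csv_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  df <- data.frame(channel = rec$channel_labels, rec$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("channel", sprintf("s%d", seq_len(ncol(rec$data))))
  write.csv(df, con, row.names = FALSE)
}

# --- Minimal EDF (16-bit European Data Format) support -----------------
# One data record spanning the whole signal; physical scaling per channel.
# No R package for EDF is assumed; the format's fixed-width ASCII header
# plus little-endian int16 samples is read and written directly.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf_recording <- function(rec, path) {
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  record_duration <- n / rec$fs
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                      eos = NULL)
  put("0", 8)
  put("X X X X", 80)
  put("Startdate X X X X", 80)
  put("01.01.00", 8)
  put("00.00.00", 8)
  put(256 * (ns + 1), 8)
  put("", 44)
  put(1, 8)                                 # number of data records
  put(format(record_duration, digits = 7), 8)
  put(ns, 4)
  for (lab in rec$channel_labels) put(lab, 16)
  for (i in seq_len(ns)) put("", 80)        # transducer
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(format(pmin_[i], digits = 7), 8)
  for (i in seq_len(ns)) put(format(pmax_[i], digits = 7), 8)
  for (i in seq_len(ns)) put(dmin, 8)
  for (i in seq_len(ns)) put(dmax, 8)
  for (i in seq_len(ns)) put("", 80)        # prefiltering
  for (i in seq_len(ns)) put(n, 8)          # samples per record
  for (i in seq_len(ns)) put("", 32)
  for (i in seq_len(ns)) {
    dig <- round((rec$data[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
}

read_edf_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  take <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  take(8)                                    # version
  take(80); take(80); take(8); take(8)
  header_bytes <- as.integer(take(8))
  take(44)
  n_records <- as.integer(take(8))
  record_duration <- as.numeric(take(8))
  ns <- as.integer(take(4))
  if (is.na(ns) || ns < 1) stopf("EDF header: bad signal count")
  if (is.na(header_bytes) || header_bytes != 256 * (ns + 1))
    stopf("EDF header: header-byte field (%s) inconsistent with %d signals",
          header_bytes, ns)
  labels <- vapply(seq_len(ns), function(i) take(16), "")
  for (i in seq_len(ns)) take(80)
  for (i in seq_len(ns)) take(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(take(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(take(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(take(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(take(8)), 0)
  for (i in seq_len(ns)) take(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(take(8)), 0L)
  for (i in seq_len(ns)) take(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr)))
    stopf("EDF header: unparseable signal fields")
  if (anyDuplicated(labels))
    stopf("EDF header: duplicated channel labels")
  expected <- 2 * sum(spr) * n_records
  actual <- file.size(path) - header_bytes
  if (actual != expected)
    stopf("EDF data size (%d bytes) does not match header (%d expected)",
          actual, expected)
  data <- matrix(NA_real_, ns, spr[1] * n_records)
  if (length(unique(spr)) != 1L)
    stopf("EDF: differing per-signal sampling rates are not supported")
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
        pmin_[i]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  fs <- spr[1] / record_duration
  eeg_recording(data, fs = fs, channel_labels = labels)
}

#' Write a template set to CSV with a JSON metadata sidecar
#'
#' @param templates A [template_set()].
#' @param path Path of the CSV (K x channels); metadata goes to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  stopifnot(inherits(templates, "template_set"))
  write.csv(as.data.frame(templates$maps), path, row.names = FALSE)
  meta <- list(K = templates$K, gev_total = templates$gev_total,
               gev_per_template = templates$gev_per_template,
               sse = templates$sse)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a template set written by [write_templates()]
#'
#' @param path CSV path.
#' @return A [template_set()].
#' @export
read_templates <- function(path) {
  maps <- as.matrix(read.csv(path, check.names = FALSE))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    template_set(maps, gev_total = meta$gev_total %||% NA_real_,
                 gev_per_template = meta$gev_per_template,
                 sse = meta$sse %||% NA_real_)
  } else template_set(maps)
}

#' Write / read a label sequence as single-column CSV
#'
#' The sampling rate travels in a `# fs=<Hz>` comment line.
#'
#' @param seq A [label_sequence()].
#' @param path File path.
#' @return `path` (write) or a [label_sequence()] (read).
#' @export
write_label_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "label_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", seq$fs), sprintf("# K=%d", seq$K),
               "label", as.character(seq$labels)), con)
  invisible(path)
}

#' @rdname write_label_sequence
#' @export
read_label_sequence <- function(path) {
  lines <- readLines(path)
  fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "",
                       grep("^#\\s*fs\\s*=", lines, value = TRUE)[1]))
  kline <- grep("^#\\s*K\\s*=", lines, value = TRUE)
  K <- if (length(kline)) as.integer(sub("^#\\s*K\\s*=\\s*", "", kline[1]))
       else NULL
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "label" & nzchar(body)]
  label_sequence(as.integer(body), fs = fs, K = K)
}
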