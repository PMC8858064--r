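# Multichannel EEG carrier.  Samples are stored channels x time in microvolts;
# sample timestamps share the clock of the landmark stream (start_time +
# k / sample_rate).

#' Construct an EEG recording
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param sample_rate sampling rate in Hz.
#' @param channel_names character vector, one name per channel.
#' @param start_time recording onset in seconds, on the same clock as the
#'   landmark timestamps.
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(samples, sample_rate,
                          channel_names = rownames(samples),
                          start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar (Hz)", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples)) {
    stop("one channel name per row of `samples` required", call. = FALSE)
  }
  rownames(samples) <- channel_names
  structure(list(samples = samples,
                 sample_rate = as.numeric(sample_rate),
                 channel_names = as.character(channel_names),
                 start_time = as.numeric(start_time)),
            class = "eeg_recording")
}

#' Sample timestamps of an EEG recording
#' @param eeg an `eeg_recording`.
#' @return numeric vector of per-sample times in seconds.
#' @export
eeg_times <- function(eeg) {
  eeg$start_time + (seq_len(ncol(eeg$samples)) - 1L) / eeg$sample_rate
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$samples), " channel(s) x ", ncol(x$samples),
      " samples @ ", x$sample_rate, " Hz\n", sep = "")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read an EEG recording from CSV
#'
#' Layout: first column `t` (seconds), remaining columns one per channel with
#' channel names in the header.  The sample rate is not stored in the file and
#' must be supplied.
#'
#' @param path CSV file.
#' @param sample_rate sampling rate in Hz.
#' @return an `eeg_recording`.
#' @export
read_eeg_csv <- function(path, sample_rate) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "t") stop("EEG CSV must start with a `t` column",
                                 call. = FALSE)
  chans <- names(df)[-1L]
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  start <- if (nrow(df)) df$t[1L] else 0
  eeg_recording(m, sample_rate, channel_names = chans, start_time = start)
}

#' Write an EEG recording to CSV
#' @param eeg an `eeg_recording`.
#' @param path output file.
#' @export
write_eeg_csv <- function(eeg, path) {
  df <- data.frame(t = eeg_times(eeg))
  df <- cbind(df, as.data.frame(t(eeg$samples)))
  names(df) <- c("t", eeg$channel_names)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Downsample an EEG recording to a target analysis rate by block means
#'
#' Brings the EEG to the same analysis frequency as the facial stream: samples
#' are grouped into consecutive 1/`fps_target`-second blocks by timestamp and
#' averaged per channel.  Non-integer rate ratios are handled by the timestamp
#' block boundaries; blocks are half-open on the right.
#'
#' @param eeg an `eeg_recording`.
#' @param fps_target target rate in Hz (e.g. 25 to match a 25 fps camera).
#' @return an `eeg_recording` at `fps_target` Hz.
#' @export
downsample_to_windows <- function(eeg, fps_target) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (!is.numeric(fps_target) || length(fps_target) != 1L || fps_target <= 0) {
    stop("fps_target must be a positive scalar", call. = FALSE)
  }
  t <- eeg_times(eeg)
  if (length(t) == 0L) return(eeg_recording(eeg$samples, fps_target,
                                            eeg$channel_names, eeg$start_time))
  block <- floor((t - eeg$start_time) * fps_target + 1e-9)
  blocks <- sort(unique(block))
  out <- vapply(blocks, function(b) {
    rowMeans(eeg$samples[, block == b, drop = FALSE])
  }, numeric(nrow(eeg$samples)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(eeg$samples))
  eeg_recording(out, fps_target, eeg$channel_names,
                start_time = eeg$start_time + blocks[1L] / fps_target)
}

## ---- 1-second analysis windows -------------------------------------------

# Window assignment is timestamp-driven and aligned to the stream start:
# window w covers [t0 + w, t0 + w + 1) seconds, half-open.  A sample or frame
# belongs to exactly one window; dropped frames leave their window short (or
# empty) instead of shifting later windows.

window_index_of <- function(t, t0, window_s = 1) {
  as.integer(floor((t - t0) / window_s + 1e-9))
}

n_windows_of <- function(t, t0, window_s = 1) {
  if (length(t) == 0L) return(0L)
  max(window_index_of(t, t0, window_s)) + 1L
}
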