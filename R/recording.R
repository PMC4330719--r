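#' Multichannel EEG recording container
#'
#' Thin S3 wrapper around a channels x samples numeric matrix in microvolts,
#' with unique channel labels, a sampling rate, and an attached
#' [event_list()].
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate (Hz).
#' @param channel_labels character vector of unique labels; defaults to
#'   existing rownames or `ch01, ch02, ...`.
#' @param events an [event_list()] (may be `NULL` for raw segments).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, events = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (is.null(channel_labels))
    channel_labels <- rownames(data) %||% sprintf("ch%02d", seq_len(nrow(data)))
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (length(channel_labels) != nrow(data))
    stop("one label per channel required")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$events)) {
    n <- table(x$events$label)
    cat(sprintf("  events: %d chirp, %d silent\n", n[["chirp"]], n[["silent"]]))
  }
  invisible(x)
}

#' @export
plot.eeg_recording <- function(x, channels = seq_len(min(8, nrow(x$data))),
                               t_lim = c(0, min(10, ncol(x$data) / x$fs)),
                               spacing = NULL, ...) {
  idx <- round(t_lim[1] * x$fs + 1):round(t_lim[2] * x$fs)
  d <- x$data[channels, idx, drop = FALSE]
  spacing <- spacing %||% (4 * stats::median(apply(d, 1, stats::sd)))
  t <- (idx - 1) / x$fs
  graphics::plot(range(t), c(0, (length(channels) + 1) * spacing), type = "n",
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  for (i in seq_along(channels))
    graphics::lines(t, d[i, ] + i * spacing, col = i)
  graphics::axis(2, at = seq_along(channels) * spacing,
                 labels = x$channel_labels[channels], las = 1, cex.axis = 0.7)
  invisible(x)
}

# Extract a span of samples (keeping events that fall wholly inside it).
crop_recording <- function(rec, from = 1L, to = ncol(rec$data)) {
  ev <- rec$events
  if (!is.null(ev)) {
    keep <- ev$onset_sample + 1L >= from & ev$onset_sample + 1L <= to
    ev <- event_list(ev$onset_sample[keep] - (from - 1L), ev$label[keep], rec$fs)
  }
  eeg_recording(rec$data[, from:to, drop = FALSE], rec$fs,
                rec$channel_labels, ev)
}
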