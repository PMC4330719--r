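#' Event lists: labelled trial onsets
#'
#' An `event_list` is a data frame with integer column `onset_sample`
#' (0-based sample index of trial onset) and factor column `label`
#' (`"chirp"` or `"silent"`), carrying the sampling rate as attribute `fs`.
#' Chirp onsets mark presentations of the 0.1 s auditory probe; silent
#' onsets mark 0.5 s segments extracted from the inter-stimulus silences.
#'
#' @param onset_sample integer vector of 0-based onset samples.
#' @param label character or factor vector, one of `"chirp"`, `"silent"`.
#' @param fs sampling rate in Hz.
#' @return An `event_list` data frame sorted by onset.
#' @export
event_list <- function(onset_sample, label, fs) {
  stopifnot(length(onset_sample) == length(label), fs > 0)
  onset_sample <- as.integer(onset_sample)
  if (any(onset_sample < 0)) stop("onset_sample must be >= 0")
  label <- factor(as.character(label), levels = c("chirp", "silent"))
  if (anyNA(label)) stop("labels must be 'chirp' or 'silent'")
  ord <- order(onset_sample)
  ev <- data.frame(onset_sample = onset_sample[ord], label = label[ord])
  for (lb in levels(ev$label)) {
    o <- ev$onset_sample[ev$label == lb]
    if (anyDuplicated(o)) stop("onsets must be strictly increasing within label ", lb)
  }
  structure(ev, fs = fs, class = c("event_list", "data.frame"))
}

#' @export
print.event_list <- function(x, ...) {
  fs <- attr(x, "fs")
  n <- table(x$label)
  cat(sprintf("<event_list> %d chirp + %d silent events @ %g Hz\n",
              n[["chirp"]], n[["silent"]], fs))
  if (nrow(x) > 0)
    cat(sprintf("  span: %.2f .. %.2f s\n",
                min(x$onset_sample) / fs, max(x$onset_sample) / fs))
  invisible(x)
}

events_of <- function(events, lab) {
  events$onset_sample[events$label == lab]
}

#' Generate a chirp/silent stimulus schedule
#'
#' Draws `n_chirp` chirp presentations separated by silences of duration
#' Uniform(`isi_min_s`, `isi_max_s`), then extracts `n_chirp` silent trial
#' onsets wholly inside those silences such that silent epochs (of length
#' `epoch_s`) overlap neither the chirp epochs nor each other. All timing is
#' resolved on the sample grid, so the inter-chirp silences are exact in
#' sample units.
#'
#' @param n_chirp number of chirp presentations (and of silent segments).
#' @param isi_min_s,isi_max_s bounds of the uniform inter-stimulus silence (s).
#' @param chirp_dur_s chirp sound duration (s).
#' @param epoch_s trial epoch length (s); silent epochs have this length and
#'   chirp epochs span `[onset, onset + epoch_s)`.
#' @param fs sampling rate (Hz).
#' @param seed optional integer seed; identical seeds give identical schedules.
#' @param lead_in_s quiet time before the first chirp (s).
#' @return An [event_list()] with `n_chirp` chirp and `n_chirp` silent events.
#' @export
generate_events <- function(n_chirp = 200, isi_min_s = 0.6, isi_max_s = 2.5,
                            chirp_dur_s = 0.1, epoch_s = 0.5, fs = 300,
                            seed = NULL, lead_in_s = 1) {
  stopifnot(n_chirp >= 1, fs > 0, chirp_dur_s > 0, epoch_s > 0)
  if (!(0 < isi_min_s && isi_min_s <= isi_max_s))
    stop("need 0 < isi_min_s <= isi_max_s")
  with_seed(seed, {
    chirp_smp <- round(chirp_dur_s * fs)
    epoch_smp <- round(epoch_s * fs)
    gaps <- round(stats::runif(n_chirp - 1, isi_min_s, isi_max_s) * fs)
    onsets <- round(lead_in_s * fs) + c(0, cumsum(gaps + chirp_smp))

    # intervals able to host silent epochs: the lead-in and each inter-chirp
    # region after the preceding chirp epoch has ended; a silent epoch may
    # end exactly where the next chirp epoch begins
    int_start <- c(0L, utils::head(onsets, -1L) + epoch_smp)
    int_end <- onsets
    cap <- pmax(0L, int_end - int_start) %/% epoch_smp
    total <- sum(cap)
    if (total < n_chirp)
      stop(sprintf(paste0("cannot place %d silent epochs: silence budget hosts ",
                          "only %d non-overlapping %g s epochs (deficit %d)"),
                   n_chirp, total, epoch_s, n_chirp - total))
    # sample capacity slots uniformly without replacement
    slots <- rep.int(seq_along(cap), cap)
    take <- slots[sample.int(length(slots), n_chirp)]
    k_per <- tabulate(take, nbins = length(cap))
    silent <- integer(0)
    for (i in which(k_per > 0)) {
      k <- k_per[i]
      len <- int_end[i] - int_start[i]
      slack <- len - k * epoch_smp
      u <- sort(stats::runif(k, 0, slack))
      silent <- c(silent, int_start[i] + (seq_len(k) - 1L) * epoch_smp + floor(u))
    }
    event_list(c(onsets, silent),
               rep(c("chirp", "silent"), c(n_chirp, length(silent))), fs)
  })
}

#' Inter-chirp silence durations of a schedule (seconds)
#'
#' Onset-to-onset spacing minus the chirp duration; by construction uniform
#' on the configured silence range.
#' @param events an [event_list()].
#' @param chirp_dur_s chirp duration used when the schedule was generated.
#' @return numeric vector of silence durations in seconds.
#' @export
inter_chirp_silences <- function(events, chirp_dur_s = 0.1) {
  fs <- attr(events, "fs")
  o <- events_of(events, "chirp")
  diff(o) / fs - chirp_dur_s
}

#' Read / write event tables as TSV
#'
#' The on-disk format is a two-column tab-separated table with header
#' `onset_s<TAB>label`; onsets in seconds are converted to the sample grid.
#'
#' @param events an [event_list()].
#' @param path file path.
#' @param fs sampling rate used to convert onsets to samples when reading.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns an [event_list()].
#' @export
write_events_tsv <- function(events, path) {
  fs <- attr(events, "fs")
  df <- data.frame(onset_s = events$onset_sample / fs,
                   label = as.character(events$label))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path, fs) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(df)))
    stop("events TSV must have columns onset_s and label")
  event_list(round(df$onset_s * fs), df$label, fs)
}
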