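#' Bad-channel rejection criteria
#'
#' The four rules used to drop unusable dry electrodes, fitted on the
#' training span only: (1) maximum absolute amplitude above `max_amp_uv`;
#' (2) a flatline (sample-to-sample change below `flat_eps_uv`) lasting
#' longer than `flatline_s`; (3) median windowed correlation between the
#' channel and its ridge-regression prediction from all other channels
#' below `min_robust_corr`; (4) line-noise score more than `line_noise_sd`
#' standard deviations above the channel-population mean, where the score is
#' the RMS ratio of the above-45 Hz residual to the below-45 Hz signal.
#'
#' @param max_amp_uv amplitude ceiling (microvolts).
#' @param flatline_s maximal tolerated flat run (seconds).
#' @param min_robust_corr minimal median correlation to the prediction from
#'   the other channels, in `(0, 1]`.
#' @param line_noise_sd z-score threshold for the line-noise rule.
#' @param window_s window length for the correlation rule (seconds).
#' @param flat_eps_uv amplitude change below which a sample counts as flat.
#' @return A `bad_channel_criteria` list.
#' @export
bad_channel_criteria <- function(max_amp_uv = 100, flatline_s = 5,
                                 min_robust_corr = 0.8, line_noise_sd = 4,
                                 window_s = 1, flat_eps_uv = 1e-6) {
  stopifnot(max_amp_uv > 0, flatline_s > 0, line_noise_sd > 0, window_s > 0,
            flat_eps_uv > 0, min_robust_corr > 0, min_robust_corr <= 1)
  structure(list(max_amp_uv = max_amp_uv, flatline_s = flatline_s,
                 min_robust_corr = min_robust_corr,
                 line_noise_sd = line_noise_sd, window_s = window_s,
                 flat_eps_uv = flat_eps_uv),
            class = "bad_channel_criteria")
}

#' Detect bad channels
#'
#' Applies the four criteria of [bad_channel_criteria()] and returns the
#' union of flagged channels. The robust per-channel estimate of rule 3 is a
#' ridge regression from all other channels fitted independently in each
#' window (regularisation `1e-3` times the mean channel variance), with the
#' median correlation over windows providing robustness to transient
#' artifacts. Channels with zero variance correlate 0 with their prediction.
#'
#' @param recording an [eeg_recording()].
#' @param criteria a [bad_channel_criteria()].
#' @return Character vector of flagged channel labels, with attribute
#'   `reasons`: a named list giving the labels flagged by each rule.
#' @export
detect_bad_channels <- function(recording, criteria = bad_channel_criteria()) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(criteria, "bad_channel_criteria"))
  X <- recording$data
  fs <- recording$fs
  nch <- nrow(X)
  n <- ncol(X)
  if (nch < 8) stop("bad-channel detection needs at least 8 channels")
  wlen <- round(criteria$window_s * fs)
  if (n < wlen) stop("recording shorter than one correlation window")
  labs <- recording$channel_labels

  ## rule 1: amplitude
  amp_flag <- apply(abs(X), 1, max) > criteria$max_amp_uv

  ## rule 2: flatline
  flat_max <- round(criteria$flatline_s * fs)
  flat_flag <- vapply(seq_len(nch), function(i) {
    runs <- abs(diff(X[i, ])) < criteria$flat_eps_uv
    longest_true_run(runs) + 1L > flat_max
  }, TRUE)

  ## rule 3: windowed ridge prediction from the other channels.
  ## With M = S + lambda*I and T = M^-1, the ridge prediction of channel i
  ## from the rest is x_i - (T x)_i / T_ii, for all i at the cost of one
  ## matrix inverse per window.
  nw <- n %/% wlen
  cors <- matrix(NA_real_, nch, nw)
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    Xw <- X[, idx, drop = FALSE]
    Xw <- Xw - rowMeans(Xw)
    S <- tcrossprod(Xw) / wlen
    lam <- 1e-3 * mean(diag(S))
    if (lam <= 0) lam <- 1e-12
    Tm <- solve(S + diag(lam, nch))
    pred <- Xw - (Tm %*% Xw) / diag(Tm)
    sx <- sqrt(rowSums(Xw^2))
    sp <- sqrt(rowSums(pred^2))
    cc <- rowSums(Xw * pred) / (sx * sp)
    cc[!is.finite(cc)] <- 0
    cors[, w] <- cc
  }
  corr_flag <- apply(cors, 1, stats::median) < criteria$min_robust_corr

  ## rule 4: line-noise score z across the channel population
  lp <- design_fir_bandpass_low45(fs)
  low <- t(vapply(seq_len(nch),
                  function(i) fft_conv_same(X[i, ], lp, (length(lp) - 1) %/% 2),
                  numeric(n)))
  hi_rms <- sqrt(rowMeans((X - low)^2))
  lo_rms <- sqrt(rowMeans(low^2))
  score <- hi_rms / pmax(lo_rms, 1e-12)
  z <- (score - mean(score)) / stats::sd(score)
  line_flag <- is.finite(z) & z > criteria$line_noise_sd

  reasons <- list(amplitude = labs[amp_flag], flatline = labs[flat_flag],
                  correlation = labs[corr_flag], line_noise = labs[line_flag])
  flagged <- labs[amp_flag | flat_flag | corr_flag | line_flag]
  structure(flagged, reasons = reasons)
}

# 45 Hz low-pass used by the line-noise rule (order-100 windowed sinc).
design_fir_bandpass_low45 <- function(fs) {
  as.numeric(signal::fir1(100, 45 / (fs / 2), type = "low"))
}

#' Write a bad-channel report as JSON
#'
#' @param flagged return value of [detect_bad_channels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bad_channel_report <- function(flagged, path) {
  jsonlite::write_json(list(removed = as.character(flagged),
                            reasons = attr(flagged, "reasons")),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
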