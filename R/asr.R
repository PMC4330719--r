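#' Select clean calibration samples
#'
#' Marks windows whose channel-wise RMS is typical of the recording, for use
#' as artifact subspace reconstruction calibration data. A window is kept
#' when, for at least 93.75% of channels, the robust z-score of its RMS
#' (median/MAD across windows, per channel) lies inside `z_bounds`.
#'
#' @param recording an [eeg_recording()] (training span).
#' @param z_bounds lower/upper robust-z bounds for windowed RMS.
#' @param window_s window length (s).
#' @param min_clean_s minimal clean duration required (s).
#' @param min_channel_frac fraction of channels that must be within bounds.
#' @return Logical vector, one entry per sample, `TRUE` on clean samples.
#' @export
select_calibration_mask <- function(recording, z_bounds = c(-3.5, 5.5),
                                    window_s = 1, min_clean_s = 30,
                                    min_channel_frac = 0.9375) {
  stopifnot(inherits(recording, "eeg_recording"))
  X <- recording$data
  fs <- recording$fs
  n <- ncol(X)
  wlen <- round(window_s * fs)
  nw <- n %/% wlen
  if (nw < 1) stop("recording shorter than one calibration window")
  wrms <- vapply(seq_len(nw), function(w) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    sqrt(rowMeans(X[, idx, drop = FALSE]^2))
  }, numeric(nrow(X)))                       # channels x windows
  med <- apply(wrms, 1, stats::median)
  madv <- apply(wrms, 1, stats::mad)
  madv[madv <= 0] <- 1e-12
  z <- (wrms - med) / madv
  ok_frac <- colMeans(z >= z_bounds[1] & z <= z_bounds[2])
  keep_w <- ok_frac >= min_channel_frac
  mask <- rep(rep(keep_w, each = wlen), length.out = nw * wlen)
  # trailing partial window inherits the last full window's decision
  if (n > nw * wlen) mask <- c(mask, rep(keep_w[nw], n - nw * wlen))
  clean_s <- sum(mask) / fs
  if (clean_s < min_clean_s)
    stop(sprintf("only %.1f s of clean calibration data (%.0f%% of the span); %g s required",
                 clean_s, 100 * mean(mask), min_clean_s))
  mask
}

#' Fit an artifact subspace reconstruction model
#'
#' Computes robust calibration statistics from clean data: the element-wise
#' median of per-window covariance matrices, its principal square root
#' (the spatial "mixing" used for reconstruction), the calibration
#' eigendirections, and per-direction rejection thresholds `mean +
#' cutoff * SD` of the calibration RMS projected on each eigendirection.
#'
#' @param calibration an [eeg_recording()] or channels x samples matrix of
#'   clean calibration data (at least 30 s).
#' @param fs sampling rate, required when `calibration` is a bare matrix.
#' @param cutoff rejection threshold in calibration standard deviations.
#' @param window_s,window_step_s analysis window length and hop (s).
#' @return An `asr_model` list: `mixing_sqrt`, `eigvecs`, `thresholds`,
#'   `cutoff`, `window_s`, `window_step_s`, `fs`, `channel_labels`.
#' @export
asr_fit <- function(calibration, fs = NULL, cutoff = 5, window_s = 0.5,
                    window_step_s = 0.25) {
  if (inherits(calibration, "eeg_recording")) {
    fs <- calibration$fs
    labs <- calibration$channel_labels
    X <- calibration$data
  } else {
    if (is.null(fs)) stop("fs required for matrix calibration data")
    X <- calibration
    labs <- rownames(X) %||% sprintf("ch%02d", seq_len(nrow(X)))
  }
  stopifnot(cutoff > 0, window_s > 0)
  nch <- nrow(X)
  n <- ncol(X)
  if (n / fs < 30)
    stop(sprintf("calibration needs >= 30 s, got %.1f s", n / fs))
  wlen <- round(window_s * fs)
  nw <- n %/% wlen
  covs <- array(0, c(nch, nch, nw))
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    covs[, , w] <- tcrossprod(X[, idx, drop = FALSE]) / wlen
  }
  C <- apply(covs, c(1, 2), stats::median)
  dg <- diag(C)
  if (any(dg < 1e-12 * max(dg)))
    stop("rank-deficient calibration covariance; degenerate channels: ",
         paste(labs[dg < 1e-12 * max(dg)], collapse = ", "))
  # the element-wise median of PSD matrices need not be PSD: project onto
  # the PSD cone with an eigenvalue floor so the spatial square root stays
  # well conditioned
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-4 * max(e$values))
  M <- e$vectors %*% (sqrt(vals) * t(e$vectors))
  V <- e$vectors
  # projected per-window RMS in each calibration eigendirection
  proj_rms <- matrix(0, nch, nw)
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    proj_rms[, w] <- sqrt(rowMeans((t(V) %*% X[, idx, drop = FALSE])^2))
  }
  thr <- rowMeans(proj_rms) + cutoff * apply(proj_rms, 1, stats::sd)
  structure(list(mixing_sqrt = M, eigvecs = V, thresholds = thr,
                 cutoff = cutoff, window_s = window_s,
                 window_step_s = window_step_s, fs = fs,
                 channel_labels = labs),
            class = "asr_model")
}

#' @export
print.asr_model <- function(x, ...) {
  cat(sprintf("<asr_model> %d channels, cutoff %g SD, window %g s (step %g s)\n",
              nrow(x$mixing_sqrt), x$cutoff, x$window_s, x$window_step_s))
  invisible(x)
}

#' Apply artifact subspace reconstruction
#'
#' Slides windows across the recording; in each, eigendirections of the
#' window covariance whose RMS exceeds the calibration threshold (mapped
#' into the window basis) are zeroed and the data reconstructed through the
#' calibration spatial square root: `R = M %*% pinv(keep * (V' M)) %*% V'`,
#' which is the identity when no direction is flagged. Overlapping windows
#' are blended with a raised-cosine ramp.
#'
#' @param model an [asr_fit()] model.
#' @param recording an [eeg_recording()] or channels x samples matrix with
#'   the same channel set the model was fitted on.
#' @return Cleaned object of the same type as the input.
#' @export
asr_process <- function(model, recording) {
  stopifnot(inherits(model, "asr_model"))
  if (inherits(recording, "eeg_recording")) {
    if (nrow(recording$data) != nrow(model$mixing_sqrt))
      stop("channel count does not match the ASR model")
    out <- recording
    out$data <- asr_process(model, recording$data)
    return(out)
  }
  X <- recording
  if (nrow(X) != nrow(model$mixing_sqrt))
    stop("channel count does not match the ASR model")
  fs <- model$fs
  nch <- nrow(X)
  n <- ncol(X)
  wlen <- round(model$window_s * fs)
  step <- max(1L, round(model$window_step_s * fs))
  if (n <= wlen) {
    starts <- 1L
    wlen <- n
  } else {
    starts <- seq(1L, n - wlen + 1L, by = step)
    if (utils::tail(starts, 1) + wlen - 1L < n)
      starts <- c(starts, n - wlen + 1L)
  }
  M <- model$mixing_sqrt
  Vc <- model$eigvecs
  thr <- model$thresholds
  edge_factor <- 1 + sqrt(nch / wlen)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
  num <- matrix(0, nch, n)
  den <- numeric(n)
  for (s in starts) {
    idx <- s:(s + wlen - 1L)
    Xw <- X[, idx, drop = FALSE]
    ew <- eigen(tcrossprod(Xw) / length(idx), symmetric = TRUE)
    V <- ew$vectors
    drms <- sqrt(pmax(ew$values, 0))
    # calibration threshold mapped into the window basis; edge_factor
    # compensates the finite-sample inflation of leading sample
    # eigenvalues (Marchenko-Pastur edge) relative to the fixed-direction
    # calibration RMS, so data statistically identical to the calibration
    # pass through untouched
    map <- edge_factor * sqrt(colSums((thr * crossprod(Vc, V))^2))
    keep <- drms <= map
    if (all(keep)) {
      Yw <- Xw
    } else {
      Tm <- crossprod(V, M)        # V' M
      Tm[!keep, ] <- 0
      R <- M %*% MASS::ginv(Tm) %*% t(V)
      Yw <- R %*% Xw
    }
    num[, idx] <- num[, idx] + Yw * rep(taper, each = nch)
    den[idx] <- den[idx] + taper
  }
  num / rep(pmax(den, 1e-12), each = nch)
}
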