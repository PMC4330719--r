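#' Build the N100/P300 ERP state-space model
#'
#' Each evoked wave is a third-order impulse response `t^2 exp(-t/tau)`
#' realised as a three-stage first-order cascade with discrete pole
#' `a = exp(-1/(fs*tau))` and `tau = peak/2` (the continuous-time argmax of
#' `t^2 exp(-t/tau)` is `2*tau`). The readout weights the cascade states as
#' `(0, a, 2a^2)`, which reproduces the exactly sampled `n^2 a^n` response;
#' at 300 Hz its discrete extremum falls exactly at sample 30 (100 ms) for
#' the early wave and sample 90 (300 ms) for the late wave. The onset input
#' drives the first state of each cascade with signed gains (negative early
#' wave - the N100 negativity - and positive late wave), and each wave's
#' readout is scaled so the noiseless unit-impulse response has unit peak
#' magnitude. State noise is white (`Q = q I`); the measurement-to-state
#' noise covariance ratio `R/q` is fixed at 0.001 so the filter trusts the
#' measurements.
#'
#' @param fs sampling rate (Hz).
#' @param peak_early_s,peak_late_s impulse-response peak latencies (s).
#' @param ratio measurement-to-state noise covariance ratio `R/q`.
#' @param q state noise variance (scale-free: only `ratio` affects the
#'   gain sequence).
#' @return An `erp_state_space` with matrices `A` (6x6), `B` (6x1),
#'   `C` (1x6), `Q`, scalar `R`, initial covariance `P0`, and the
#'   configuration.
#' @export
build_erp_model <- function(fs, peak_early_s = 0.100, peak_late_s = 0.300,
                            ratio = 0.001, q = 1) {
  stopifnot(fs > 0, ratio > 0, q > 0)
  if (!(0 < peak_early_s && peak_early_s < peak_late_s))
    stop("need 0 < peak_early_s < peak_late_s")
  if (round(peak_early_s * fs) < 3)
    stop("early peak not representable: fewer than 3 samples to peak")
  cascade <- function(tau, sign_gain) {
    a <- exp(-1 / (fs * tau))
    A <- matrix(c(a, 0, 0,
                  1, a, 0,
                  0, 1, a), 3, 3, byrow = TRUE)
    # readout reproducing the sampled n^2 a^n response, normalised to
    # unit peak over the discrete grid
    nmax <- ceiling(6 * 2 * tau * fs)
    nn <- 0:nmax
    peak_val <- max(nn^2 * a^nn)
    Cw <- c(0, a, 2 * a^2) / peak_val
    list(A = A, B = c(sign_gain, 0, 0), C = Cw, a = a)
  }
  early <- cascade(peak_early_s / 2, -1)
  late <- cascade(peak_late_s / 2, +1)
  A <- rbind(cbind(early$A, matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), late$A))
  B <- matrix(c(early$B, late$B), 6, 1)
  C <- matrix(c(early$C, late$C), 1, 6)
  structure(list(A = A, B = B, C = C, Q = q * diag(6), R = ratio * q,
                 P0 = 10 * diag(6), fs = fs,
                 tau_early_s = peak_early_s / 2, tau_late_s = peak_late_s / 2,
                 peak_early_s = peak_early_s, peak_late_s = peak_late_s,
                 ratio = ratio, q = q),
            class = "erp_state_space")
}

#' @export
print.erp_state_space <- function(x, ...) {
  cat(sprintf(paste0("<erp_state_space> 6-state N100/P300 model @ %g Hz\n",
                     "  peaks %g / %g ms, R/Q ratio %g\n"),
              x$fs, 1000 * x$peak_early_s, 1000 * x$peak_late_s, x$ratio))
  invisible(x)
}

#' Noiseless unit-impulse responses of the two wave subsystems
#'
#' Drives the model with a single unit onset impulse and zero noise and
#' returns the early-wave and late-wave readouts separately, plus their sum.
#'
#' @param model an `erp_state_space`.
#' @param duration_s length of the returned responses (s).
#' @return List with numeric vectors `early`, `late`, `combined` and the
#'   sample times `t_s`; sample `k` corresponds to `(k-1)/fs` seconds after
#'   onset.
#' @export
erp_impulse_response <- function(model, duration_s = 0.5) {
  n <- round(duration_s * model$fs)
  x <- matrix(0, 6, 1)
  early <- late <- numeric(n)
  for (k in seq_len(n)) {
    u <- if (k == 1) 1 else 0
    x <- model$A %*% x + model$B * u
    early[k] <- sum(model$C[1, 1:3] * x[1:3])
    late[k] <- sum(model$C[1, 4:6] * x[4:6])
  }
  list(early = early, late = late, combined = early + late,
       t_s = (seq_len(n) - 1) / model$fs)
}

#' @export
plot.erp_state_space <- function(x, duration_s = 0.5, ...) {
  ir <- erp_impulse_response(x, duration_s)
  graphics::plot(ir$t_s * 1000, ir$combined, type = "l",
                 xlab = "time after onset (ms)", ylab = "response", ...)
  graphics::lines(ir$t_s * 1000, ir$early, col = 2, lty = 2)
  graphics::lines(ir$t_s * 1000, ir$late, col = 4, lty = 2)
  graphics::abline(v = 1000 * c(x$peak_early_s, x$peak_late_s), col = "grey")
  invisible(x)
}

#' Kalman-filter a trace with the ERP model
#'
#' Standard causal recursions: predict `x = A x + B u_k`,
#' `P = A P A' + Q`; update with gain `K = P C' / (C P C' + R)`. The onset
#' input `u_k` is 1 at every trial onset - chirp and silent alike, since
#' labels are unknown at test time - and 0 elsewhere. The error covariance
#' is iterated until it reaches its steady state, after which the constant
#' gain is used (the gain sequence is signal-independent). Output is the
#' causal instantaneous estimate `y_hat_k = C x_k|k`.
#'
#' @param model an `erp_state_space`.
#' @param signal numeric vector (single trace, e.g. one channel or one
#'   component activation).
#' @param onsets integer vector of 0-based onset samples, or an
#'   [event_list()] (all labels are used).
#' @param onset_gain amplitude of the onset impulse; the filter is jointly
#'   linear in the signal and this gain.
#' @return An `erp_estimate`: `estimate` (same length as input),
#'   `state_covariance_trace` per sample, `final_covariance` (the 6x6
#'   posterior covariance after the last step, at steady state for any
#'   signal longer than the transient), and the model.
#' @export
kalman_filter_erp <- function(model, signal, onsets, onset_gain = 1) {
  stopifnot(inherits(model, "erp_state_space"))
  if (inherits(onsets, "event_list")) onsets <- onsets$onset_sample
  n <- length(signal)
  bad <- which(!is.finite(signal))
  if (length(bad))
    stop("non-finite signal value at sample ", bad[1])
  if (length(onsets) && (min(onsets) < 0 || max(onsets) >= n))
    stop("onsets must lie within the signal")
  u <- numeric(n)
  u[onsets + 1L] <- onset_gain
  A <- model$A; B <- as.numeric(model$B); Cv <- as.numeric(model$C)
  Q <- model$Q; R <- model$R
  x <- numeric(6)
  P <- model$P0
  est <- numeric(n)
  ptr <- numeric(n)
  Kg <- NULL
  steady <- FALSE
  trP <- NA_real_
  for (k in seq_len(n)) {
    xp <- A %*% x + B * u[k]
    if (!steady) {
      Pp <- A %*% P %*% t(A) + Q
      s <- sum(Cv * (Pp %*% Cv)) + R
      Kg <- (Pp %*% Cv) / s
      Pn <- Pp - Kg %*% (Cv %*% Pp)
      Pn <- (Pn + t(Pn)) / 2
      if (max(abs(Pn - P)) < 1e-12 * max(1, max(abs(Pn)))) {
        steady <- TRUE
        trP <- sum(diag(Pn))
      }
      P <- Pn
    }
    innov <- signal[k] - sum(Cv * xp)
    x <- xp + Kg * innov
    est[k] <- sum(Cv * x)
    ptr[k] <- if (steady) trP else sum(diag(P))
  }
  structure(list(estimate = est, state_covariance_trace = ptr,
                 final_covariance = P, model = model),
            class = "erp_estimate")
}

#' @export
print.erp_estimate <- function(x, ...) {
  cat(sprintf("<erp_estimate> %d samples, RMS %.3g\n",
              length(x$estimate), rms(x$estimate)))
  invisible(x)
}

#' Steady-state error covariance by Riccati iteration
#'
#' Iterates the discrete Riccati map of the model to its fixed point;
#' used as the reference the running filter covariance must converge to.
#'
#' @param model an `erp_state_space`.
#' @param tol relative convergence tolerance (max element change relative
#'   to the covariance magnitude).
#' @param max_iter iteration cap.
#' @return The 6x6 steady-state (posterior) covariance.
#' @export
riccati_fixed_point <- function(model, tol = 1e-14, max_iter = 100000) {
  A <- model$A; Cv <- as.numeric(model$C); Q <- model$Q; R <- model$R
  P <- model$P0
  for (i in seq_len(max_iter)) {
    Pp <- A %*% P %*% t(A) + Q
    s <- sum(Cv * (Pp %*% Cv)) + R
    Kg <- (Pp %*% Cv) / s
    Pn <- Pp - Kg %*% (Cv %*% Pp)
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol * max(1, max(abs(Pn)))) return(Pn)
    P <- Pn
  }
  warning("Riccati iteration did not reach the fixed point")
  P
}

#' Epoch a trace into trial windows
#'
#' Row `t` holds samples `[onset_t, onset_t + round(window_s * fs))`;
#' at 300 Hz and a 0.5 s window each trial contributes 150 samples.
#'
#' @param x numeric vector (a trace or an `erp_estimate`).
#' @param events an [event_list()] or 0-based onset vector.
#' @param window_s epoch length (s).
#' @param fs sampling rate (Hz; taken from the event list if available).
#' @return trials x samples matrix, with the labels (if any) as attribute
#'   `labels`.
#' @export
epoch_signal <- function(x, events, window_s = 0.5, fs = NULL) {
  if (inherits(x, "erp_estimate")) x <- x$estimate
  labels <- NULL
  if (inherits(events, "event_list")) {
    fs <- fs %||% attr(events, "fs")
    labels <- events$label
    onsets <- events$onset_sample
  } else onsets <- as.integer(events)
  if (is.null(fs)) stop("fs required")
  nsmp <- round(window_s * fs)
  bad <- which(onsets + nsmp > length(x) | onsets < 0)
  if (length(bad))
    stop("epochs cross the signal bounds for events: ",
         paste(utils::head(bad, 10), collapse = ", "))
  out <- matrix(0, length(onsets), nsmp)
  for (t in seq_along(onsets))
    out[t, ] <- x[(onsets[t] + 1L):(onsets[t] + nsmp)]
  structure(out, labels = labels)
}
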