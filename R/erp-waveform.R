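#' Canonical two-wave auditory evoked potential template
#'
#' The evoked response is modelled as the sum of two third-order impulse
#' responses `h(t; tau) = t^2 exp(-t/tau)`, one negative wave peaking at
#' `2 * tau_early_s` (the N100 at 100 ms for `tau_early_s = 0.05`) and one
#' positive wave peaking at `2 * tau_late_s` (the P300 at 300 ms for
#' `tau_late_s = 0.15`). Each wave is normalised to unit peak magnitude over
#' the sampled epoch before being scaled by its amplitude, so `amp_early`
#' and `amp_late` are the peak values in microvolts.
#'
#' @param fs sampling rate (Hz).
#' @param epoch_s epoch length (s); samples run from 0 to `epoch_s - 1/fs`.
#' @param amp_early peak amplitude of the early (negative) wave; `< 0` for
#'   the physiological N100 polarity.
#' @param amp_late peak amplitude of the late (positive) wave.
#' @param tau_early_s,tau_late_s time constants (s); the continuous-time
#'   peak of `t^2 exp(-t/tau)` falls at `2 * tau`.
#' @return numeric vector of `round(epoch_s * fs)` samples (microvolts).
#' @examples
#' w <- canonical_erp()
#' which.min(w) - 1L  # sample 30 = 100 ms at 300 Hz
#' @export
canonical_erp <- function(fs = 300, epoch_s = 0.5, amp_early = -1,
                          amp_late = 1, tau_early_s = 0.050,
                          tau_late_s = 0.150) {
  stopifnot(fs > 0, epoch_s > 0)
  if (tau_early_s <= 0 || tau_late_s <= 0)
    stop("time constants must be positive")
  n <- round(epoch_s * fs)
  t <- (seq_len(n) - 1) / fs
  h <- function(tau) {
    w <- t^2 * exp(-t / tau)
    w / max(w)
  }
  amp_early * h(tau_early_s) + amp_late * h(tau_late_s)
}
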