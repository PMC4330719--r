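#' Synthetic session configuration
#'
#' Describes one simulated recording session: the stimulus schedule, the
#' evoked-response strength, the artifact regime, and any planted bad
#' channels. Defaults mirror the study conditions the pipeline was designed
#' for: 64 dry electrodes at 300 Hz, 200 chirp presentations of 0.1 s
#' separated by 0.6-2.5 s of silence, and 200 silent 0.5 s segments.
#'
#' @param n_channels number of EEG channels.
#' @param fs sampling rate (Hz).
#' @param n_chirp number of chirp presentations (the same number of silent
#'   segments is extracted).
#' @param chirp_dur_s,isi_min_s,isi_max_s,epoch_s stimulus timing (s); see
#'   [generate_events()].
#' @param erp_snr ratio of evoked-response RMS to background RMS at the best
#'   (fronto-central) channel. Scales the ERP source only, so doubling it
#'   doubles the ERP contribution at every channel. The default 0.25 puts the
#'   single-trial ERP peak near 5 uV against a 7 uV background.
#' @param artifact_severity `"off"` (bench-quiet: sparse small blinks, faint
#'   muscle) or `"on"` (operational: frequent large blinks, dense muscle
#'   bursts, strong low-frequency vibration).
#' @param planted_bad_channels list of `list(channel =, kind =)` entries with
#'   kind one of `"flatline"`, `"high_amplitude"`, `"decorrelated"`.
#' @param line_freq_hz mains frequency of the optional line sinusoid.
#' @param line_amp_uv amplitude of the line sinusoid (0 disables it).
#' @param bg_rms_uv background (1/f + alpha) RMS at the best ERP channel.
#' @param amp_jitter_sd trial-to-trial multiplicative amplitude jitter SD
#'   (fraction of 1).
#' @param lat_jitter_sd_s trial-to-trial latency jitter SD (s).
#' @param seed integer seed; fixed seeds give bit-identical recordings.
#' @return A `session_config` list.
#' @export
session_config <- function(n_channels = 64, fs = 300, n_chirp = 200,
                           chirp_dur_s = 0.1, isi_min_s = 0.6, isi_max_s = 2.5,
                           epoch_s = 0.5, erp_snr = 0.25,
                           artifact_severity = c("off", "on"),
                           planted_bad_channels = list(),
                           line_freq_hz = 60, line_amp_uv = 0,
                           bg_rms_uv = 7, amp_jitter_sd = 0.2,
                           lat_jitter_sd_s = 0.010, seed = 1) {
  artifact_severity <- match.arg(artifact_severity)
  stopifnot(n_channels >= 1, fs > 0, n_chirp >= 1, erp_snr >= 0,
            bg_rms_uv > 0)
  if (!(0 < isi_min_s && isi_min_s <= isi_max_s))
    stop("need 0 < isi_min_s <= isi_max_s")
  if (length(planted_bad_channels)) {
    ch <- vapply(planted_bad_channels, function(p) as.integer(p$channel), 1L)
    kinds <- vapply(planted_bad_channels, function(p) p$kind, "")
    if (anyDuplicated(ch)) stop("planted bad channel indices collide")
    if (any(ch < 1 | ch > n_channels)) stop("planted bad channel index out of range")
    if (!all(kinds %in% c("flatline", "high_amplitude", "decorrelated")))
      stop("unknown planted bad channel kind")
  }
  structure(list(n_channels = n_channels, fs = fs, n_chirp = n_chirp,
                 chirp_dur_s = chirp_dur_s, isi_min_s = isi_min_s,
                 isi_max_s = isi_max_s, epoch_s = epoch_s, erp_snr = erp_snr,
                 artifact_severity = artifact_severity,
                 planted_bad_channels = planted_bad_channels,
                 line_freq_hz = line_freq_hz, line_amp_uv = line_amp_uv,
                 bg_rms_uv = bg_rms_uv, amp_jitter_sd = amp_jitter_sd,
                 lat_jitter_sd_s = lat_jitter_sd_s, seed = seed),
            class = "session_config")
}

# Smooth random topography over the channel array: a Gaussian bump at
# `center` (fractional position in [0,1]) modulated by spatially smoothed
# noise, normalised to unit maximum magnitude. Smoothness across neighbouring
# channels stands in for volume conduction.
smooth_topography <- function(n_ch, center = NULL, width = 0.25,
                              roughness = 0.3) {
  pos <- seq(0, 1, length.out = n_ch)
  if (is.null(center)) center <- stats::runif(1)
  bump <- exp(-(pos - center)^2 / (2 * width^2))
  z <- stats::rnorm(n_ch)
  kw <- max(2, round(n_ch / 8))
  kern <- stats::dnorm(seq(-2, 2, length.out = 2 * kw + 1))
  sm <- as.numeric(stats::filter(c(rev(z[1:kw]), z, rev(z[(n_ch - kw + 1):n_ch])),
                                 kern / sum(kern), sides = 2))[(kw + 1):(kw + n_ch)]
  topo <- bump * (1 + roughness * sm / max(abs(sm)))
  topo / max(abs(topo))
}

# 1/f ("pink") noise of length n via spectral shaping, unit RMS.
pink_noise <- function(n, fs, f_floor = 1) {
  nfft <- stats::nextn(n, 2)
  f <- c(0, seq_len(nfft - 1)) * fs / nfft
  f <- pmin(f, fs - f)                      # two-sided
  shape <- 1 / sqrt(pmax(f, f_floor))
  shape[1] <- 0
  spec <- stats::fft(stats::rnorm(nfft)) * shape
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x / rms(x)
}

# Band-limited noise via FFT masking, unit RMS.
band_noise <- function(n, fs, lo, hi) {
  nfft <- stats::nextn(n, 2)
  f <- c(0, seq_len(nfft - 1)) * fs / nfft
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= lo & f <= hi)
  x <- Re(stats::fft(stats::fft(stats::rnorm(nfft)) * mask, inverse = TRUE))[seq_len(n)]
  x / rms(x)
}

# Transient bump train: events at rate `rate` per second, each a raised-cosine
# bump of `dur_s` seconds with per-event amplitude jitter. Unit peak scale.
bump_train <- function(n, fs, rate, dur_s) {
  x <- numeric(n)
  n_ev <- stats::rpois(1, rate * n / fs)
  if (n_ev == 0) return(x)
  starts <- sort(sample.int(max(1, n - round(dur_s * fs)), n_ev, replace = TRUE))
  w <- round(dur_s * fs)
  bump <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  for (s in starts) {
    idx <- s:min(n, s + w - 1)
    x[idx] <- x[idx] + bump[seq_along(idx)] * stats::runif(1, 0.6, 1.4)
  }
  x
}

#' Simulate a synthetic EEG session with ground truth
#'
#' Builds a forward-mixed multichannel recording `data = mixing %*% sources`
#' containing (a) an evoked-response source - an impulse train at chirp
#' onsets convolved with a per-trial jittered [canonical_erp()] template;
#' (b) per-channel 1/f background sources plus a 10 Hz alpha source;
#' (c) frontal blink transients; (d) 20-80 Hz muscle bursts; (e) a
#' low-frequency vibration component; and (f) an optional mains sinusoid.
#' Artifact amplitudes are scaled up under `artifact_severity = "on"`.
#' Planted bad channels overwrite the mixed data afterwards (flatline:
#' constant; high_amplitude: repeated >= 300 uV excursions; decorrelated:
#' independent noise).
#'
#' @param config a [session_config()].
#' @return A list with elements `recording` (an [eeg_recording()]) and
#'   `truth` (mixing matrix, source matrix, per-trial realised ERP epochs,
#'   planted bad channels, per-trial jitters). Without planted bad channels,
#'   `recording$data == truth$mixing %*% truth$sources` exactly.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "session_config"))
  cf <- config
  with_seed(derive_seed(cf$seed, "events"), {
    events <- generate_events(cf$n_chirp, cf$isi_min_s, cf$isi_max_s,
                              cf$chirp_dur_s, cf$epoch_s, cf$fs)
  })
  fs <- cf$fs
  epoch_smp <- round(cf$epoch_s * fs)
  n <- max(events$onset_sample) + epoch_smp + round(1 * fs)  # 1 s tail pad
  if (n <= 0) stop("zero-duration session")
  nch <- cf$n_channels

  sev <- cf$artifact_severity
  amp <- list(blink = if (sev == "on") 120 else 18,
              blink_rate = if (sev == "on") 0.25 else 0.05,
              muscle = if (sev == "on") 35 else 4,
              muscle_rate = if (sev == "on") 0.20 else 0.02,
              vib = if (sev == "on") 30 else 2)

  with_seed(derive_seed(cf$seed, "sources"), {
    chirps <- events_of(events, "chirp")
    n_tr <- length(chirps)
    template <- canonical_erp(fs, cf$epoch_s, amp_early = -1, amp_late = 1)

    # per-trial jitters
    amp_j <- pmax(0.1, 1 + stats::rnorm(n_tr, 0, cf$amp_jitter_sd))
    lat_j <- round(stats::rnorm(n_tr, 0, cf$lat_jitter_sd_s) * fs)

    erp_src <- numeric(n)
    for (t in seq_len(n_tr)) {
      s <- chirps[t] + 1L + lat_j[t]
      idx <- s:(s + epoch_smp - 1L)
      ok <- idx >= 1 & idx <= n
      erp_src[idx[ok]] <- erp_src[idx[ok]] + amp_j[t] * template[ok]
    }

    # background: one pink source per channel + one alpha source
    bg <- matrix(0, nch, n)
    for (i in seq_len(nch)) bg[i, ] <- pink_noise(n, fs)
    alpha_src <- band_noise(n, fs, 8, 12)
    blink_src <- bump_train(n, fs, amp$blink_rate, 0.30)
    muscle_src <- band_noise(n, fs, 20, 80) *
      (0.15 + bump_train(n, fs, amp$muscle_rate, 0.60))
    vib_src <- band_noise(n, fs, 0.5, 3)
    line_src <- sin(2 * pi * cf$line_freq_hz * (seq_len(n) - 1) / fs +
                      stats::runif(1, 0, 2 * pi))

    # topographies
    topo_erp <- smooth_topography(nch, center = 0.35, width = 0.20)
    topo_alpha <- smooth_topography(nch, center = 0.85, width = 0.30)
    topo_blink <- smooth_topography(nch, center = 0.02, width = 0.10)
    topo_muscle <- smooth_topography(nch, center = stats::runif(1), width = 0.15)
    topo_vib <- smooth_topography(nch, center = stats::runif(1), width = 0.60)
    topo_line <- smooth_topography(nch, center = stats::runif(1), width = 0.40)
    topo_bg <- matrix(0, nch, nch)
    for (i in seq_len(nch))
      topo_bg[, i] <- smooth_topography(nch, center = (i - 0.5) / nch,
                                        width = 0.18)

    # scaling: background RMS at the best ERP channel fixes the scale;
    # the ERP source is then set from erp_snr at that channel
    best <- which.max(abs(topo_erp))
    bg_mix <- topo_bg %*% bg + topo_alpha %o% (0.8 * alpha_src)
    bg_scale <- cf$bg_rms_uv / rms(bg_mix[best, ])
    topo_bg <- topo_bg * bg_scale
    topo_alpha <- topo_alpha * 0.8 * bg_scale
    erp_rms_target <- cf$erp_snr * cf$bg_rms_uv
    erp_scale <- if (rms(erp_src[erp_src != 0]) > 0 && cf$erp_snr > 0)
      erp_rms_target / (rms(template) * abs(topo_erp[best])) else 0
    # rms over an epoch of the unit template times the topography weight
    # equals erp_snr * bg_rms at the best channel

    sources <- rbind(erp_src * erp_scale,
                     alpha_src,
                     bg,
                     blink_src * amp$blink,
                     muscle_src * amp$muscle,
                     vib_src * amp$vib,
                     line_src * cf$line_amp_uv)
    mixing <- cbind(topo_erp, topo_alpha, topo_bg, topo_blink, topo_muscle,
                    topo_vib, topo_line)
    rownames(sources) <- c("erp", "alpha", sprintf("bg%02d", seq_len(nch)),
                           "blink", "muscle", "vibration", "line")
    colnames(mixing) <- rownames(sources)

    data <- mixing %*% sources

    erp_trials <- matrix(0, n_tr, epoch_smp)
    for (t in seq_len(n_tr)) {
      s <- chirps[t] + 1L
      idx <- s:(s + epoch_smp - 1L)
      ok <- idx >= 1 & idx <= n
      erp_trials[t, ok] <- erp_src[idx[ok]] * erp_scale * topo_erp[best]
    }

    # planted bad channels overwrite the mixed data
    bad <- cf$planted_bad_channels
    for (p in bad) {
      i <- p$channel
      data[i, ] <- switch(p$kind,
        flatline = 0,
        high_amplitude = data[i, ] +
          350 * bump_train(n, fs, 0.3, 0.15) * sample(c(-1, 1), 1),
        decorrelated = cf$bg_rms_uv * pink_noise(n, fs))
    }

    rec <- eeg_recording(data, fs, events = events)
    truth <- list(mixing = mixing, sources = sources,
                  erp_waveform_per_trial = erp_trials,
                  bad_channels = bad,
                  jitters = data.frame(amplitude = amp_j, latency = lat_j),
                  best_channel = best)
    list(recording = rec, truth = truth)
  })
}
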