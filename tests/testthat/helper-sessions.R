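# Lazily built, cached synthetic sessions shared across test files.
.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, builder) {
  if (!exists(key, envir = .session_cache))
    assign(key, builder(), envir = .session_cache)
  get(key, envir = .session_cache)
}

# small artifact-free session used by several stages
quiet_session <- function() cached_session("quiet", function()
  simulate_recording(session_config(n_channels = 16, n_chirp = 40, seed = 42)))

# Amari index: permutation/scale-invariant distance between the estimated
# global matrix G = unmixing %*% sphering %*% true_mixing and a scaled
# permutation; 0 means exact source recovery.
amari_index <- function(G) {
  P <- abs(G)
  n <- nrow(P)
  a1 <- sum(apply(P, 1, function(r) sum(r) / max(r) - 1))
  a2 <- sum(apply(P, 2, function(cc) sum(cc) / max(cc) - 1))
  (a1 + a2) / (2 * n * (n - 1))
}

rms <- function(x) sqrt(mean(x^2))

# one 3-source mixture and its ICA fit, reused by the ICA unit tests and
# the recovery acceptance check
three_source_fit <- function() cached_session("ica3", function() {
  fs <- 300
  set.seed(42)
  ns <- 60 * fs
  S <- rbind(runif(ns, -1, 1),
             rexp(ns) * sign(runif(ns, -1, 1)),
             sin(2 * pi * 7 * seq_len(ns) / fs))
  M <- matrix(rnorm(9), 3, 3)
  fit <- fit_extended_infomax(M %*% S, seed = 1, max_iter = 1024)
  list(S = S, M = M, fit = fit)
})

# amplitude of a sinusoid at frequency f in a series, by least squares
sine_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t) - 1))
  sqrt(sum(co^2))
}
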