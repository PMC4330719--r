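# Internal helpers shared across the pipeline.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded operations never perturb the global random stream. A `NULL` seed
#' leaves the RNG untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named sub-stream seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed through named
#' substreams (events, ica, folds, permutation, ...), so that changing the
#' number of draws in one stage never shifts another stage's stream.
#' Kept below 2^31 - 1 (R integers are 32-bit).
#' @noRd
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (as.double(seed) * 48271 + h * 16807 + as.double(index) * 69621) %%
    2147483629
  as.integer(val + 1)
}

# Principal square root of a symmetric positive (semi-)definite matrix.
sqrtm_psd <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

rms <- function(x) sqrt(mean(x^2))

# FFT-based linear convolution of a long series with a short kernel.
# Returns the "same"-aligned result for a kernel whose group delay is
# `delay` samples (delay = (length(kernel)-1)/2 for symmetric kernels).
fft_conv_same <- function(x, kernel, delay) {
  n <- length(x)
  nk <- length(kernel)
  nfft <- stats::nextn(n + nk - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(kernel, numeric(nfft - nk))),
                     inverse = TRUE)) / nfft
  y[(delay + 1L):(delay + n)]
}

# Longest run of TRUE in a logical vector (0 when none).
longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
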