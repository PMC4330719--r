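#' Extended-infomax independent component analysis
#'
#' Natural-gradient infomax with the extended (sub/super-Gaussian) switching
#' nonlinearity: after sphering the data to unit covariance, weights are
#' updated in random blocks by
#' `W <- W + lrate * (I - K tanh(u) u' - u u') W`, where `K` is a diagonal
#' of +/-1 switched by the running kurtosis sign of each component. The
#' learning rate is annealed whenever the weight-update direction turns by
#' more than `anneal_deg` degrees. Components are reordered by descending
#' mean projected variance. Weights are learned on training data only and
#' transferred unchanged to test data via [project_components()].
#'
#' @param data channels x samples numeric matrix (assumed band-passed,
#'   approximately zero-mean: no centering is applied, keeping the
#'   decomposition strictly linear).
#' @param seed integer seed for block order and the initial state.
#' @param max_iter maximal number of passes over the data.
#' @param tol stop when the summed squared weight change of a pass falls
#'   below this.
#' @param block block size (samples) for the stochastic updates.
#' @param lrate initial learning rate; default `0.001 / log(n_channels)`.
#' @param anneal_deg,anneal annealing angle (degrees) and factor.
#' @return An `ica_decomposition`: `sphering`, `unmixing`, `mixing`
#'   (pseudo-inverse of `unmixing %*% sphering`), `component_order`,
#'   `kurtosis_sign`, `seed`, `n_iterations`, `converged`.
#' @export
fit_extended_infomax <- function(data, seed = 1, max_iter = 512, tol = 1e-7,
                                 block = 256, lrate = NULL, anneal_deg = 60,
                                 anneal = 0.98) {
  stopifnot(is.matrix(data), nrow(data) >= 2)
  nc <- nrow(data)
  ns <- ncol(data)
  if (ns < 20 * nc)
    warning("few samples relative to channel count; ICA may be unstable")
  ev <- eigen(tcrossprod(data) / ns, symmetric = TRUE)
  if (min(ev$values) < 1e-10 * max(ev$values))
    stop("data are rank deficient; remove degenerate channels first")
  S <- ev$vectors %*% ((1 / sqrt(ev$values)) * t(ev$vectors))
  Xw <- S %*% data
  if (is.null(lrate)) lrate <- 0.001 / log(nc)
  n_it <- 0L
  converged <- FALSE
  with_seed(seed, {
    W <- diag(nc)
    K <- rep(1, nc)
    oldW <- W
    olddelta <- NULL
    Id <- diag(nc)
    for (it in seq_len(max_iter)) {
      n_it <- it
      perm <- sample.int(ns)
      nblocks <- ns %/% block
      blowup <- FALSE
      for (b in seq_len(nblocks)) {
        idx <- perm[((b - 1) * block + 1):(b * block)]
        u <- W %*% Xw[, idx, drop = FALSE]
        W <- W + lrate *
          (Id - (K * tanh(u)) %*% t(u) / block - tcrossprod(u) / block) %*% W
        if (max(abs(W)) > 1e8) { blowup <- TRUE; break }
      }
      if (blowup) {               # diverged: restart colder
        W <- diag(nc); oldW <- W; olddelta <- NULL
        K <- rep(1, nc); lrate <- lrate * 0.5
        next
      }
      u <- W %*% Xw
      K <- sign(rowMeans(1 - tanh(u)^2) * rowMeans(u^2) -
                  rowMeans(u * tanh(u)))
      K[K == 0] <- 1
      delta <- as.vector(W - oldW)
      change <- sum(delta^2)
      if (!is.null(olddelta)) {
        cosang <- sum(delta * olddelta) /
          sqrt(sum(delta^2) * sum(olddelta^2))
        if (is.finite(cosang) && cosang < cos(anneal_deg * pi / 180))
          lrate <- lrate * anneal
      }
      olddelta <- delta
      oldW <- W
      if (change < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning(sprintf("extended infomax did not converge in %d iterations",
                      max_iter))
    mix <- MASS::ginv(W %*% S)
    act_var <- rowMeans((W %*% Xw)^2)
    pvar <- colMeans(mix^2) * act_var
    ord <- order(pvar, decreasing = TRUE)
    W <- W[ord, , drop = FALSE]      # rows reordered; sphering kept separate
    structure(list(sphering = S, unmixing = W,
                   mixing = MASS::ginv(W %*% S),
                   component_order = ord,
                   projected_variance = pvar[ord],
                   kurtosis_sign = K[ord], seed = seed,
                   n_iterations = n_it, converged = converged),
              class = "ica_decomposition")
  })
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components, %d iterations, %s\n",
              nrow(x$unmixing), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  kurtosis signs: %d super-, %d sub-Gaussian\n",
              sum(x$kurtosis_sign > 0), sum(x$kurtosis_sign < 0)))
  invisible(x)
}

#' Project data through a fitted decomposition
#'
#' `activations = unmixing %*% sphering %*% data`; strictly linear and
#' deterministic, so training-set weights transfer unchanged to test data.
#'
#' @param decomp an `ica_decomposition`.
#' @param data channels x samples matrix with the fitted channel count.
#' @return components x samples activation matrix.
#' @export
project_components <- function(decomp, data) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  if (inherits(data, "eeg_recording")) data <- data$data
  if (nrow(data) != ncol(decomp$unmixing))
    stop("channel count does not match the decomposition")
  decomp$unmixing %*% decomp$sphering %*% data
}

#' Select evoked-response components by template correlation
#'
#' Replaces visual inspection: each component's chirp-locked average
#' activation (0-500 ms) is correlated with the [canonical_erp()] template;
#' the top `k` components with `|r| >= min_abs_r` are returned in descending
#' score order. Sign and scale of components are immaterial (absolute
#' correlation).
#'
#' @param decomp an `ica_decomposition` (only used for dimension checks).
#' @param activations components x samples matrix from
#'   [project_components()].
#' @param events an [event_list()]; only chirp events are used.
#' @param fs sampling rate (Hz).
#' @param k maximal number of components to select.
#' @param min_abs_r minimal absolute template correlation.
#' @param epoch_s epoch length (s).
#' @return Integer vector of component indices (possibly empty, with a
#'   warning, in which case callers fall back to all components), with the
#'   scores as attribute `score`.
#' @export
select_erp_components <- function(decomp, activations, events, fs, k = 2,
                                  min_abs_r = 0.4, epoch_s = 0.5) {
  chirps <- events_of(events, "chirp")
  if (length(chirps) < 1) stop("need at least one chirp event")
  template <- canonical_erp(fs, epoch_s)
  nsmp <- length(template)
  keep <- chirps + nsmp <= ncol(activations)
  chirps <- chirps[keep]
  scores <- vapply(seq_len(nrow(activations)), function(ci) {
    m <- rowMeans(vapply(chirps, function(o)
      activations[ci, (o + 1):(o + nsmp)], numeric(nsmp)))
    abs(stats::cor(m, template))
  }, 0)
  cand <- which(scores >= min_abs_r)
  if (!length(cand)) {
    warning("no component reaches the template-correlation threshold")
    return(structure(integer(0), score = scores))
  }
  sel <- cand[order(scores[cand], decreasing = TRUE)]
  sel <- utils::head(sel, k)
  structure(sel, score = scores)
}
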