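#' Fit a least-squares probabilistic classifier
#'
#' Models the class-posterior probability as a Gaussian-kernel expansion
#' over the training points, fitted per class by regularised least squares
#' in closed form: with Gram matrix `G_ij = exp(-||x_i - x_j||^2 / (2
#' sigma^2))` and class-indicator vector `b_y`,
#' `theta_y = (G'G/n + lambda I)^{-1} G' b_y / n`. No iteration is
#' involved, so fits are fast and exactly reproducible.
#'
#' @param x trials x features numeric matrix.
#' @param y class labels (two or more classes present).
#' @param sigma Gaussian kernel width (> 0).
#' @param lambda ridge weight (> 0).
#' @return An `lspc_model`: `centers`, `sigma`, `lambda`, `theta`
#'   (centers x classes), `classes`.
#' @export
lspc_fit <- function(x, y, sigma, lambda) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2 || length(unique(y)) < 2)
    stop("need at least two classes present")
  if (!(sigma > 0) || !(lambda >= 0)) stop("sigma > 0 and lambda >= 0 required")
  if (anyNA(x)) stop("features contain NA")
  n <- nrow(x)
  G <- gauss_kernel(x, x, sigma)
  H <- crossprod(G) / n + diag(lambda, n)
  Bm <- vapply(levels(y), function(lv) as.numeric(y == lv), numeric(n))
  rhs <- crossprod(G, Bm) / n
  theta <- tryCatch(solve(H, rhs), error = function(e)
    stop("singular LSPC system; use lambda > 0 (", conditionMessage(e), ")"))
  structure(list(centers = x, sigma = sigma, lambda = lambda,
                 theta = theta, classes = levels(y)),
            class = "lspc_model")
}

gauss_kernel <- function(a, b, sigma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' @export
print.lspc_model <- function(x, ...) {
  cat(sprintf("<lspc_model> %d centers, %d features, sigma %.3g, lambda %.3g\n",
              nrow(x$centers), ncol(x$centers), x$sigma, x$lambda))
  invisible(x)
}

#' Predict from an LSPC model
#'
#' Raw per-class scores `s_y(x) = k(x)' theta_y` are clipped at zero and
#' normalised to posteriors; if every score is non-positive the posterior
#' is uniform. The predicted label is the posterior argmax, with exact ties
#' broken toward `"silent"` when present (conservative: avoids false
#' alarms), otherwise toward the last class.
#'
#' @param object an `lspc_model`.
#' @param newdata trials x features matrix with the training feature count.
#' @param ... unused.
#' @return List with `labels` (factor) and `posteriors` (trials x classes).
#' @export
predict.lspc_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$centers))
    stop("feature dimension does not match the model")
  K <- gauss_kernel(newdata, object$centers, object$sigma)
  s <- K %*% object$theta
  s[s < 0] <- 0
  tot <- rowSums(s)
  flat <- tot <= 0
  s[flat, ] <- 1
  post <- s / rowSums(s)
  colnames(post) <- object$classes
  tie_to <- if ("silent" %in% object$classes)
    match("silent", object$classes) else length(object$classes)
  pick <- apply(post, 1, function(p) {
    best <- which(p == max(p))
    if (length(best) > 1 && tie_to %in% best) tie_to else best[1]
  })
  list(labels = factor(object$classes[pick], levels = object$classes),
       posteriors = post)
}

#' Median pairwise distance heuristic for the kernel width grid
#'
#' @param x trials x features matrix.
#' @param max_n deterministic subsample cap (evenly spaced rows).
#' @return Median Euclidean distance between distinct rows.
#' @export
median_pairwise_distance <- function(x, max_n = 400) {
  x <- as.matrix(x)
  if (nrow(x) > max_n)
    x <- x[round(seq(1, nrow(x), length.out = max_n)), , drop = FALSE]
  d <- stats::dist(x)
  stats::median(d[d > 0])
}
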