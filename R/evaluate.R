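#' Classification metrics for chirp-vs-silent decoding
#'
#' Accuracy, false positive rate (silent trials predicted chirp), false
#' negative rate (chirp trials predicted silent), and the sensitivity index
#' `d' = z(hit rate) - z(false-alarm rate)` with rates clipped to
#' `[1/(2N), 1 - 1/(2N)]` to keep the quantiles finite. On balanced test
#' sets `accuracy = 1 - (FPR + FNR)/2` holds exactly.
#'
#' @param predictions predicted labels.
#' @param truth true labels (both classes must be present).
#' @param positive label counted as a detection (default `"chirp"`).
#' @return A `classification_metrics` list: `accuracy`, `false_positive_rate`,
#'   `false_negative_rate`, `dprime`, `n_pos`, `n_neg` (rates as fractions).
#' @export
compute_metrics <- function(predictions, truth, positive = "chirp") {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  stopifnot(length(predictions) == length(truth))
  if (length(unique(truth)) < 2)
    stop("truth contains a single class; metrics undefined")
  pos <- truth == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  fnr <- sum(predictions[pos] != positive) / n_pos
  fpr <- sum(predictions[!pos] == positive) / n_neg
  acc <- mean(predictions == truth)
  clip <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  dprime <- stats::qnorm(clip(1 - fnr, n_pos)) - stats::qnorm(clip(fpr, n_neg))
  structure(list(accuracy = acc, false_positive_rate = fpr,
                 false_negative_rate = fnr, dprime = dprime,
                 n_pos = n_pos, n_neg = n_neg),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  FPR %.1f%%  FNR %.1f%%  d' %.2f  (n = %d + %d)\n",
              100 * x$accuracy, 100 * x$false_positive_rate,
              100 * x$false_negative_rate, x$dprime, x$n_pos, x$n_neg))
  invisible(x)
}

# Stratified randomised fold assignment; every fold gets (nearly) equal
# class counts. Returns an integer fold id per trial.
make_folds <- function(y, n_folds, seed = NULL, max_attempts = 10) {
  y <- factor(y)
  with_seed(seed, {
    for (att in seq_len(max_attempts)) {
      fold <- integer(length(y))
      for (lv in levels(y)) {
        idx <- which(y == lv)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      ok <- all(vapply(seq_len(n_folds), function(f)
        length(unique(y[fold == f])) == nlevels(y), TRUE))
      if (ok) return(fold)
    }
    stop("could not build folds containing every class")
  })
}

#' Inner cross-validated LSPC model selection
#'
#' Randomised stratified `n_folds`-fold cross-validation over a
#' `sigma x lambda` grid; the grid point with the best mean validation
#' accuracy is refit on all training data. Ties break toward smaller
#' `sigma`, then larger `lambda` (the smoother, more regularised model).
#' The default width grid is the median pairwise distance scaled by
#' `c(0.1, 0.3, 1, 3, 10)`; the default ridge grid is `10^(-3:0)`.
#'
#' @param x trials x features training matrix.
#' @param y training labels.
#' @param n_folds number of folds (with 150 + 150 trials the fold
#'   complements hold 135 + 135).
#' @param sigma_grid,lambda_grid hyperparameter grids.
#' @param seed integer seed controlling the fold randomisation.
#' @return List: `sigma`, `lambda`, `model` (refit on all data),
#'   `cv_accuracy` (grid data frame), `folds`.
#' @export
inner_cv_select <- function(x, y, n_folds = 10, sigma_grid = NULL,
                            lambda_grid = c(1e-3, 1e-2, 1e-1, 1),
                            seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (is.null(sigma_grid))
    sigma_grid <- median_pairwise_distance(x) * c(0.1, 0.3, 1, 3, 10)
  fold <- make_folds(y, n_folds, seed)
  n <- nrow(x)
  grid <- expand.grid(sigma = sigma_grid, lambda = lambda_grid)
  acc <- matrix(0, nrow(grid), n_folds)
  for (si in seq_along(sigma_grid)) {
    G <- gauss_kernel(x, x, sigma_grid[si])
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      Gtr <- G[tr, tr, drop = FALSE]
      ntr <- sum(tr)
      H0 <- crossprod(Gtr) / ntr
      Bm <- vapply(levels(y), function(lv) as.numeric(y[tr] == lv),
                   numeric(ntr))
      rhs <- crossprod(Gtr, Bm) / ntr
      Kval <- G[!tr, tr, drop = FALSE]
      yval <- y[!tr]
      for (li in seq_along(lambda_grid)) {
        theta <- solve(H0 + diag(lambda_grid[li], ntr), rhs)
        s <- Kval %*% theta
        s[s < 0] <- 0
        pred <- max.col(cbind(s, 1e-300), ties.method = "last")
        # ties (all-zero rows) fall to the sentinel column -> treat as the
        # tie-break class below
        lab <- ifelse(pred > nlevels(y),
                      tiebreak_level(levels(y)), levels(y)[pred])
        gi <- which(grid$sigma == sigma_grid[si] &
                      grid$lambda == lambda_grid[li])
        acc[gi, f] <- mean(lab == as.character(yval))
      }
    }
  }
  mean_acc <- rowMeans(acc)
  best <- order(-mean_acc, grid$sigma, -grid$lambda)[1]
  model <- lspc_fit(x, y, grid$sigma[best], grid$lambda[best])
  list(sigma = grid$sigma[best], lambda = grid$lambda[best], model = model,
       cv_accuracy = cbind(grid, accuracy = mean_acc), folds = fold)
}

tiebreak_level <- function(classes) {
  if ("silent" %in% classes) "silent" else classes[length(classes)]
}

#' Repeated model selection and evaluation
#'
#' Repeats the full inner-CV selection `n_repeats` times with fresh fold
#' randomisation, evaluating each selected model on the fixed held-out test
#' set, to measure the performance distribution induced by the random
#' aspects of training.
#'
#' @param x_train,y_train,x_test,y_test disjoint train/test features and
#'   labels.
#' @param n_repeats number of repetitions.
#' @param seed master seed; repeat `r` uses substream `r`.
#' @param ... passed to [inner_cv_select()].
#' @return A `metrics_distribution`: data frame `per_repeat` (accuracy,
#'   FPR, FNR, d' per repeat), list `mean`, list `se`, and the selected
#'   hyperparameters per repeat.
#' @export
evaluate_repeated <- function(x_train, y_train, x_test, y_test,
                              n_repeats = 100, seed = 1, ...) {
  rows <- vector("list", n_repeats)
  sel <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    cv <- inner_cv_select(x_train, y_train,
                          seed = derive_seed(seed, "folds", r), ...)
    pr <- predict(cv$model, x_test)
    m <- compute_metrics(pr$labels, y_test)
    rows[[r]] <- data.frame(repeat_id = r, accuracy = m$accuracy,
                            false_positive_rate = m$false_positive_rate,
                            false_negative_rate = m$false_negative_rate,
                            dprime = m$dprime)
    sel[[r]] <- c(sigma = cv$sigma, lambda = cv$lambda)
  }
  per <- do.call(rbind, rows)
  mcols <- c("accuracy", "false_positive_rate", "false_negative_rate", "dprime")
  structure(list(per_repeat = per,
                 mean = as.list(colMeans(per[mcols])),
                 se = as.list(vapply(per[mcols], stats::sd, 0) /
                                sqrt(n_repeats)),
                 selected = do.call(rbind, sel), n_repeats = n_repeats),
            class = "metrics_distribution")
}

#' @export
print.metrics_distribution <- function(x, ...) {
  cat(sprintf(paste0("<metrics_distribution> %d repeats\n",
                     "  accuracy %.1f%% (SE %.2f)  FPR %.1f%%  FNR %.1f%%  d' %.2f\n"),
              x$n_repeats, 100 * x$mean$accuracy, 100 * x$se$accuracy,
              100 * x$mean$false_positive_rate,
              100 * x$mean$false_negative_rate, x$mean$dprime))
  invisible(x)
}

#' Permutation test of decoding performance
#'
#' Retrains the full selection pipeline on label-shuffled training data
#' `n_perm` times (the strict reading: the comparator models are trained
#' with correct labels, the null models with shuffled ones), evaluating each
#' null model on the intact test set. The p-value uses the add-one
#' correction `p = (1 + #{null >= observed}) / (n_perm + 1)`, which is never
#' zero.
#'
#' @param x_train,y_train,x_test,y_test as in [evaluate_repeated()].
#' @param observed observed mean accuracy of the correctly trained models;
#'   when `NULL` it is computed from a single correct-label fit.
#' @param n_perm number of label shuffles.
#' @param seed master seed.
#' @param ... passed to [inner_cv_select()].
#' @return List: `p_value`, `null_accuracy` (length `n_perm`), `observed`.
#' @export
permutation_test <- function(x_train, y_train, x_test, y_test,
                             observed = NULL, n_perm = 100, seed = 1, ...) {
  if (is.null(observed)) {
    cv <- inner_cv_select(x_train, y_train,
                          seed = derive_seed(seed, "perm-obs"), ...)
    observed <- compute_metrics(predict(cv$model, x_test)$labels,
                                y_test)$accuracy
  }
  null_acc <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    ys <- with_seed(derive_seed(seed, "perm-shuffle", p),
                    sample(as.character(y_train)))
    cv <- inner_cv_select(x_train, ys,
                          seed = derive_seed(seed, "perm-folds", p), ...)
    null_acc[p] <- compute_metrics(predict(cv$model, x_test)$labels,
                                   y_test)$accuracy
  }
  list(p_value = (1 + sum(null_acc >= observed)) / (n_perm + 1),
       null_accuracy = null_acc, observed = observed)
}

#' Paired Wilcoxon signed-rank comparison of two conditions
#'
#' Two-sided signed-rank test on paired per-run metrics. Zero differences
#' are dropped (and counted); the null distribution is exact (full sign
#' enumeration) for up to 25 non-zero untied differences and a normal
#' approximation with continuity correction beyond.
#'
#' @param metric_a,metric_b equal-length paired numeric vectors (length
#'   >= 5 after pairing).
#' @return List: `p_value`, `statistic` (V), `n_used`, `n_zero`.
#' @export
compare_conditions <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 5)
  d <- metric_a - metric_b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero")
    return(list(p_value = 1, statistic = NA_real_,
                n_used = 0L, n_zero = n_zero))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !ties
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  list(p_value = min(1, ht$p.value), statistic = unname(ht$statistic),
       n_used = length(d), n_zero = n_zero)
}
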