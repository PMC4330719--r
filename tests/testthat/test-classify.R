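test_that("LSPC solves the regularised least-squares system exactly", {
  set.seed(2)
  x <- matrix(rnorm(12), 6, 2)
  y <- rep(c("chirp", "silent"), 3)
  m <- lspc_fit(x, y, sigma = 0.8, lambda = 0.05)
  # independent dense normal-equation solve
  G <- exp(-as.matrix(stats::dist(x))^2 / (2 * 0.8^2))
  B <- cbind(as.numeric(y == "chirp"), as.numeric(y == "silent"))
  th <- solve(crossprod(G) / 6 + diag(0.05, 6), crossprod(G, B) / 6)
  expect_lt(max(abs(m$theta - th)), 1e-8)
})

test_that("LSPC posteriors behave like probabilities and interpolate", {
  x <- matrix(c(0, 5, 0, 5), 2, 2)   # rows: (0,0) and (5,5)
  y <- c("chirp", "silent")
  m <- lspc_fit(x, y, sigma = 1, lambda = 1e-6)
  pr <- predict(m, x)
  expect_gt(pr$posteriors[1, "chirp"], 0.99)
  expect_gt(pr$posteriors[2, "silent"], 0.99)
  expect_equal(as.character(pr$labels), y)

  set.seed(3)
  xt <- matrix(rnorm(40), 20, 2)
  pt <- predict(m, xt)$posteriors
  expect_true(all(pt >= 0 & pt <= 1))
  expect_equal(rowSums(pt), rep(1, 20))

  # duplicating every training point leaves the decision function unchanged
  m2 <- lspc_fit(rbind(x, x), c(y, y), sigma = 1, lambda = 1e-6)
  expect_equal(predict(m2, xt)$labels, predict(m, xt)$labels)

  expect_error(predict(m, xt[, 1, drop = FALSE]), "dimension")
})

test_that("LSPC separates Gaussian blobs", {
  set.seed(11)
  n <- 100
  x <- rbind(matrix(rnorm(2 * n), n), matrix(rnorm(2 * n, mean = 4), n))
  y <- rep(c("chirp", "silent"), each = n)
  tr <- c(1:70, n + 1:70)
  te <- setdiff(seq_len(2 * n), tr)
  cv <- inner_cv_select(x[tr, ], y[tr], seed = 1)
  acc <- mean(predict(cv$model, x[te, ])$labels == y[te])
  expect_gt(acc, 0.95)
})

test_that("inner CV folds are stratified with the protocol counts", {
  y <- rep(c("chirp", "silent"), each = 150)
  set.seed(1)
  x <- matrix(rnorm(300 * 2), 300)
  cv <- inner_cv_select(x, y, n_folds = 10, sigma_grid = 1, lambda_grid = 0.1,
                        seed = 9)
  for (f in 1:10) {
    val <- table(y[cv$folds == f])
    expect_equal(as.vector(val), c(15, 15))
    comp <- table(y[cv$folds != f])
    expect_equal(as.vector(comp), c(135, 135))
  }
  # a one-point grid returns that point
  expect_equal(cv$sigma, 1)
  expect_equal(cv$lambda, 0.1)
  # fixed seed reproduces fold assignment and selection
  cv2 <- inner_cv_select(x, y, n_folds = 10, sigma_grid = 1,
                         lambda_grid = 0.1, seed = 9)
  expect_identical(cv$folds, cv2$folds)

  # a class too rare for the folds fails loudly
  ybad <- c("chirp", rep("silent", 29))
  expect_error(inner_cv_select(matrix(rnorm(60), 30), ybad, n_folds = 10,
                               sigma_grid = 1, lambda_grid = 0.1, seed = 1),
               "folds")
})

test_that("metrics satisfy the balanced-set identity and the d-prime oracle", {
  set.seed(21)
  n <- 80
  truth <- rep(c("chirp", "silent"), each = n)
  pred <- sample(truth)
  m <- compute_metrics(pred, truth)
  expect_equal(m$accuracy,
               1 - (m$false_positive_rate + m$false_negative_rate) / 2)
  # hit = fa = 0.5 gives d' = 0
  pred5 <- rep(c("chirp", "silent"), n)
  expect_equal(compute_metrics(pred5, truth)$dprime, 0)
  # hit 0.8, fa 0.2: d' = 2 * qnorm(0.8)
  pred8 <- c(rep("chirp", 64), rep("silent", 16),
             rep("chirp", 16), rep("silent", 64))
  expect_equal(compute_metrics(pred8, truth)$dprime, 2 * qnorm(0.8),
               tolerance = 1e-12)
  expect_equal(round(compute_metrics(pred8, truth)$dprime, 3), 1.683)
  expect_error(compute_metrics(pred5, rep("chirp", 2 * n)), "single class")
})

test_that("evaluate_repeated aggregates repeats with the textbook SE", {
  set.seed(6)
  n <- 30
  xtr <- rbind(matrix(rnorm(2 * n), n), matrix(rnorm(2 * n, 3), n))
  ytr <- rep(c("chirp", "silent"), each = n)
  xte <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 3), 10))
  yte <- rep(c("chirp", "silent"), each = 10)
  d <- evaluate_repeated(xtr, ytr, xte, yte, n_repeats = 5, seed = 2,
                         n_folds = 5, sigma_grid = c(1, 3),
                         lambda_grid = c(0.01, 0.1))
  expect_equal(nrow(d$per_repeat), 5L)
  expect_equal(d$se$accuracy, stats::sd(d$per_repeat$accuracy) / sqrt(5))
  expect_gt(d$mean$accuracy, 0.8)
  # a single repeat reduces to one selection + prediction
  d1 <- evaluate_repeated(xtr, ytr, xte, yte, n_repeats = 1, seed = 2,
                          n_folds = 5, sigma_grid = 1, lambda_grid = 0.1)
  cv <- inner_cv_select(xtr, ytr, n_folds = 5, sigma_grid = 1,
                        lambda_grid = 0.1,
                        seed = aepdecode:::derive_seed(2, "folds", 1))
  m1 <- compute_metrics(predict(cv$model, xte)$labels, yte)
  expect_equal(d1$per_repeat$accuracy, m1$accuracy)
})

test_that("permutation p-values hit their attainable bounds", {
  set.seed(31)
  n <- 10
  xtr <- matrix(rnorm(4 * n), 2 * n)
  ytr <- rep(c("chirp", "silent"), each = n)
  xte <- matrix(rnorm(2 * n), n)
  yte <- rep(c("chirp", "silent"), length.out = n)
  base <- list(n_folds = 5, sigma_grid = 1, lambda_grid = 0.1)
  # observed below every null value
  p_lo <- do.call(permutation_test,
                  c(list(xtr, ytr, xte, yte, observed = -1, n_perm = 20,
                         seed = 1), base))
  expect_equal(p_lo$p_value, 1)
  # observed above every null value
  p_hi <- do.call(permutation_test,
                  c(list(xtr, ytr, xte, yte, observed = 1.01, n_perm = 20,
                         seed = 1), base))
  expect_equal(p_hi$p_value, 1 / 21)
  expect_length(p_lo$null_accuracy, 20L)
})

test_that("the permutation null is calibrated on label-shuffled data", {
  set.seed(17)
  over <- 0
  for (sd in 1:50) {
    n <- 12
    xtr <- matrix(rnorm(4 * n), 2 * n)
    ytr <- sample(rep(c("chirp", "silent"), each = n))
    xte <- matrix(rnorm(4 * n), 2 * n)
    yte <- rep(c("chirp", "silent"), each = n)
    p <- permutation_test(xtr, ytr, xte, yte, n_perm = 40, seed = sd,
                          n_folds = 4, sigma_grid = 1, lambda_grid = 0.1)
    if (p$p_value > 0.05) over <- over + 1
  }
  expect_gte(over, 45)
})

test_that("the paired Wilcoxon matches full sign enumeration and is symmetric", {
  # distinct absolute differences so the exact path is taken
  b <- c(1, 0, 2, 0.9, 2, 3, 1.0, 2, 4.0, 5)
  a <- b + c(2.1, 1.0, -0.7, 3.3, 0.4, 5.9, 1.6, 4.2, -1.3, 2.8)
  got <- compare_conditions(a, b)
  # oracle: enumerate all 2^10 sign assignments of the signed-rank statistic
  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 10))
  v_null <- as.matrix(signs) %*% r
  p_oracle <- min(1, 2 * min(mean(v_null >= v_obs), mean(v_null <= v_obs)))
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  # all-positive distinct differences at n = 10: p = 2/1024
  expect_equal(compare_conditions(1:10 + 0.001 * (1:10)^2, rep(0, 10))$p_value,
               2 / 1024, tolerance = 1e-12)
  # symmetry and the all-zero edge case
  expect_equal(compare_conditions(a, b)$p_value,
               compare_conditions(b, a)$p_value)
  expect_warning(z <- compare_conditions(a, a), "zero")
  expect_equal(z$p_value, 1)
})
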