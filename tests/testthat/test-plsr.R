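test_that("PLS1 reproduces an exactly linear response with one component", {
  set.seed(7)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y01 <- rep(c(0L, 1L), 10)
  yc <- y01 - mean(y01)
  # column 3 carries y exactly; all other columns orthogonalized against it
  X[, 3] <- y01
  for (j in c(1, 2, 4, 5, 6)) {
    xj <- X[, j] - mean(X[, j])
    X[, j] <- xj - yc * sum(xj * yc) / sum(yc^2)
  }
  s <- tiny_set(X, label = y01)
  m <- suppressWarnings(fit_plsr(s, max_lv = 3L))
  fit1 <- ftirauth:::pls1_nipals(X, as.numeric(y01), 1L)
  yhat1 <- fit1$y_mean +
    drop(sweep(X, 2, fit1$x_mean) %*% ftirauth:::pls1_beta(fit1, 1L))
  expect_lte(rmse(as.numeric(y01), yhat1), 1e-8)
  expect_lte(m$rmse_train, 1e-8)
})

test_that("beta matches the independent Krylov-subspace closed form", {
  for (seed in 1:5) {
    set.seed(110L + seed)
    X <- matrix(rnorm(20 * 6), 20, 6)
    y <- rep(c(0L, 1L), 10)
    fit <- ftirauth:::pls1_nipals(X, as.numeric(y), 3L)
    beta <- ftirauth:::pls1_beta(fit, 3L)
    oracle <- krylov_pls1_beta(X, as.numeric(y), 3L)
    expect_equal(beta, oracle, tolerance = 1e-8,
                 label = paste("seed", seed))
  }
})

test_that("fitting is invariant to training row order", {
  s <- make_blobs(15, 12, delta = 2, sd = 1, seed = 113L)
  m <- suppressWarnings(fit_plsr(s, max_lv = 5L))
  perm <- sample(nrow(s$absorbance))
  m_perm <- suppressWarnings(fit_plsr(subset_rows(s, perm), max_lv = 5L))
  expect_equal(m_perm$beta, m$beta, tolerance = 1e-10)
})

test_that("VIP scores obey the Wold normalization identities", {
  # A = 1 with equal-magnitude weights: every VIP = 1
  m_fake <- structure(list(weights = matrix(c(1, -1, 1, -1) / 2, 4, 1),
                           s = 2.5), class = "plsr_model")
  expect_equal(vip_scores(m_fake), rep(1, 4), tolerance = 1e-12)

  # mean squared VIP = 1 for real fits
  s <- make_blobs(20, 15, delta = 2, sd = 1, seed = 127L)
  m <- suppressWarnings(fit_plsr(s, max_lv = 6L))
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)

  # planted informative band beats the noise-column VIP distribution
  wins <- 0L
  for (seed in 1:20) {
    set.seed(130L + seed)
    n <- 80; p <- 50
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[, 25] <- X[, 25] + 5 * (y - mean(y))     # SNR 5 band
    m <- suppressWarnings(fit_plsr(tiny_set(X, label = y), max_lv = 5L))
    if (m$vip[25] > quantile(m$vip[-25], 0.95)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("LV selection minimizes LOO RMSE with ties to the smallest count", {
  s <- make_blobs(15, 10, delta = 3, sd = 1, seed = 139L)
  m <- suppressWarnings(fit_plsr(s, max_lv = 6L))
  expect_equal(m$selection$rmse_loo[m$A], min(m$selection$rmse_loo))
  expect_true(all(m$selection$rmse_loo[seq_len(m$A - 1L)] >
                    m$selection$rmse_loo[m$A] - 1e-15))

  # training RMSE is non-increasing in the component count
  fit <- ftirauth:::pls1_nipals(s$absorbance, as.numeric(s$label), 6L)
  rtrain <- vapply(seq_len(fit$A), function(A) {
    beta <- ftirauth:::pls1_beta(fit, A)
    yhat <- fit$y_mean +
      drop(sweep(s$absorbance, 2, fit$x_mean) %*% beta)
    rmse(as.numeric(s$label), yhat)
  }, numeric(1L))
  expect_true(all(diff(rtrain) <= 1e-10))
})

test_that("LOO RMSE exceeds training RMSE on average over seeds", {
  diffs <- vapply(1:20, function(seed) {
    s <- make_blobs(12, 15, delta = 2, sd = 1, seed = 140L + seed)
    m <- suppressWarnings(fit_plsr(s, max_lv = 4L))
    m$rmse_loo - m$rmse_train
  }, numeric(1L))
  expect_gt(mean(diffs), 0)
})

test_that("the 0.5 threshold rule is strict and classification is shift-stable", {
  s <- make_blobs(15, 10, delta = 6, sd = 1, seed = 149L)
  m <- suppressWarnings(fit_plsr(s, max_lv = 3L))

  # yhat exactly 0.5 -> class 0 (strict >)
  fake <- m
  fake$beta <- rep(0, 10)
  fake$y_mean <- 0.5
  pr <- predict(fake, s)
  expect_true(all(pr$yhat == 0.5))
  expect_true(all(pr$label == 0L))

  # separated training data classifies itself correctly
  expect_identical(predict(m, s)$label, s$label)

  # adding a constant column leaves predictions unchanged after centering
  s_aug <- tiny_set(cbind(s$absorbance, 7), wn = 1:11, label = s$label)
  m_aug <- suppressWarnings(fit_plsr(s_aug, max_lv = 3L))
  expect_equal(predict(m_aug, s_aug)$yhat, predict(m, s)$yhat,
               tolerance = 1e-8)
})

test_that("rmse matches its closed form and rejects bad input", {
  expect_equal(rmse(c(0, 1), c(0, 1)), 0)
  expect_equal(rmse(c(0, 1), c(0.5, 0.5)), 0.5)
  set.seed(151)
  a <- rnorm(40); b <- rnorm(40)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(rmse(a, b), sqrt(acc / 40), tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:2), "mismatch")
})

test_that("beta recovers planted coefficients at high SNR", {
  cors <- vapply(1:20, function(seed) {
    set.seed(160L + seed)
    n <- 100; p <- 50
    beta_star <- numeric(p)
    beta_star[c(10, 25, 40)] <- c(1, -1.5, 0.8)
    X <- matrix(rnorm(n * p), n, p)
    signal <- drop(X %*% beta_star)
    y <- signal + rnorm(n, sd = sd(signal) / 10)   # SNR 10
    s <- tiny_set(X, label = as.integer(y > median(y)))
    s$absorbance <- X
    fit <- ftirauth:::pls1_nipals(X, y, 10L)
    cor(ftirauth:::pls1_beta(fit, fit$A), beta_star)
  }, numeric(1L))
  expect_gte(mean(cors), 0.8)
})
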