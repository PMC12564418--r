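test_that("SNV forces zero mean and unit n-1 sd on every row", {
  s <- tiny_set(rbind(c(1, 2, 3)))
  expect_equal(unname(snv(s)$absorbance[1, ]), c(-1, 0, 1))

  # idempotence
  set.seed(1)
  s2 <- tiny_set(matrix(rnorm(50 * 20, mean = 3, sd = 2), 50, 20))
  once <- snv(s2)
  expect_equal(snv(once)$absorbance, once$absorbance, tolerance = 1e-12)
  expect_true(all(abs(rowMeans(once$absorbance)) < 1e-12))
  expect_true(all(abs(apply(once$absorbance, 1, sd) - 1) < 1e-12))

  expect_error(snv(tiny_set(rbind(c(1, 1, 1), c(1, 2, 3)))), "row.*1")
})

test_that("SG derivative is exact on polynomials and matches the local-fit oracle", {
  wn <- 0:40
  s <- tiny_set(rbind(rep(5, 41), wn^2), wn = wn)

  d1 <- sg_derivative(s, order = 1L, window = 5L, polyorder = 2L)
  expect_true(all(abs(d1$absorbance[1, ]) < 1e-10))          # constant -> 0
  interior <- 3:39
  expect_equal(unname(d1$absorbance[2, interior]), 2 * wn[interior],
               tolerance = 1e-9)                             # d/dv v^2 = 2v

  d2 <- sg_derivative(s, order = 2L, window = 7L, polyorder = 3L)
  expect_equal(unname(d2$absorbance[2, 5:37]), rep(2, 33),
               tolerance = 1e-9)                             # d2/dv2 v^2 = 2

  # random spectrum vs brute-force normal-equations oracle, interior points
  set.seed(11)
  x <- rnorm(60)
  got <- sg_derivative(tiny_set(rbind(x), wn = 0:59), 1L, 7L, 3L)$absorbance[1, ]
  want <- naive_sg(x, 7L, 3L, 1L)
  idx <- which(!is.na(want))
  expect_equal(unname(got[idx]), want[idx], tolerance = 1e-9)

  # derivative honours grid spacing (AU per cm^-1)
  h2 <- sg_derivative(tiny_set(rbind((0:40) * 2), wn = seq(0, 80, 2)),
                      1L, 5L, 2L)
  expect_equal(unname(h2$absorbance[1, 10]), 1, tolerance = 1e-9)

  expect_error(sg_derivative(s, 1L, window = 6L), "odd")
  expect_error(sg_derivative(s, 2L, window = 5L, polyorder = 1L), ">=")
  expect_error(
    sg_derivative(tiny_set(rbind(rnorm(5)), wn = c(1, 2, 3, 5, 8)), 1L, 3L, 1L),
    "uniform")
})

test_that("MSC removes affine distortion and matches the OLS oracle", {
  set.seed(3)
  ref_shape <- exp(-((1:80) - 40)^2 / 200)
  train <- tiny_set(rbind(ref_shape, ref_shape * 1.2 + 0.05,
                          ref_shape * 0.8 - 0.02))
  ref <- colMeans(train$absorbance)

  # a row equal to the reference is unchanged
  probe <- tiny_set(rbind(ref, 3 + 2 * ref))
  out <- msc_fit_apply(train, probe)$corrected
  expect_equal(unname(out$absorbance[1, ]), unname(ref), tolerance = 1e-9)
  # an affinely distorted copy of the reference is restored exactly
  expect_equal(unname(out$absorbance[2, ]), unname(ref), tolerance = 1e-9)

  # slope/intercept match closed-form normal equations on random rows
  rows <- matrix(rnorm(5 * 80), 5, 80) + matrix(ref, 5, 80, byrow = TRUE)
  corr <- msc_fit_apply(train, tiny_set(rows))$corrected$absorbance
  for (i in 1:5) {
    fit <- lm(rows[i, ] ~ ref)
    a <- coef(fit)[1]; b <- coef(fit)[2]
    expect_equal(unname(corr[i, ]), unname((rows[i, ] - a) / b),
                 tolerance = 1e-9)
  }
})

test_that("detrend projects out the polynomial baseline", {
  wn <- seq(600, 1800, by = 2)
  s <- tiny_set(rbind(5 + 0.01 * wn), wn = wn)
  expect_true(all(abs(detrend(s, 1L)$absorbance) < 1e-9))

  # degree 0 is mean-centering
  set.seed(5)
  x <- rnorm(601)
  got <- detrend(tiny_set(rbind(x), wn = wn), 0L)$absorbance[1, ]
  expect_equal(unname(got), x - mean(x), tolerance = 1e-12)

  # quadratic baseline + peak: residual equals the oracle lm() residual
  peak <- exp(-(wn - 1200)^2 / 2000)
  row <- 1e-6 * (wn - 1200)^2 + 0.3 + peak
  got2 <- detrend(tiny_set(rbind(row), wn = wn), 2L)$absorbance[1, ]
  want <- resid(lm(row ~ poly(wn, 2)))
  expect_equal(unname(got2), unname(want), tolerance = 1e-9)

  expect_error(detrend(tiny_set(rbind(1:3)), 3L), "degree")
})

test_that("median filter removes spikes and matches the naive oracle at edges", {
  s <- tiny_set(rbind(c(1, 1, 9, 1, 1)))
  expect_equal(unname(median_filter(s, 5L)$absorbance[1, 3]), 1)

  mono <- tiny_set(rbind(as.numeric(1:20)))
  out <- median_filter(mono, 5L)$absorbance[1, ]
  expect_equal(unname(out[3:18]), as.numeric(3:18))   # interior unchanged

  set.seed(9)
  x <- rnorm(30)
  expect_equal(unname(median_filter(tiny_set(rbind(x)), 7L)$absorbance[1, ]),
               naive_median_filter(x, 7L), tolerance = 1e-12)

  expect_error(median_filter(s, 4L), "odd")
})

test_that("quantile normalization equalizes sorted value sets", {
  tr <- tiny_set(rbind(c(1, 2, 3), c(4, 5, 6)))
  out <- quantile_normalize(tr)$corrected$absorbance
  expect_equal(unname(out[1, ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[2, ]), c(2.5, 3.5, 4.5))

  # identical rows unchanged
  same <- tiny_set(rbind(c(2, 1, 5), c(2, 1, 5)))
  expect_equal(quantile_normalize(same)$corrected$absorbance,
               same$absorbance, tolerance = 1e-12, ignore_attr = TRUE)

  # 20 random rows share one sorted value set afterwards
  set.seed(13)
  rnd <- tiny_set(matrix(rnorm(20 * 15), 20, 15))
  post <- quantile_normalize(rnd)$corrected$absorbance
  sorted <- t(apply(post, 1, sort))
  expect_true(all(abs(sweep(sorted, 2, sorted[1, ])) < 1e-12))

  expect_error(quantile_normalize(tiny_set(rbind(1:3))), ">= 2")
})

test_that("OSC removes y-orthogonal structure and leaves y-correlated signal", {
  set.seed(21)
  n <- 40; p <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  signal_dir <- rnorm(p); signal_dir <- signal_dir / sqrt(sum(signal_dir^2))
  artifact_dir <- rnorm(p)
  artifact_dir <- artifact_dir -
    signal_dir * sum(artifact_dir * signal_dir)
  artifact_dir <- artifact_dir / sqrt(sum(artifact_dir^2))
  yc <- y - mean(y)
  artifact_coef <- rnorm(n, sd = 4)
  artifact_coef <- artifact_coef - yc * sum(artifact_coef * yc) / sum(yc^2)
  X <- outer(2 * yc, signal_dir) + outer(artifact_coef, artifact_dir) +
    matrix(rnorm(n * p, sd = 0.05), n, p)
  s <- tiny_set(X, label = y)

  res <- osc_fit_apply(s, n_components = 1L)
  # removed component scores orthogonal to y
  Xc <- sweep(X, 2, colMeans(X))
  t1 <- Xc %*% res$transform$weights[, 1]
  expect_lt(abs(sum(t1 * yc)), 1e-8 * sqrt(sum(t1^2)) * sqrt(sum(yc^2)))

  # artifact variance mostly gone, signal variance mostly kept
  corrected <- sweep(res$corrected$absorbance, 2,
                     colMeans(res$corrected$absorbance))
  var_along <- function(M, d) sum((M %*% d)^2)
  expect_lt(var_along(corrected, artifact_dir),
            0.05 * var_along(Xc, artifact_dir))
  expect_gt(var_along(corrected, signal_dir),
            0.95 * var_along(Xc, signal_dir))

  # zero components is the identity
  id <- osc_fit_apply(s, n_components = 0L)
  expect_equal(id$corrected$absorbance, s$absorbance, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("deresolve composes smoothing with differentiation and beats raw differences on noise", {
  wn <- 0:60
  const <- tiny_set(rbind(rep(2, 61)), wn = wn)
  expect_true(all(abs(deresolve(const)$absorbance) < 1e-10))

  set.seed(31)
  x <- rnorm(61)
  s <- tiny_set(rbind(x), wn = wn)
  manual <- sg_derivative(sg_smooth(s, 11L, 2L), 1L, 11L, 2L)
  expect_equal(deresolve(s, 11L, 2L)$absorbance, manual$absorbance,
               tolerance = 1e-12)

  # noisy ramp: smoothed derivative closer to the true slope than diff()
  slope <- 0.7
  mse_d <- mse_raw <- numeric(20)
  for (k in 1:20) {
    set.seed(100 + k)
    noisy <- slope * wn + rnorm(61, sd = 0.5)
    der <- deresolve(tiny_set(rbind(noisy), wn = wn))$absorbance[1, 6:56]
    mse_d[k] <- mean((der - slope)^2)
    mse_raw[k] <- mean((diff(noisy)[6:56] - slope)^2)
  }
  expect_lt(mean(mse_d), mean(mse_raw))
})

test_that("ATR correction scales columns by nu over nu_ref and inverts", {
  wn <- c(500, 1000, 2000)
  s <- tiny_set(rbind(c(1, 1, 1)), wn = wn)
  out <- atr_correct(s, 1000)
  expect_equal(unname(out$absorbance[1, ]), c(0.5, 1, 2))

  # invertible by the reciprocal axis-wise scaling
  back <- out
  back$absorbance <- sweep(out$absorbance, 2, wn / 1000, `/`)
  expect_equal(back$absorbance, s$absorbance, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(atr_correct(s, 5000), "outside")
})

test_that("SNV+detrend equals the composition and kills polynomial projections", {
  set.seed(17)
  wn <- seq(600, 1800, by = 4)
  s <- tiny_set(matrix(rnorm(8 * length(wn)), 8), wn = wn)
  combo <- snv_detrend(s, 2L)
  expect_equal(combo$absorbance, detrend(snv(s), 2L)$absorbance,
               tolerance = 1e-12)
  B <- cbind(1, poly(wn, 2))
  expect_true(all(abs(combo$absorbance %*% B) < 1e-8))
})

test_that("all eleven operators preserve matrix shape and row-local ones commute with row permutation", {
  set.seed(23)
  s <- gen_fp(fp_config(n_per_class = 5L, seed = 23L))
  specs <- preprocess_preset()
  expect_setequal(names(specs),
                  c("raw", "sg1", "sg2", "deresolve", "detrend", "median5",
                    "msc", "osc", "quantile", "snv", "snv_detrend",
                    "atr_correct"))
  for (nm in names(specs)) {
    out <- apply_pipeline(specs[[nm]], s)$train
    expect_identical(dim(out$absorbance), dim(s$absorbance),
                     label = paste("shape preserved by", nm))
  }
  perm <- sample(nrow(s$absorbance))
  for (nm in c("snv", "detrend", "sg1", "median5", "atr_correct")) {
    a <- apply_pipeline(specs[[nm]], subset_rows(s, perm))$train
    b <- subset_rows(apply_pipeline(specs[[nm]], s)$train, perm)
    expect_equal(a$absorbance, b$absorbance, tolerance = 1e-12,
                 label = paste("row-locality of", nm))
  }
})

test_that("pipelines fit stateful steps on training rows only and are order-stable", {
  s <- gen_fp(fp_config(n_per_class = 6L, seed = 29L))
  tr <- subset_rows(s, 1:24)
  te <- subset_rows(s, 25:36)

  # [raw] is the identity on both sets
  out <- apply_pipeline(list(pp_spec("raw")), tr, te)
  expect_equal(out$train$absorbance, tr$absorbance)
  expect_equal(out$test$absorbance, te$absorbance)

  # [snv, detrend] equals manual composition
  out2 <- apply_pipeline(list(pp_spec("snv"), pp_spec("detrend", degree = 1L)),
                         tr, te)
  expect_equal(out2$test$absorbance,
               detrend(snv(te), 1L)$absorbance, tolerance = 1e-12)

  # refit on a shuffled training set gives identical fitted state
  perm <- sample(24)
  for (nm in c("msc", "quantile", "osc")) {
    r1 <- apply_pipeline(list(pp_spec(nm)), tr, te)
    r2 <- apply_pipeline(list(pp_spec(nm)), subset_rows(tr, perm), te)
    expect_equal(r1$test$absorbance, r2$test$absorbance, tolerance = 1e-10,
                 label = paste("order invariance of", nm))
  }

  # held-out rows cannot influence the fitted state (sentinel probe)
  te_corrupt <- te
  te_corrupt$absorbance <- te$absorbance +
    matrix(rnorm(length(te$absorbance), sd = 100), nrow(te$absorbance))
  r1 <- apply_pipeline(list(pp_spec("msc")), tr, te)
  r2 <- apply_pipeline(list(pp_spec("msc")), tr, te_corrupt)
  expect_equal(r1$train$absorbance, r2$train$absorbance)
})
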