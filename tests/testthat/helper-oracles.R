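# Independent brute-force oracles and fixture builders used across the
# suite. Oracles are deliberately naive implementations, kept free of any
# package internals they are used to check.

# Build a spectra_set from a bare matrix.
tiny_set <- function(mat, wn = seq_len(ncol(mat)), label = NULL,
                     sample_id = NULL) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  spectra_set(mat, wn,
              sample_id = sample_id %||% sprintf("s%03d", seq_len(n)),
              replicate_id = rep(1L, n),
              label = label %||% rep(0L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two Gaussian blobs in p dimensions with class-mean separation delta on
# every coordinate of a random unit direction.
make_blobs <- function(n_per_class, p, delta, sd = 1, seed = 1L) {
  set.seed(seed)
  dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
  X0 <- matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p)
  X1 <- matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p) +
    matrix(delta * dir, n_per_class, p, byrow = TRUE)
  tiny_set(rbind(X0, X1), label = rep(c(0L, 1L), each = n_per_class))
}

# Savitzky-Golay by explicit per-window least squares (interior points).
naive_sg <- function(x, window, polyorder, order) {
  half <- (window - 1L) %/% 2L
  p <- length(x)
  out <- rep(NA_real_, p)
  z <- -half:half
  B <- outer(z, 0:polyorder, `^`)
  for (j in (half + 1L):(p - half)) {
    coef <- solve(crossprod(B), crossprod(B, x[(j - half):(j + half)]))
    out[j] <- coef[order + 1L] * factorial(order)
  }
  out
}

# Sliding median with reflect padding, naive sort-and-pick.
naive_median_filter <- function(x, width) {
  p <- length(x)
  half <- (width - 1L) %/% 2L
  xp <- c(x[(half + 1L):2L], x, x[(p - 1L):(p - half)])
  vapply(seq_len(p), function(j) {
    w <- sort(xp[j:(j + width - 1L)])
    w[half + 1L]
  }, numeric(1L))
}

# PLS1 regression coefficients via the Krylov-subspace closed form:
# beta_A = K (K' X'X K)^{-1} K' X'y with K = [s, Gs, ..., G^{A-1}s],
# G = X'X, s = X'y (centered X and y). Algebraically equal to NIPALS PLS1
# but computed by an entirely different route.
krylov_pls1_beta <- function(X, y, A) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  G <- crossprod(Xc)
  s <- crossprod(Xc, yc)
  K <- matrix(0, ncol(X), A)
  v <- s
  for (a in seq_len(A)) {
    K[, a] <- v
    v <- G %*% v
  }
  K <- qr.Q(qr(K))                     # orthonormalize for stability
  drop(K %*% solve(crossprod(K, G %*% K), crossprod(K, s)))
}

# All-pairs concordance AUC (ties count one half).
auc_pairs <- function(true, score) {
  pos <- score[true == 1L]; neg <- score[true == 0L]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Reduced ANN search grid keeping runs fast; the full default grid is
# exercised once in the pipeline smoke test.
fast_ann_cfg <- function(seed = 1L, hidden = list(32L), max_iter = 1500L)
  ann_config(hidden_layouts = hidden, max_iter = max_iter, seed = seed,
             patience = 50L, learning_rate = 5e-3)

# Small synthetic config over the fingerprint region only; generating from
# it drops the C-H stretch bands above 1800, hence the suppressed warning
# in gen_fp().
fp_config <- function(n_per_class = 10L, seed = 1L, step = 4, ...)
  synth_config(n_per_class = n_per_class, grid = c(900, 1800, step),
               seed = seed, ...)

gen_fp <- function(cfg) suppressWarnings(generate_spectra(cfg))
gen_fp_null <- function(cfg) suppressWarnings(null_dataset(cfg))
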