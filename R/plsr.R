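# PLS1 regression on the 0/1 class response: NIPALS fitting, LOO-driven
# latent-variable selection, regression coefficients, VIP scores, and the
# 0.5-threshold classification rule.

# Core NIPALS PLS1. X and y are mean-centered internally. Returns weights
# W, X-loadings P, y-loadings q, per-LV explained y-variance s_a, and the
# number of components actually extracted (may be < A when X variance is
# exhausted).
pls1_nipals <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean); yc <- y - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  q <- numeric(A); s <- numeric(A); Tm <- matrix(0, n, A)
  a <- 0L
  while (a < A) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < 1e-14) break
    p_ <- crossprod(Xc, t_) / tt
    q_ <- sum(t_ * yc) / tt
    Xc <- Xc - t_ %*% t(p_)
    yc <- yc - q_ * t_
    a <- a + 1L
    W[, a] <- w; P[, a] <- p_; q[a] <- q_
    Tm[, a] <- t_
    s[a] <- q_^2 * tt                       # y sum of squares explained by LV a
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], s = s[seq_len(a)],
       scores = Tm[, seq_len(a), drop = FALSE],
       x_mean = x_mean, y_mean = y_mean, A = a)
}

# beta for the first `A` components: W* q with W* = W (P'W)^{-1}.
pls1_beta <- function(fit, A = fit$A) {
  idx <- seq_len(A)
  W <- fit$W[, idx, drop = FALSE]; P <- fit$P[, idx, drop = FALSE]
  drop(W %*% solve(crossprod(P, W), fit$q[idx]))
}

#' Fit a PLS1 regression with LOO-driven component selection
#'
#' NIPALS PLS1 on the mean-centered spectra against the 0/1 class response.
#' For every candidate component count up to `max_lv` the leave-one-out
#' RMSE is computed by refitting on each reduced training set; the count
#' minimizing LOO RMSE is chosen (ties to the smallest count) and the final
#' model is refit on all rows. X is centered, not variance-scaled.
#'
#' @param train labeled `spectra_set`.
#' @param max_lv largest candidate component count; capped at
#'   `min(n - 1, p)`. Default 15.
#' @return An object of class `plsr_model` with `beta`, `weights`,
#'   `x_loadings`, `y_loadings`, `vip`, `A` (chosen count), `selection`
#'   (candidate counts with their LOO RMSEs), `rmse_train`, `rmse_loo`, and
#'   centering state.
#' @export
fit_plsr <- function(train, max_lv = 15L) {
  X <- train$absorbance; y <- as.numeric(train$label)
  n <- nrow(X); p <- ncol(X)
  cap <- min(n - 1L, p)
  if (max_lv > cap) {
    warning("max_lv reduced to min(n - 1, p) = ", cap, call. = FALSE)
    max_lv <- cap
  }
  full <- pls1_nipals(X, y, max_lv)
  if (full$A < max_lv)
    warning("X variance exhausted: candidate list truncated at ", full$A,
            " components", call. = FALSE)
  max_lv <- full$A
  # LOO predictions for every candidate A in one pass per fold
  press <- matrix(0, n, max_lv)
  for (i in seq_len(n)) {
    f <- pls1_nipals(X[-i, , drop = FALSE], y[-i], max_lv)
    xc <- X[i, ] - f$x_mean
    for (A in seq_len(max_lv)) {
      Aeff <- min(A, f$A)
      press[i, A] <- (y[i] - (f$y_mean + sum(xc * pls1_beta(f, Aeff))))^2
    }
  }
  rmse_loo <- sqrt(colMeans(press))
  A_best <- which.min(rmse_loo)            # which.min takes the first minimum
  beta <- pls1_beta(full, A_best)
  yhat_train <- full$y_mean + drop(sweep(X, 2L, full$x_mean) %*% beta)
  m <- structure(list(beta = beta,
                      weights = full$W[, seq_len(A_best), drop = FALSE],
                      x_loadings = full$P[, seq_len(A_best), drop = FALSE],
                      y_loadings = full$q[seq_len(A_best)],
                      s = full$s[seq_len(A_best)],
                      scores = full$scores[, seq_len(A_best), drop = FALSE],
                      x_mean = full$x_mean, y_mean = full$y_mean,
                      A = A_best,
                      wavenumbers = train$wavenumbers,
                      selection = data.frame(A = seq_len(max_lv),
                                             rmse_loo = rmse_loo),
                      rmse_train = rmse(y, yhat_train),
                      rmse_loo = rmse_loo[A_best]),
                 class = "plsr_model")
  m$vip <- vip_scores(m)
  m
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("plsr_model: ", x$A, " latent variable(s), RMSE train ",
      sprintf("%.4f", x$rmse_train), ", RMSE LOO ",
      sprintf("%.4f", x$rmse_loo), "\n", sep = "")
  invisible(x)
}

#' Variable Importance in Projection scores
#'
#' Standard Wold VIP:
#' `VIP_j = sqrt( p * sum_a (w_ja / ||w_a||)^2 s_a / sum_a s_a )`
#' where `s_a` is the y-variance explained by latent variable `a`. The
#' normalization guarantees `mean(VIP^2) = 1`, giving the usual "VIP > 1"
#' importance threshold its meaning.
#'
#' @param m a `plsr_model`.
#' @return Numeric vector of VIP scores, one per wavenumber.
#' @export
vip_scores <- function(m) {
  s <- m$s
  if (sum(s) <= 0) stop("no explained y-variance; VIP undefined",
                        call. = FALSE)
  p <- nrow(m$weights)
  Wn2 <- sweep(m$weights^2, 2L, colSums(m$weights^2), `/`)
  sqrt(p * drop(Wn2 %*% s) / sum(s))
}

#' Predict the continuous response and the 0.5-threshold class
#'
#' The binary class is coded 1 for the target class; predictions strictly
#' above 0.5 are labeled 1, all others 0.
#'
#' @param object a `plsr_model`.
#' @param newdata `spectra_set` or matrix.
#' @param ... unused.
#' @return A list with `yhat` (continuous) and `label`.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- as_matrix_input(newdata)
  if (ncol(X) != length(object$x_mean))
    stop("newdata has ", ncol(X), " variables; model expects ",
         length(object$x_mean), call. = FALSE)
  yhat <- object$y_mean +
    drop(sweep(X, 2L, object$x_mean) %*% object$beta)
  list(yhat = yhat, label = as.integer(yhat > 0.5))
}

#' Root mean squared error
#' @param y_true,y_pred equal-length numeric vectors (non-empty).
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty vectors", call. = FALSE)
  if (length(y_true) != length(y_pred))
    stop("length mismatch", call. = FALSE)
  sqrt(mean((y_true - y_pred)^2))
}

#' Export beta coefficients and VIP scores as CSV
#' @param m a `plsr_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plsr_csv <- function(m, path) {
  utils::write.csv(data.frame(wavenumber = m$wavenumbers, beta = m$beta,
                              vip = m$vip),
                   path, row.names = FALSE)
  invisible(path)
}
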