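# Hybrid discriminant classifiers: column z-scoring, then PCA or PLS1
# dimensionality reduction, then two-class LDA (pooled covariance) on the
# reduced scores.

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev < 1e-12] <- 1e-12
  list(mean = mu, sd = sdev)
}

apply_scaler <- function(sc, X) sweep(sweep(X, 2L, sc$mean), 2L, sc$sd, `/`)

# Two-class LDA with pooled within-class covariance. Ridge-regularizes a
# singular pooled covariance and warns.
fit_lda2 <- function(S, y) {
  mu0 <- colMeans(S[y == 0L, , drop = FALSE])
  mu1 <- colMeans(S[y == 1L, , drop = FALSE])
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  C0 <- stats::cov(S[y == 0L, , drop = FALSE])
  C1 <- stats::cov(S[y == 1L, , drop = FALSE])
  Sw <- ((n0 - 1L) * C0 + (n1 - 1L) * C1) / (n0 + n1 - 2L)
  Sw_inv <- tryCatch(solve(Sw), error = function(e) {
    warning("singular within-class covariance; ridge-regularizing",
            call. = FALSE)
    solve(Sw + diag(1e-8 * sum(diag(Sw)), ncol(Sw)))
  })
  list(mu0 = mu0, mu1 = mu1, Sw_inv = Sw_inv,
       w = drop(Sw_inv %*% (mu1 - mu0)),   # discriminant direction
       log_prior = log(c(n0, n1) / (n0 + n1)))
}

lda2_predict <- function(lda, S) {
  # linear discriminant scores delta_k = x' Si mu_k - mu_k' Si mu_k / 2 + log pi_k
  d0 <- drop(S %*% (lda$Sw_inv %*% lda$mu0)) -
    sum(lda$mu0 * (lda$Sw_inv %*% lda$mu0)) / 2 + lda$log_prior[1L]
  d1 <- drop(S %*% (lda$Sw_inv %*% lda$mu1)) -
    sum(lda$mu1 * (lda$Sw_inv %*% lda$mu1)) / 2 + lda$log_prior[2L]
  list(label = as.integer(d1 > d0),
       canonical = drop(sweep(S, 2L, (lda$mu0 + lda$mu1) / 2) %*% lda$w))
}

#' Fit a PCA-LDA classifier
#'
#' Columns are z-scored (training mean and n-1 standard deviation, floored
#' at 1e-12), the standardized matrix is reduced to at most 10 principal
#' components, and a two-class pooled-covariance LDA is fit on the scores.
#'
#' @param train labeled `spectra_set` with both classes present.
#' @param n_components number of principal components (<= 10 by
#'   convention); default `min(10, n - 2, p)`.
#' @return An object of class `discriminant_model` (kind `"pca_lda"`).
#' @export
fit_pca_lda <- function(train,
                        n_components = min(10L,
                                           nrow(train$absorbance) - 2L,
                                           length(train$wavenumbers))) {
  X <- train$absorbance; y <- train$label
  if (nrow(X) < n_components + 2L)
    stop("need at least n_components + 2 samples", call. = FALSE)
  sc <- fit_scaler(X)
  Z <- apply_scaler(sc, X)
  red <- fit_pca(Z, n_components)
  S <- red$scores
  lda <- fit_lda2(S, y)
  fitted_can <- lda2_predict(lda, S)$canonical
  structure(list(kind = "pca_lda", scaler = sc, reducer = red, lda = lda,
                 n_components = n_components, canonical = fitted_can,
                 wavenumbers = train$wavenumbers),
            class = "discriminant_model")
}

#' Fit a PLS-LDA classifier
#'
#' Columns are z-scored, PLS1 latent variables maximally covarying with the
#' 0/1 label are extracted (at most 10), and a two-class LDA is fit on the
#' X-scores.
#'
#' @param train labeled `spectra_set` with both classes present.
#' @param n_lv number of latent variables (<= 10 by convention); default
#'   `min(10, n - 2, p)`.
#' @return An object of class `discriminant_model` (kind `"pls_lda"`).
#' @export
fit_pls_lda <- function(train,
                        n_lv = min(10L, nrow(train$absorbance) - 2L,
                                   length(train$wavenumbers))) {
  X <- train$absorbance; y <- train$label
  sc <- fit_scaler(X)
  Z <- apply_scaler(sc, X)
  red <- pls1_nipals(Z, as.numeric(y), n_lv)
  if (red$A < 1L) stop("no usable PLS component", call. = FALSE)
  S <- red$scores
  lda <- fit_lda2(S, y)
  fitted_can <- lda2_predict(lda, S)$canonical
  structure(list(kind = "pls_lda", scaler = sc, reducer = red, lda = lda,
                 n_components = red$A, canonical = fitted_can,
                 wavenumbers = train$wavenumbers),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("discriminant_model (", x$kind, "): ", x$n_components,
      " component(s) + two-class LDA\n", sep = "")
  invisible(x)
}

reduce_scores <- function(m, Z) {
  if (m$kind == "pca_lda") sweep(Z, 2L, m$reducer$mean) %*% m$reducer$loadings
  else {
    # sequential NIPALS projection with deflation, as at fit time
    Xc <- sweep(Z, 2L, m$reducer$x_mean)
    A <- m$reducer$A
    S <- matrix(0, nrow(Z), A)
    for (a in seq_len(A)) {
      S[, a] <- Xc %*% m$reducer$W[, a]
      Xc <- Xc - S[, a] %*% t(m$reducer$P[, a])
    }
    S
  }
}

#' Predict classes and canonical scores from a discriminant model
#'
#' Applies the stored column scaler and reducer, then the LDA rule
#' (posterior argmax with training priors). The canonical score is the
#' sample's coordinate along the single discriminant axis a two-class LDA
#' admits.
#'
#' @param object a `discriminant_model`.
#' @param newdata `spectra_set` or matrix on the training wavenumber axis.
#' @param ... unused.
#' @return A list with `label` and `canonical`.
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  X <- as_matrix_input(newdata)
  if (ncol(X) != length(object$scaler$mean))
    stop("wavenumber axis mismatch: newdata has ", ncol(X),
         " columns, model expects ", length(object$scaler$mean),
         call. = FALSE)
  if (inherits(newdata, "spectra_set") &&
      !isTRUE(all.equal(newdata$wavenumbers, object$wavenumbers,
                        tolerance = 1e-9)))
    stop("wavenumber axis mismatch with the training data", call. = FALSE)
  S <- reduce_scores(object, apply_scaler(object$scaler, X))
  lda2_predict(object$lda, S)
}
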