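# PCA with Hotelling T^2 / Q-residual diagnostics. The decomposition is
# X_centered = T P' + E with orthonormal loadings P; outliers are flagged
# with the empirical mean + 3 SD rule on either statistic.

as_matrix_input <- function(x) {
  if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
}

#' Fit a principal component model
#'
#' Mean-centered SVD-based PCA with a deterministic sign convention: the
#' largest-magnitude element of every loading vector is positive. Explained
#' variance fractions are relative to the total variance of the centered
#' data.
#'
#' @param x a `spectra_set` or numeric matrix (rows = samples).
#' @param A number of components to retain, `1 <= A <= min(n - 1, p)`.
#' @return An object of class `pca_model` with elements `mean`, `loadings`
#'   (p x A, orthonormal), `scores` (n x A), `explained_variance`
#'   (per-component fraction), `score_cov` (A x A covariance of training
#'   scores), `A` and `n`.
#' @export
fit_pca <- function(x, A) {
  X <- as_matrix_input(x)
  n <- nrow(X); p <- ncol(X)
  if (A < 1L || A > min(n - 1L, p))
    stop("A must be between 1 and min(n - 1, p) = ", min(n - 1L, p),
         call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  total <- sum(sv$d^2)
  P <- sv$v[, seq_len(A), drop = FALSE]
  # sign convention: largest-|.| loading entry positive
  for (a in seq_len(A)) {
    j <- which.max(abs(P[, a]))
    if (P[j, a] < 0) P[, a] <- -P[, a]
  }
  Tm <- Xc %*% P
  ev <- sv$d[seq_len(A)]^2 / total
  structure(list(mean = mu, loadings = P, scores = Tm,
                 explained_variance = ev,
                 all_explained = sv$d^2 / total,
                 score_cov = stats::cov(Tm),
                 A = A, n = n),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model: ", x$A, " components on ", x$n, " samples x ",
      nrow(x$loadings), " variables\n", sep = "")
  cat("  explained variance (%):",
      paste(sprintf("%.1f", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project new spectra onto a PCA model
#' @param object a `pca_model`.
#' @param newdata `spectra_set` or matrix.
#' @param ... unused.
#' @return Score matrix (n x A).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  X <- as_matrix_input(newdata)
  if (ncol(X) != length(object$mean))
    stop("newdata has ", ncol(X), " variables; model expects ",
         length(object$mean), call. = FALSE)
  sweep(X, 2L, object$mean) %*% object$loadings
}

#' Hotelling T-squared leverage statistic
#'
#' `T2_i = t_i' S_t^{-1} t_i` where `t_i` is the score vector of sample i
#' and `S_t` the covariance matrix of the training scores.
#'
#' @param m a `pca_model`.
#' @param x a `spectra_set`, a matrix of spectra, or a single spectrum.
#' @return Numeric vector of T-squared values, one per row.
#' @export
hotelling_t2 <- function(m, x) {
  X <- as_matrix_input(if (is.null(dim(x)) && !inherits(x, "spectra_set"))
                         matrix(x, nrow = 1L) else x)
  Tm <- predict(m, X)
  Sinv <- tryCatch(solve(m$score_cov),
                   error = function(e)
                     stop("singular score covariance; refit with fewer ",
                          "components", call. = FALSE))
  rowSums((Tm %*% Sinv) * Tm)
}

#' Q residual (squared prediction error)
#'
#' Squared Euclidean norm of the part of a centered spectrum not captured
#' by the model: `Q_i = || x_i - x^hat_i ||^2` with `x^hat_i = t_i P'`.
#'
#' @inheritParams hotelling_t2
#' @return Numeric vector of Q residuals, one per row.
#' @export
q_residual <- function(m, x) {
  X <- as_matrix_input(if (is.null(dim(x)) && !inherits(x, "spectra_set"))
                         matrix(x, nrow = 1L) else x)
  if (ncol(X) != length(m$mean))
    stop("spectrum length ", ncol(X), " does not match model (",
         length(m$mean), ")", call. = FALSE)
  Xc <- sweep(X, 2L, m$mean)
  E <- Xc - (Xc %*% m$loadings) %*% t(m$loadings)
  rowSums(E^2)
}

# Smallest A reaching the cumulative explained-variance target, capped.
choose_components <- function(x, target = 0.95, cap = 10L) {
  X <- as_matrix_input(x)
  kmax <- min(nrow(X) - 1L, ncol(X))
  sv <- svd(sweep(X, 2L, colMeans(X)), nu = 0L, nv = 0L)
  cum <- cumsum(sv$d^2) / sum(sv$d^2)
  min(which(cum >= target - 1e-12)[1L], cap, kmax)
}

#' Flag spectral outliers with the mean + 3 SD rule
#'
#' Fits a PCA model, computes Hotelling T-squared and Q residuals for the
#' modeled samples, thresholds each statistic at its empirical mean plus
#' three (n-1) standard deviations, and flags the union. The component
#' count defaults to the smallest number reaching 95% cumulative explained
#' variance, capped at 10.
#'
#' @param s a `spectra_set` with at least 3 rows.
#' @param A component count for the outlier model; `NULL` for the default.
#' @return An object of class `outlier_report`: a list with `sample_id`,
#'   `t2`, `q`, `t2_threshold`, `q_threshold`, `flagged` (logical), `A`, and
#'   `filtered`, the `spectra_set` with flagged rows removed.
#' @export
flag_outliers <- function(s, A = NULL) {
  if (nrow(s$absorbance) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (is.null(A)) A <- choose_components(s)
  m <- fit_pca(s, A)
  t2 <- hotelling_t2(m, s)
  q <- q_residual(m, s)
  t2_thr <- mean(t2) + 3 * stats::sd(t2)
  q_thr <- mean(q) + 3 * stats::sd(q)
  flagged <- t2 > t2_thr | q > q_thr
  if (all(flagged))
    stop("every sample flagged as an outlier; data degenerate", call. = FALSE)
  structure(list(sample_id = s$sample_id, t2 = t2, q = q,
                 t2_threshold = t2_thr, q_threshold = q_thr,
                 flagged = flagged, A = A,
                 filtered = subset_rows(s, !flagged)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report: ", sum(x$flagged), " of ", length(x$flagged),
      " samples flagged (A = ", x$A, ")\n", sep = "")
  cat("  thresholds: T2 > ", format(x$t2_threshold, digits = 4),
      ", Q > ", format(x$q_threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Serialize an outlier report to CSV
#' @param x an `outlier_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outlier_csv <- function(x, path) {
  utils::write.csv(data.frame(sample_id = x$sample_id, t2 = x$t2, q = x$q,
                              flagged = x$flagged),
                   path, row.names = FALSE)
  invisible(path)
}
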