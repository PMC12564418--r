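# RBF-kernel support vector regression on the 0/1 response: exhaustive
# grid search (C x epsilon x gamma) with five-fold CV selected on R^2, and
# permutation importance over the wavenumbers. The underlying epsilon-SVR
# solver is e1071::svm; grid search, fold handling and importance are local.

#' Hyperparameter grid for RBF support vector regression
#'
#' @param cost regularization grid.
#' @param epsilon insensitive-loss grid.
#' @param gamma kernel-width options: `"scale"` (1 / (p * var(X))) and/or
#'   `"auto"` (1 / p).
#' @param cv_folds number of CV folds (>= 2).
#' @return An object of class `svr_config`.
#' @export
svr_config <- function(cost = c(0.1, 1, 10, 100),
                       epsilon = c(0.01, 0.1, 0.5, 1.0),
                       gamma = c("scale", "auto"),
                       cv_folds = 5L) {
  if (!length(cost) || !length(epsilon) || !length(gamma))
    stop("empty hyperparameter grid", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(cost = cost, epsilon = epsilon, gamma = gamma,
                 cv_folds = cv_folds),
            class = "svr_config")
}

r_squared <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / ss_tot
}

gamma_value <- function(kind, X) {
  p <- ncol(X)
  switch(kind,
         scale = 1 / (p * stats::var(as.vector(X))),
         auto = 1 / p,
         as.numeric(kind))
}

# epsilon-SVR fit that degrades gracefully: with a wide epsilon tube the
# solver can end up with zero support vectors ("empty" model, prediction
# undefined in e1071); fall back to the constant mean predictor, which is
# what the epsilon-insensitive loss implies there.
svm_fit_safe <- function(X, y, cost, epsilon, gamma) {
  fit <- tryCatch(
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
               cost = cost, epsilon = epsilon, gamma = gamma,
               scale = FALSE, fitted = FALSE),
    error = function(e) NULL)
  ok <- !is.null(fit) && tryCatch({
    stats::predict(fit, X[1L, , drop = FALSE]); TRUE
  }, error = function(e) FALSE)
  if (ok) fit else structure(list(constant = mean(y)),
                             class = "svr_constant_fit")
}

svm_predict_safe <- function(fit, X) {
  if (inherits(fit, "svr_constant_fit")) rep(fit$constant, nrow(X))
  else as.numeric(stats::predict(fit, X))
}

#' Grid-searched RBF support vector regression
#'
#' Evaluates every (cost, epsilon, gamma) cell of the grid by k-fold
#' cross-validated mean R-squared on the 0/1 response treated as
#' continuous, refits the best cell on all training rows, and reports
#' training R-squared and RMSE. Fold assignment is a seeded shuffle, so
#' results are reproducible.
#'
#' @param train labeled `spectra_set` with >= 10 rows.
#' @param cfg an [svr_config()].
#' @param seed integer seed for the fold shuffle.
#' @return An object of class `svr_model` with `best` (named list C,
#'   epsilon, gamma), `fit` (the refit regressor), `cv_table` (R-squared
#'   per grid cell), `r2_train` and `rmse_train`.
#' @export
fit_svr_grid <- function(train, cfg = svr_config(), seed = 1L) {
  X <- train$absorbance; y <- as.numeric(train$label)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 training rows", call. = FALSE)
  if (stats::var(y) == 0) warning("constant response: R^2 reported as 0",
                                  call. = FALSE)
  k <- cfg$cv_folds
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  grid <- expand.grid(cost = cfg$cost, epsilon = cfg$epsilon,
                      gamma = cfg$gamma, stringsAsFactors = FALSE)
  cv_r2 <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    gam <- gamma_value(grid$gamma[g], X)
    r2s <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- svm_fit_safe(X[tr, , drop = FALSE], y[tr], grid$cost[g],
                        grid$epsilon[g], gam)
      r2 <- r_squared(y[!tr], svm_predict_safe(m, X[!tr, , drop = FALSE]))
      if (is.na(r2)) 0 else r2
    }, numeric(1L))
    cv_r2[g] <- mean(r2s)
  }
  best <- which.max(cv_r2)
  gam <- gamma_value(grid$gamma[best], X)
  fit <- svm_fit_safe(X, y, grid$cost[best], grid$epsilon[best], gam)
  yhat <- svm_predict_safe(fit, X)
  r2_train <- r_squared(y, yhat)
  structure(list(best = list(cost = grid$cost[best],
                             epsilon = grid$epsilon[best],
                             gamma = grid$gamma[best],
                             gamma_value = gam),
                 fit = fit,
                 cv_table = cbind(grid, cv_r2 = cv_r2),
                 r2_train = if (is.na(r2_train)) 0 else r2_train,
                 rmse_train = rmse(y, yhat),
                 wavenumbers = train$wavenumbers),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat("svr_model: RBF, C=", x$best$cost, ", epsilon=", x$best$epsilon,
      ", gamma=", x$best$gamma, "; train R^2 ",
      sprintf("%.4f", x$r2_train), "\n", sep = "")
  invisible(x)
}

#' Predict the continuous response from an SVR model
#' @param object an `svr_model`.
#' @param newdata `spectra_set` or matrix.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  svm_predict_safe(object$fit, as_matrix_input(newdata))
}

#' Permutation importance of each wavenumber for an SVR model
#'
#' For every wavenumber column: the mean drop in R-squared over seeded
#' permutation repeats when that column is shuffled. Negative drops are
#' reported as-is, never clipped. The `top` (default 30) wavenumbers are
#' ranked by mean importance.
#'
#' @param model an `svr_model`.
#' @param data labeled `spectra_set` to score on.
#' @param repeats number of randomized repetitions (>= 1).
#' @param seed integer seed.
#' @param top number of top-ranked wavenumbers to report.
#' @return A list with `importance` (data.frame: wavenumber, mean, sd,
#'   rank) and `top30` (the top-ranked wavenumbers, mean-descending).
#' @export
permutation_importance <- function(model, data, repeats = 10L, seed = 1L,
                                   top = 30L) {
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  X <- data$absorbance; y <- as.numeric(data$label)
  baseline <- r_squared(y, predict(model, X))
  p <- ncol(X)
  set.seed(seed)
  drops <- matrix(0, repeats, p)
  for (r in seq_len(repeats)) {
    perm <- sample.int(nrow(X))
    for (j in seq_len(p)) {
      Xp <- X
      Xp[, j] <- X[perm, j]
      drops[r, j] <- baseline - r_squared(y, predict(model, Xp))
    }
  }
  imp_mean <- colMeans(drops)
  imp_sd <- apply(drops, 2L, stats::sd)
  ord <- order(imp_mean, decreasing = TRUE)
  rank_of <- integer(p); rank_of[ord] <- seq_len(p)
  list(importance = data.frame(wavenumber = data$wavenumbers,
                               mean = imp_mean, sd = imp_sd,
                               rank = rank_of),
       top30 = data$wavenumbers[ord[seq_len(min(top, p))]])
}
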