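# SIMCA: one PCA model per class, classification by smallest residual
# distance d_k = sqrt(Q_k) to each class model.

#' Fit a two-class SIMCA model
#'
#' Fits an independent PCA model to the rows of each class. Per-class
#' component counts default to the smallest number reaching 90% cumulative
#' class variance, capped at `cap`.
#'
#' @param train labeled `spectra_set` containing both classes, >= 3 rows
#'   per class.
#' @param components `"auto"`, a single integer used for both classes, or a
#'   named vector/list `c("0" = A0, "1" = A1)`.
#' @param cap maximum per-class component count under `"auto"`.
#' @param var_target cumulative explained-variance target under `"auto"`.
#' @return An object of class `simca_model`: per-class `pca_model`s,
#'   component counts, and each class's training residual distances (used
#'   for Coomans critical distances).
#' @export
fit_simca <- function(train, components = "auto", cap = 10L,
                      var_target = 0.90) {
  classes <- c(0L, 1L)
  rows <- lapply(classes, function(k) which(train$label == k))
  names(rows) <- classes
  for (k in classes)
    if (length(rows[[as.character(k)]]) < 3L)
      stop("class ", k, " has fewer than 3 training rows", call. = FALSE)
  pick_A <- function(Xk) {
    if (identical(components, "auto"))
      choose_components(Xk, target = var_target, cap = cap)
    else if (length(components) == 1L && is.numeric(components))
      as.integer(components)
    else as.integer(components[[as.character(k)]])
  }
  class_models <- list(); class_A <- c(); train_dist <- list()
  for (k in classes) {
    Xk <- train$absorbance[rows[[as.character(k)]], , drop = FALSE]
    A <- min(pick_A(Xk), nrow(Xk) - 1L, ncol(Xk))
    mdl <- fit_pca(Xk, A)
    class_models[[as.character(k)]] <- mdl
    class_A[as.character(k)] <- A
    train_dist[[as.character(k)]] <- sqrt(q_residual(mdl, Xk))
  }
  structure(list(class_models = class_models, class_components = class_A,
                 train_distances = train_dist),
            class = "simca_model")
}

#' @export
print.simca_model <- function(x, ...) {
  cat("simca_model: per-class PCA with",
      paste0("A(", names(x$class_components), ")=", x$class_components,
             collapse = ", "), "\n")
  invisible(x)
}

#' Classify spectra with a SIMCA model
#'
#' Each spectrum is assigned to the class whose PCA model reconstructs it
#' best, i.e. the smallest residual distance `d_k = sqrt(Q_k)`. Exact ties
#' go to class 0 with a warning.
#'
#' @param object a `simca_model`.
#' @param newdata `spectra_set` or matrix of spectra.
#' @param ... unused.
#' @return A list with `label` (integer vector) and `distances`
#'   (n x 2 matrix, columns `d0`, `d1`).
#' @export
predict.simca_model <- function(object, newdata, ...) {
  d0 <- sqrt(q_residual(object$class_models[["0"]], newdata))
  d1 <- sqrt(q_residual(object$class_models[["1"]], newdata))
  if (any(d0 == d1))
    warning(sum(d0 == d1), " tie(s) in SIMCA distances broken to class 0",
            call. = FALSE)
  list(label = as.integer(d1 < d0),
       distances = cbind(d0 = d0, d1 = d1))
}

#' Evaluate a SIMCA model on labeled data
#'
#' @param m a `simca_model`.
#' @param data labeled `spectra_set`.
#' @return A [metrics_report()] with confusion counts, accuracy,
#'   specificity and selectivity (class 1 positive).
#' @export
evaluate_simca <- function(m, data) {
  pred <- predict(m, data)
  confusion_metrics(data$label, pred$label)
}

#' Coomans coordinates and critical distances
#'
#' For every sample, the pair of residual distances to the two class models
#' (the Coomans plot axes), the true and predicted labels, and per-class
#' critical distances taken as the 95th percentile of that class's training
#' distances.
#'
#' @param m a `simca_model`.
#' @param data labeled `spectra_set`.
#' @return A list with `points` (data.frame: sample_id, d0, d1, true,
#'   predicted) and `critical` (named vector of per-class critical
#'   distances).
#' @export
coomans_coordinates <- function(m, data) {
  pred <- predict(m, data)
  # inverse-ECDF (type 1) percentile guarantees >= 95% of the training
  # distances fall at or below the critical value
  critical <- c("0" = stats::quantile(m$train_distances[["0"]], 0.95,
                                      names = FALSE, type = 1),
                "1" = stats::quantile(m$train_distances[["1"]], 0.95,
                                      names = FALSE, type = 1))
  list(points = data.frame(sample_id = data$sample_id,
                           d0 = pred$distances[, "d0"],
                           d1 = pred$distances[, "d1"],
                           true = data$label,
                           predicted = pred$label),
       critical = critical)
}

#' Export Coomans coordinates as CSV
#' @param cc result of [coomans_coordinates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coomans_csv <- function(cc, path) {
  utils::write.csv(cc$points, path, row.names = FALSE)
  invisible(path)
}
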