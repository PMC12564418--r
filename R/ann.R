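# Feed-forward multilayer perceptron classifier: ReLU hidden layers,
# softmax output, Adam optimizer, validation-loss early stopping. Written
# in-package (vectorized base R) because the candidate architectures have
# several hidden layers. Candidate (layout, max_iter) pairs are trained and
# the one with the lowest early-stopping validation loss wins.

#' Configuration for the neural-network classifier
#'
#' @param hidden_layouts list of hidden-layer size vectors; the default
#'   candidates are 50, 100, 50-20, 100-50 and 50-30-10.
#' @param max_iter vector of iteration caps to try.
#' @param learning_rate Adam step size.
#' @param validation_fraction fraction of training rows held out for early
#'   stopping.
#' @param patience iterations without validation-loss improvement (beyond
#'   `tol`) before stopping.
#' @param tol minimum loss improvement that resets the patience counter.
#' @param seed integer seed for weight init and the validation split.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(hidden_layouts = list(50L, 100L, c(50L, 20L),
                                             c(100L, 50L), c(50L, 30L, 10L)),
                       max_iter = c(1000L, 2000L, 3000L),
                       learning_rate = 1e-3,
                       validation_fraction = 0.1,
                       patience = 10L, tol = 1e-4, seed = 1L) {
  structure(list(hidden_layouts = hidden_layouts, max_iter = max_iter,
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 patience = patience, tol = tol, seed = seed),
            class = "ann_config")
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

mlp_init <- function(sizes) {
  # He initialization per layer
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L],
                                 sd = sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < L) relu(Z) else softmax_rows(Z)
  }
  acts
}

mlp_loss <- function(prob, y01) {
  p1 <- pmin(pmax(prob[, 2L], 1e-12), 1 - 1e-12)
  -mean(y01 * log(p1) + (1 - y01) * log(1 - p1))
}

# One full-batch Adam training run for a fixed layout. Returns the weights
# at the best validation loss seen.
mlp_train <- function(X, y01, hidden, max_iter, lr, val_frac, patience,
                      tol) {
  n <- nrow(X)
  n_val <- max(1L, round(val_frac * n))
  val_idx <- sample.int(n, n_val)
  Xtr <- X[-val_idx, , drop = FALSE]; ytr <- y01[-val_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y01[val_idx]
  Y <- cbind(1 - ytr, ytr)                      # one-hot targets
  sizes <- c(ncol(X), hidden, 2L)
  layers <- mlp_init(sizes)
  L <- length(layers)
  mom <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                         mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_val <- Inf; best_layers <- layers; wait <- 0L; it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    acts <- mlp_forward(layers, Xtr)
    delta <- (acts[[L + 1L]] - Y) / nrow(Xtr)   # softmax + CE gradient
    for (l in rev(seq_len(L))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
      m <- mom[[l]]
      m$mW <- b1 * m$mW + (1 - b1) * gW; m$vW <- b2 * m$vW + (1 - b2) * gW^2
      m$mb <- b1 * m$mb + (1 - b1) * gb; m$vb <- b2 * m$vb + (1 - b2) * gb^2
      mom[[l]] <- m
      corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
      layers[[l]]$W <- layers[[l]]$W -
        lr * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
      layers[[l]]$b <- layers[[l]]$b -
        lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
    }
    val_loss <- mlp_loss(mlp_forward(layers, Xval)[[L + 1L]], yval)
    if (val_loss < best_val - tol) {
      best_val <- val_loss; best_layers <- layers; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { converged <- TRUE; break }
    }
  }
  list(layers = best_layers, val_loss = best_val, iterations = it,
       converged = converged)
}

n_params <- function(hidden, p) {
  sizes <- c(p, hidden, 2L)
  sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
}

#' Fit the neural-network classifier over the architecture grid
#'
#' Features are z-scored with the training scaler, every (hidden layout,
#' iteration cap) candidate is trained with early stopping on a held-out
#' validation fraction, and the candidate with the lowest validation loss
#' is selected (ties go to the smaller network). If no candidate's early
#' stopping triggered, the best-so-far weights are returned with a
#' convergence warning flag.
#'
#' @param train labeled `spectra_set` with >= 20 rows.
#' @param cfg an [ann_config()].
#' @return An object of class `ann_model` with the selected weights,
#'   candidate table, training [confusion_metrics()] report and
#'   `converged` flag.
#' @export
fit_ann <- function(train, cfg = ann_config()) {
  X <- train$absorbance; y <- train$label
  if (nrow(X) < 20L) stop("need at least 20 training rows", call. = FALSE)
  sc <- fit_scaler(X)
  Z <- apply_scaler(sc, X)
  cand <- expand.grid(layout = seq_along(cfg$hidden_layouts),
                      max_iter = cfg$max_iter)
  results <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    set.seed(cfg$seed)          # same init/split per candidate: comparable
    results[[i]] <- mlp_train(Z, y,
                              cfg$hidden_layouts[[cand$layout[i]]],
                              cand$max_iter[i], cfg$learning_rate,
                              cfg$validation_fraction, cfg$patience,
                              cfg$tol)
  }
  val <- vapply(results, `[[`, numeric(1L), "val_loss")
  size <- vapply(cand$layout, function(l)
    n_params(cfg$hidden_layouts[[l]], ncol(Z)), numeric(1L))
  best <- order(val, size)[1L]               # ties -> smaller network
  if (!any(vapply(results, `[[`, logical(1L), "converged")))
    warning("no candidate converged before its iteration cap; ",
            "returning best-so-far weights", call. = FALSE)
  m <- structure(list(scaler = sc, layers = results[[best]]$layers,
                      hidden = cfg$hidden_layouts[[cand$layout[best]]],
                      max_iter = cand$max_iter[best],
                      candidates = cbind(cand, val_loss = val,
                                         n_params = size),
                      converged = results[[best]]$converged,
                      wavenumbers = train$wavenumbers, cfg = cfg),
                 class = "ann_model")
  m$train_metrics <- evaluate_ann(m, train)
  m
}

#' @export
print.ann_model <- function(x, ...) {
  cat("ann_model: hidden [", paste(x$hidden, collapse = "-"),
      "], max_iter ", x$max_iter,
      if (!x$converged) " (did not converge)", "\n", sep = "")
  invisible(x)
}

#' Predict class probabilities and labels from the neural network
#' @param object an `ann_model`.
#' @param newdata `spectra_set` or matrix.
#' @param ... unused.
#' @return A list with `prob` (n x 2 matrix, columns class 0/1, rows sum
#'   to 1) and `label`.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  Z <- apply_scaler(object$scaler, as_matrix_input(newdata))
  prob <- mlp_forward(object$layers, Z)[[length(object$layers) + 1L]]
  colnames(prob) <- c("0", "1")
  list(prob = prob, label = as.integer(prob[, 2L] > 0.5))
}

#' Evaluate the neural network on labeled data
#'
#' Reports the full metric suite: accuracy, precision, recall, specificity,
#' F1, misclassification percent, mean binary cross-entropy (probabilities
#' clipped at 1e-12) and AUC. AUC is `NA` on single-class data.
#'
#' @param model an `ann_model`.
#' @param data labeled `spectra_set`.
#' @return A [confusion_metrics()] report.
#' @export
evaluate_ann <- function(model, data) {
  pred <- predict(model, data)
  confusion_metrics(data$label, pred$label, prob = pred$prob[, 2L])
}

#' Region-of-importance map for the neural network
#'
#' Sliding-window block-permutation importance: for every window of
#' `window` contiguous wavenumbers the block is permuted jointly (same row
#' shuffle within a repeat) and the mean increase in log-loss over repeats
#' is assigned to the window center. The normalized map floors negative
#' drops at 0 and scales to max 1; raw values are retained.
#'
#' @param model an `ann_model`.
#' @param data labeled `spectra_set`.
#' @param window odd window width in points (<= p).
#' @param repeats permutation repeats per window.
#' @param seed integer seed.
#' @return An object of class `roi_map`: data.frame-like list with
#'   `wavenumber`, `raw_drop` and `normalized` (in [0, 1], same length as
#'   the axis), plus the window width.
#' @export
roi_mapping <- function(model, data, window = 11L, repeats = 10L,
                        seed = 1L) {
  X <- data$absorbance; y <- data$label
  p <- ncol(X)
  if (window > p) stop("window exceeds number of wavenumbers", call. = FALSE)
  half <- window %/% 2L
  base_loss <- mlp_loss(predict(model, X)$prob, y)
  set.seed(seed)
  raw <- numeric(p)
  perms <- replicate(repeats, sample.int(nrow(X)))
  for (j in seq_len(p)) {
    lo <- max(1L, j - half); hi <- min(p, j + half)
    d <- numeric(repeats)
    for (r in seq_len(repeats)) {
      Xp <- X
      Xp[, lo:hi] <- X[perms[, r], lo:hi]
      d[r] <- mlp_loss(predict(model, Xp)$prob, y) - base_loss
    }
    raw[j] <- mean(d)
  }
  pos <- pmax(raw, 0)
  normalized <- if (max(pos) > 0) pos / max(pos) else pos
  structure(list(wavenumber = data$wavenumbers, raw_drop = raw,
                 normalized = normalized, window = window),
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  peak <- x$wavenumber[which.max(x$normalized)]
  cat("roi_map: window ", x$window, " points; strongest region near ",
      format(peak), " cm^-1\n", sep = "")
  invisible(x)
}
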