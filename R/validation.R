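# Shared metric plumbing and the three validation schemes: resubstitution
# (training) accuracy, leave-one-out cross-validation, and Venetian-blinds
# excluded-row validation (every stride-th sample withheld).

#' Confusion counts and derived classification metrics
#'
#' Class 1 is the positive class. Metrics whose denominator is empty (e.g.
#' selectivity with no positives present) are reported as `NA`, never 0.
#' Selectivity is the field's synonym for sensitivity/recall.
#'
#' @param true integer vector of true labels in \{0, 1\}.
#' @param pred integer vector of predicted labels.
#' @param prob optional vector of class-1 probabilities (enables
#'   cross-entropy and AUC).
#' @param scheme optional label naming the validation scheme.
#' @return An object of class `metrics_report`: counts TP/TN/FP/FN plus
#'   accuracy, specificity, selectivity, precision, recall, F1,
#'   misclassification (percent), and, when `prob` is given, cross-entropy
#'   and AUC.
#' @export
confusion_metrics <- function(true, pred, prob = NULL, scheme = NULL) {
  stopifnot(length(true) == length(pred))
  true <- as.integer(true); pred <- as.integer(pred)
  tp <- sum(true == 1L & pred == 1L)
  tn <- sum(true == 0L & pred == 0L)
  fp <- sum(true == 0L & pred == 1L)
  fn <- sum(true == 1L & pred == 0L)
  safe_div <- function(num, den) if (den == 0L) NA_real_ else num / den
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  out <- list(TP = tp, TN = tn, FP = fp, FN = fn,
              accuracy = acc,
              specificity = safe_div(tn, tn + fp),
              selectivity = rec,
              precision = prec,
              recall = rec,
              f1 = f1,
              misclassification = 100 * (1 - acc),
              scheme = scheme)
  if (!is.null(prob)) {
    p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
    out$cross_entropy <- -mean(true * log(p) + (1 - true) * log(1 - p))
    out$auc <- auc_mann_whitney(true, prob)
  }
  structure(out, class = "metrics_report")
}

# AUC as the Mann-Whitney concordance probability (ties count 1/2).
auc_mann_whitney <- function(true, score) {
  n1 <- sum(true == 1L); n0 <- sum(true == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report", if (!is.null(x$scheme)) paste0(" [", x$scheme, "]"),
      ": TP=", x$TP, " TN=", x$TN, " FP=", x$FP, " FN=", x$FN, "\n",
      sep = "")
  cat(sprintf("  accuracy %.3f  specificity %.3f  selectivity %.3f\n",
              x$accuracy, x$specificity, x$selectivity))
  if (!is.null(x$auc))
    cat(sprintf("  F1 %.3f  cross-entropy %.4f  AUC %.3f\n",
                x$f1, x$cross_entropy, x$auc))
  invisible(x)
}

#' Venetian-blinds split
#'
#' Systematically withholds every `stride`-th sample: with the default
#' stride 3 and 0-based offset 2, rows 3, 6, 9, ... (1-based) are excluded
#' — one third of the data — and the remaining two thirds train the model.
#'
#' @param n number of samples (>= stride).
#' @param stride withhold every `stride`-th sample.
#' @param offset 0-based position within each block that is withheld.
#' @return A list with integer index vectors `train` and `excluded`
#'   (1-based, disjoint, covering `1:n`).
#' @export
venetian_split <- function(n, stride = 3L, offset = 2L) {
  if (n < stride) stop("n must be >= stride", call. = FALSE)
  if (stride < 2L) stop("stride must be >= 2", call. = FALSE)
  if (offset < 0L || offset >= stride)
    stop("offset must be in [0, stride)", call. = FALSE)
  excluded <- which((seq_len(n) - 1L) %% stride == offset)
  list(train = setdiff(seq_len(n), excluded), excluded = excluded)
}

# Dispatch helper: every model family returns labels through predict();
# regression families threshold the continuous prediction at 0.5.
predict_labels <- function(model, data) {
  pred <- predict(model, data)
  if (is.list(pred) && !is.null(pred$label)) as.integer(pred$label)
  else as.integer(as.numeric(pred) > 0.5)
}

#' Training (resubstitution) accuracy
#'
#' @param model a fitted classifier (any class with a `predict` method
#'   returning labels or a `$label` element).
#' @param data labeled `spectra_set`.
#' @return Accuracy on `data`, in percent.
#' @export
training_accuracy <- function(model, data) {
  if (nrow(data$absorbance) == 0L) stop("empty data", call. = FALSE)
  100 * mean(predict_labels(model, data) == data$label)
}

#' Leave-one-out cross-validated accuracy
#'
#' Refits the whole modeling recipe — including any stateful preprocessing
#' inside `model_factory` — once per left-out sample and predicts that
#' sample.
#'
#' @param model_factory function(`spectra_set`) returning a fitted model;
#'   the factory owns preprocessing so fitted state never sees the held-out
#'   row.
#' @param data labeled `spectra_set` (>= 3 rows).
#' @return A list with `accuracy` (percent), `predictions` (per-sample LOO
#'   labels) and `n_fits`.
#' @export
loo_accuracy <- function(model_factory, data) {
  n <- nrow(data$absorbance)
  if (n < 3L) stop("need at least 3 samples for LOO", call. = FALSE)
  preds <- integer(n)
  for (i in seq_len(n)) {
    m <- tryCatch(model_factory(subset_rows(data, -i)),
                  error = function(e)
                    stop("model fit failed on LOO fold ", i, ": ",
                         conditionMessage(e), call. = FALSE))
    preds[i] <- predict_labels(m, subset_rows(data, i))
  }
  list(accuracy = 100 * mean(preds == data$label),
       predictions = preds, n_fits = n)
}

#' Excluded-row (Venetian blinds) accuracy
#'
#' Fits on the training part of the split and evaluates on the withheld
#' part; stateful preprocessing inside `model_factory` is fit on the
#' training part only.
#'
#' @param model_factory as in [loo_accuracy()].
#' @param data labeled `spectra_set`.
#' @param stride,offset forwarded to [venetian_split()].
#' @return A list with `accuracy` (percent), `metrics` (a
#'   [confusion_metrics()] report), `predictions` and the `split`.
#' @export
excluded_accuracy <- function(model_factory, data, stride = 3L,
                              offset = 2L) {
  sp <- venetian_split(nrow(data$absorbance), stride, offset)
  m <- model_factory(subset_rows(data, sp$train))
  held <- subset_rows(data, sp$excluded)
  preds <- predict_labels(m, held)
  list(accuracy = 100 * mean(preds == held$label),
       metrics = confusion_metrics(held$label, preds, scheme = "venetian"),
       predictions = preds, split = sp)
}
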