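# Factorial experiment driver: preprocessing x region x model family x
# validation scheme, with per-cell PCA outlier rejection, emitting the
# tabular reports the workflow is summarized by (explained-variance table,
# SIMCA table, discriminant/PLSR/SVR/ANN tables).

#' The canonical eleven-transform preprocessing set
#'
#' @return Named list of [pp_spec()] lists, one entry per transform
#'   (`raw`, `sg1`, `sg2`, `deresolve`, `detrend`, `median5`, `msc`, `osc`,
#'   `quantile`, `snv`, `snv_detrend`, `atr_correct` — the raw baseline plus
#'   the eleven applied treatments).
#' @export
preprocess_preset <- function() {
  out <- lapply(pp_names, function(nm) list(pp_spec(nm)))
  names(out) <- pp_names
  out
}

#' Default region set: whole spectrum and fingerprint
#'
#' Whole spectrum 650-4000 cm^-1 with the atmospheric CO2
#' (2250-2390 cm^-1) and water-vapor (3200-3400 cm^-1) windows masked;
#' fingerprint region 600-1800 cm^-1.
#'
#' @return Named list of [region_spec()] objects.
#' @export
region_preset <- function() {
  list(whole = region_spec(include = list(c(650, 4000)),
                           exclude = list(c(2250, 2390), c(3200, 3400))),
       fingerprint = region_spec(include = list(c(600, 1800))))
}

# Deterministic fan-out of one experiment seed into per-cell seeds,
# kept below 2^31.
cell_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index * 7919) %% 2147483563) + 1L
}

# A model wrapped with its preprocessing recipe: predict() re-applies the
# training-fit preprocessing to the incoming raw spectra first.
recipe_model <- function(recipe, model) {
  structure(list(recipe = recipe, model = model), class = "recipe_model")
}

#' @export
predict.recipe_model <- function(object, newdata, ...) {
  predict(object$model, apply_recipe(object$recipe, newdata), ...)
}

make_factory <- function(specs, fit_fun) {
  function(train_raw) {
    r <- fit_recipe(specs, train_raw)
    recipe_model(r, fit_fun(r$train))
  }
}

#' Run the factorial authentication experiment
#'
#' For every (preprocessing x region) cell: averages replicates, masks the
#' region, fits the preprocessing, optionally removes PCA T2/Q outliers,
#' then fits and validates every requested model family under the requested
#' schemes, refitting stateful preprocessing inside each fold. All
#' randomness derives deterministically from `seed`.
#'
#' @param data labeled `spectra_set` (replicates allowed; they are averaged
#'   first).
#' @param preprocess named list of pipelines (lists of [pp_spec()]);
#'   default [preprocess_preset()].
#' @param regions named list of [region_spec()]; default [region_preset()].
#' @param models character subset of `c("pca", "simca", "pca_lda",
#'   "pls_lda", "plsr", "svr", "ann")`.
#' @param schemes character subset of `c("train", "loo", "venetian")`.
#' @param remove_outliers flag PCA T2/Q outliers per cell and drop them
#'   before modeling.
#' @param max_lv candidate cap for PLSR component selection.
#' @param svr_cfg an [svr_config()].
#' @param ann_cfg an [ann_config()]; the default full grid is slow — pass a
#'   reduced grid for exploratory runs.
#' @param seed integer master seed.
#' @return An object of class `experiment_result`: a list of data.frames
#'   (`pca_variance`, `simca`, `discriminant`, `plsr`, `svr`, `ann` as
#'   requested), plus `manifest` (per-cell status and seeds).
#' @export
run_experiment <- function(data,
                           preprocess = preprocess_preset(),
                           regions = region_preset(),
                           models = c("pca", "simca", "pca_lda", "pls_lda",
                                      "plsr"),
                           schemes = c("train", "loo", "venetian"),
                           remove_outliers = TRUE,
                           max_lv = 15L,
                           svr_cfg = svr_config(),
                           ann_cfg = ann_config(),
                           seed = 1L) {
  models <- match.arg(models, c("pca", "simca", "pca_lda", "pls_lda",
                                "plsr", "svr", "ann"),
                      several.ok = TRUE)
  schemes <- match.arg(schemes, c("train", "loo", "venetian"),
                       several.ok = TRUE)
  averaged <- average_replicates(data)
  rows <- list(pca_variance = list(), simca = list(), discriminant = list(),
               plsr = list(), svr = list(), ann = list())
  manifest <- list()
  idx <- 0L
  any_failed <- FALSE
  for (pp_name in names(preprocess)) for (rg_name in names(regions)) {
    idx <- idx + 1L
    cseed <- cell_seed(seed, idx)
    status <- tryCatch({
      specs <- preprocess[[pp_name]]
      base <- apply_region(averaged, regions[[rg_name]])
      proc <- fit_recipe(specs, base)$train
      n_out <- 0L
      if (remove_outliers) {
        rep_out <- flag_outliers(proc)
        n_out <- sum(rep_out$flagged)
        base <- subset_rows(base, !rep_out$flagged)
        proc <- subset_rows(proc, !rep_out$flagged)
      }
      cell <- list(preprocess = pp_name, region = rg_name)
      acc3 <- function(fit_fun) {
        fac <- make_factory(specs, fit_fun)
        m <- fac(base)
        out <- list(train = NA_real_, loo = NA_real_,
                    venetian = NA_real_, model = m)
        if ("train" %in% schemes)
          out$train <- training_accuracy(m, base)
        if ("loo" %in% schemes)
          out$loo <- loo_accuracy(fac, base)$accuracy
        if ("venetian" %in% schemes)
          out$venetian <- excluded_accuracy(fac, base)$accuracy
        out
      }
      if ("pca" %in% models) {
        pm <- fit_pca(proc, min(2L, nrow(proc$absorbance) - 1L))
        rows$pca_variance[[idx]] <- data.frame(cell,
          pc1 = 100 * pm$explained_variance[1L],
          pc2 = if (pm$A >= 2L) 100 * pm$explained_variance[2L]
                else NA_real_)
      }
      if ("simca" %in% models) {
        a <- acc3(function(tr) fit_simca(tr))
        em <- evaluate_simca(a$model$model, apply_recipe(a$model$recipe,
                                                         base))
        rows$simca[[idx]] <- data.frame(cell,
          training_accuracy = a$train / 100,
          specificity = em$specificity, selectivity = em$selectivity,
          loo_accuracy = a$loo / 100, excluded_accuracy = a$venetian / 100,
          outliers_removed = n_out)
      }
      for (dk in intersect(models, c("pca_lda", "pls_lda"))) {
        fitf <- if (dk == "pca_lda") function(tr) fit_pca_lda(tr)
                else function(tr) fit_pls_lda(tr)
        a <- acc3(fitf)
        rows$discriminant[[length(rows$discriminant) + 1L]] <-
          data.frame(cell, model = dk, training_accuracy = a$train / 100,
                     loo_accuracy = a$loo / 100,
                     excluded_accuracy = a$venetian / 100)
      }
      if ("plsr" %in% models) {
        r <- fit_recipe(specs, base)
        pm <- fit_plsr(r$train, max_lv = min(max_lv,
                                             nrow(base$absorbance) - 1L))
        yhat <- predict(pm, r$train)$yhat
        rmse_exc <- NA_real_
        if ("venetian" %in% schemes) {
          sp <- venetian_split(nrow(base$absorbance))
          rv <- fit_recipe(specs, subset_rows(base, sp$train))
          pv <- fit_plsr(rv$train, max_lv = min(max_lv,
                                                length(sp$train) - 1L))
          held <- apply_recipe(rv, subset_rows(base, sp$excluded))
          rmse_exc <- rmse(held$label, predict(pv, held)$yhat)
        }
        rows$plsr[[idx]] <- data.frame(cell,
          r2 = r_squared(base$label, yhat), lv = pm$A,
          rmse_train = pm$rmse_train, rmse_loo = pm$rmse_loo,
          rmse_excluded = rmse_exc)
      }
      if ("svr" %in% models) {
        r <- fit_recipe(specs, base)
        sm <- fit_svr_grid(r$train, svr_cfg, seed = cseed)
        rmse_exc <- NA_real_
        if ("venetian" %in% schemes) {
          sp <- venetian_split(nrow(base$absorbance))
          rv <- fit_recipe(specs, subset_rows(base, sp$train))
          sv <- fit_svr_grid(rv$train, svr_cfg, seed = cseed)
          held <- apply_recipe(rv, subset_rows(base, sp$excluded))
          rmse_exc <- rmse(held$label, predict(sv, held))
        }
        rows$svr[[idx]] <- data.frame(cell,
          r2 = sm$r2_train, rmse_train = sm$rmse_train,
          rmse_excluded = rmse_exc,
          cost = sm$best$cost, epsilon = sm$best$epsilon,
          gamma = sm$best$gamma)
      }
      if ("ann" %in% models) {
        cfg <- ann_cfg; cfg$seed <- cseed
        fac <- make_factory(specs, function(tr) fit_ann(tr, cfg))
        m <- fac(base)
        tm <- evaluate_ann(m$model, apply_recipe(m$recipe, base))
        exc <- if ("venetian" %in% schemes)
          excluded_accuracy(fac, base)$accuracy / 100 else NA_real_
        rows$ann[[idx]] <- data.frame(cell,
          accuracy = tm$accuracy, precision = tm$precision,
          recall = tm$recall, specificity = tm$specificity, f1 = tm$f1,
          misclassification = tm$misclassification,
          cross_entropy = tm$cross_entropy, auc = tm$auc,
          excluded_accuracy = exc)
      }
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    if (!identical(status, "ok")) any_failed <- TRUE
    manifest[[idx]] <- data.frame(cell_index = idx, preprocess = pp_name,
                                  region = rg_name, seed = cseed,
                                  status = status)
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  structure(list(pca_variance = bind(rows$pca_variance),
                 simca = bind(rows$simca),
                 discriminant = bind(rows$discriminant),
                 plsr = bind(rows$plsr), svr = bind(rows$svr),
                 ann = bind(rows$ann),
                 manifest = do.call(rbind, manifest),
                 seed = seed, any_failed = any_failed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result: ", nrow(x$manifest), " cells (",
      sum(x$manifest$status == "ok"), " ok), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write experiment tables as CSV files
#' @param x an `experiment_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_csv <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("pca_variance", "simca", "discriminant", "plsr", "svr",
               "ann", "manifest"))
    if (!is.null(x[[nm]]))
      utils::write.csv(x[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  invisible(dir)
}

#' Summarize an experiment: best cell per model family
#'
#' Selects, for each model family present, the cell with the highest
#' excluded-set accuracy (lowest excluded RMSE for the regression
#' families); ties are broken by fewer components then by lexical
#' preprocessing name.
#'
#' @param x an `experiment_result`.
#' @return A data.frame with one row per model family.
#' @export
report_summary <- function(x) {
  stopifnot(inherits(x, "experiment_result"))
  out <- list()
  pick <- function(df, score, comp = rep(0, nrow(df))) {
    ord <- order(-score, comp, df$preprocess)
    df[ord[1L], c("preprocess", "region"), drop = FALSE]
  }
  if (!is.null(x$simca) && nrow(x$simca)) {
    b <- pick(x$simca, x$simca$excluded_accuracy)
    out$simca <- data.frame(family = "simca", b,
      score = max(x$simca$excluded_accuracy, na.rm = TRUE))
  }
  if (!is.null(x$discriminant) && nrow(x$discriminant))
    for (dk in unique(x$discriminant$model)) {
      df <- x$discriminant[x$discriminant$model == dk, , drop = FALSE]
      out[[dk]] <- data.frame(family = dk,
        pick(df, df$excluded_accuracy),
        score = max(df$excluded_accuracy, na.rm = TRUE))
    }
  if (!is.null(x$plsr) && nrow(x$plsr)) {
    b <- pick(x$plsr, -x$plsr$rmse_excluded, x$plsr$lv)
    out$plsr <- data.frame(family = "plsr", b,
      score = -min(x$plsr$rmse_excluded, na.rm = TRUE))
  }
  if (!is.null(x$svr) && nrow(x$svr)) {
    b <- pick(x$svr, -x$svr$rmse_excluded)
    out$svr <- data.frame(family = "svr", b,
      score = -min(x$svr$rmse_excluded, na.rm = TRUE))
  }
  if (!is.null(x$ann) && nrow(x$ann)) {
    b <- pick(x$ann, x$ann$excluded_accuracy)
    out$ann <- data.frame(family = "ann", b,
      score = max(x$ann$excluded_accuracy, na.rm = TRUE))
  }
  if (!length(out)) stop("empty experiment tables", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
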