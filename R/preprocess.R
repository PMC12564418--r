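# Eleven spectral pre-processing operators. Row-local (stateless) operators
# act on one spectra_set; scatter/response-referenced operators (MSC, OSC,
# quantile normalization) are fit on a training set and applied to any set,
# so cross-validated pipelines stay leakage-free.

check_uniform_grid <- function(wn) {
  d <- diff(wn)
  h <- mean(d)
  if (any(abs(d - h) > 1e-9 * abs(h)))
    stop("wavenumber grid is not uniform (required for derivative filters)",
         call. = FALSE)
  h
}

# Split a wavenumber axis into maximal contiguous runs of uniform spacing.
# Region masking (e.g. dropping the atmospheric CO2 window) leaves gaps in
# the axis; derivative filters are applied per segment, never across a gap.
grid_segments <- function(wn) {
  if (length(wn) < 2L) return(list(seq_along(wn)))
  d <- diff(wn)
  h <- stats::median(d)
  brk <- which(abs(d - h) > 1e-9 * abs(h) + 1e-12)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(wn))
  lapply(seq_along(starts), function(i) starts[i]:ends[i])
}

# Row-wise Savitzky-Golay filtering per uniform grid segment.
rowwise_sgolay <- function(s, window, polyorder, m) {
  segs <- grid_segments(s$wavenumbers)
  short <- vapply(segs, length, integer(1L)) < window
  if (any(short))
    stop("wavenumber grid is not uniform: a contiguous segment of ",
         min(vapply(segs, length, integer(1L))), " point(s) is shorter ",
         "than the filter window (", window, ")", call. = FALSE)
  filt <- signal::sgolay(p = polyorder, n = window, m = m)
  out <- s$absorbance
  for (seg in segs) {
    h <- s$wavenumbers[seg[2L]] - s$wavenumbers[seg[1L]]
    block <- t(apply(s$absorbance[, seg, drop = FALSE], 1L,
                     function(x) signal::sgolayfilt(x, filt)))
    out[, seg] <- block / h^m
  }
  out
}

with_absorbance <- function(s, ab) {
  spectra_set(ab, s$wavenumbers, s$sample_id, s$replicate_id, s$label)
}

#' Savitzky-Golay derivative of each spectrum
#'
#' Per-row local polynomial derivative with respect to the wavenumber axis.
#' The output is scaled by the grid spacing so units are AU per cm^-1
#' (per (cm^-1)^order for higher orders). Edges use the standard
#' polynomial-fit edge rule. Defaults (window 11, polyorder 2 for the first
#' derivative) suit a 2 cm^-1 grid.
#'
#' @param s a `spectra_set`.
#' @param order derivative order, 1 or 2.
#' @param window odd filter window length (points).
#' @param polyorder local polynomial degree; must satisfy
#'   `order <= polyorder < window`.
#' @return A `spectra_set` of the same shape.
#' @details When region masking has left gaps in the axis (e.g. an excluded
#'   atmospheric window), the filter runs independently on every contiguous
#'   uniformly spaced segment; it never differentiates across a gap.
#' @export
sg_derivative <- function(s, order = 1L,
                          window = if (order == 1L) 11L else 15L,
                          polyorder = if (order == 1L) 2L else 3L) {
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (polyorder < order) stop("polyorder must be >= derivative order",
                              call. = FALSE)
  with_absorbance(s, rowwise_sgolay(s, window, polyorder, order))
}

#' Standard Normal Variate scaling
#'
#' Centers every spectrum to mean zero and scales it to unit sample standard
#' deviation (n-1 denominator), removing multiplicative scatter and
#' pathlength differences row by row.
#'
#' @param s a `spectra_set`.
#' @return A `spectra_set` of the same shape.
#' @export
snv <- function(s) {
  mu <- rowMeans(s$absorbance)
  sdev <- apply(s$absorbance, 1L, stats::sd)
  bad <- which(sdev == 0)
  if (length(bad))
    stop("constant spectrum cannot be SNV-scaled; row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  with_absorbance(s, (s$absorbance - mu) / sdev)
}

#' Multiplicative Scatter Correction
#'
#' Regresses every spectrum on a reference spectrum (ordinary least squares,
#' x = a + b * reference) and returns (x - a) / b. The reference is the
#' column-wise mean of the training set, so the transform is fit on training
#' rows and applied to any set.
#'
#' @param train `spectra_set` used to form the reference spectrum.
#' @param apply_to `spectra_set` to correct; defaults to `train`.
#' @return A list with `corrected` (a `spectra_set`) and `transform`
#'   (the fitted state, reusable via [apply_fitted()]).
#' @export
msc_fit_apply <- function(train, apply_to = train) {
  ref <- colMeans(train$absorbance)
  tr <- structure(list(name = "msc", reference = ref),
                  class = "fitted_transform")
  list(corrected = apply_fitted(tr, apply_to), transform = tr)
}

msc_apply <- function(ref, s) {
  refc <- ref - mean(ref)
  denom <- sum(refc^2)
  out <- s$absorbance
  for (i in seq_len(nrow(out))) {
    x <- out[i, ]
    b <- sum((x - mean(x)) * refc) / denom
    a <- mean(x) - b * mean(ref)
    if (abs(b) < 1e-10)
      stop("degenerate MSC fit (slope ~ 0) for row ", i, call. = FALSE)
    out[i, ] <- (x - a) / b
  }
  with_absorbance(s, out)
}

#' Polynomial detrending of each spectrum
#'
#' Subtracts, per row, the least-squares polynomial of the given degree in
#' the wavenumber. Degree 0 is mean-centering; degree 1 removes linear
#' baseline drift.
#'
#' @param s a `spectra_set`.
#' @param degree polynomial degree (>= 0, < number of columns).
#' @return A `spectra_set` of the same shape.
#' @export
detrend <- function(s, degree = 1L) {
  p <- length(s$wavenumbers)
  if (degree < 0L) stop("degree must be >= 0", call. = FALSE)
  if (degree >= p) stop("degree must be < number of wavenumbers",
                        call. = FALSE)
  # orthonormal polynomial basis over the axis; project it out of every row
  B <- cbind(rep(1 / sqrt(p), p),
             if (degree > 0L) stats::poly(s$wavenumbers, degree = degree))
  with_absorbance(s, s$absorbance - (s$absorbance %*% B) %*% t(B))
}

#' Sliding median filter
#'
#' Per-row running median with reflect padding at the edges; the classic
#' 5-point spike remover at the default width.
#'
#' @param s a `spectra_set`.
#' @param width odd window width in points.
#' @return A `spectra_set` of the same shape.
#' @export
median_filter <- function(s, width = 5L) {
  if (width %% 2L == 0L) stop("width must be odd", call. = FALSE)
  p <- length(s$wavenumbers)
  if (width > p) stop("width exceeds number of wavenumbers", call. = FALSE)
  half <- (width - 1L) %/% 2L
  pad_idx <- c(rev(seq_len(half) + 1L), seq_len(p),
               p - seq_len(half))          # reflect (no edge duplication)
  out <- t(apply(s$absorbance, 1L, function(x) {
    xp <- x[pad_idx]
    vapply(seq_len(p), function(j) stats::median(xp[j:(j + width - 1L)]),
           numeric(1L))
  }))
  with_absorbance(s, out)
}

#' Quantile normalization against a training reference distribution
#'
#' The reference distribution is the per-rank mean of the sorted training
#' rows; each applied row's values are replaced by the reference value at
#' their within-row rank (tied ranks get the average of the bracketing
#' reference values). After the transform all rows share one sorted value
#' set.
#'
#' @param train `spectra_set` defining the reference distribution (>= 2 rows).
#' @param apply_to `spectra_set` to normalize; defaults to `train`.
#' @return A list with `corrected` and `transform` as in [msc_fit_apply()].
#' @export
quantile_normalize <- function(train, apply_to = train) {
  if (nrow(train$absorbance) < 2L)
    stop("quantile normalization needs >= 2 training rows", call. = FALSE)
  ref <- rowMeans(apply(train$absorbance, 1L, sort))  # per-rank means (p values)
  tr <- structure(list(name = "quantile", reference = ref),
                  class = "fitted_transform")
  list(corrected = apply_fitted(tr, apply_to), transform = tr)
}

quantile_apply <- function(ref, s) {
  out <- t(apply(s$absorbance, 1L, function(x) {
    r <- rank(x, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  }))
  with_absorbance(s, out)
}

#' Orthogonal Signal Correction
#'
#' Iteratively removes from the spectra the dominant variance directions
#' that are orthogonal to the response: each pass takes the leading
#' principal score of X, orthogonalizes it against y, refits a weight vector
#' mapping X onto that orthogonalized score, and deflates X by the resulting
#' score/loading outer product (single-pass Wold OSC). Stored weights and
#' loadings deflate new data identically.
#'
#' @param train labeled `spectra_set` (the response is its 0/1 label).
#' @param n_components number of orthogonal components to remove (>= 0).
#' @param apply_to `spectra_set` to correct; defaults to `train`.
#' @return A list with `corrected` and `transform`; the transform stores the
#'   weight and loading vectors actually removed.
#' @export
osc_fit_apply <- function(train, n_components = 1L, apply_to = train) {
  if (n_components < 0L) stop("n_components must be >= 0", call. = FALSE)
  X <- scale(train$absorbance, center = TRUE, scale = FALSE)
  x_mean <- attr(X, "scaled:center")
  y <- train$label - mean(train$label)
  W <- NULL; P <- NULL
  k <- 0L
  while (k < n_components) {
    sv <- svd(X)
    if (sv$d[1L]^2 < 1e-12) {
      warning("OSC stopped early: only ", k, " of ", n_components,
              " components had usable variance", call. = FALSE)
      break
    }
    t_pc <- X %*% sv$v[, 1L]
    t_orth <- t_pc - y * sum(y * t_pc) / sum(y * y)   # remove y-correlated part
    keep <- sv$d > sv$d[1L] * 1e-10                   # min-norm LS: w = X^+ t
    w <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], t_orth) / sv$d[keep])
    w <- w / sqrt(sum(w^2))
    t_osc <- X %*% w
    if (sum(t_osc^2) < 1e-12) {
      warning("OSC stopped early: only ", k, " of ", n_components,
              " components had usable variance", call. = FALSE)
      break
    }
    p_osc <- crossprod(X, t_osc) / sum(t_osc^2)
    X <- X - t_osc %*% t(p_osc)
    W <- cbind(W, w); P <- cbind(P, p_osc)
    k <- k + 1L
  }
  tr <- structure(list(name = "osc", x_mean = x_mean, weights = W,
                       loadings = P, n_removed = k),
                  class = "fitted_transform")
  list(corrected = apply_fitted(tr, apply_to), transform = tr)
}

osc_apply <- function(tr, s) {
  X <- sweep(s$absorbance, 2L, tr$x_mean)
  if (!is.null(tr$weights))
    for (a in seq_len(ncol(tr$weights))) {
      t_osc <- X %*% tr$weights[, a]
      X <- X - t_osc %*% t(tr$loadings[, a])
    }
  with_absorbance(s, sweep(X, 2L, -tr$x_mean))
}

#' Derivative with smoothing ("deresolve")
#'
#' Savitzky-Golay smoothing (order-0 evaluation) followed by a
#' Savitzky-Golay first derivative: differentiation with extra noise
#' filtering.
#'
#' @inheritParams sg_derivative
#' @return A `spectra_set` of the same shape.
#' @export
deresolve <- function(s, window = 11L, polyorder = 2L) {
  smoothed <- sg_smooth(s, window, polyorder)
  sg_derivative(smoothed, order = 1L, window = window, polyorder = polyorder)
}

#' Savitzky-Golay smoothing (no differentiation)
#' @inheritParams sg_derivative
#' @return A `spectra_set` of the same shape.
#' @export
sg_smooth <- function(s, window = 11L, polyorder = 2L) {
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  with_absorbance(s, rowwise_sgolay(s, window, polyorder, 0L))
}

#' ATR penetration-depth correction
#'
#' In attenuated total reflectance the effective pathlength scales with
#' wavelength, inflating low-wavenumber bands. The correction rescales each
#' absorbance column by nu / nu_ref so band intensities are comparable to a
#' transmission-like spectrum around the reference wavenumber.
#'
#' @param s a `spectra_set`.
#' @param reference_wavenumber reference nu_ref in cm^-1; must lie within
#'   the axis range.
#' @return A `spectra_set` of the same shape.
#' @export
atr_correct <- function(s, reference_wavenumber = 1000) {
  wn <- s$wavenumbers
  if (reference_wavenumber < min(wn) || reference_wavenumber > max(wn))
    stop("reference wavenumber ", reference_wavenumber,
         " outside the axis range", call. = FALSE)
  with_absorbance(s, sweep(s$absorbance, 2L, wn / reference_wavenumber, `*`))
}

#' SNV followed by polynomial detrending
#'
#' The classic Barnes scatter correction: per-row SNV scaling, then removal
#' of a degree-2 (by default) baseline polynomial.
#'
#' @param s a `spectra_set`.
#' @param degree detrend polynomial degree.
#' @return A `spectra_set` of the same shape.
#' @export
snv_detrend <- function(s, degree = 2L) detrend(snv(s), degree)

# ---------------------------------------------------------------------------
# Pipeline plumbing

pp_names <- c("raw", "sg1", "sg2", "deresolve", "detrend", "median5",
              "msc", "osc", "quantile", "snv", "snv_detrend", "atr_correct")

#' Declare one pre-processing step
#'
#' @param name one of `"raw"`, `"sg1"`, `"sg2"`, `"deresolve"`, `"detrend"`,
#'   `"median5"`, `"msc"`, `"osc"`, `"quantile"`, `"snv"`, `"snv_detrend"`,
#'   `"atr_correct"`.
#' @param ... parameters for the operator (e.g. `window`, `polyorder`,
#'   `degree`, `width`, `n_components`, `reference_wavenumber`).
#' @return An object of class `pp_spec`.
#' @export
pp_spec <- function(name, ...) {
  name <- match.arg(name, pp_names)
  params <- list(...)
  if (name %in% c("sg1", "sg2", "deresolve")) {
    w <- params$window %||% if (name == "sg2") 15L else 11L
    po <- params$polyorder %||% if (name == "sg2") 3L else 2L
    if (w %% 2L == 0L || po >= w)
      stop("SG window must be odd and > polyorder", call. = FALSE)
  }
  if (name == "median5" && (params$width %||% 5L) %% 2L == 0L)
    stop("median width must be odd", call. = FALSE)
  if (name == "osc" && (params$n_components %||% 1L) < 1L)
    stop("osc needs n_components >= 1", call. = FALSE)
  structure(list(name = name, params = params), class = "pp_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an ordered pre-processing pipeline from YAML
#'
#' The file holds a list of `{name: ..., params: {...}}` entries.
#' @param path YAML file path.
#' @return A list of [pp_spec()] objects.
#' @export
read_pipeline_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(step)
    do.call(pp_spec, c(list(name = step$name),
                       if (is.null(step$params)) list() else step$params)))
}

#' Re-apply a fitted stateful transform to new data
#'
#' @param tr a `fitted_transform` returned by [msc_fit_apply()],
#'   [quantile_normalize()], [osc_fit_apply()] or [apply_pipeline()].
#' @param s `spectra_set` to transform.
#' @return The transformed `spectra_set`.
#' @export
apply_fitted <- function(tr, s) {
  switch(tr$name,
         msc = msc_apply(tr$reference, s),
         quantile = quantile_apply(tr$reference, s),
         osc = osc_apply(tr, s),
         stop("unknown fitted transform: ", tr$name, call. = FALSE))
}

apply_stateless <- function(spec, s) {
  pr <- spec$params
  switch(spec$name,
    raw = s,
    sg1 = sg_derivative(s, 1L, pr$window %||% 11L, pr$polyorder %||% 2L),
    sg2 = sg_derivative(s, 2L, pr$window %||% 15L, pr$polyorder %||% 3L),
    deresolve = deresolve(s, pr$window %||% 11L, pr$polyorder %||% 2L),
    detrend = detrend(s, pr$degree %||% 1L),
    median5 = median_filter(s, pr$width %||% 5L),
    snv = snv(s),
    snv_detrend = snv_detrend(s, pr$degree %||% 2L),
    atr_correct = atr_correct(s, pr$reference_wavenumber %||% 1000),
    stop("not a stateless transform: ", spec$name, call. = FALSE))
}

#' Fit an ordered pre-processing pipeline on training data
#'
#' Stateless row-local operators are applied directly; stateful operators
#' (MSC, OSC, quantile normalization) are fit on the training rows only and
#' their state stored, so re-applying the recipe to held-out data leaks no
#' information.
#'
#' @param specs list of [pp_spec()] steps, applied in order.
#' @param train training `spectra_set` (provides labels for OSC).
#' @return An object of class `pp_recipe` with `train` (the processed
#'   training set), `specs` and `fitted` (stateful transform states in
#'   pipeline order); re-apply with [apply_recipe()].
#' @export
fit_recipe <- function(specs, train) {
  if (inherits(specs, "pp_spec")) specs <- list(specs)
  fitted <- list()
  for (spec in specs) {
    if (spec$name %in% c("msc", "quantile", "osc")) {
      res <- switch(spec$name,
        msc = msc_fit_apply(train),
        quantile = quantile_normalize(train),
        osc = osc_fit_apply(train,
                            spec$params$n_components %||% 1L))
      train <- res$corrected
      fitted <- c(fitted, list(res$transform))
    } else {
      train <- apply_stateless(spec, train)
    }
  }
  structure(list(train = train, specs = specs, fitted = fitted),
            class = "pp_recipe")
}

#' Apply a fitted pre-processing recipe to new data
#'
#' @param recipe a `pp_recipe` from [fit_recipe()].
#' @param s `spectra_set` to process with the training-fit state.
#' @return The processed `spectra_set`.
#' @export
apply_recipe <- function(recipe, s) {
  i <- 0L
  for (spec in recipe$specs) {
    if (spec$name %in% c("msc", "quantile", "osc")) {
      i <- i + 1L
      s <- apply_fitted(recipe$fitted[[i]], s)
    } else s <- apply_stateless(spec, s)
  }
  s
}

#' Apply an ordered pre-processing pipeline, leakage-safe
#'
#' Convenience wrapper over [fit_recipe()] / [apply_recipe()]: fits the
#' stateful steps on `train` only and applies the whole pipeline to both
#' sets.
#'
#' @inheritParams fit_recipe
#' @param test optional `spectra_set` processed with the training-fit state.
#' @return A list with `train`, `test` (or `NULL`) and `fitted`.
#' @export
apply_pipeline <- function(specs, train, test = NULL) {
  r <- fit_recipe(specs, train)
  list(train = r$train,
       test = if (!is.null(test)) apply_recipe(r, test),
       fitted = r$fitted)
}
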