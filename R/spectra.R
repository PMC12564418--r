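#' Labeled FTIR spectra container
#'
#' A `spectra_set` holds an n x p absorbance matrix on a shared wavenumber
#' axis, together with per-row sample metadata: a sample identifier, a
#' replicate number, and a binary class label (1 = target class, e.g. local
#' origin; 0 = other). Wavenumbers are always stored ascending; descending
#' input axes are accepted and flipped on construction.
#'
#' @param absorbance numeric matrix, rows = spectra, columns = wavenumbers
#'   (absorbance units).
#' @param wavenumbers numeric vector of strictly monotonic wavenumbers
#'   (cm^-1), one per column of `absorbance`.
#' @param sample_id character vector, one id per row.
#' @param replicate_id integer vector, one replicate number per row.
#' @param label integer vector of class labels in \{0, 1\}, one per row.
#' @return An object of class `spectra_set`.
#' @examples
#' s <- spectra_set(matrix(rnorm(6), 2, 3), c(600, 602, 604),
#'                  sample_id = c("a", "b"), replicate_id = c(1L, 1L),
#'                  label = c(0L, 1L))
#' s
#' @export
spectra_set <- function(absorbance, wavenumbers, sample_id, replicate_id,
                        label) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  p <- length(wavenumbers)
  if (ncol(absorbance) != p)
    stop("absorbance has ", ncol(absorbance), " columns but ", p,
         " wavenumbers were given", call. = FALSE)
  d <- diff(wavenumbers)
  if (p > 1 && !(all(d > 0) || all(d < 0)))
    stop("wavenumbers must be strictly monotonic", call. = FALSE)
  if (p > 1 && all(d < 0)) {           # descending input: flip to ascending
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, p:1, drop = FALSE]
  }
  n <- nrow(absorbance)
  sample_id <- as.character(sample_id)
  replicate_id <- as.integer(replicate_id)
  label <- as.integer(label)
  if (length(sample_id) != n || length(replicate_id) != n ||
      length(label) != n)
    stop("metadata vectors must have one entry per spectrum", call. = FALSE)
  bad <- which(!(label %in% c(0L, 1L)))
  if (length(bad))
    stop("label must be 0 or 1; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (any(!is.finite(absorbance))) {
    idx <- which(!is.finite(absorbance), arr.ind = TRUE)[1L, ]
    stop("non-finite absorbance at row ", idx[1L], ", column ", idx[2L],
         call. = FALSE)
  }
  colnames(absorbance) <- format(wavenumbers, trim = TRUE)
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 sample_id = sample_id, replicate_id = replicate_id,
                 label = label),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set: ", nrow(x$absorbance), " spectra x ",
      length(x$wavenumbers), " wavenumbers (",
      format(min(x$wavenumbers)), "-", format(max(x$wavenumbers)),
      " cm^-1)\n", sep = "")
  cat("  samples: ", length(unique(x$sample_id)),
      "  class 1: ", sum(x$label == 1L),
      " rows, class 0: ", sum(x$label == 0L), " rows\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

# Row subset preserving all metadata.
#' Subset the rows of a spectra_set
#' @param s a `spectra_set`.
#' @param i integer or logical row index.
#' @return A `spectra_set` with the selected rows.
#' @export
subset_rows <- function(s, i) {
  spectra_set(s$absorbance[i, , drop = FALSE], s$wavenumbers,
              s$sample_id[i], s$replicate_id[i], s$label[i])
}

meta_cols <- c("sample_id", "replicate_id", "label")

#' Read a wide-format labeled spectra CSV
#'
#' Expects metadata columns `sample_id`, `replicate_id`, `label`, followed by
#' one numeric absorbance column per wavenumber, the wavenumber itself being
#' the column header. Column order of the wavenumbers may be ascending or
#' descending; the result is always stored ascending.
#'
#' @param path path to the CSV file.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(meta_cols, names(df))
  if (length(missing))
    stop("missing metadata column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  wn_names <- setdiff(names(df), meta_cols)
  wn <- suppressWarnings(as.numeric(wn_names))
  if (anyNA(wn))
    stop("non-numeric wavenumber header(s): ",
         paste(utils::head(wn_names[is.na(wn)], 3L), collapse = ", "),
         call. = FALSE)
  ab <- df[, wn_names, drop = FALSE]
  for (j in seq_along(ab)) {
    v <- suppressWarnings(as.numeric(ab[[j]]))
    bad <- which(is.na(v) & !is.na(ab[[j]]))
    if (length(bad))
      stop("non-numeric absorbance at row ", bad[1L], ", column '",
           wn_names[j], "'", call. = FALSE)
    ab[[j]] <- v
  }
  spectra_set(as.matrix(ab), wn, df$sample_id, df$replicate_id, df$label)
}

#' Write a spectra_set as a wide CSV
#'
#' Round-trips losslessly with [read_spectra_csv()] to within 1e-12 relative
#' tolerance. Wavenumbers are written ascending unless `descending = TRUE`,
#' which mirrors the common instrument-export convention.
#'
#' @param s a `spectra_set`.
#' @param path output path.
#' @param descending write columns high-to-low wavenumber.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path, descending = FALSE) {
  if (nrow(s$absorbance) == 0L || length(s$wavenumbers) == 0L)
    stop("refusing to write an empty spectra_set", call. = FALSE)
  ord <- if (descending) rev(seq_along(s$wavenumbers))
         else seq_along(s$wavenumbers)
  ab <- s$absorbance[, ord, drop = FALSE]
  df <- data.frame(sample_id = s$sample_id, replicate_id = s$replicate_id,
                   label = s$label, check.names = FALSE,
                   stringsAsFactors = FALSE)
  # full double precision so the round-trip is exact to ~1e-16
  for (j in seq_len(ncol(ab)))
    df[[format(s$wavenumbers[ord][j], trim = TRUE)]] <-
      sprintf("%.17g", ab[, j])
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Minimal reader for AFFN-encoded `##XYDATA=(X++(Y..Y))` and
#' `##XYPOINTS=(XY..XY)` records (the plain-number dialect). Compressed
#' dialects (SQZ/DIF/DUP) are rejected explicitly. The result carries no
#' label; the caller attaches metadata.
#'
#' @param path path to a JCAMP-DX file.
#' @return A list with `wavenumbers` and `absorbance` numeric vectors.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub("^##[^=]*=", "", hit[1L]))
  }
  xfac <- get_field("XFACTOR"); xfac <- if (is.na(xfac)) 1 else as.numeric(xfac)
  yfac <- get_field("YFACTOR"); yfac <- if (is.na(yfac)) 1 else as.numeric(yfac)
  npoints <- get_field("NPOINTS")
  npoints <- if (is.na(npoints)) NA_integer_ else as.integer(npoints)

  start <- grep("^##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (!length(start))
    stop("no XYDATA or XYPOINTS record in '", path, "'", call. = FALSE)
  start <- start[1L]
  is_xy_pairs <- grepl("XYPOINTS", lines[start], ignore.case = TRUE)
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start]
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  body <- lines[(start + 1L):end]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty data block in '", path, "'", call. = FALSE)
  if (any(grepl("[A-DF-Za-df-z%@J-Rj-r]", gsub("[Ee][+-]?[0-9]+", "", body))))
    stop("compressed JCAMP data (SQZ/DIF/DUP) is not supported",
         call. = FALSE)

  if (is_xy_pairs) {
    toks <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    if (anyNA(toks) || length(toks) %% 2L != 0L)
      stop("malformed XYPOINTS data in '", path, "'", call. = FALSE)
    x <- toks[seq(1L, length(toks), 2L)] * xfac
    y <- toks[seq(2L, length(toks), 2L)] * yfac
  } else {
    x <- c(); y <- c()
    for (ln in body) {
      toks <- as.numeric(unlist(strsplit(trimws(ln), "[,;[:space:]]+")))
      if (anyNA(toks) || length(toks) < 2L)
        stop("malformed XYDATA line in '", path, "'", call. = FALSE)
      x <- c(x, toks[1L] * xfac)
      y <- c(y, toks[-1L] * yfac)
    }
    # catch short reads before trying to reconstruct the x axis
    if (!is.na(npoints) && length(y) != npoints)
      stop("truncated JCAMP file: NPOINTS=", npoints, " but ", length(y),
           " values read", call. = FALSE)
    # expand X via DELTAX implied spacing (FIRSTX per line is the anchor)
    deltax <- get_field("DELTAX")
    if (is.na(deltax)) {
      if (length(x) < 2L)
        stop("cannot infer DELTAX from a single data line", call. = FALSE)
      nper <- (length(y)) / length(x)
      deltax <- (x[2L] - x[1L]) / nper
    } else deltax <- as.numeric(deltax) * xfac
    xs <- unlist(lapply(seq_along(x), function(i) {
      ni <- if (i < length(x)) round((x[i + 1L] - x[i]) / deltax)
            else length(y) - (length(x) - 1L) * round((x[2L] - x[1L]) / deltax)
      if (length(x) == 1L) ni <- length(y)
      x[i] + deltax * (seq_len(ni) - 1L)
    }))
    x <- xs
  }
  if (!is.na(npoints) && length(y) != npoints)
    stop("truncated JCAMP file: NPOINTS=", npoints, " but ", length(y),
         " values read", call. = FALSE)
  if (length(x) != length(y))
    stop("x/y length mismatch in '", path, "'", call. = FALSE)
  list(wavenumbers = x, absorbance = y)
}

#' Average replicate spectra into one row per sample
#'
#' Collapses the replicate rows of every sample to their arithmetic mean,
#' giving the row-per-sample modeling matrix. Replicates of one sample must
#' agree on the class label.
#'
#' @param s a `spectra_set`.
#' @return A `spectra_set` with one row per unique `sample_id`.
#' @export
average_replicates <- function(s) {
  ids <- s$sample_id
  lab_by_id <- tapply(s$label, ids, function(v) length(unique(v)))
  bad <- names(lab_by_id)[lab_by_id > 1L]
  if (length(bad))
    stop("replicates with conflicting labels for sample(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  f <- factor(ids, levels = unique(ids))   # keep first-appearance order
  counts <- as.vector(table(f))
  means <- rowsum(s$absorbance, f) / counts
  first <- !duplicated(f)
  spectra_set(means, s$wavenumbers, levels(f),
              rep(1L, nlevels(f)), s$label[first])
}

#' Wavenumber region specification
#'
#' Intervals are closed on both ends; bounds given in either order are
#' normalized. A column survives if it falls inside at least one include
#' interval and outside every exclude interval. Typical use: keep the
#' fingerprint region 600-1800 cm^-1 while masking atmospheric CO2
#' (2250-2390 cm^-1) and water-vapor (3200-3400 cm^-1) windows.
#'
#' @param include list of `c(low, high)` intervals to keep.
#' @param exclude list of `c(low, high)` intervals to drop.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(include, exclude = list()) {
  norm <- function(iv) {
    iv <- as.numeric(iv)
    if (length(iv) != 2L || anyNA(iv))
      stop("each interval must be c(low, high)", call. = FALSE)
    sort(iv)
  }
  if (is.numeric(include)) include <- list(include)
  if (is.numeric(exclude)) exclude <- list(exclude)
  structure(list(include = lapply(include, norm),
                 exclude = lapply(exclude, norm)),
            class = "region_spec")
}

#' Read a region_spec from a YAML file
#'
#' The file holds `include` and (optionally) `exclude` lists of
#' `[low, high]` pairs.
#'
#' @param path YAML file path.
#' @return A [region_spec()].
#' @export
read_region_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  region_spec(include = cfg$include,
              exclude = if (is.null(cfg$exclude)) list() else cfg$exclude)
}

#' Mask a spectra_set to a wavenumber region
#'
#' @param s a `spectra_set`.
#' @param region a [region_spec()].
#' @return A `spectra_set` restricted to the surviving columns.
#' @export
apply_region <- function(s, region) {
  stopifnot(inherits(region, "region_spec"))
  wn <- s$wavenumbers
  inside <- function(iv) wn >= iv[1L] & wn <= iv[2L]
  keep <- Reduce(`|`, lapply(region$include, inside), rep(FALSE, length(wn)))
  if (length(region$exclude))
    keep <- keep & !Reduce(`|`, lapply(region$exclude, inside),
                           rep(FALSE, length(wn)))
  if (!any(keep))
    stop("region selection leaves no wavenumber columns", call. = FALSE)
  spectra_set(s$absorbance[, keep, drop = FALSE], wn[keep],
              s$sample_id, s$replicate_id, s$label)
}
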