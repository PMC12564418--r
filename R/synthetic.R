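# Two-class synthetic FTIR spectrum generator. Emulates the structure the
# chemometric workflow assumes: Gaussian absorption bands at the canonical
# meat-tissue positions with class-specific intensity effects, per-sample
# linear baseline drift, multiplicative scatter, per-replicate additive
# noise and smooth baseline wiggle, three replicates per sample.

#' Default absorption-band library for meat-like spectra
#'
#' Gaussian band positions covering the lipid C-H stretch region
#' (2850-2955 cm^-1), the protein Amide I/II/III bands (1650, 1540,
#' 1450/1240 cm^-1), lipid scissoring and fatty-acid bands, phospholipid
#' P=O (1080 cm^-1) and carbohydrate/collagen C-O bands (1030, 970,
#' 920 cm^-1). `class_effect` multiplies the amplitude for class 1 (the
#' target origin): lipid-associated bands run stronger in class 1,
#' carbohydrate/collagen bands stronger in class 0, Amide I is shared.
#'
#' @param effect multiplicative intensity effect applied to the
#'   class-discriminating bands (class-1-stronger bands get `effect`,
#'   class-0-stronger bands get `1/effect`).
#' @return A data.frame with columns `center`, `width`, `base_amplitude`,
#'   `class_effect`.
#' @export
peak_library <- function(effect = 1.15) {
  slight <- 1 + (effect - 1) / 3
  data.frame(
    center         = c(2955, 2920, 2850, 1650, 1540, 1450, 1400,
                       1330, 1240, 1080, 1030, 970, 920),
    width          = c(18, 16, 18, 28, 24, 16, 14, 12, 18, 20, 16, 12, 10),
    base_amplitude = c(0.55, 0.60, 0.35, 1.00, 0.55, 0.30, 0.40,
                       0.10, 0.35, 0.30, 0.20, 0.12, 0.08),
    class_effect   = c(effect, slight, effect, 1, effect, 1 / slight,
                       effect, 1, 1 / slight, slight, 1 / effect,
                       1 / slight, 1 / effect))
}

#' Configuration for the synthetic spectrum generator
#'
#' @param n_per_class samples per class (>= 3).
#' @param replicates replicate spectra per sample.
#' @param grid `c(low, high, step)` wavenumber grid in cm^-1.
#' @param peaks a [peak_library()]-style data.frame.
#' @param baseline_offset_sd SD of the per-sample constant baseline (AU).
#' @param baseline_slope_sd SD of the per-sample linear drift (AU per
#'   cm^-1).
#' @param scatter_sd SD (log scale) of the per-sample multiplicative
#'   scatter factor.
#' @param noise_sd SD of per-replicate additive white noise (AU).
#' @param replicate_jitter_sd amplitude of the per-replicate smooth
#'   baseline wiggle (AU).
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 40L, replicates = 3L,
                         grid = c(600, 4000, 2), peaks = peak_library(),
                         baseline_offset_sd = 0.02,
                         baseline_slope_sd = 5e-6,
                         scatter_sd = 0.05, noise_sd = 0.005,
                         replicate_jitter_sd = 0.002, seed = 1L) {
  if (n_per_class < 3L) stop("n_per_class must be >= 3", call. = FALSE)
  if (grid[3L] <= 0) stop("grid step must be > 0", call. = FALSE)
  if (noise_sd < 0 || replicate_jitter_sd < 0)
    stop("noise and jitter SDs must be >= 0", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 replicates = as.integer(replicates), grid = grid,
                 peaks = peaks, baseline_offset_sd = baseline_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 scatter_sd = scatter_sd, noise_sd = noise_sd,
                 replicate_jitter_sd = replicate_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a two-class synthetic FTIR dataset
#'
#' Every sample is a sum of Gaussian bands (class-1 amplitudes multiplied
#' by each band's `class_effect`), plus a per-sample linear baseline and a
#' lognormal multiplicative scatter factor; every replicate adds white
#' noise and a smooth low-frequency wiggle. Labels are balanced and the
#' output is bitwise-reproducible from the seed.
#'
#' @param cfg a [synth_config()].
#' @return A labeled `spectra_set` with
#'   `2 * n_per_class * replicates` rows.
#' @export
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  wn <- seq(cfg$grid[1L], cfg$grid[2L], by = cfg$grid[3L])
  p <- length(wn)
  peaks <- cfg$peaks
  outside <- peaks$center < min(wn) | peaks$center > max(wn)
  if (any(outside)) {
    warning(sum(outside), " peak(s) outside the grid skipped",
            call. = FALSE)
    peaks <- peaks[!outside, , drop = FALSE]
  }
  # band shapes, one column per peak
  shapes <- vapply(seq_len(nrow(peaks)), function(i)
    exp(-0.5 * ((wn - peaks$center[i]) / peaks$width[i])^2), numeric(p))
  wn_scaled <- wn - mean(wn)
  n_rows <- 2L * cfg$n_per_class * cfg$replicates
  ab <- matrix(0, n_rows, p)
  sample_id <- character(n_rows); replicate_id <- integer(n_rows)
  label <- integer(n_rows)
  row <- 0L
  for (k in 0:1) {
    amp <- peaks$base_amplitude * if (k == 1L) peaks$class_effect else 1
    clean <- drop(shapes %*% amp)
    for (i in seq_len(cfg$n_per_class)) {
      baseline <- stats::rnorm(1L, sd = cfg$baseline_offset_sd) +
        stats::rnorm(1L, sd = cfg$baseline_slope_sd) * wn_scaled
      scatter <- exp(stats::rnorm(1L, sd = cfg$scatter_sd))
      for (r in seq_len(cfg$replicates)) {
        wiggle <- smooth_wiggle(wn, cfg$replicate_jitter_sd)
        row <- row + 1L
        ab[row, ] <- scatter * clean + baseline + wiggle +
          stats::rnorm(p, sd = cfg$noise_sd)
        sample_id[row] <- sprintf("c%d_s%03d", k, i)
        replicate_id[row] <- r
        label[row] <- k
      }
    }
  }
  spectra_set(ab, wn, sample_id, replicate_id, label)
}

# Smooth random baseline wiggle: a few low-frequency sinusoids with random
# phase, scaled so the pointwise SD is ~amp.
smooth_wiggle <- function(wn, amp) {
  if (amp == 0) return(numeric(length(wn)))
  span <- diff(range(wn))
  x <- (wn - min(wn)) / span
  w <- numeric(length(wn))
  for (f in 1:3)
    w <- w + stats::rnorm(1L) * sin(2 * pi * (f * x + stats::runif(1L)))
  amp * w / sqrt(3 / 2)                     # sinusoid variance is 1/2
}

#' Generate a null (no class signal) synthetic dataset
#'
#' Identical to [generate_spectra()] with every band's class effect forced
#' to 1, so the labels carry no information: the calibration bed for
#' type-I-error-style checks of every classifier.
#'
#' @param cfg a [synth_config()].
#' @return A labeled `spectra_set` whose labels are uninformative.
#' @export
null_dataset <- function(cfg) {
  cfg$peaks$class_effect <- 1
  generate_spectra(cfg)
}
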