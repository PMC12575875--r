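# Quantitative evaluation of reconstructions: synthetic-aperture redundancy
# maps, PSNR against ground truth, circularly averaged power spectra and
# reflection I/sigma scores.

#' Per-frequency redundancy of the synthetic aperture
#'
#' Counts, at every object frequency q of the grid, how many illuminations
#' (axial and tilted) transfer information there: a tilt with wavevector
#' k_tau covers q when |w'(q, k_tau)| >= threshold (envelope mode), or when
#' |q + k_tau| <= aperture radius (binary-disc mode, a purely geometric
#' model useful for testing). Only frequencies measured at least twice
#' (redundancy >= 2) determine the complex wavefunction; the usable
#' synthetic aperture is the redundancy >= 2 region.
#'
#' @param system An [optical_system()].
#' @param tilts List of [beam_tilt()] (one per illumination; include a
#'   zero-magnitude tilt for the axial image).
#' @param grid A [frequency_grid()] of object frequencies.
#' @param threshold Transfer fraction in (0, 1] defining coverage
#'   (default `system$transfer_threshold`, conventionally 0.10).
#' @param mode `"envelope"` (full effective transfer) or `"disc"` (hard
#'   discs of radius `aperture_kmax`).
#' @param aperture_kmax Disc radius in 1/nm for `"disc"` mode (defaults to
#'   `system$aperture_kmax`).
#' @return Object of class `redundancy_map`: integer matrix `counts` on the
#'   grid, plus `threshold`, `mode`, `tilts`.
#' @export
redundancy_map <- function(system, tilts, grid,
                           threshold = system$transfer_threshold,
                           mode = c("envelope", "disc"),
                           aperture_kmax = system$aperture_kmax) {
  mode <- match.arg(mode)
  stopifnot(inherits(system, "optical_system"), inherits(grid, "frequency_grid"))
  if (length(tilts) == 0L) stop("empty tilt list", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]", call. = FALSE)
  counts <- matrix(0L, grid$shape[1], grid$shape[2])
  for (tl in tilts) {
    covered <- if (mode == "disc") {
      if (is.null(aperture_kmax)) stop("disc mode needs `aperture_kmax`", call. = FALSE)
      (grid$kx + tl$k_tau[1])^2 + (grid$ky + tl$k_tau[2])^2 <= aperture_kmax^2
    } else {
      # a tilt only measures image frequencies the detector samples, so
      # envelope coverage is capped at the recording Nyquist |q + k_tau|
      nyq <- 1 / (2 * grid$pixel_size)
      in_band <- (grid$kx + tl$k_tau[1])^2 + (grid$ky + tl$k_tau[2])^2 <= nyq^2
      (Mod(effective_wtf(grid, system, tl)) >= threshold) & in_band
    }
    counts <- counts + covered
  }
  structure(list(counts = counts, threshold = threshold, mode = mode,
                 tilts = tilts, grid = grid),
            class = "redundancy_map")
}

#' Mask of frequencies with at least `min_count` measurements
#'
#' @param map A [redundancy_map()].
#' @param min_count Minimum redundancy (default 2, the reconstructable
#'   aperture).
#' @return Logical matrix on the map's grid.
#' @export
redundancy_mask <- function(map, min_count = 2L) {
  stopifnot(inherits(map, "redundancy_map"))
  map$counts >= min_count
}

#' Band-limit a real field to a frequency mask
#'
#' Zeroes all Fourier components outside `mask` (given in the unshifted
#' grid layout) and returns the real part of the inverse transform. Used to
#' compare reconstructed and true phases over the same synthetic aperture.
#'
#' @param field Real matrix.
#' @param mask Logical matrix of the same shape, unshifted FFT layout.
#' @return Real matrix.
#' @export
mask_filter <- function(field, mask) {
  stopifnot(all(dim(field) == dim(mask)))
  Re(ifft2(fft2(field) * (mask * 1)))
}

#' Peak signal-to-noise ratio of a reconstructed phase
#'
#' PSNR = 10 log10(P^2 / MSE) with P the dynamic range (max - min) of the
#' ground-truth phase. Phase retrieval carries a global phase gauge, so the
#' mean difference between the two fields is removed before the MSE. For a
#' perfect reconstruction the PSNR is unbounded; it is capped at `cap` dB.
#'
#' @param reconstructed Real matrix (phase, radians).
#' @param truth Real matrix, same shape, non-constant.
#' @param peak `"range"` (default, max - min of truth) or `"max"`.
#' @param cap Sentinel for a zero-MSE match (default 300 dB).
#' @return PSNR in dB.
#' @export
psnr <- function(reconstructed, truth, peak = c("range", "max"), cap = 300) {
  peak <- match.arg(peak)
  stopifnot(all(dim(reconstructed) == dim(truth)))
  p <- if (peak == "range") diff(range(truth)) else max(truth)
  if (p == 0) stop("ground truth has zero dynamic range", call. = FALSE)
  d <- reconstructed - truth
  d <- d - mean(d)
  mse <- mean(d^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(p^2 / mse))
}

#' Circularly averaged radial profile
#'
#' Mean of a 2-D field over annular frequency bins of width one frequency
#' step. Optionally normalizes the profile to its value at a named
#' frequency (e.g. the strongest reflection).
#'
#' @param field Real matrix (e.g. a power spectrum, unshifted layout
#'   matching `grid`).
#' @param grid A [frequency_grid()] of the same shape.
#' @param normalize_at Optional frequency (1/nm); the profile is divided by
#'   its value in the bin containing it.
#' @return Object of class `radial_profile`: `k` (bin centres, 1/nm),
#'   `value` (bin means), `count` (grid points per bin).
#' @export
circular_average <- function(field, grid, normalize_at = NULL) {
  stopifnot(inherits(grid, "frequency_grid"), all(dim(field) == grid$shape))
  dk <- 1 / (min(grid$shape) * grid$pixel_size)
  bin <- floor(as.vector(grid$kr) / dk)
  sums <- tapply(as.vector(field), bin, sum)
  cnts <- tapply(rep(1, length(bin)), bin, sum)
  k <- (as.numeric(names(sums)) + 0.5) * dk
  value <- as.numeric(sums / cnts)
  if (!is.null(normalize_at)) {
    i <- which.min(abs(k - normalize_at))
    if (value[i] == 0) stop("normalization bin has zero value", call. = FALSE)
    value <- value / value[i]
  }
  structure(list(k = k, value = value, count = as.numeric(cnts)),
            class = "radial_profile")
}

#' Reflection detectability score I/sigma
#'
#' Scores a Bragg reflection in a power spectrum: I is the mean intensity
#' inside a disc around the peak minus the mean of a surrounding background
#' annulus, and sigma is the standard deviation of that annulus.
#'
#' @param spectrum Real matrix (power spectrum, unshifted layout matching
#'   `grid`).
#' @param grid A [frequency_grid()].
#' @param peak Length-2 frequency vector (kx, ky) of the reflection, 1/nm.
#' @param peak_radius Disc radius around the peak, 1/nm.
#' @param bg_radii Length-2 inner/outer radii of the background annulus,
#'   1/nm; the annulus must enclose and exclude the peak disc.
#' @return Object of class `reflection_score`: `peak`, `intensity`
#'   (background-subtracted), `background_sd`, `i_over_sigma`.
#' @export
reflection_i_over_sigma <- function(spectrum, grid, peak, peak_radius, bg_radii) {
  stopifnot(inherits(grid, "frequency_grid"), all(dim(spectrum) == grid$shape),
            length(peak) == 2L, length(bg_radii) == 2L)
  if (bg_radii[1] < peak_radius || bg_radii[2] <= bg_radii[1]) {
    stop("background annulus must enclose and exclude the peak disc", call. = FALSE)
  }
  d2 <- (grid$kx - peak[1])^2 + (grid$ky - peak[2])^2
  in_peak <- d2 <= peak_radius^2
  in_bg <- d2 >= bg_radii[1]^2 & d2 <= bg_radii[2]^2
  if (!any(in_peak) || sum(in_bg) < 2L) {
    stop("peak disc or background annulus contains too few grid points", call. = FALSE)
  }
  bg_sd <- stats::sd(spectrum[in_bg])
  intensity <- mean(spectrum[in_peak]) - mean(spectrum[in_bg])
  ios <- if (bg_sd > 0) intensity / bg_sd else NA_real_
  if (is.na(ios)) warning("zero-variance background: I/sigma undefined")
  structure(list(peak = peak, intensity = intensity, background_sd = bg_sd,
                 i_over_sigma = ios),
            class = "reflection_score")
}

#' Display weighting for power spectra
#'
#' Raises a nonnegative field to a small power (0.2 by convention) to make
#' high-frequency detail visible alongside the dominant low frequencies.
#' Visualization only — never used inside metrics.
#'
#' @param field Nonnegative real matrix.
#' @param power Exponent (default 0.2).
#' @return Real matrix.
#' @export
spectrum_display <- function(field, power = 0.2) {
  if (any(field < 0)) stop("display weighting requires a nonnegative field", call. = FALSE)
  field^power
}
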