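# Pre-reconstruction steps: CTF-based defocus estimation from amplitude
# spectra, phase-correlation registration, and compensation of the
# tilt-induced image shift.

#' Reject outliers by the median-absolute-deviation rule
#'
#' Drops values further than `k` times the raw median absolute deviation
#' from the median (the MAD here is unscaled, i.e. median(|x - median(x)|)).
#'
#' @param x Numeric vector.
#' @param k Multiplier (default 3).
#' @return Logical vector, `TRUE` for values kept.
#' @export
reject_outliers_mad <- function(x, k = 3) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) return(abs(x - med) <= .Machine$double.eps^0.5 * max(1, abs(med)))
  abs(x - med) <= k * mad0
}

# Rotationally averaged amplitude spectrum of one image tile, with a smooth
# radial background (running median) subtracted. Returns bin centres (1/nm)
# and the background-subtracted profile.
radial_amplitude_profile <- function(image, pixel_size, bg_window_frac = 1 / 20) {
  g <- frequency_grid(dim(image), pixel_size)
  amp <- Mod(fft2(image - mean(image)))
  nyq <- 1 / (2 * pixel_size)
  dk <- 1 / (min(dim(image)) * pixel_size)
  bins <- floor(as.vector(g$kr) / dk)
  nbin <- floor(nyq / dk)
  keep <- bins >= 1 & bins <= nbin
  prof <- tapply(as.vector(amp)[keep], bins[keep], mean)
  centres <- (as.numeric(names(prof)) + 0.5) * dk
  # smooth radial background: running median with window ~ Nyquist/20
  win <- max(3L, round(bg_window_frac * nbin))
  if (win %% 2L == 0L) win <- win + 1L
  bg <- stats::runmed(prof, k = min(win, 2L * floor((length(prof) - 1L) / 2L) + 1L))
  list(k = centres, profile = as.numeric(prof - bg))
}

# |sin chi| CTF template damped by the coherence envelopes, sampled at radii k.
ctf_template <- function(k, system, c1) {
  sys2 <- system
  sys2$c1 <- c1
  chi <- aberration_phase(sys2, k, 0)
  et <- exp(-((pi * sys2$wavelength * sys2$focal_spread / 2) * k^2)^2)
  g <- aberration_gradient(sys2, k, 0)
  es <- exp(-0.5 * (sys2$illum_semiangle / sys2$wavelength)^2 * (g$gx^2 + g$gy^2))
  abs(sin(chi)) * et * es
}

zncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# Best C1 on the grid for one radial profile, with parabolic refinement of
# the correlation peak. Returns c(c1, peak_correlation).
fit_c1_profile <- function(prof, system, c1_grid, band) {
  sel <- prof$k >= band[1] & prof$k <= band[2]
  if (sum(sel) < 8L) stop("too few spectral bins in the fit band", call. = FALSE)
  scores <- vapply(c1_grid, function(c1) {
    zncc(prof$profile[sel], ctf_template(prof$k[sel], system, c1))
  }, numeric(1))
  i <- which.max(scores)
  c1 <- c1_grid[i]
  if (i > 1L && i < length(c1_grid)) {
    y1 <- scores[i - 1L]; y2 <- scores[i]; y3 <- scores[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (den < 0) c1 <- c1 + 0.5 * (y1 - y3) / den * (c1_grid[i + 1L] - c1_grid[i])
  }
  c(c1, scores[i])
}

#' Estimate defocus from the amplitude spectrum of a micrograph
#'
#' Correlates the rotationally averaged, background-subtracted amplitude
#' spectrum of the image (or of each tile of a `patches[1] x patches[2]`
#' partition) against envelope-damped |sin chi(k; C1)| templates over a
#' defocus grid, taking the zero-mean normalized cross-correlation argmax
#' with parabolic refinement. With patches, per-tile estimates beyond three
#' times the median absolute deviation from the median are rejected and the
#' mean +/- standard error of the survivors is returned.
#'
#' Since |sin chi| is invariant under C1 -> -C1 when C3 = 0, the estimate is
#' flagged sign-ambiguous in that case; supply a one-signed `c1_grid`
#' (e.g. all-negative for underfocused cryo data) to resolve the sign from
#' prior knowledge.
#'
#' @param image Real matrix, at least 128 x 128.
#' @param system An [optical_system()] (C1 is ignored; everything else is
#'   used for the templates).
#' @param c1_grid Monotone numeric vector of candidate C1 values (nm).
#' @param pixel_size Pixel size in nm.
#' @param patches `NULL` for a whole-image fit, or integer (rows, cols) for
#'   the patch protocol (e.g. `c(4, 4)`).
#' @param fit_band Fraction of Nyquist delimiting the fitted band
#'   (default `c(0.1, 0.9)`), excluding the structure-dominated low
#'   frequencies.
#' @param min_correlation Peak correlation below which the estimate is
#'   flagged low-confidence (default 0.3).
#' @return Object of class `defocus_estimate`: `c1` (nm), `se` (nm, `NA`
#'   for a whole-image fit), `estimates` (all per-patch values), `n_used`,
#'   `sign_ambiguous`, `low_confidence`.
#' @export
estimate_defocus <- function(image, system, c1_grid, pixel_size,
                             patches = c(4L, 4L), fit_band = c(0.1, 0.9),
                             min_correlation = 0.3) {
  stopifnot(inherits(system, "optical_system"))
  if (any(dim(image) < 128L)) stop("image must be at least 128 x 128", call. = FALSE)
  if (is.unsorted(c1_grid) && is.unsorted(rev(c1_grid))) {
    stop("`c1_grid` must be monotone", call. = FALSE)
  }
  nyq <- 1 / (2 * pixel_size)
  band <- fit_band * nyq

  tiles <- if (is.null(patches)) {
    list(image)
  } else {
    split_patches(image, patches)
  }
  fits <- lapply(tiles, function(tile) {
    fit_c1_profile(radial_amplitude_profile(tile, pixel_size), system, c1_grid, band)
  })
  est <- vapply(fits, `[`, numeric(1), 1L)
  corr <- vapply(fits, `[`, numeric(1), 2L)

  if (length(est) > 1L) {
    keep <- reject_outliers_mad(est, 3)
    if (!any(keep)) stop("defocus estimation failed: all patches rejected", call. = FALSE)
    used <- est[keep]
    c1 <- mean(used)
    se <- if (length(used) >= 2L) stats::sd(used) / sqrt(length(used)) else NA_real_
    n_used <- length(used)
  } else {
    c1 <- est
    se <- NA_real_
    n_used <- 1L
  }
  structure(list(
    c1 = unname(c1), se = unname(se), estimates = unname(est), n_used = n_used,
    sign_ambiguous = abs(system$c3) < 1e3,    # < 0.001 mm: spectrum is sign-blind
    low_confidence = max(corr) < min_correlation,
    peak_correlation = unname(max(corr))
  ), class = "defocus_estimate")
}

split_patches <- function(image, patches) {
  pr <- as.integer(patches[1]); pc <- as.integer(patches[2])
  nr <- floor(nrow(image) / pr); nc <- floor(ncol(image) / pc)
  out <- list()
  for (i in seq_len(pr)) {
    for (j in seq_len(pc)) {
      out[[length(out) + 1L]] <-
        image[((i - 1L) * nr + 1L):(i * nr), ((j - 1L) * nc + 1L):(j * nc)]
    }
  }
  out
}

#' Register an image stack by phase correlation
#'
#' Measures the translation of each image relative to the reference from the
#' peak of the inverse transform of the unit-normalized cross-power
#' spectrum, refined to subpixel precision by a parabolic fit around the
#' peak. For an image that is a circular shift of the reference by integer
#' (dr, dc) pixels the result is exact.
#'
#' @param stack List of real matrices of identical shape (>= 2 images), or
#'   a `tilt_series`.
#' @param reference_index Index of the reference image (default 1).
#' @return n x 2 matrix of (row, col) shifts in pixels: image i is the
#'   reference translated by `shifts[i, ]`.
#' @export
register_images <- function(stack, reference_index = 1L) {
  if (inherits(stack, "tilt_series")) stack <- stack$images
  stopifnot(length(stack) >= 2L)
  ref <- stack[[reference_index]]
  if (stats::sd(as.vector(ref)) == 0) stop("reference image has zero variance", call. = FALSE)
  Fr <- fft2(ref)
  t(vapply(stack, function(img) {
    if (stats::sd(as.vector(img)) == 0) stop("image has zero variance", call. = FALSE)
    cps <- fft2(img) * Conj(Fr)
    m <- Mod(cps)
    cps <- cps / (m + .Machine$double.eps * max(m))
    corr <- Re(ifft2(cps))
    peak_subpixel(corr)
  }, numeric(2)))
}

# Peak of a circular correlation surface with parabolic subpixel refinement
# along each axis; returns the (row, col) shift with wrap-around applied.
peak_subpixel <- function(corr) {
  d <- dim(corr)
  i <- which.max(corr)
  pr <- ((i - 1L) %% d[1]) + 1L
  pc <- ((i - 1L) %/% d[1]) + 1L
  wrap <- function(idx, n) ((idx - 1L) %% n) + 1L
  refine <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    if (den < 0) 0.5 * (ym - yp) / den else 0
  }
  dr <- refine(corr[wrap(pr - 1L, d[1]), pc], corr[pr, pc], corr[wrap(pr + 1L, d[1]), pc])
  dc <- refine(corr[pr, wrap(pc - 1L, d[2])], corr[pr, pc], corr[pr, wrap(pc + 1L, d[2])])
  sr <- (pr - 1L) + dr
  sc <- (pc - 1L) + dc
  if (sr > d[1] / 2) sr <- sr - d[1]
  if (sc > d[2] / 2) sc <- sc - d[2]
  c(sr, sc)
}

#' Compensate drift and tilt-induced image shift
#'
#' Beam tilt displaces the image by s = (C1 tau + C3 tau^3) along the tilt
#' azimuth (uncorrected axial aberrations), on top of any stage drift. The
#' two cannot be separated by registration alone, so each image is first
#' drift-corrected by the measured shift minus the predicted tilt shift, and
#' then the predicted tilt shift itself is removed — the order used in
#' practice. Both translations are applied in one Fourier-domain subpixel
#' shift (their sum equals the measured shift).
#'
#' @param stack List of real matrices or a `tilt_series`.
#' @param shifts n x 2 measured shifts from [register_images()], pixels.
#' @param system An [optical_system()].
#' @param tilts List of [beam_tilt()] aligned with the stack.
#' @param pixel_size Pixel size in nm.
#' @return List with `stack` (corrected images) and `report`
#'   (class `preprocess_report`): per-image measured, predicted and
#'   applied-drift shift vectors in pixels.
#' @export
compensate_tilt_shift <- function(stack, shifts, system, tilts, pixel_size) {
  series <- NULL
  if (inherits(stack, "tilt_series")) {
    series <- stack
    stack <- series$images
  }
  n <- length(stack)
  if (nrow(shifts) != n || length(tilts) != n) {
    stop("stack, shifts and tilts must have matching lengths", call. = FALSE)
  }
  predicted <- t(vapply(tilts, function(tl) {
    tilt_induced_shift(system, tl) / pixel_size
  }, numeric(2)))
  drift <- shifts - predicted
  corrected <- vector("list", n)
  for (j in seq_len(n)) {
    # undo drift, then undo the predicted tilt shift (net: -measured shift)
    corrected[[j]] <- fourier_shift(stack[[j]], -(drift[j, ] + predicted[j, ]))
  }
  report <- structure(list(
    measured_shift = shifts,
    predicted_shift = predicted,
    applied_shift = drift,
    notes = "applied_shift is the drift component (measured - predicted); the total translation removed per image is measured_shift"
  ), class = "preprocess_report")
  if (!is.null(series)) {
    series$images <- corrected
    return(list(stack = series, report = report))
  }
  list(stack = corrected, report = report)
}

#' Convert an effective (tilted-image) defocus to the axial defocus
#'
#' Tilted-illumination images carry an effective defocus offset of
#' 2 C3 tau^2; the axial C1 is the tilted-image estimate minus that offset.
#' Used when no axial image exists (the low-fluence protocol) and the axial
#' defocus must be inferred from the tilted images.
#'
#' @param c1_effective Effective defocus estimated from a tilted image, nm.
#' @param system An [optical_system()].
#' @param tau Tilt magnitude in radians.
#' @return Axial C1 in nm.
#' @export
axial_from_effective_defocus <- function(c1_effective, system, tau) {
  c1_effective - tilt_defocus_offset(system, tau)$delta_c1
}
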