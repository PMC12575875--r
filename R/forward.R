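# Forward imaging model: tilted-plane-wave illumination, multislice exit
# wave, wave-transfer-function imaging, and a fluence-budgeted parametric
# detector (Poisson shot noise + Gaussian MTF).

#' Exit wave of a phantom under tilted plane-wave illumination
#'
#' The incident wave is the tilted plane wave psi_inc(r) = exp(2 pi i
#' k_tau . r). The wave is passed through the phantom slice by slice:
#' multiplication by the slice transmission t_s(r) = a_s(r) exp(i phi_s(r)),
#' then Fresnel propagation over the slice thickness (Fourier-space
#' propagator exp(-i pi lambda z |k|^2)) between consecutive slices. For a
#' single slice of zero thickness this reduces exactly to
#' O(r) exp(2 pi i k_tau . r), the thin-object exit wave.
#'
#' @param phantom A [make_phantom()] object.
#' @param tilt A [beam_tilt()].
#' @param system An [optical_system()].
#' @return Complex matrix: the specimen exit wave.
#' @export
multislice_exit_wave <- function(phantom, tilt, system) {
  stopifnot(inherits(phantom, "phantom"), inherits(tilt, "beam_tilt"),
            inherits(system, "optical_system"))
  if (phantom$slice_thickness < 0) stop("negative slice thickness", call. = FALSE)
  shape <- dim(phantom$phase[[1]])
  px <- phantom$pixel_size
  x <- (seq_len(shape[1]) - 1) * px
  y <- (seq_len(shape[2]) - 1) * px
  kt <- tilt$k_tau
  psi <- exp(2i * pi * (outer(kt[1] * x, rep(1, shape[2])) +
                        outer(rep(1, shape[1]), kt[2] * y)))
  n <- length(phantom$phase)
  prop <- NULL
  if (n > 1L && phantom$slice_thickness > 0) {
    g <- frequency_grid(shape, px)
    prop <- exp(-1i * pi * system$wavelength * phantom$slice_thickness * g$kr^2)
  }
  for (s in seq_len(n)) {
    psi <- psi * (phantom$amplitude[[s]] * exp(1i * phantom$phase[[s]]))
    if (!is.null(prop) && s < n) psi <- ifft2(fft2(psi) * prop)
  }
  psi
}

#' Image intensity from an exit wave
#'
#' Applies the axial wave transfer function to the exit-wave spectrum and
#' takes the squared magnitude:
#' I(r) = |F^-1[ F[psi_ex](k) w(k) ]|^2. This is the image-plane intensity
#' before any detector effects; for tilted illumination the tilt lives in
#' the exit wave itself (its spectrum is the shifted object spectrum), so
#' the transfer function here is always the axial one.
#'
#' @param exit_wave Complex matrix from [multislice_exit_wave()].
#' @param system An [optical_system()].
#' @param pixel_size Pixel size in nm of the exit-wave grid.
#' @return Nonnegative real matrix.
#' @export
image_from_exit_wave <- function(exit_wave, system, pixel_size) {
  stopifnot(is.complex(exit_wave) || is.numeric(exit_wave))
  g <- frequency_grid(dim(exit_wave), pixel_size)
  w <- axial_wtf(g, system)
  Mod(ifft2(fft2(exit_wave) * w))^2
}

#' Parametric detector model
#'
#' Stand-in for a real camera characterization: Poisson shot noise at the
#' expected count level plus a Gaussian modulation-transfer kernel. The MTF
#' is applied in Fourier space as exp(-f^2 / (2 sigma^2)) with f in
#' cycles/pixel, i.e. a unit-sum real-space blur (unit DC gain), so the
#' expected total count is unchanged by the blur.
#'
#' @param mtf_sigma Standard deviation of the Gaussian MTF in cycles/pixel
#'   (default 0.35); `Inf` disables the blur.
#' @param gain Counts recorded per incident electron (default 1).
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(mtf_sigma = 0.35, gain = 1) {
  if (gain <= 0) stop("`gain` must be positive", call. = FALSE)
  if (mtf_sigma <= 0) stop("`mtf_sigma` must be positive", call. = FALSE)
  structure(list(mtf_sigma = mtf_sigma, gain = gain), class = "detector_model")
}

#' Record an expected image with a fluence budget
#'
#' Scales a mean-one expected intensity to expected electron counts
#' (fluence x pixel_size^2 per pixel x intensity), draws Poisson counts,
#' and applies the detector MTF blur. With `noise = FALSE` the scaled
#' expected image is returned exactly (the infinite-fluence limit).
#'
#' @param expected_image Nonnegative real matrix, normalized so its mean is
#'   ~1 for unit incident flux.
#' @param fluence Electrons per nm^2 allotted to this image (> 0).
#' @param pixel_size Pixel size in nm.
#' @param detector A [detector_model()].
#' @param noise Draw Poisson counts (default TRUE)?
#' @param seed Optional integer seed for the Poisson draw.
#' @return Real matrix of detector counts.
#' @export
apply_detector <- function(expected_image, fluence, pixel_size, detector,
                           noise = TRUE, seed = NULL) {
  stopifnot(inherits(detector, "detector_model"), fluence > 0, pixel_size > 0)
  if (any(expected_image < 0)) stop("expected image has negative pixels", call. = FALSE)
  counts <- fluence * pixel_size^2 * expected_image * detector$gain
  if (noise) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    counts <- matrix(stats::rpois(length(counts), as.vector(counts)),
                     nrow(counts), ncol(counts))
  }
  if (is.finite(detector$mtf_sigma)) {
    fr <- fft_freqs(nrow(counts))
    fc <- fft_freqs(ncol(counts))
    f2 <- outer(fr^2, rep(1, length(fc))) + outer(rep(1, length(fr)), fc^2)
    mtf <- exp(-f2 / (2 * detector$mtf_sigma^2))
    counts <- Re(ifft2(fft2(counts) * mtf))
    counts[counts < 0] <- 0
  }
  counts
}

#' Acquisition protocol for a tilt series
#'
#' @param tilt_magnitude Tilt magnitude in radians shared by all tilted
#'   images.
#' @param n_azimuths Number of tilted images, at equally spaced azimuths
#'   2 pi j / n, j = 0..n-1.
#' @param axial Include one axial (zero-tilt) image first? The
#'   radiation-robust protocol uses one axial + six tilts; the low-fluence
#'   protocol uses four tilts and no axial image.
#' @return Object of class `tilt_protocol`.
#' @export
tilt_protocol <- function(tilt_magnitude, n_azimuths, axial = TRUE) {
  if (n_azimuths < 1L && !axial) stop("protocol requests zero images", call. = FALSE)
  structure(list(tilt_magnitude = tilt_magnitude,
                 n_azimuths = as.integer(n_azimuths), axial = isTRUE(axial)),
            class = "tilt_protocol")
}

# Snap a tilt to the nearest frequency-grid sample so that forward model and
# reconstruction share an exactly periodic plane-wave factor. The snapped
# magnitude/azimuth are recomputed from the snapped wavevector, preserving
# |k_tau| = magnitude / lambda.
snap_tilt_to_grid <- function(tilt, system, shape, pixel_size) {
  dk <- 1 / (shape * pixel_size)
  kt <- round(tilt$k_tau / dk) * dk
  mag <- sqrt(sum(kt^2)) * system$wavelength
  az <- if (all(kt == 0)) 0 else atan2(kt[2], kt[1])
  beam_tilt(system, mag, az)
}

#' Simulate a complete eFP tilt series
#'
#' Runs the full forward model for every illumination of the protocol:
#' exit wave (multislice), transfer-function imaging, detector. The total
#' fluence budget is split equally across the images. Tilt wavevectors are
#' quantized to the simulation frequency grid so the plane-wave factor is
#' exactly periodic on the field of view.
#'
#' @param phantom A [make_phantom()] object.
#' @param protocol A [tilt_protocol()].
#' @param system An [optical_system()].
#' @param detector A [detector_model()].
#' @param total_fluence Total budget in electrons/nm^2 across all images.
#' @param seed Integer seed controlling the detector noise.
#' @param noise Poisson noise on (default); `FALSE` gives the
#'   infinite-fluence expected images.
#' @return Object of class `tilt_series`: fields `images` (list of real
#'   matrices), `tilts` (list of [beam_tilt()]), `fluence_per_image`,
#'   `optics`, `pixel_size`, `provenance`.
#' @export
simulate_tilt_series <- function(phantom, protocol, system, detector,
                                 total_fluence, seed = 1L, noise = TRUE) {
  stopifnot(inherits(phantom, "phantom"), inherits(protocol, "tilt_protocol"),
            inherits(system, "optical_system"), inherits(detector, "detector_model"))
  tilts <- list()
  if (protocol$axial) tilts <- c(tilts, list(beam_tilt(system, 0)))
  if (protocol$n_azimuths > 0L) {
    for (j in seq_len(protocol$n_azimuths) - 1L) {
      tilts <- c(tilts, list(beam_tilt(system, protocol$tilt_magnitude,
                                       2 * pi * j / protocol$n_azimuths)))
    }
  }
  n_img <- length(tilts)
  if (n_img == 0L) stop("protocol requests zero images", call. = FALSE)
  shape <- dim(phantom$phase[[1]])
  tilts <- lapply(tilts, snap_tilt_to_grid, system = system,
                  shape = shape, pixel_size = phantom$pixel_size)
  fl <- total_fluence / n_img
  images <- vector("list", n_img)
  for (j in seq_len(n_img)) {
    psi <- multislice_exit_wave(phantom, tilts[[j]], system)
    img <- image_from_exit_wave(psi, system, phantom$pixel_size)
    images[[j]] <- apply_detector(img, fl, phantom$pixel_size, detector,
                                  noise = noise, seed = seed + j)
  }
  structure(list(
    images = images,
    tilts = tilts,
    fluence_per_image = fl,
    optics = system,
    pixel_size = phantom$pixel_size,
    provenance = list(seed = as.integer(seed), noise = noise,
                      protocol = unclass(protocol),
                      phantom_kind = phantom$kind)
  ), class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  mags <- vapply(x$tilts, function(t) t$magnitude, numeric(1))
  cat(sprintf("Tilt series: %d images of %d x %d px (%.4g nm/px)\n",
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
              x$pixel_size))
  cat(sprintf("  tilt magnitudes (mrad): %s\n",
              paste(sprintf("%.2f", mags * 1e3), collapse = ", ")))
  cat(sprintf("  fluence per image: %.4g e-/nm^2\n", x$fluence_per_image))
  invisible(x)
}
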