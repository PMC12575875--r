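# Optical system, beam tilts, aberration phase and wave transfer functions.
#
# Conventions used throughout:
#   * lengths in nm, spatial frequencies in 1/nm, angles in radians;
#   * constructors accept the instrument-facing units (kV, mm for C3, mrad)
#     and convert once at the boundary;
#   * Saxton notation for the aberration coefficients, truncated at C1
#     (defocus, overfocus positive) and C3 (spherical aberration);
#   * the aberration phase is chi(k) = pi*lambda*C1*|k|^2 +
#     (pi/2)*lambda^3*C3*|k|^4.

#' Relativistic electron wavelength
#'
#' de Broglie wavelength of an electron accelerated through `voltage_kv`
#' kilovolts, with the relativistic correction:
#' lambda = hc / sqrt(E (E + 2 m0 c^2)).
#'
#' @param voltage_kv Accelerating voltage in kV; must be positive.
#' @return Wavelength in nm (1.9687e-3 nm at 300 kV).
#' @export
electron_wavelength <- function(voltage_kv) {
  if (!is.numeric(voltage_kv) || length(voltage_kv) != 1L || !is.finite(voltage_kv) ||
      voltage_kv <= 0) {
    stop("`voltage_kv` must be a single positive number", call. = FALSE)
  }
  hc_kev_nm <- 1.23984193      # Planck constant times c, keV nm
  m0c2_kev <- 510.99895        # electron rest energy, keV
  e_kev <- voltage_kv          # kinetic energy in keV
  hc_kev_nm / sqrt(e_kev * (e_kev + 2 * m0c2_kev))
}

#' Describe the imaging optics
#'
#' Bundles the microscope parameters entering every transfer-function
#' evaluation. The wavelength is always recomputed from the voltage; it is
#' never stored independently.
#'
#' @param voltage_kv Accelerating voltage, kV.
#' @param c1_nm Defocus C1 in nm, overfocus positive (Saxton convention).
#' @param c3_mm Spherical aberration C3 in mm; converted to nm internally.
#' @param focal_spread_nm Focal spread Delta (nm), the 1/e half-width scale
#'   of the defocus distribution driving the temporal-coherence envelope.
#' @param illum_semiangle_mrad Illumination semi-angle beta (mrad), the RMS
#'   angular spread of the source driving the spatial-coherence envelope.
#' @param aperture_kmax_invnm Optional hard objective-aperture radius in
#'   1/nm; `NULL` means no hard aperture.
#' @param transfer_threshold Information-transfer fraction in (0, 1] used to
#'   delimit passbands (default 0.10, the conventional 10% limit).
#' @return An object of class `optical_system` with all quantities in
#'   internal units (nm, 1/nm, radians).
#' @export
optical_system <- function(voltage_kv, c1_nm = 0, c3_mm = 0,
                           focal_spread_nm = 0, illum_semiangle_mrad = 0,
                           aperture_kmax_invnm = NULL,
                           transfer_threshold = 0.10) {
  if (voltage_kv <= 0) stop("`voltage_kv` must be positive", call. = FALSE)
  if (focal_spread_nm < 0) stop("`focal_spread_nm` must be >= 0", call. = FALSE)
  if (illum_semiangle_mrad < 0) stop("`illum_semiangle_mrad` must be >= 0", call. = FALSE)
  if (transfer_threshold <= 0 || transfer_threshold > 1) {
    stop("`transfer_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(aperture_kmax_invnm) && aperture_kmax_invnm <= 0) {
    stop("`aperture_kmax_invnm` must be positive when given", call. = FALSE)
  }
  structure(list(
    voltage_kv = voltage_kv,
    wavelength = electron_wavelength(voltage_kv),
    c1 = c1_nm,
    c3 = c3_mm * 1e6,                       # mm -> nm
    focal_spread = focal_spread_nm,
    illum_semiangle = illum_semiangle_mrad * 1e-3,  # mrad -> rad
    aperture_kmax = aperture_kmax_invnm,
    transfer_threshold = transfer_threshold
  ), class = "optical_system")
}

#' @export
print.optical_system <- function(x, ...) {
  cat("Optical system:\n")
  cat(sprintf("  voltage       %g kV  (lambda = %.5g nm)\n", x$voltage_kv, x$wavelength))
  cat(sprintf("  C1 (defocus)  %g nm  (overfocus positive)\n", x$c1))
  cat(sprintf("  C3            %g mm\n", x$c3 / 1e6))
  cat(sprintf("  focal spread  %g nm\n", x$focal_spread))
  cat(sprintf("  illum. angle  %g mrad\n", x$illum_semiangle * 1e3))
  if (!is.null(x$aperture_kmax)) {
    cat(sprintf("  aperture      %g 1/nm\n", x$aperture_kmax))
  }
  invisible(x)
}

#' Beam tilt of the plane-wave illumination
#'
#' A tilt of magnitude tau at a given azimuth shifts the object spectrum by
#' the in-plane wavevector k_tau = tau / lambda along the azimuth direction.
#'
#' @param system An [optical_system()] (supplies the wavelength).
#' @param magnitude Tilt magnitude tau in radians (>= 0; 0 is axial
#'   illumination).
#' @param azimuth Tilt azimuth in radians, measured from the first (x) axis.
#' @return Object of class `beam_tilt` with fields `magnitude`, `azimuth`
#'   and the 2-vector `k_tau` (1/nm).
#' @export
beam_tilt <- function(system, magnitude, azimuth = 0) {
  stopifnot(inherits(system, "optical_system"))
  if (magnitude < 0) stop("tilt `magnitude` must be >= 0", call. = FALSE)
  k <- magnitude / system$wavelength
  structure(list(
    magnitude = magnitude,
    azimuth = azimuth,
    k_tau = c(k * cos(azimuth), k * sin(azimuth))
  ), class = "beam_tilt")
}

#' @export
print.beam_tilt <- function(x, ...) {
  cat(sprintf("Beam tilt: %.3f mrad at azimuth %.1f deg  (|k_tau| = %.4g 1/nm)\n",
              x$magnitude * 1e3, x$azimuth * 180 / pi, sqrt(sum(x$k_tau^2))))
  invisible(x)
}

#' Spatial-frequency grid for a sampled image
#'
#' Frequency coordinates (1/nm) for each pixel of a `shape[1] x shape[2]`
#' image with the given pixel size, in unshifted FFT ordering (the zero
#' frequency sits at element `[1, 1]`). The frequency step along each axis is
#' 1/(n * pixel_size) and frequencies span the Nyquist range
#' +/- 1/(2 pixel_size).
#'
#' @param shape Integer vector (rows, cols).
#' @param pixel_size Pixel size in nm.
#' @return Object of class `frequency_grid` with matrices `kx` (varies along
#'   rows), `ky` (along columns), `kr` = sqrt(kx^2+ky^2), plus `shape` and
#'   `pixel_size`.
#' @export
frequency_grid <- function(shape, pixel_size) {
  stopifnot(length(shape) == 2L, pixel_size > 0)
  shape <- as.integer(shape)
  fx <- fft_freqs(shape[1], pixel_size)
  fy <- fft_freqs(shape[2], pixel_size)
  kx <- matrix(fx, shape[1], shape[2])
  ky <- matrix(fy, shape[1], shape[2], byrow = TRUE)
  structure(list(shape = shape, pixel_size = pixel_size,
                 kx = kx, ky = ky, kr = sqrt(kx^2 + ky^2)),
            class = "frequency_grid")
}

#' Aberration phase chi(k)
#'
#' chi(k) = pi lambda C1 |k|^2 + (pi/2) lambda^3 C3 |k|^4, the lens-induced
#' phase error for the C1/C3-only aberration function in Saxton notation
#' (overfocus-positive C1).
#'
#' @param system An [optical_system()].
#' @param kx,ky Spatial-frequency coordinates (1/nm); scalars, vectors or
#'   matrices of equal shape.
#' @return chi in radians, same shape as `kx`.
#' @export
aberration_phase <- function(system, kx, ky) {
  stopifnot(inherits(system, "optical_system"))
  k2 <- kx^2 + ky^2
  lam <- system$wavelength
  pi * lam * system$c1 * k2 + (pi / 2) * lam^3 * system$c3 * k2^2
}

#' Gradient of the aberration phase
#'
#' Returns the two components of grad chi(k) = 2 pi lambda (C1 + lambda^2
#' C3 |k|^2) k, used by the spatial-coherence envelope and the tilt-induced
#' image shift.
#'
#' @inheritParams aberration_phase
#' @return List with components `gx`, `gy` (radians per 1/nm).
#' @export
aberration_gradient <- function(system, kx, ky) {
  stopifnot(inherits(system, "optical_system"))
  lam <- system$wavelength
  fac <- 2 * pi * lam * (system$c1 + lam^2 * system$c3 * (kx^2 + ky^2))
  list(gx = fac * kx, gy = fac * ky)
}

# Shared kernel: aperture, aberration and coherence envelopes evaluated at
# image frequency (kx, ky), with the temporal envelope referenced to |kref|^2
# (0 for axial, |k_tau|^2 for tilted illumination) and the constant phase
# chi(kref) subtracted. The linear (image-shift) phase ramp is never included
# here; shift compensation is an explicit preprocessing step.
wtf_kernel <- function(system, kx, ky, kref2 = 0, chi_ref = 0) {
  lam <- system$wavelength
  k2 <- kx^2 + ky^2
  chi <- aberration_phase(system, kx, ky)
  et <- exp(-((pi * lam * system$focal_spread / 2) * (k2 - kref2))^2)
  g <- aberration_gradient(system, kx, ky)
  es <- exp(-0.5 * (system$illum_semiangle / lam)^2 * (g$gx^2 + g$gy^2))
  a <- if (is.null(system$aperture_kmax)) 1 else (k2 <= system$aperture_kmax^2) * 1
  a * exp(-1i * (chi - chi_ref)) * et * es
}

#' Axial wave transfer function
#'
#' w(k) = A(k) exp(-i chi(k)) Et(k) Es(k): hard aperture (if any), aberration
#' phase, partial temporal coherence envelope
#' Et = exp(-[(pi lambda Delta / 2) |k|^2]^2) and partial spatial coherence
#' envelope Es = exp(-(1/2) (beta/lambda)^2 |grad chi|^2).
#'
#' @param grid A [frequency_grid()].
#' @param system An [optical_system()].
#' @return Complex matrix on the grid; |w| <= 1 everywhere.
#' @export
axial_wtf <- function(grid, system) {
  stopifnot(inherits(grid, "frequency_grid"))
  wtf_kernel(system, grid$kx, grid$ky)
}

#' Effective wave transfer function under tilted illumination
#'
#' For object frequency q and tilt wavevector k_tau,
#' w'(q, k_tau) = A(q+k_tau) exp(-i[chi(q+k_tau) - chi(k_tau)])
#' Et'(q,k_tau) Es'(q,k_tau), with
#' Et' = exp(-[(pi lambda Delta/2)(|q+k_tau|^2 - |k_tau|^2)]^2) and
#' Es' = exp(-(1/2)(beta/lambda)^2 |grad chi(q+k_tau)|^2). The temporal
#' envelope attains its maximum of 1 on the achromatic circle
#' |q+k_tau| = |k_tau|, producing the annular transfer characteristic of
#' tilted illumination. The linear phase ramp (a pure image shift) is
#' excluded; it is compensated explicitly in preprocessing.
#'
#' @param grid A [frequency_grid()] of object frequencies q.
#' @param system An [optical_system()].
#' @param tilt A [beam_tilt()].
#' @return Complex matrix on the grid; reduces exactly to [axial_wtf()] for
#'   a zero-magnitude tilt.
#' @export
effective_wtf <- function(grid, system, tilt) {
  stopifnot(inherits(grid, "frequency_grid"), inherits(tilt, "beam_tilt"))
  kt <- tilt$k_tau
  nyq <- 1 / (2 * grid$pixel_size)
  if (sqrt(sum(kt^2)) > 2 * nyq) {
    stop("tilt passband lies entirely outside the frequency grid", call. = FALSE)
  }
  chi_ref <- aberration_phase(system, kt[1], kt[2])
  wtf_kernel(system, grid$kx + kt[1], grid$ky + kt[2],
             kref2 = sum(kt^2), chi_ref = chi_ref)
}

#' Information-transfer loss at the centre of the tilted passband
#'
#' The partial temporal coherence envelope, referenced to the tilt
#' wavevector, is below 1 at the passband centre q = -k_tau:
#' loss = 1 - exp(-[(pi lambda Delta / 2) |k_tau|^2]^2) with
#' |k_tau| = tau / lambda. This is the maximum transfer loss at the centre
#' of the effective wave transfer function; it grows steeply with tilt
#' magnitude and vanishes for Delta = 0 or tau = 0.
#'
#' @param system An [optical_system()].
#' @param tau Tilt magnitude in radians (>= 0).
#' @return Loss as a fraction in [0, 1).
#' @export
central_transfer_loss <- function(system, tau) {
  stopifnot(inherits(system, "optical_system"), tau >= 0)
  lam <- system$wavelength
  ktau2 <- (tau / lam)^2
  1 - exp(-((pi * lam * system$focal_spread / 2) * ktau2)^2)
}

#' Optimal-coupling beam tilt
#'
#' The tilt magnitude for which defocus and spherical aberration couple
#' symmetrically, C1 = -C3 tau^2, i.e. tau = sqrt(-C1/C3). Requires C1 and
#' C3 of opposite sign (or C1 = 0).
#'
#' @param c1_nm Defocus in nm.
#' @param c3_mm Spherical aberration in mm (nonzero).
#' @return Tilt magnitude in radians.
#' @export
optimal_tilt <- function(c1_nm, c3_mm) {
  c3_nm <- c3_mm * 1e6
  if (c3_nm == 0) stop("`c3_mm` must be nonzero", call. = FALSE)
  r <- -c1_nm / c3_nm
  if (r < 0) {
    stop("no real optimal tilt: C1 and C3 must have opposite signs", call. = FALSE)
  }
  sqrt(r)
}

#' Tilt-induced defocus change
#'
#' Tilting the beam changes the effective defocus of the image by
#' Delta C1 = 2 C3 tau^2. The relative offset |Delta C1| / |C1| is reported
#' alongside (NA with a warning when C1 = 0).
#'
#' @param system An [optical_system()].
#' @param tau Tilt magnitude in radians.
#' @return List with `delta_c1` (nm) and `relative` (fraction of |C1|).
#' @export
tilt_defocus_offset <- function(system, tau) {
  stopifnot(inherits(system, "optical_system"), tau >= 0)
  dc1 <- 2 * system$c3 * tau^2
  rel <- if (system$c1 == 0) {
    if (dc1 != 0) warning("relative defocus offset undefined for C1 = 0")
    if (dc1 == 0) 0 else NA_real_
  } else {
    abs(dc1) / abs(system$c1)
  }
  list(delta_c1 = dc1, relative = rel)
}

#' Tilt-induced image shift
#'
#' Beam tilt combined with uncorrected axial aberrations displaces the image
#' by s = (C1 tau + C3 tau^3) u, with u the unit vector along the tilt
#' azimuth. This equals grad chi(k_tau) / (2 pi) for the C1/C3-only
#' aberration phase.
#'
#' @param system An [optical_system()].
#' @param tilt A [beam_tilt()].
#' @return Length-2 numeric vector, shift in nm along (x, y).
#' @export
tilt_induced_shift <- function(system, tilt) {
  stopifnot(inherits(system, "optical_system"), inherits(tilt, "beam_tilt"))
  tau <- tilt$magnitude
  mag <- system$c1 * tau + system$c3 * tau^3
  mag * c(cos(tilt$azimuth), sin(tilt$azimuth))
}

#' Resolution extension from a beam tilt
#'
#' A tilt of magnitude tau shifts the transfer passband by |k_tau| =
#' tau/lambda, extending the highest accessible spatial frequency from
#' 1/d_axial to 1/d_axial + tau/lambda along the tilt direction. Returns the
#' extended resolution 1 / (1/d_axial + tau/lambda) in nm.
#'
#' @param system An [optical_system()].
#' @param tau Tilt magnitude in radians.
#' @param axial_resolution_nm Axial information limit, nm.
#' @return Extended resolution in nm (<= `axial_resolution_nm`).
#' @export
extended_resolution <- function(system, tau, axial_resolution_nm) {
  stopifnot(inherits(system, "optical_system"), tau >= 0, axial_resolution_nm > 0)
  1 / (1 / axial_resolution_nm + tau / system$wavelength)
}
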