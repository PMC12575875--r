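# Modified Ptychographic Iterative Engine for electron Fourier
# ptychography. Each tilted image constrains a shifted crop of the object
# spectrum: the image-wave amplitude is replaced by the measurement in real
# space, and the exit-wave update is applied in Fourier space on an
# upsampled canvas — the reverse of the update spaces of conventional PIE.
#
# Canvas layout: the object spectrum is stored fftshift-centred on a canvas
# of upsample * measurement shape, same field of view (so the same frequency
# step as the measurement grid, extended Nyquist). A tilt k_tau moves the
# measurement passband to the canvas block centred at -k_tau, rounded to the
# nearest canvas sample.

#' Reconstruction configuration
#'
#' @param iterations Number of PIE sweeps over all tilts (default 50, the
#'   point at which reconstructions converge in practice).
#' @param step0 Initial update step size, expressed as the fraction of the
#'   full amplitude-replacement projection applied per tilt (default 1:
#'   full projection; the decay schedule then anneals it).
#' @param decay_factor Multiplicative step decay (default 0.5).
#' @param decay_every Apply the decay every this many iterations
#'   (default 10).
#' @param momentum Heavy-ball momentum applied to the object spectrum after
#'   each sweep (default 0.9; 0 disables). Accelerates the slowly
#'   converging low-frequency phase/amplitude separation without changing
#'   the fixed point.
#' @param upsample Integer canvas upsampling factor >= 1 (default 2,
#'   sufficient while |k_tau| does not exceed the measurement Nyquist).
#' @param epsilon Regularizer as a fraction of max |w|^2 in the Fourier
#'   update denominator (default 1e-3).
#' @param order Tilt visiting order: `"fixed"` (as listed) or `"shuffled"`
#'   (reshuffled each iteration from `seed`).
#' @param seed Seed for the shuffled order.
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(iterations = 50L, step0 = 1.0, decay_factor = 0.5,
                         decay_every = 10L, momentum = 0.9, upsample = 2L,
                         epsilon = 1e-3, order = c("fixed", "shuffled"),
                         seed = 1L) {
  order <- match.arg(order)
  stopifnot(iterations >= 0, step0 > 0, step0 <= 1,
            decay_factor > 0, decay_factor <= 1, decay_every >= 1,
            momentum >= 0, momentum < 1, upsample >= 1, epsilon >= 0)
  structure(list(iterations = as.integer(iterations), step0 = step0,
                 decay_factor = decay_factor, decay_every = as.integer(decay_every),
                 momentum = momentum,
                 upsample = as.integer(upsample), epsilon = epsilon,
                 order = order, seed = as.integer(seed)),
            class = "recon_config")
}

# Step size at 1-based iteration i under the decay schedule.
step_at <- function(config, i) {
  config$step0 * config$decay_factor^floor((i - 1) / config$decay_every)
}

#' Initial exit-wave estimate
#'
#' The estimate starts as unit amplitude and zero phase in real space: its
#' spectrum is zero except at the zero-frequency sample of the upsampled
#' canvas.
#'
#' @param shape Measurement image shape (rows, cols).
#' @param pixel_size Measurement pixel size, nm.
#' @param upsample Integer canvas upsampling factor.
#' @return Object of class `exit_wave_estimate`: `spectrum` (complex,
#'   fftshift-centred, `upsample * shape`), `meas_shape`, `pixel_size`,
#'   `upsample`, `canvas_pixel_size`, `history` (per-iteration data error,
#'   empty).
#' @export
initialize_estimate <- function(shape, pixel_size, upsample = 2L) {
  shape <- as.integer(shape)
  upsample <- as.integer(upsample)
  stopifnot(upsample >= 1L)
  cshape <- shape * upsample
  spec <- matrix(0 + 0i, cshape[1], cshape[2])
  ctr <- floor(cshape / 2) + 1L
  spec[ctr[1], ctr[2]] <- prod(cshape) + 0i   # fft of the constant-1 field
  structure(list(spectrum = spec, meas_shape = shape, pixel_size = pixel_size,
                 upsample = upsample, canvas_pixel_size = pixel_size / upsample,
                 history = numeric(0)),
            class = "exit_wave_estimate")
}

#' Reconstructed exit wave in real space
#'
#' Inverse-transforms the object spectrum. With `shape = "canvas"` the wave
#' is returned on the full upsampled grid; with `shape = "measurement"` the
#' spectrum is first cropped to the measurement passband, giving the wave at
#' the original sampling (convenient for comparison with ground truth).
#'
#' @param estimate An [initialize_estimate()] / [pie_reconstruct()] result.
#' @param shape `"canvas"` or `"measurement"`.
#' @return Complex matrix.
#' @export
exit_wave <- function(estimate, shape = c("canvas", "measurement")) {
  stopifnot(inherits(estimate, "exit_wave_estimate"))
  shape <- match.arg(shape)
  if (shape == "canvas") {
    return(ifft2(ifftshift(estimate$spectrum)))
  }
  crop <- crop_centered(estimate$spectrum, estimate$meas_shape, c(0L, 0L))
  scale <- prod(estimate$meas_shape) / prod(dim(estimate$spectrum))
  ifft2(ifftshift(crop * scale))
}

# Indices of the measurement-shaped block of a centered canvas spectrum,
# displaced by integer `offset` (row, col) samples. Errors if the block
# leaves the canvas.
crop_indices <- function(d, shape, offset) {
  ctr <- floor(d / 2) + 1L
  mctr <- floor(shape / 2) + 1L
  r0 <- ctr[1] + offset[1] - (mctr[1] - 1L)
  c0 <- ctr[2] + offset[2] - (mctr[2] - 1L)
  if (r0 < 1L || c0 < 1L || r0 + shape[1] - 1L > d[1] || c0 + shape[2] - 1L > d[2]) {
    stop("tilt passband exceeds the upsampled canvas; increase `upsample`",
         call. = FALSE)
  }
  list(rows = r0:(r0 + shape[1] - 1L), cols = c0:(c0 + shape[2] - 1L))
}

# Centered crop of a centered spectrum.
crop_centered <- function(spec, shape, offset) {
  idx <- crop_indices(dim(spec), shape, offset)
  spec[idx$rows, idx$cols, drop = FALSE]
}

# Integer canvas offset of the passband for a tilt: the measurement
# frequency k samples the object spectrum at q = k - k_tau.
tilt_offset <- function(tilt, meas_shape, pixel_size) {
  dk <- 1 / (meas_shape * pixel_size)
  as.integer(round(-tilt$k_tau / dk))
}

# Model the image wave for one tilt from the current spectrum (centred
# measurement-layout spectrum and its real-space field).
model_image_wave <- function(estimate, w_centred, offset) {
  scale <- prod(estimate$meas_shape) / prod(dim(estimate$spectrum))
  sub <- crop_centered(estimate$spectrum, estimate$meas_shape, offset) * scale
  psi_f <- sub * w_centred
  list(psi_f = psi_f, psi_r = ifft2(ifftshift(psi_f)))
}

#' Exit-wave reconstruction with the modified PIE
#'
#' Iterates over the tilt series: for each illumination j the current object
#' spectrum is cropped at the passband shifted by -k_tau_j, multiplied by
#' the axial wave transfer function (envelopes included) to model the image
#' wave, inverse-transformed, and its real-space amplitude replaced by the
#' measured one, sqrt(I_j / mean(I_j)) (each image is mean-normalized to
#' remove exposure fluctuations). The resulting Fourier-space difference
#' updates the object spectrum in place on the canvas:
#' O <- O + alpha conj(w) / (max|w|^2 (1 + epsilon)) * (Psi' - Psi),
#' with alpha the fraction of the full replacement applied, annealed by the
#' step-decay schedule (halved every 10 iterations by default), and a
#' heavy-ball momentum term applied to the spectrum after each sweep.
#'
#' The input series is expected to be preprocessed: registered and
#' compensated for the tilt-induced image shift.
#'
#' @param series A `tilt_series` (preprocessed).
#' @param system An [optical_system()]; defaults to `series$optics`.
#' @param config A [recon_config()].
#' @return An `exit_wave_estimate` whose `history` holds the per-iteration
#'   normalized amplitude-mismatch error monitored during each sweep.
#' @export
pie_reconstruct <- function(series, system = series$optics,
                            config = recon_config()) {
  stopifnot(inherits(series, "tilt_series"), inherits(system, "optical_system"),
            inherits(config, "recon_config"))
  n <- length(series$images)
  shape <- dim(series$images[[1]])
  est <- initialize_estimate(shape, series$pixel_size, config$upsample)
  if (config$iterations == 0L) return(est)

  g <- frequency_grid(shape, series$pixel_size)
  w <- fftshift(axial_wtf(g, system))          # centred measurement layout
  wmax2 <- max(Mod(w)^2)
  denom <- wmax2 * (1 + config$epsilon)
  upd_w <- Conj(w) / denom
  scale <- prod(shape) / prod(dim(est$spectrum))

  targets <- lapply(series$images, function(im) {
    if (any(im < 0)) stop("negative intensities in series", call. = FALSE)
    sqrt(im / mean(im))
  })
  t2sum <- sum(vapply(targets, function(t) sum(t^2), numeric(1)))
  offsets <- lapply(series$tilts, tilt_offset, meas_shape = shape,
                    pixel_size = series$pixel_size)
  # fail early if any passband leaves the canvas
  for (o in offsets) invisible(crop_indices(dim(est$spectrum), shape, o))

  tiny <- .Machine$double.eps
  history <- numeric(config$iterations)
  velocity <- est$spectrum * 0
  if (config$order == "shuffled") set.seed(config$seed)
  for (it in seq_len(config$iterations)) {
    alpha <- step_at(config, it)
    ord <- if (config$order == "shuffled") sample.int(n) else seq_len(n)
    sweep_start <- est$spectrum
    err_num <- 0
    for (j in ord) {
      idx <- crop_indices(dim(est$spectrum), shape, offsets[[j]])
      sub <- est$spectrum[idx$rows, idx$cols] * scale
      psi_f <- sub * w
      psi_r <- ifft2(ifftshift(psi_f))
      amp <- Mod(psi_r)
      # compare amplitudes in mean-square-normalized form: the measured
      # intensities carry an arbitrary exposure scale, and the model loses
      # a little scattered power outside the passband, so both sides are
      # reduced to unit RMS and the model keeps its own flux
      s <- sqrt(mean(amp^2))
      err_num <- err_num + sum((amp / s - targets[[j]])^2)
      psi_new <- (s * targets[[j]]) * psi_r / (amp + tiny)
      dpsi <- fftshift(fft2(psi_new)) - psi_f
      upd <- alpha * upd_w * dpsi / scale
      if (anyNA(upd)) stop(sprintf("NaN in PIE update at iteration %d", it), call. = FALSE)
      est$spectrum[idx$rows, idx$cols] <- est$spectrum[idx$rows, idx$cols] + upd
    }
    if (config$momentum > 0) {
      velocity <- config$momentum * velocity + (est$spectrum - sweep_start)
      est$spectrum <- est$spectrum + config$momentum * velocity
    }
    history[it] <- err_num / t2sum
  }
  est$history <- history
  est
}

#' Normalized amplitude-mismatch data error
#'
#' sum_j sum_r (|psi_im,j(r)| - sqrt(I_j(r)/mean(I_j)))^2 divided by
#' sum_j sum_r I_j(r)/mean(I_j): a dimensionless misfit between the modelled
#' image-wave amplitudes and the measured ones. It is zero when the model
#' reproduces every measurement exactly, and is invariant under a global
#' phase factor applied to the estimate.
#'
#' @param estimate An `exit_wave_estimate`.
#' @param series The `tilt_series` it models.
#' @param system An [optical_system()]; defaults to `series$optics`.
#' @return Nonnegative scalar.
#' @export
data_error <- function(estimate, series, system = series$optics) {
  stopifnot(inherits(estimate, "exit_wave_estimate"), inherits(series, "tilt_series"))
  shape <- dim(series$images[[1]])
  g <- frequency_grid(shape, series$pixel_size)
  w <- fftshift(axial_wtf(g, system))
  num <- 0; den <- 0
  for (j in seq_along(series$images)) {
    off <- tilt_offset(series$tilts[[j]], shape, series$pixel_size)
    mod <- model_image_wave(estimate, w, off)
    target <- sqrt(series$images[[j]] / mean(series$images[[j]]))
    amp <- Mod(mod$psi_r)
    amp <- amp / sqrt(mean(amp^2))     # same unit-RMS convention as the update
    num <- num + sum((amp - target)^2)
    den <- den + sum(target^2)
  }
  num / den
}

#' @export
print.exit_wave_estimate <- function(x, ...) {
  cat(sprintf("Exit-wave estimate: %d x %d canvas (upsample %d, %.4g nm/px)\n",
              nrow(x$spectrum), ncol(x$spectrum), x$upsample, x$canvas_pixel_size))
  if (length(x$history)) {
    cat(sprintf("  %d iterations, final monitored error %.3e\n",
                length(x$history), x$history[length(x$history)]))
  }
  invisible(x)
}
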