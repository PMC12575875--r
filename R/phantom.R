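# Synthetic specimen phantoms: complex transmission functions (or stacks of
# thin phase slices) that stand in for atomistic specimen models. Kinds:
#   lattice   - Gaussian phase bumps on a square lattice (crystalline foil)
#   blobs     - randomly placed soft discs (particles such as protein shells)
#   ice       - zero-mean band-passed Gaussian noise phase (amorphous ice)
#   composite - blobs embedded in ice

#' Build a synthetic specimen phantom
#'
#' Generates a deterministic (seeded) complex specimen transmission on a
#' real-space grid, represented as one or more thin slices each holding a
#' phase-shift field (radians) and an amplitude-attenuation field in (0, 1].
#' A single-slice phantom with amplitude a(r) and phase phi(r) is equivalent
#' to the transmission O(r) = a(r) exp(i phi(r)).
#'
#' @param kind One of `"lattice"`, `"blobs"`, `"ice"`, `"composite"`.
#' @param shape Integer (rows, cols); at least 64 x 64.
#' @param pixel_size Pixel size in nm.
#' @param params Named list of kind-specific parameters:
#'   * lattice: `spacing` (nm), `peak_phase` (rad), `sigma` (bump width, nm;
#'     default `spacing/4`);
#'   * blobs: `n`, `radius_range` (nm, length 2), `peak_phase` (rad);
#'   * ice: `k_lo`, `k_hi` (band-pass radii, 1/nm), `rms_phase` (rad);
#'   * composite: union of the blobs and ice parameter sets.
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical phantom.
#' @param n_slices Number of slices the phase is split across (default 1).
#' @param slice_thickness Slice thickness in nm (default 0: thin object).
#' @return Object of class `phantom` with fields `kind`, `phase` (list of
#'   matrices, radians), `amplitude` (list of matrices), `pixel_size`,
#'   `slice_thickness`.
#' @export
make_phantom <- function(kind, shape, pixel_size, params = list(), seed = 1L,
                         n_slices = 1L, slice_thickness = 0) {
  kind <- match.arg(kind, c("lattice", "blobs", "ice", "composite"))
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L)
  if (any(shape < 64L)) stop("phantom `shape` must be at least 64 x 64", call. = FALSE)
  if (slice_thickness < 0) stop("`slice_thickness` must be >= 0", call. = FALSE)

  set.seed(as.integer(seed))
  phase <- switch(kind,
    lattice = phantom_lattice(shape, pixel_size, params),
    blobs = phantom_blobs(shape, pixel_size, params),
    ice = phantom_ice(shape, pixel_size, params),
    composite = phantom_blobs(shape, pixel_size, params) +
                phantom_ice(shape, pixel_size, params)
  )
  if (max(abs(phase)) > pi / 2) {
    warning("phantom peak phase exceeds pi/2; weak-phase assumptions may not hold")
  }
  amp <- matrix(1, shape[1], shape[2])

  # split the projected phase evenly across slices
  n_slices <- max(1L, as.integer(n_slices))
  structure(list(
    kind = kind,
    phase = replicate(n_slices, phase / n_slices, simplify = FALSE),
    amplitude = replicate(n_slices, if (identical(n_slices, 1L)) amp else amp^(1 / n_slices),
                          simplify = FALSE),
    pixel_size = pixel_size,
    slice_thickness = slice_thickness,
    seed = as.integer(seed)
  ), class = "phantom")
}

phantom_lattice <- function(shape, px, params) {
  d <- params$spacing %||% 0.235
  peak <- params$peak_phase %||% 0.05
  sigma <- params$sigma %||% (d / 4)
  x <- (seq_len(shape[1]) - 1) * px
  y <- (seq_len(shape[2]) - 1) * px
  # fold coordinates into one lattice cell; Gaussian bump at the cell centre
  ux <- (x %% d) - d / 2
  uy <- (y %% d) - d / 2
  bump <- outer(exp(-ux^2 / (2 * sigma^2)), exp(-uy^2 / (2 * sigma^2)))
  peak * bump
}

phantom_blobs <- function(shape, px, params) {
  n <- params$n %||% 12L
  rr <- params$radius_range %||% (c(0.04, 0.10) * shape[1] * px)
  peak <- params$peak_phase %||% 0.05
  extent <- shape * px
  phase <- matrix(0, shape[1], shape[2])
  x <- (seq_len(shape[1]) - 0.5) * px
  y <- (seq_len(shape[2]) - 0.5) * px
  for (i in seq_len(n)) {
    cx <- stats::runif(1, 0, extent[1])
    cy <- stats::runif(1, 0, extent[2])
    r0 <- stats::runif(1, rr[1], rr[2])
    h <- peak * stats::runif(1, 0.5, 1)
    # soft-edged disc (raised cosine over the outer 30% of the radius)
    dist <- sqrt(outer((x - cx)^2, (y - cy)^2, `+`))
    prof <- ifelse(dist <= 0.7 * r0, 1,
                   ifelse(dist >= r0, 0, 0.5 * (1 + cos(pi * (dist - 0.7 * r0) / (0.3 * r0)))))
    phase <- phase + h * prof
  }
  phase
}

phantom_ice <- function(shape, px, params) {
  k_lo <- params$k_lo %||% (0.05 / px / 2)   # default band inside Nyquist
  k_hi <- params$k_hi %||% (0.60 / px / 2)
  rms <- params$rms_phase %||% 0.03
  g <- frequency_grid(shape, px)
  noise <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  band <- (g$kr >= k_lo & g$kr <= k_hi) * 1
  filt <- Re(ifft2(fft2(noise) * band))
  s <- stats::sd(as.vector(filt))
  if (s == 0) return(filt)
  (filt - mean(filt)) / s * rms
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complex transmission of a thin (single-slice-equivalent) phantom
#'
#' Collapses all slices into one projected transmission
#' O(r) = prod_s a_s(r) exp(i phi_s(r)), valid when inter-slice propagation
#' is negligible.
#'
#' @param phantom A [make_phantom()] object.
#' @return Complex matrix.
#' @export
phantom_transmission <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  amp <- Reduce(`*`, phantom$amplitude)
  phase <- Reduce(`+`, phantom$phase)
  amp * exp(1i * phase)
}
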