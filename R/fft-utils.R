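# Small Fourier helpers shared by the forward model, preprocessing and PIE.
# All 2-D transforms use stats::fft on matrices; the inverse is normalized
# by length(x) so fft2/ifft2 are exact inverses.

#' Two-dimensional discrete Fourier transform
#'
#' Thin wrappers around [stats::fft()] for matrices. `ifft2` divides by the
#' number of elements so that `ifft2(fft2(x))` recovers `x` to machine
#' precision.
#'
#' @param x A numeric or complex matrix.
#' @return A complex matrix of the same shape.
#' @export
fft2 <- function(x) stats::fft(x)

#' @rdname fft2
#' @export
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' DFT sample frequencies
#'
#' Frequencies in cycles per unit length for an `n`-point transform with
#' sample spacing `d`, in the unshifted FFT ordering (zero frequency first,
#' then positive, then negative frequencies).
#'
#' @param n Number of samples.
#' @param d Sample spacing (e.g. pixel size in nm); frequencies come out in
#'   1/unit of `d`.
#' @return Numeric vector of length `n`.
#' @export
fft_freqs <- function(n, d = 1) {
  idx <- 0:(n - 1L)
  idx[idx >= ceiling(n / 2)] <- idx[idx >= ceiling(n / 2)] - n
  idx / (n * d)
}

#' Shift the zero-frequency component to (from) the array centre
#'
#' `fftshift` moves the zero-frequency element of an unshifted spectrum to
#' the centre `(floor(n/2)+1, floor(m/2)+1)`; `ifftshift` is its exact
#' inverse (they differ for odd dimensions).
#'
#' @param x A matrix.
#' @return A matrix of the same shape.
#' @export
fftshift <- function(x) {
  d <- dim(x)
  i <- c(seq(floor(d[1] / 2) + 1L, d[1]), seq_len(floor(d[1] / 2)))
  j <- c(seq(floor(d[2] / 2) + 1L, d[2]), seq_len(floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  d <- dim(x)
  i <- c(seq(ceiling(d[1] / 2) + 1L, d[1]), seq_len(ceiling(d[1] / 2)))
  j <- c(seq(ceiling(d[2] / 2) + 1L, d[2]), seq_len(ceiling(d[2] / 2)))
  x[i, j, drop = FALSE]
}

#' Subpixel image translation via the Fourier shift theorem
#'
#' Translates the content of `x` by `shift` pixels (row, column), i.e.
#' `out(r) = in(r - shift)` under circular boundary conditions. Non-integer
#' shifts are exact in the band-limited sense.
#'
#' @param x Real or complex matrix.
#' @param shift Length-2 numeric vector, pixels along (row, column).
#' @return Matrix of the same shape; real input returns the real part.
#' @export
fourier_shift <- function(x, shift) {
  stopifnot(length(shift) == 2L)
  d <- dim(x)
  fr <- fft_freqs(d[1])
  fc <- fft_freqs(d[2])
  ramp <- exp(-2i * pi * (outer(fr * shift[1], rep(1, d[2])) +
                          outer(rep(1, d[1]), fc * shift[2])))
  out <- ifft2(fft2(x) * ramp)
  if (is.complex(x)) out else Re(out)
}
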