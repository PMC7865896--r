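#' Angular-spectrum transfer function
#'
#' Builds the free-space transfer function H(eps, eta) for scalar
#' propagation over a signed distance z:
#' \deqn{H = \exp\left(j z \frac{2\pi}{\lambda}
#'   \sqrt{1 - (\lambda\epsilon)^2 - (\lambda\eta)^2}\right)}
#' on the propagating band \eqn{(\lambda\epsilon)^2 + (\lambda\eta)^2 < 1},
#' and exactly 0 on the evanescent band (hard cutoff, no apodization).
#' Frequencies eps, eta are cycles per meter on the standard DFT grid
#' (spacing `1/(N * pixel_pitch)`, DC at the \[1,1\] corner). A negative
#' distance yields the complex conjugate of the positive-distance mask on
#' the propagating band, which is what makes [propagate()] invertible for
#' band-limited fields.
#'
#' @param geometry An [optical_geometry()].
#' @param distance Signed propagation distance in meters (positive: towards
#'   the sensor; negative: back towards the object).
#' @return A complex matrix of dimension `grid_rows x grid_cols`.
#' @examples
#' g <- optical_geometry(grid_rows = 16, grid_cols = 16)
#' H <- angular_spectrum_transfer(g, 0.5e-3)
#' H[1, 1]  # DC: exp(2i*pi*z/lambda)
#' @export
angular_spectrum_transfer <- function(geometry, distance) {
  stopifnot(is.numeric(distance), length(distance) == 1L, is.finite(distance))
  nr <- geometry$grid_rows
  nc <- geometry$grid_cols
  lambda <- geometry$wavelength
  pitch <- geometry$pixel_pitch

  fr <- dft_frequencies(nr, pitch) # cycles per meter, rows
  fc <- dft_frequencies(nc, pitch) # cycles per meter, cols

  # 1 - (lambda*eps)^2 - (lambda*eta)^2 over the full grid
  arg <- outer((lambda * fr)^2, (lambda * fc)^2, `+`)
  root2 <- 1 - arg
  propagating <- root2 > 0
  if (!any(propagating[-1])) {
    # only DC (or nothing) propagates: the sampling is grossly sub-wavelength
    stop("degenerate geometry: the entire non-DC frequency grid is evanescent",
      call. = FALSE
    )
  }
  H <- matrix(0 + 0i, nr, nc)
  H[propagating] <- exp(1i * distance * (2 * pi / lambda) * sqrt(root2[propagating]))
  H
}

# DFT frequency coordinates in cycles per meter, DC first (corner convention)
dft_frequencies <- function(n, pitch) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * pitch)
}

#' Propagate a complex field through free space
#'
#' Angular-spectrum propagation: the field's 2-D spectrum is multiplied by
#' [angular_spectrum_transfer()] and transformed back. Exact scalar
#' propagation (no Fresnel approximation); evanescent components are
#' removed, so total energy never increases and is conserved exactly for
#' band-limited fields. No zero padding is applied by default; `pad_factor`
#' embeds the field in a grid enlarged by a power of two to suppress
#' wrap-around for large distances.
#'
#' @param field A [complex_field()].
#' @param distance Signed distance in meters.
#' @param pad_factor Integer >= 1; power of two enlargement of the working
#'   grid (1 = plain transform, the default).
#' @return A [complex_field()] on the same grid. The `plane` tag flips
#'   between `"sensor"` and `"object"` when `abs(distance)` equals the
#'   geometry's `z2`.
#' @export
propagate <- function(field, distance, pad_factor = 1L) {
  stopifnot(inherits(field, "complex_field"))
  pad_factor <- as.integer(pad_factor)
  if (pad_factor < 1L || bitwAnd(pad_factor, pad_factor - 1L) != 0L) {
    stop("`pad_factor` must be a power of two >= 1", call. = FALSE)
  }
  g <- field$geometry
  v <- field$values
  if (pad_factor > 1L) {
    nr <- nrow(v) * pad_factor
    nc <- ncol(v) * pad_factor
    big <- matrix(0 + 0i, nr, nc)
    r0 <- (nr - nrow(v)) %/% 2
    c0 <- (nc - ncol(v)) %/% 2
    big[r0 + seq_len(nrow(v)), c0 + seq_len(ncol(v))] <- v
    gbig <- optical_geometry(
      wavelength = g$wavelength, z2 = g$z2, pixel_pitch = g$pixel_pitch,
      grid_rows = nr, grid_cols = nc, z1 = g$z1
    )
    H <- angular_spectrum_transfer(gbig, distance)
    out <- stats::fft(stats::fft(big) * H, inverse = TRUE) / length(big)
    v <- out[r0 + seq_len(nrow(field$values)), c0 + seq_len(ncol(field$values))]
  } else {
    H <- angular_spectrum_transfer(g, distance)
    v <- stats::fft(stats::fft(v) * H, inverse = TRUE) / length(v)
  }
  plane <- field$plane
  if (isTRUE(all.equal(abs(distance), g$z2))) {
    plane <- if (identical(field$plane, "sensor")) "object" else "sensor"
  }
  complex_field(v, g, plane)
}
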