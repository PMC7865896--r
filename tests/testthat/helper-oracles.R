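# Shared fixtures and independent oracles, built in code at test time.

# default small geometry for fast tests
small_geometry <- function(n = 64L) {
  optical_geometry(grid_rows = n, grid_cols = n)
}

# direct O(N^2) 2-D DFT / inverse DFT, loop-free over output but summing
# over all input pixels per frequency: independent of stats::fft
direct_dft <- function(x, inverse = FALSE) {
  m <- nrow(x)
  n <- ncol(x)
  sgn <- if (inverse) 1 else -1
  out <- matrix(0 + 0i, m, n)
  for (u in 0:(m - 1)) {
    for (v in 0:(n - 1)) {
      ph <- exp(sgn * 2i * pi * (u * (0:(m - 1)) / m))
      pw <- exp(sgn * 2i * pi * (v * (0:(n - 1)) / n))
      out[u + 1, v + 1] <- sum(x * outer(ph, pw))
    }
  }
  if (inverse) out / (m * n) else out
}

# loop evaluation of the angular-spectrum transfer function, written
# directly from the formula and independent of the vectorized path
direct_transfer <- function(geometry, distance) {
  nr <- geometry$grid_rows
  nc <- geometry$grid_cols
  lambda <- geometry$wavelength
  pitch <- geometry$pixel_pitch
  freq <- function(k, n) {
    k <- k - 1
    if (k >= ceiling(n / 2)) k <- k - n
    k / (n * pitch)
  }
  H <- matrix(0 + 0i, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      eps <- freq(r, nr)
      eta <- freq(c, nc)
      s <- 1 - (lambda * eps)^2 - (lambda * eta)^2
      if (s > 0) {
        H[r, c] <- exp(1i * distance * (2 * pi / lambda) * sqrt(s))
      }
    }
  }
  H
}

# remove all evanescent content from a complex matrix for a given geometry
band_limit <- function(values, geometry, distance = geometry$z2) {
  H <- angular_spectrum_transfer(geometry, distance)
  sp <- stats::fft(values)
  sp[H == 0] <- 0
  stats::fft(sp, inverse = TRUE) / length(sp)
}

random_band_limited_field <- function(geometry, seed = 1) {
  set.seed(seed)
  n <- geometry$grid_rows * geometry$grid_cols
  v <- matrix(
    complex(real = rnorm(n), imaginary = rnorm(n)),
    geometry$grid_rows, geometry$grid_cols
  )
  complex_field(band_limit(v, geometry), geometry, "object")
}

# binary disc mask on an n x n grid; centers as rows of (row, col)
disc_mask <- function(centers, radius_px, n = 256L) {
  m <- matrix(FALSE, n, n)
  ri <- matrix(seq_len(n), n, n)
  ci <- t(ri)
  for (k in seq_len(nrow(centers))) {
    m <- m | ((ri - centers[k, 1])^2 + (ci - centers[k, 2])^2 <= radius_px^2)
  }
  m
}

# amplitude image of bright background with darker discs, as the counting
# pipeline sees after recovery
disc_amplitude <- function(cell_centers, particle_centers, radius_px,
                           n = 256L, cell_level = 0.7, particle_level = 0.3) {
  img <- matrix(1, n, n)
  if (!is.null(cell_centers) && nrow(cell_centers) > 0) {
    img[disc_mask(cell_centers, radius_px, n)] <- cell_level
  }
  if (!is.null(particle_centers) && nrow(particle_centers) > 0) {
    img[disc_mask(particle_centers, radius_px, n)] <- particle_level
  }
  img
}

# mean intensity over concentric radial bins around a center
radial_profile <- function(img, center, n_bins = 40, r_max = NULL) {
  ri <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  ci <- t(matrix(seq_len(ncol(img)), ncol(img), nrow(img)))
  r <- sqrt((ri - center[1])^2 + (ci - center[2])^2)
  if (is.null(r_max)) r_max <- min(dim(img)) / 4
  bins <- cut(r[r <= r_max], breaks = seq(0, r_max, length.out = n_bins + 1))
  as.numeric(tapply(img[r <= r_max], bins, mean))
}

count_local_extrema <- function(profile) {
  p <- profile[is.finite(profile)]
  d <- diff(p)
  sum(diff(sign(d)) != 0)
}
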