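#' Optical geometry of the lensless recording setup
#'
#' Bundles the physical parameters shared by every propagation, simulation
#' and reconstruction step: illumination wavelength, sample-to-sensor
#' distance, sensor pixel pitch and grid dimensions. All lengths are in
#' meters (SI); helper constructors for the config layer convert from the
#' unit-suffixed YAML fields.
#'
#' @param wavelength Illumination wavelength in meters (default 587e-9,
#'   a yellow LED).
#' @param z2 Sample-to-sensor distance in meters (default 0.5e-3). Must be
#'   positive; backward propagation is expressed through the signed
#'   `distance` argument of [propagate()], never by a negative `z2`.
#' @param pixel_pitch Sensor pixel pitch in meters (default 1.12e-6).
#' @param grid_rows,grid_cols Grid dimensions in pixels (>= 2).
#' @param z1 Source-to-sample distance in meters; carried as metadata only
#'   (plane-wave illumination is assumed), default 5e-2.
#'
#' @return An object of class `optical_geometry`.
#' @examples
#' geom <- optical_geometry(grid_rows = 256, grid_cols = 256)
#' geom
#' @export
optical_geometry <- function(wavelength = 587e-9,
                             z2 = 0.5e-3,
                             pixel_pitch = 1.12e-6,
                             grid_rows = 512L,
                             grid_cols = 512L,
                             z1 = 5e-2) {
  stopifnot(
    is.numeric(wavelength), length(wavelength) == 1L, is.finite(wavelength),
    wavelength > 0,
    is.numeric(z2), length(z2) == 1L, is.finite(z2), z2 > 0,
    is.numeric(pixel_pitch), length(pixel_pitch) == 1L, is.finite(pixel_pitch),
    pixel_pitch > 0,
    grid_rows >= 2, grid_cols >= 2
  )
  structure(
    list(
      wavelength = as.numeric(wavelength),
      z2 = as.numeric(z2),
      z1 = as.numeric(z1),
      pixel_pitch = as.numeric(pixel_pitch),
      grid_rows = as.integer(grid_rows),
      grid_cols = as.integer(grid_cols)
    ),
    class = "optical_geometry"
  )
}

#' @export
print.optical_geometry <- function(x, ...) {
  cat("<optical_geometry>\n")
  cat(sprintf("  wavelength : %.1f nm\n", x$wavelength * 1e9))
  cat(sprintf("  z2         : %.3f mm\n", x$z2 * 1e3))
  cat(sprintf("  pixel pitch: %.2f um\n", x$pixel_pitch * 1e6))
  cat(sprintf("  grid       : %d x %d px\n", x$grid_rows, x$grid_cols))
  invisible(x)
}

geometry_dim <- function(geometry) {
  c(geometry$grid_rows, geometry$grid_cols)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf(
      "%s must have identical dimensions (got %s vs %s)", what,
      paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' A complex optical field sampled on the sensor/object grid
#'
#' Thin container for a 2-D complex amplitude together with its
#' [optical_geometry()] and a tag naming the plane it lives in. All
#' propagation and phase-recovery state flows through this type.
#'
#' @param values Complex (or numeric, promoted to complex) matrix whose
#'   dimensions match the geometry. Must be finite.
#' @param geometry An [optical_geometry()].
#' @param plane Either `"object"` or `"sensor"`.
#'
#' @return An object of class `complex_field` with elements `values`,
#'   `geometry`, `plane`.
#' @export
complex_field <- function(values, geometry, plane = c("sensor", "object")) {
  plane <- match.arg(plane)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!identical(dim(values), as.integer(geometry_dim(geometry)))) {
    stop(sprintf(
      "field shape %s does not match geometry %s",
      paste(dim(values), collapse = "x"),
      paste(geometry_dim(geometry), collapse = "x")
    ), call. = FALSE)
  }
  if (is.numeric(values)) values <- values + 0i
  if (!is.complex(values)) stop("`values` must be numeric or complex", call. = FALSE)
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values)))) {
    stop("field contains non-finite entries", call. = FALSE)
  }
  structure(
    list(values = values, geometry = geometry, plane = plane),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf(
    "<complex_field> %d x %d at %s plane, energy %.6g\n",
    nrow(x$values), ncol(x$values), x$plane, field_energy(x)
  ))
  invisible(x)
}

#' Total energy of a complex field
#'
#' Sum of squared moduli over the grid. Conserved by [propagate()] for
#' fields with no evanescent content.
#'
#' @param field A [complex_field()] or a complex/numeric matrix.
#' @return A non-negative scalar.
#' @export
field_energy <- function(field) {
  v <- if (inherits(field, "complex_field")) field$values else field
  sum(Mod(v)^2)
}
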