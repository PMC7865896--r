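#' Ground-truth phantoms and simulated sensor recordings
#'
#' The simulator is the package's source of test data: semi-transparent
#' phantoms are described by a complex transmittance map t(x0, y0) = 1 +
#' dt(x0, y0) with |dt| small (weak-object regime), imaged through
#' [propagate()] onto the sensor where only the intensity is recorded.
#'
#' @name simulator
NULL

new_phantom <- function(transmittance, objects, geometry, seed = NA_integer_,
                        kind = "disc", elements = NULL) {
  structure(
    list(
      transmittance = transmittance,
      objects = objects,
      geometry = geometry,
      seed = seed,
      kind = kind,
      elements = elements,
      max_dt = max(Mod(transmittance - 1))
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %s, %d x %d px, %d objects, max|dt| = %.3f\n",
    x$kind, nrow(x$transmittance), ncol(x$transmittance),
    nrow(x$objects), x$max_dt
  ))
  invisible(x)
}

empty_objects <- function() {
  data.frame(
    center_row = integer(0), center_col = integer(0),
    radius_m = numeric(0), class = character(0),
    amplitude_transmittance = numeric(0), phase_shift = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Disc phantom mimicking a cell/particle smear
#'
#' Places hard-edged discs of two classes on a unit-transmittance field:
#' "cells" (weakly absorbing, higher amplitude transmittance) and
#' "particles" (polystyrene-bead-like, more strongly absorbing). The
#' returned object metadata is the exact ground truth used by the counting
#' tests. Placement is rejection sampling with a seeded RNG; positions are
#' reproducible bit-for-bit for a given seed.
#'
#' @param geometry An [optical_geometry()].
#' @param n_cells,n_particles Number of discs per class.
#' @param cell_radius_m,particle_radius_m Disc radii in meters (defaults:
#'   7.5e-6, i.e. 15 um diameter beads/cells).
#' @param cell_transmittance,particle_transmittance Amplitude transmittance
#'   in \[0, 1\] inside the disc (defaults 0.7 and 0.3: particles darker
#'   than cells, mirroring their higher refractive index).
#' @param cell_phase,particle_phase Phase shift in radians inside the disc
#'   (defaults 0).
#' @param min_separation_m Minimum center-to-center distance. The default
#'   `2.4 * max(radius)` keeps discs well separated; values below two radii
#'   deliberately allow touching/overlapping discs for watershed tests.
#' @param margin_px Margin from the image border within which no center is
#'   placed (default: 3 radii in pixels); set to 0 to allow border-clipped
#'   objects.
#' @param seed Integer seed for placement.
#' @return A `phantom` object: complex `transmittance` matrix, `objects`
#'   data.frame (center_row, center_col in pixels, radius_m, class,
#'   amplitude_transmittance, phase_shift), `geometry`, `seed`.
#' @export
make_disc_phantom <- function(geometry,
                              n_cells = 0L,
                              n_particles = 0L,
                              cell_radius_m = 7.5e-6,
                              particle_radius_m = 7.5e-6,
                              cell_transmittance = 0.7,
                              particle_transmittance = 0.3,
                              cell_phase = 0,
                              particle_phase = 0,
                              min_separation_m = NULL,
                              margin_px = NULL,
                              seed = 1L) {
  stopifnot(
    n_cells >= 0, n_particles >= 0,
    cell_transmittance >= 0, cell_transmittance <= 1,
    particle_transmittance >= 0, particle_transmittance <= 1
  )
  nr <- geometry$grid_rows
  nc <- geometry$grid_cols
  pitch <- geometry$pixel_pitch
  rmax <- max(cell_radius_m, particle_radius_m)
  if (is.null(min_separation_m)) min_separation_m <- 2.4 * rmax
  if (is.null(margin_px)) margin_px <- ceiling(3 * rmax / pitch)

  n_total <- n_cells + n_particles
  classes <- c(rep("cell", n_cells), rep("particle", n_particles))
  radii <- ifelse(classes == "cell", cell_radius_m, particle_radius_m)
  amp <- ifelse(classes == "cell", cell_transmittance, particle_transmittance)
  phs <- ifelse(classes == "cell", cell_phase, particle_phase)

  centers <- matrix(NA_real_, n_total, 2)
  if (n_total > 0) {
    lo_r <- 1 + margin_px
    hi_r <- nr - margin_px
    lo_c <- 1 + margin_px
    hi_c <- nc - margin_px
    if (lo_r >= hi_r || lo_c >= hi_c) {
      stop("discs do not fit: margin exceeds the field", call. = FALSE)
    }
    sep_px <- min_separation_m / pitch
    placed <- 0L
    with_seed(seed, {
      attempts <- 0L
      max_attempts <- 2000L * n_total
      while (placed < n_total && attempts < max_attempts) {
        attempts <- attempts + 1L
        cand <- c(
          lo_r + stats::runif(1) * (hi_r - lo_r),
          lo_c + stats::runif(1) * (hi_c - lo_c)
        )
        ok <- TRUE
        if (placed > 0L) {
          d <- sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2)
          ok <- all(d >= sep_px)
        }
        if (ok) {
          placed <- placed + 1L
          centers[placed, ] <- cand
        }
      }
    })
    if (placed < n_total) {
      stop(sprintf(
        "impossible packing: placed %d of %d discs (grid %dx%d, separation %.1f px)",
        placed, n_total, nr, nc, sep_px
      ), call. = FALSE)
    }
  }

  t_map <- matrix(1 + 0i, nr, nc)
  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(n_total)) {
    r_px <- radii[k] / pitch
    inside <- (row_idx - centers[k, 1])^2 + (col_idx - centers[k, 2])^2 <= r_px^2
    t_map[inside] <- amp[k] * exp(1i * phs[k])
  }

  objects <- if (n_total > 0) {
    data.frame(
      center_row = centers[, 1], center_col = centers[, 2],
      radius_m = radii, class = classes,
      amplitude_transmittance = amp, phase_shift = phs,
      stringsAsFactors = FALSE
    )
  } else {
    empty_objects()
  }
  new_phantom(t_map, objects, geometry, seed = as.integer(seed), kind = "disc")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' USAF-1951 three-bar resolution phantom
#'
#' Renders horizontal and vertical three-bar elements for the requested
#' groups using the standard USAF-1951 layout: element e of group g has
#' line-pair frequency `2^(g + (e-1)/6)` lp/mm, bar width `0.5/f` and bar
#' length 5x the width. Elements whose bar width falls below one pixel at
#' the geometry's pitch are skipped (and recorded as such). Bounding boxes
#' of every rendered element are returned for later contrast probing.
#'
#' @param geometry An [optical_geometry()].
#' @param groups Integer vector of USAF groups to render (default 6).
#' @param elements Integer vector of elements within each group (1..6).
#' @param dark_transmittance Amplitude transmittance of the chrome bars
#'   (default 0.1; the surround is clear, t = 1).
#' @return A `phantom` whose `elements` field is a data.frame with one row
#'   per rendered (group, element, orientation): bounding box in pixels,
#'   bar width in pixels, lp/mm, and a `rendered` flag.
#' @export
make_usaf_phantom <- function(geometry, groups = 6L, elements = 1:6,
                              dark_transmittance = 0.1) {
  stopifnot(all(elements >= 1), all(elements <= 6))
  nr <- geometry$grid_rows
  nc <- geometry$grid_cols
  pitch <- geometry$pixel_pitch
  t_map <- matrix(1 + 0i, nr, nc)

  specs <- expand.grid(element = sort(elements), group = sort(groups))
  recs <- list()
  # column-wise layout: each (group, element) gets a block containing the
  # horizontal-bar and vertical-bar patterns side by side
  cursor_row <- 6L
  cursor_col <- 6L
  row_block_max <- 0L
  for (k in seq_len(nrow(specs))) {
    g <- specs$group[k]
    e <- specs$element[k]
    f_lpmm <- usaf_frequency(g, e)
    bar_w_m <- 0.5 / (f_lpmm * 1e3) # meters
    bar_w <- bar_w_m / pitch # pixels, fractional
    if (bar_w < 1) {
      recs[[length(recs) + 1L]] <- data.frame(
        group = g, element = e, orientation = NA_character_,
        row0 = NA_integer_, row1 = NA_integer_,
        col0 = NA_integer_, col1 = NA_integer_,
        bar_width_px = bar_w, lp_per_mm = f_lpmm, rendered = FALSE
      )
      next
    }
    bw <- max(1L, round(bar_w))
    bl <- 5L * bw # bar length
    # element footprint: three bars + two gaps (gap = bar width)
    ext <- 5L * bw # across-bar extent
    block_h <- max(bl, ext)
    block_w <- bl + 3L * bw + ext
    if (cursor_col + block_w + 6L > nc) {
      cursor_col <- 6L
      cursor_row <- cursor_row + row_block_max + 6L
      row_block_max <- 0L
    }
    if (cursor_row + block_h + 6L > nr) {
      recs[[length(recs) + 1L]] <- data.frame(
        group = g, element = e, orientation = NA_character_,
        row0 = NA_integer_, row1 = NA_integer_,
        col0 = NA_integer_, col1 = NA_integer_,
        bar_width_px = bar_w, lp_per_mm = f_lpmm, rendered = FALSE
      )
      next
    }
    dark <- dark_transmittance + 0i

    # horizontal bars (long axis along columns, stacked along rows)
    r0 <- cursor_row
    c0 <- cursor_col
    for (b in 0:2) {
      rr <- r0 + b * 2L * bw
      t_map[rr:(rr + bw - 1L), c0:(c0 + bl - 1L)] <- dark
    }
    recs[[length(recs) + 1L]] <- data.frame(
      group = g, element = e, orientation = "horizontal",
      row0 = r0, row1 = r0 + ext - 1L, col0 = c0, col1 = c0 + bl - 1L,
      bar_width_px = bw, lp_per_mm = f_lpmm, rendered = TRUE
    )

    # vertical bars (long axis along rows, side by side along columns)
    c0v <- c0 + bl + 3L * bw
    for (b in 0:2) {
      cc <- c0v + b * 2L * bw
      t_map[r0:(r0 + bl - 1L), cc:(cc + bw - 1L)] <- dark
    }
    recs[[length(recs) + 1L]] <- data.frame(
      group = g, element = e, orientation = "vertical",
      row0 = r0, row1 = r0 + bl - 1L, col0 = c0v, col1 = c0v + ext - 1L,
      bar_width_px = bw, lp_per_mm = f_lpmm, rendered = TRUE
    )

    cursor_col <- cursor_col + block_w + 6L
    row_block_max <- max(row_block_max, block_h)
  }
  elements_df <- do.call(rbind, recs)
  new_phantom(t_map, empty_objects(), geometry,
    kind = "usaf", elements = elements_df
  )
}

new_sensor_image <- function(intensity, geometry, kind, bit_depth = "float") {
  stopifnot(all(intensity >= 0))
  structure(
    list(
      intensity = intensity, geometry = geometry,
      kind = kind, bit_depth = bit_depth
    ),
    class = "sensor_image"
  )
}

#' @export
print.sensor_image <- function(x, ...) {
  cat(sprintf(
    "<sensor_image> %s, %d x %d px, mean intensity %.4g\n",
    x$kind, nrow(x$intensity), ncol(x$intensity), mean(x$intensity)
  ))
  invisible(x)
}

apply_noise <- function(intensity, noise_model, seed) {
  if (is.null(noise_model) || identical(noise_model$type, "none")) {
    return(intensity)
  }
  out <- with_seed(seed, switch(noise_model$type,
    poisson = {
      s <- noise_model$photon_scale
      matrix(stats::rpois(length(intensity), intensity * s) / s,
        nrow(intensity), ncol(intensity)
      )
    },
    gaussian = intensity +
      matrix(stats::rnorm(length(intensity), 0, noise_model$sigma),
        nrow(intensity), ncol(intensity)
      ),
    stop(sprintf("unknown noise model '%s'", noise_model$type), call. = FALSE)
  ))
  pmax(out, 0)
}

#' Noise model constructors for the simulator
#'
#' @param photon_scale Expected photon count per unit intensity.
#' @param sigma Additive Gaussian standard deviation in intensity units.
#' @return A list describing the noise model, for [record_hologram()].
#' @export
noise_none <- function() list(type = "none")

#' @rdname noise_none
#' @export
noise_poisson <- function(photon_scale = 1e4) {
  stopifnot(photon_scale > 0)
  list(type = "poisson", photon_scale = photon_scale)
}

#' @rdname noise_none
#' @export
noise_gaussian <- function(sigma = 0.01) {
  stopifnot(sigma >= 0)
  list(type = "gaussian", sigma = sigma)
}

#' Record a simulated in-line hologram
#'
#' Forward model of the recording: a unit-amplitude plane wave passes
#' through the phantom's transmittance, propagates z2 to the sensor by the
#' angular-spectrum method, and the sensor records the intensity
#' `I = |P[z2](A t)|^2`. Optional shot/read noise is applied afterwards
#' and the result clipped at zero. With no objects and no noise the record
#' equals the background exactly.
#'
#' @param phantom A `phantom` from [make_disc_phantom()] or
#'   [make_usaf_phantom()].
#' @param geometry Optional [optical_geometry()]; defaults to the
#'   phantom's own.
#' @param illumination_amplitude Plane-wave amplitude A (default 1).
#' @param noise_model See [noise_none()], [noise_poisson()],
#'   [noise_gaussian()].
#' @param seed Seed for the noise draw.
#' @return A `sensor_image` of kind `"hologram"`.
#' @export
record_hologram <- function(phantom, geometry = NULL,
                            illumination_amplitude = 1,
                            noise_model = noise_none(), seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), illumination_amplitude >= 0)
  if (is.null(geometry)) geometry <- phantom$geometry
  check_same_shape(phantom$transmittance,
    matrix(0, geometry$grid_rows, geometry$grid_cols),
    what = "phantom and geometry grids"
  )
  f0 <- complex_field(illumination_amplitude * phantom$transmittance,
    geometry,
    plane = "object"
  )
  fz <- propagate(f0, geometry$z2)
  intensity <- Mod(fz$values)^2
  intensity <- apply_noise(intensity, noise_model, seed)
  new_sensor_image(intensity, geometry, kind = "hologram")
}

#' Record a sample-free background image
#'
#' Identical to [record_hologram()] with unit transmittance everywhere:
#' with no noise the record is the uniform reference intensity A^2.
#'
#' @inheritParams record_hologram
#' @return A `sensor_image` of kind `"background"`.
#' @export
record_background <- function(geometry, illumination_amplitude = 1,
                              noise_model = noise_none(), seed = 1L) {
  stopifnot(illumination_amplitude >= 0)
  intensity <- matrix(
    illumination_amplitude^2,
    geometry$grid_rows, geometry$grid_cols
  )
  intensity <- apply_noise(intensity, noise_model, seed)
  new_sensor_image(intensity, geometry, kind = "background")
}

#' Binary object mask of a phantom
#'
#' Pixels where the transmittance departs from unity.
#'
#' @param phantom A `phantom`.
#' @return A logical matrix.
#' @export
phantom_mask <- function(phantom) {
  Mod(phantom$transmittance - 1) > 1e-12
}
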