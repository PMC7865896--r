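#' Read a grayscale intensity image
#'
#' Reads 8/16-bit PNG or (float or integer) TIFF into a numeric matrix.
#' Color images are averaged to grayscale. PNG values arrive in \[0, 1\]
#' (the decoder's convention); float TIFFs are returned as stored.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (length(pages) == 2L && length(pages[[2]]) == 1L) {
        # second page is the 1x1 reciprocal-scale marker (see write_image)
        pages[[1]] * (1 / as.numeric(pages[[2]]))
      } else {
        pages[[1]]
      }
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale image
#'
#' PNG output is quantized to 8 or 16 bits after scaling to the image
#' maximum. TIFF output is 32-bit float, the quantitative format: values
#' above 1 are rescaled for the encoder and the reciprocal scale stored as
#' a 1x1 second page, so [read_image()] recovers the original values to
#' single precision. The scale factor is returned invisibly.
#'
#' @param image Numeric matrix.
#' @param path Destination ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth 8 or 16 (PNG only).
#' @return Invisibly, the scale factor the pixels were divided by.
#' @export
write_image <- function(image, path, bit_depth = 16L) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  ext <- tolower(tools::file_ext(path))
  scale <- max(image, 1e-12)
  switch(ext,
    png = png::writePNG(pmin(pmax(image / scale, 0), 1), path,
      dpi = NULL, asp = NULL
    ),
    tif = ,
    tiff = {
      if (any(image < 0)) {
        stop("TIFF output stores non-negative images only", call. = FALSE)
      }
      # the encoder stores [0, 1] only; values above 1 are rescaled and the
      # reciprocal scale (itself in (0, 1]) kept as a 1x1 second page so
      # read_image() can undo the scaling exactly
      scale <- max(image, 1)
      what <- if (scale > 1) {
        list(image / scale, matrix(1 / scale))
      } else {
        image
      }
      tiff::writeTIFF(what, path,
        bits.per.sample = 32L, compression = "none", reduce = FALSE
      )
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(scale)
}

#' Load a run configuration from YAML
#'
#' The on-disk format uses unit-suffixed names (`wavelength_nm`, `z2_mm`,
#' `pixel_um`) to keep units explicit; they are converted to SI here, at
#' the boundary, and never used internally. Missing blocks fall back to
#' the documented defaults (587 nm, 0.5 mm, 1.12 um pixels, 512x512).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list merged over the file contents.
#' @return A list of class `run_config` with elements `geometry`
#'   (an [optical_geometry()]), `recovery` (a [recovery_config()]),
#'   `metrics`, `counting`, `seed`, `output_dir`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  g <- raw$geometry %||% list()
  geometry <- optical_geometry(
    wavelength = (g$wavelength_nm %||% 587) * 1e-9,
    z2 = (g$z2_mm %||% 0.5) * 1e-3,
    pixel_pitch = (g$pixel_um %||% 1.12) * 1e-6,
    grid_rows = g$rows %||% 512L,
    grid_cols = g$cols %||% 512L
  )
  r <- raw$recovery %||% list()
  recovery <- recovery_config(
    max_iterations = r$max_iterations %||% 15L,
    convergence_tol = r$convergence_tol %||% 1e-3,
    background_mode = r$background_mode %||% "divide",
    support_method = r$support_method %||% "otsu",
    support_threshold = r$support_threshold,
    support_dilation_px = r$support_dilation_px %||% 2L,
    support_update_every = r$support_update_every %||% 0L,
    m_region = r$m_region %||% "outside_support"
  )
  m <- raw$metrics %||% list()
  metrics <- list(
    contrast_threshold = m$contrast_threshold %||% 0.1,
    kernel_id = attr(oblique_kernel(), "id")
  )
  cfg_c <- raw$counting %||% list()
  counting <- list(
    class_thresholds = if (!is.null(cfg_c$cell_threshold)) {
      c(cell = cfg_c$cell_threshold, particle = cfg_c$particle_threshold)
    } else {
      NULL
    },
    min_area_px = cfg_c$min_area_px %||% 20L,
    border_policy = cfg_c$border_policy %||% "remove",
    min_separation_px = cfg_c$min_separation_px %||% 7
  )
  structure(
    list(
      geometry = geometry, recovery = recovery, metrics = metrics,
      counting = counting,
      seed = raw$seed %||% 1L,
      output_dir = raw$output_dir %||% "."
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# serializable echo of a run_config (SI converted back to display units)
config_echo <- function(config) {
  g <- config$geometry
  list(
    geometry = list(
      wavelength_nm = g$wavelength * 1e9, z2_mm = g$z2 * 1e3,
      pixel_um = g$pixel_pitch * 1e6, rows = g$grid_rows, cols = g$grid_cols
    ),
    recovery = unclass(config$recovery),
    metrics = config$metrics,
    counting = config$counting,
    seed = config$seed
  )
}

write_manifest <- function(path, files, config, extra = list()) {
  hashes <- vapply(files, function(f) {
    unname(tools::md5sum(f))
  }, character(1))
  manifest <- c(
    list(
      files = as.list(hashes),
      config = config_echo(config)
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
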