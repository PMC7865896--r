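#' Remove the reference-light term from a recorded hologram
#'
#' The recorded intensity contains the reference light |A'|^2 plus the
#' interference terms carrying the object information. A sample-free
#' background exposure estimates |A'|^2 so it can be removed before
#' amplitude extraction: division (the default; also flattens illumination
#' non-uniformity), subtraction (re-centered at the background mean and
#' floored at zero), or left untouched.
#'
#' @param hologram A `sensor_image` of kind hologram, or a non-negative
#'   matrix.
#' @param background Optional `sensor_image`/matrix of the same shape.
#' @param mode One of `"divide"`, `"subtract"`, `"none"`.
#' @return A non-negative numeric matrix: the normalized intensity.
#' @export
normalize_hologram <- function(hologram, background = NULL,
                               mode = c("divide", "subtract", "none")) {
  mode <- match.arg(mode)
  I <- as_intensity(hologram)
  if (identical(mode, "none")) {
    return(I)
  }
  if (is.null(background)) {
    stop("`background` is required for mode '", mode, "'", call. = FALSE)
  }
  B <- as_intensity(background)
  check_same_shape(I, B, "hologram and background")
  if (all(B == 0)) stop("background is identically zero", call. = FALSE)
  switch(mode,
    divide = I / pmax(B, .Machine$double.eps),
    subtract = pmax(I - B + mean(B), 0)
  )
}

as_intensity <- function(x) {
  if (inherits(x, "sensor_image")) x <- x$intensity
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a sensor_image or a numeric matrix", call. = FALSE)
  }
  if (any(x < 0)) stop("intensity must be non-negative", call. = FALSE)
  x
}

#' Backpropagation decoding of a hologram
#'
#' The square root of the (normalized) intensity is taken as the field
#' modulus at the sensor, the phase assumed zero, and the field propagated
#' back over -z2 to the object plane. This is the plain single-shot
#' reconstruction; its twin-image artifact is what the iterative loop of
#' [iterate_phase_recovery()] suppresses. It also serves as iteration-one
#' state of that loop.
#'
#' @param normalized_intensity Non-negative matrix (see
#'   [normalize_hologram()]).
#' @param geometry An [optical_geometry()].
#' @return A [complex_field()] at the object plane.
#' @export
backpropagate_hologram <- function(normalized_intensity, geometry) {
  I <- as_intensity(normalized_intensity)
  f <- complex_field(sqrt(I), geometry, plane = "sensor")
  propagate(f, -geometry$z2)
}

#' Estimate the object support by threshold segmentation
#'
#' For absorbing samples the object-plane modulus is darker inside objects
#' than in the surround, so the support is `modulus < threshold`. The
#' threshold is Otsu's by default; the raw mask is then closed and dilated
#' a few pixels so that the support safely covers object edges.
#'
#' @param object_field A [complex_field()] at the object plane (or a
#'   numeric modulus matrix).
#' @param method `"otsu"` or `"fixed_threshold"`.
#' @param threshold_value Threshold on the modulus for
#'   `"fixed_threshold"`; ignored for `"otsu"`.
#' @param dilation_px Radius of the final dilation (default 2).
#' @return An object of class `support_mask`: logical `mask` plus the
#'   parameters used. A constant-modulus field yields an all-false mask
#'   with a warning.
#' @export
estimate_support <- function(object_field,
                             method = c("otsu", "fixed_threshold"),
                             threshold_value = NULL,
                             dilation_px = 2L) {
  method <- match.arg(method)
  modulus <- if (inherits(object_field, "complex_field")) {
    Mod(object_field$values)
  } else {
    object_field
  }
  stopifnot(is.matrix(modulus), all(is.finite(modulus)))
  rng <- range(modulus)
  if (diff(rng) < 1e-12) {
    warning("constant-modulus field: empty support", call. = FALSE)
    return(structure(
      list(
        mask = matrix(FALSE, nrow(modulus), ncol(modulus)),
        method = method, threshold_value = NA_real_,
        dilation_px = as.integer(dilation_px)
      ),
      class = "support_mask"
    ))
  }
  thr <- switch(method,
    otsu = {
      scaled <- (modulus - rng[1]) / diff(rng)
      EBImage::otsu(scaled, range = c(0, 1)) * diff(rng) + rng[1]
    },
    fixed_threshold = {
      if (is.null(threshold_value)) {
        stop("`threshold_value` required for fixed_threshold", call. = FALSE)
      }
      threshold_value
    }
  )
  mask <- modulus < thr
  if (any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L, shape = "disc")
    m <- EBImage::closing(mask * 1, brush)
    m <- EBImage::dilate(m, brush)
    mask <- m > 0.5
  }
  structure(
    list(
      mask = mask, method = method, threshold_value = thr,
      dilation_px = as.integer(dilation_px)
    ),
    class = "support_mask"
  )
}

#' @export
print.support_mask <- function(x, ...) {
  cat(sprintf(
    "<support_mask> %d x %d, %d px inside (%.1f%%), %s threshold %.4g\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask),
    100 * mean(x$mask), x$method, x$threshold_value
  ))
  invisible(x)
}

#' Configuration of the iterative phase-recovery loop
#'
#' @param max_iterations Iteration cap (default 15; the loop typically
#'   converges before it).
#' @param convergence_tol Relative L2 change of the object-plane modulus
#'   between successive iterations below which the loop stops
#'   (default 1e-3).
#' @param background_mode How the reference light is removed; see
#'   [normalize_hologram()].
#' @param support_method,support_threshold,support_dilation_px Support
#'   estimation parameters; see [estimate_support()].
#' @param support_update_every Recompute the support every k iterations;
#'   the default 0 freezes it after iteration 1 (deterministic and the
#'   recommended setting).
#' @param m_region Region over which the iteration coefficient m (the
#'   scalar matching the replaced outside-support field to the
#'   backpropagated background level) is averaged: `"outside_support"`
#'   (default) or `"full_field"`.
#' @return A list of class `recovery_config`.
#' @export
recovery_config <- function(max_iterations = 15L,
                            convergence_tol = 1e-3,
                            background_mode = c("divide", "subtract", "none"),
                            support_method = c("otsu", "fixed_threshold"),
                            support_threshold = NULL,
                            support_dilation_px = 2L,
                            support_update_every = 0L,
                            m_region = c("outside_support", "full_field")) {
  stopifnot(max_iterations >= 1, convergence_tol > 0)
  structure(
    list(
      max_iterations = as.integer(max_iterations),
      convergence_tol = convergence_tol,
      background_mode = match.arg(background_mode),
      support_method = match.arg(support_method),
      support_threshold = support_threshold,
      support_dilation_px = as.integer(support_dilation_px),
      support_update_every = as.integer(support_update_every),
      m_region = match.arg(m_region)
    ),
    class = "recovery_config"
  )
}

#' Iterative support-constrained phase recovery
#'
#' Suppresses the twin image of in-line holography by alternating
#' constraints between the object and sensor planes:
#'
#' 1. The square root of the normalized hologram is backpropagated to the
#'    object plane with zero initial phase (the naive reconstruction).
#' 2. An object support S is estimated by threshold segmentation of the
#'    object-plane modulus. Outside S the field is replaced by `m * D`,
#'    where D is the backpropagation of the square root of the (normalized)
#'    background and the iteration coefficient
#'    `m = mean(|U|) / mean(|D|)` matches the levels (averaged outside S
#'    by default); inside S the field is kept.
#' 3. The constrained field is propagated forward to the sensor, its phase
#'    kept, and its modulus reset to the square root of the recorded
#'    hologram; the result is backpropagated to the object plane.
#'
#' Steps 2-3 repeat until the relative L2 change of the object-plane
#' modulus drops below `convergence_tol` or `max_iterations` is reached.
#' The loop contains no randomness: identical inputs give bit-identical
#' results.
#'
#' @param hologram `sensor_image` or non-negative matrix.
#' @param background Optional `sensor_image`/matrix; if absent a uniform
#'   field at the hologram's mean level is used for both normalization
#'   fallback and the D term (with a warning).
#' @param geometry An [optical_geometry()]; defaults to the hologram's.
#' @param config A [recovery_config()].
#' @return An object of class `recovery_result`: `object_field` (the
#'   recovered [complex_field()] at the object plane), `support`,
#'   `iterations_run`, `residual_history`, `converged`, `naive_field`
#'   (the plain backpropagation, kept for comparison) and `sensor_field`
#'   (the last sensor-plane field, whose modulus equals the square root of
#'   the normalized hologram by construction).
#' @export
iterate_phase_recovery <- function(hologram, background = NULL,
                                   geometry = NULL,
                                   config = recovery_config()) {
  stopifnot(inherits(config, "recovery_config"))
  if (is.null(geometry)) {
    if (!inherits(hologram, "sensor_image")) {
      stop("`geometry` is required when `hologram` is a bare matrix",
        call. = FALSE
      )
    }
    geometry <- hologram$geometry
  }
  I_raw <- as_intensity(hologram)

  if (is.null(background)) {
    if (!identical(config$background_mode, "none")) {
      warning(
        "no background supplied: using a uniform field at the hologram mean",
        call. = FALSE
      )
    }
    B <- matrix(mean(I_raw), nrow(I_raw), ncol(I_raw))
  } else {
    B <- as_intensity(background)
    check_same_shape(I_raw, B, "hologram and background")
  }

  mode <- config$background_mode
  I_norm <- if (identical(mode, "none")) {
    I_raw
  } else {
    normalize_hologram(I_raw, B, mode)
  }
  # the background seen through the same normalization (uniform for divide)
  B_norm <- if (identical(mode, "none")) B else normalize_hologram(B, B, mode)

  amp_sensor <- sqrt(I_norm)
  U <- backpropagate_hologram(I_norm, geometry)
  naive <- U
  D <- backpropagate_hologram(B_norm, geometry)

  support <- estimate_support(U,
    method = config$support_method,
    threshold_value = config$support_threshold,
    dilation_px = config$support_dilation_px
  )
  if (!any(support$mask)) {
    warning("empty support: returning the plain backpropagation", call. = FALSE)
    return(structure(
      list(
        object_field = U, support = support, iterations_run = 1L,
        residual_history = 0, converged = TRUE, naive_field = naive,
        config = config
      ),
      class = "recovery_result"
    ))
  }

  residuals <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  sensor_field <- NULL
  outside <- !support$mask
  for (i in seq_len(config$max_iterations)) {
    iterations <- i
    if (config$support_update_every > 0L && i > 1L &&
      (i - 1L) %% config$support_update_every == 0L) {
      support <- estimate_support(U,
        method = config$support_method,
        threshold_value = config$support_threshold,
        dilation_px = config$support_dilation_px
      )
      if (!any(support$mask)) {
        iterations <- i - 1L
        break
      }
      outside <- !support$mask
    }
    region <- if (identical(config$m_region, "outside_support")) outside else TRUE
    m <- mean(Mod(U$values)[region]) / mean(Mod(D$values)[region])

    constrained <- U$values
    constrained[outside] <- m * D$values[outside]

    V <- propagate(complex_field(constrained, geometry, "object"), geometry$z2)
    sensor_field <- complex_field(amp_sensor * exp(1i * Arg(V$values)),
      geometry, "sensor")
    U_next <- propagate(sensor_field, -geometry$z2)

    rel <- sqrt(sum((Mod(U_next$values) - Mod(U$values))^2)) /
      sqrt(sum(Mod(U$values)^2))
    residuals <- c(residuals, rel)
    U <- U_next
    if (rel < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      object_field = U, support = support, iterations_run = iterations,
      residual_history = residuals, converged = converged,
      naive_field = naive, sensor_field = sensor_field, config = config
    ),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "<recovery_result> %d iteration(s), %s (last residual %.3g)\n",
    x$iterations_run,
    if (x$converged) "converged" else "not converged",
    if (length(x$residual_history)) utils::tail(x$residual_history, 1) else NA
  ))
  invisible(x)
}

#' Recovered amplitude image
#'
#' Convenience accessor: the modulus of the recovered object-plane field,
#' the image fed to the quality metrics and the counting pipeline.
#'
#' @param result A `recovery_result`.
#' @param naive If `TRUE`, return the plain backpropagation modulus
#'   instead.
#' @return A numeric matrix.
#' @export
recovered_amplitude <- function(result, naive = FALSE) {
  stopifnot(inherits(result, "recovery_result"))
  Mod((if (naive) result$naive_field else result$object_field)$values)
}
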