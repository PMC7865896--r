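#' Oblique differential kernel used by the edge-energy metric
#'
#' A fixed, versioned 3x3 kernel: a diagonal first difference summed with
#' its mirror, responding to edges along both diagonals and vanishing on
#' constants. The kernel's identity string is recorded in metric reports
#' so results remain comparable across versions.
#'
#' @return A 3x3 numeric matrix with attribute `id`.
#' @export
oblique_kernel <- function() {
  k1 <- matrix(c(
    0, 0, -1,
    0, 1, 0,
    0, 0, 0
  ), 3, 3, byrow = TRUE)
  k <- k1 + t(k1) # add the mirrored diagonal difference
  attr(k, "id") <- "oblique-diag-3x3-v1"
  k
}

#' Oblique edge energy of an image
#'
#' Convolves the image with the [oblique_kernel()] (valid region only, no
#' padding) and sums the absolute responses:
#' \deqn{S = \sum_i \sum_j |y_f(i, j)|}
#' A constant image has zero edge energy; blur strictly reduces it on any
#' non-constant image.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return A non-negative scalar.
#' @export
oblique_edge_energy <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  k <- oblique_kernel()
  if (nrow(image) < nrow(k) || ncol(image) < ncol(k)) {
    stop("image smaller than the 3x3 kernel", call. = FALSE)
  }
  sum(abs(correlate_valid(image, k)))
}

# valid-mode 2-D correlation via shifted sub-matrices (kernel is small)
correlate_valid <- function(image, kernel) {
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  nr <- nrow(image) - kr + 1L
  nc <- ncol(image) - kc + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w != 0) {
        out <- out + w * image[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
      }
    }
  }
  out
}

#' Blur coefficient Kblur
#'
#' Ratio of the oblique edge energy of a test image to that of a reference
#' image: `Kblur = S_out / S_in`. For a blurred (lower-quality) test image
#' the value lies in (0, 1), and the closer to 1 the sharper the test
#' image; noise or ringing can push the ratio above 1 because spurious
#' structure adds edge energy.
#'
#' @param reference_image,test_image Numeric matrices of equal shape; the
#'   reference plays the "input" role (e.g. a 10x microscope image).
#' @return A non-negative scalar.
#' @export
kblur <- function(reference_image, test_image) {
  check_same_shape(reference_image, test_image, "reference and test images")
  s_in <- oblique_edge_energy(reference_image)
  if (s_in == 0) stop("reference image has zero edge energy", call. = FALSE)
  oblique_edge_energy(test_image) / s_in
}

#' Full-reference quality index Q
#'
#' A single global score combining correlation, luminance and contrast
#' agreement between a reference image x and a test image y:
#' \deqn{Q = \frac{4\,\sigma_{xy}\,\bar x\,\bar y}
#'   {(\sigma_x^2 + \sigma_y^2)\,(\bar x^2 + \bar y^2)}}
#' with pixel means, variances and the covariance all computed over the
#' whole image with the same n-1 normalization, so that Q(x, x) = 1
#' exactly. The value lies in \[-1, 1\]; negative values indicate
#' anti-correlation about the mean.
#'
#' @param reference_image,test_image Numeric matrices of equal shape, not
#'   both constant.
#' @return A scalar in \[-1, 1\].
#' @export
quality_index <- function(reference_image, test_image) {
  check_same_shape(reference_image, test_image, "reference and test images")
  x <- as.numeric(reference_image)
  y <- as.numeric(test_image)
  mx <- mean(x)
  my <- mean(y)
  vx <- stats::var(x)
  vy <- stats::var(y)
  cxy <- stats::cov(x, y)
  denom <- (vx + vy) * (mx^2 + my^2)
  if (denom == 0) {
    stop("quality index undefined: both images are constant", call. = FALSE)
  }
  4 * cxy * mx * my / denom
}

#' Assemble a metric report for a reference/test image pair
#'
#' @param reference_image,test_image Numeric matrices of equal shape.
#' @param reference_id,test_id Identifier strings echoed in the report.
#' @return A one-row data.frame with columns `reference_id`, `test_id`,
#'   `kblur`, `q_index`, `filter_kernel_id`.
#' @export
metric_report <- function(reference_image, test_image,
                          reference_id = "reference", test_id = "test") {
  data.frame(
    reference_id = reference_id,
    test_id = test_id,
    kblur = kblur(reference_image, test_image),
    q_index = quality_index(reference_image, test_image),
    filter_kernel_id = attr(oblique_kernel(), "id"),
    stringsAsFactors = FALSE
  )
}

#' USAF-1951 element frequency
#'
#' Line-pair frequency of element `element` in group `group` of the
#' USAF-1951 resolution target: `2^(group + (element - 1)/6)` line pairs
#' per millimeter. Frequencies double every six elements, i.e. from one
#' group to the next at the same element.
#'
#' @param group Integer group index (may be negative).
#' @param element Element index in 1..6.
#' @return Frequency in line pairs per mm.
#' @examples
#' usaf_frequency(6, 1) # 64
#' usaf_frequency(6, 4) # 90.51
#' @export
usaf_frequency <- function(group, element) {
  if (any(element < 1) || any(element > 6)) {
    stop("`element` must be in 1..6", call. = FALSE)
  }
  2^(group + (element - 1) / 6)
}

#' Determine the resolution limit from a rendered USAF target image
#'
#' For every rendered element of a [make_usaf_phantom()] layout, in both
#' bar orientations, the across-bar intensity profile is extracted
#' (averaged along the bars) and the three bars are tested for separation:
#' each bar level must sit below its neighbouring gap levels with a
#' Michelson contrast `(gap - bar) / (gap + bar)` of at least
#' `contrast_threshold`. The finest element resolved in both orientations
#' is reported with its [usaf_frequency()].
#'
#' @param image Numeric intensity/amplitude matrix covering the phantom's
#'   grid.
#' @param layout Either the `phantom` returned by [make_usaf_phantom()] or
#'   its `elements` data.frame.
#' @param contrast_threshold Minimum Michelson contrast (default 0.1).
#' @return A list `(group, element, lp_per_mm, resolved)` where `resolved`
#'   is a data.frame of per-element outcomes; `group`/`element` are `NA`
#'   and `lp_per_mm` 0 when nothing is resolved.
#' @export
resolve_limit <- function(image, layout, contrast_threshold = 0.1) {
  elements <- if (inherits(layout, "phantom")) {
    layout$elements
  } else if (is.data.frame(layout)) {
    layout
  } else {
    layout$elements
  }
  if (!is.data.frame(elements)) {
    stop("missing USAF layout metadata", call. = FALSE)
  }
  stopifnot(is.matrix(image))

  rendered <- elements[!is.na(elements$orientation) & elements$rendered, ]
  if (nrow(rendered) == 0) stop("layout contains no rendered elements", call. = FALSE)

  keys <- unique(rendered[, c("group", "element")])
  out <- data.frame(
    group = keys$group, element = keys$element,
    lp_per_mm = usaf_frequency(keys$group, keys$element),
    min_contrast = NA_real_, resolved = FALSE
  )
  for (k in seq_len(nrow(keys))) {
    rows <- rendered[rendered$group == keys$group[k] &
      rendered$element == keys$element[k], ]
    if (nrow(rows) < 2) next # need both orientations
    contrasts <- vapply(seq_len(nrow(rows)), function(i) {
      element_contrast(image, rows[i, ])
    }, numeric(1))
    out$min_contrast[k] <- min(contrasts)
    out$resolved[k] <- all(contrasts >= contrast_threshold)
  }
  res <- out[out$resolved, ]
  if (nrow(res) == 0) {
    return(list(group = NA_integer_, element = NA_integer_, lp_per_mm = 0,
      resolved = out))
  }
  best <- res[which.max(res$lp_per_mm), ]
  list(
    group = best$group, element = best$element,
    lp_per_mm = best$lp_per_mm, resolved = out
  )
}

# Worst-case Michelson contrast of the three bars of one element,
# measured on the across-bar profile averaged along the bars.
element_contrast <- function(image, rec) {
  sub <- image[rec$row0:rec$row1, rec$col0:rec$col1, drop = FALSE]
  profile <- if (identical(rec$orientation, "horizontal")) {
    rowMeans(sub) # bars stacked along rows
  } else {
    colMeans(sub) # bars side by side along columns
  }
  bw <- rec$bar_width_px
  n <- length(profile)
  # bar centers at offsets 0, 2bw, 4bw; gaps between at bw, 3bw
  centers <- function(start) {
    idx <- round(start + bw / 2)
    max(1L, min(n, idx))
  }
  bar_lvl <- vapply(c(0, 2, 4) * bw, function(s) profile[centers(s)], numeric(1))
  gap_lvl <- vapply(c(1, 3) * bw, function(s) profile[centers(s)], numeric(1))
  # each bar against its adjacent gap(s)
  pairs <- rbind(
    c(bar_lvl[1], gap_lvl[1]),
    c(bar_lvl[2], gap_lvl[1]),
    c(bar_lvl[2], gap_lvl[2]),
    c(bar_lvl[3], gap_lvl[2])
  )
  cmin <- min(apply(pairs, 1, function(p) {
    if (p[2] + p[1] <= 0) return(-1)
    (p[2] - p[1]) / (p[2] + p[1])
  }))
  cmin
}
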