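#' Three-class pixel classification of a recovered amplitude image
#'
#' Splits pixels into background, cell and particle by two intensity
#' thresholds. In recovered amplitude images the surround is bright
#' (near 1), weakly absorbing low-refractive-index cells are darker, and
#' high-refractive-index polystyrene particles darker still, so intensity
#' alone separates the classes. Thresholds default to Otsu-derived
#' multi-level values: a first Otsu split isolates objects from
#' background, a second Otsu split of the object pixels separates the two
#' classes.
#'
#' The thresholds are named by class: `c(cell = a, particle = b)`. Pixels
#' at or above `max(a, b)` are background; pixels below `min(a, b)` take
#' the class whose threshold is the smaller value (the darker class);
#' pixels in between take the other class. Swapping the two values
#' therefore swaps the class labels exactly.
#'
#' @param amplitude_image Numeric matrix (recovered modulus, or simulator
#'   ground truth in tests).
#' @param class_thresholds Named numeric vector `c(cell=, particle=)`, or
#'   `NULL` for Otsu defaults.
#' @return An integer matrix of class `class_map` with levels 0 =
#'   background, 1 = cell, 2 = particle, and attribute `thresholds`.
#' @export
classify_pixels <- function(amplitude_image, class_thresholds = NULL) {
  stopifnot(is.matrix(amplitude_image), all(is.finite(amplitude_image)))
  img <- amplitude_image
  rng <- range(img)
  if (is.null(class_thresholds)) {
    if (diff(rng) < 1e-12) {
      stop("degenerate histogram: constant image, supply thresholds",
        call. = FALSE
      )
    }
    scaled <- (img - rng[1]) / diff(rng)
    t_bg <- EBImage::otsu(scaled, range = c(0, 1)) * diff(rng) + rng[1]
    obj <- img[img < t_bg]
    t_split <- if (length(obj) > 1 && diff(range(obj)) > 1e-12) {
      s2 <- (obj - min(obj)) / diff(range(obj))
      EBImage::otsu(matrix(s2, nrow = 1), range = c(0, 1)) *
        diff(range(obj)) + min(obj)
    } else {
      t_bg # no sub-split possible: everything darker is one class
    }
    class_thresholds <- c(cell = t_bg, particle = t_split)
  }
  if (is.null(names(class_thresholds)) ||
    !setequal(names(class_thresholds), c("cell", "particle"))) {
    stop("`class_thresholds` must be named c(cell=, particle=)", call. = FALSE)
  }
  hi <- max(class_thresholds)
  lo <- min(class_thresholds)
  darker_class <- names(class_thresholds)[which.min(class_thresholds)]
  lighter_class <- setdiff(c("cell", "particle"), darker_class)

  out <- matrix(0L, nrow(img), ncol(img))
  code <- c(cell = 1L, particle = 2L)
  out[img < hi & img >= lo] <- code[[lighter_class]]
  out[img < lo] <- code[[darker_class]]
  structure(out, class = c("class_map", class(out)),
    thresholds = class_thresholds)
}

#' Clean class masks: border, size and hole rules
#'
#' Applies the edge-incompleteness rule (objects touching the image border
#' are removed), a minimum-area rule, and interior hole filling, per
#' class. Removed-object counts are reported separately for the two
#' rules.
#'
#' @param class_map A `class_map` from [classify_pixels()] (or an integer
#'   matrix with levels 0/1/2).
#' @param min_area_px Minimum object area in pixels (default 20).
#' @param border_policy `"remove"` (default) drops components touching
#'   the border; `"keep"` retains them.
#' @return A list of class `clean_masks`: logical `cell` and `particle`
#'   masks plus `n_removed_edge` and `n_removed_small` totals.
#' @export
clean_and_binarize <- function(class_map, min_area_px = 20L,
                               border_policy = c("remove", "keep")) {
  border_policy <- match.arg(border_policy)
  removed_edge <- 0L
  removed_small <- 0L
  clean_one <- function(mask) {
    if (!any(mask)) {
      return(mask)
    }
    lab <- EBImage::bwlabel(mask * 1)
    ids <- seq_len(max(lab))
    if (identical(border_policy, "remove")) {
      border_ids <- unique(c(
        lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]
      ))
      border_ids <- border_ids[border_ids > 0]
      removed_edge <<- removed_edge + length(border_ids)
      mask[lab %in% border_ids] <- FALSE
      lab[lab %in% border_ids] <- 0L
    }
    if (any(lab > 0)) {
      areas <- tabulate(lab[lab > 0])
      small_ids <- which(areas > 0 & areas < min_area_px)
      removed_small <<- removed_small + length(small_ids)
      mask[lab %in% small_ids] <- FALSE
    }
    if (any(mask)) {
      mask <- EBImage::fillHull(mask * 1) > 0.5
    }
    mask
  }
  cell <- clean_one(class_map == 1L)
  particle <- clean_one(class_map == 2L)
  structure(
    list(
      cell = cell, particle = particle,
      n_removed_edge = removed_edge, n_removed_small = removed_small
    ),
    class = "clean_masks"
  )
}

#' Split touching objects by distance-transform watershed
#'
#' Adherent convex objects merge into one connected component; the
#' watershed of the (negated) distance transform, seeded at distance-map
#' maxima with a minimum separation, splits them. Two overlapping discs
#' separate into two labels once their centers are about 1.2 radii apart
#' (below that the saddle between the distance-map peaks is shallower than
#' the discretization ripple and the pair is kept as one object); a single
#' convex disc is never over-split.
#'
#' @param binary_mask Logical matrix.
#' @param min_separation_px Minimum seed separation in pixels, typically
#'   the expected object radius (default 7).
#' @return An integer label matrix (0 background, 1..n objects,
#'   8-connected), labels in raster order of object centroids.
#' @export
split_touching <- function(binary_mask, min_separation_px = 7) {
  stopifnot(is.matrix(binary_mask))
  mask <- binary_mask > 0
  if (!any(mask)) {
    return(matrix(0L, nrow(mask), ncol(mask)))
  }
  dm <- EBImage::distmap(mask * 1)
  # the tolerance (watershed basin depth) scales with the expected radius:
  # the saddle between two discs one radius apart is ~0.13 r deep, while
  # discretization ripples on a single convex disc stay well below 0.5 px
  tol <- max(0.5, 0.1 * min_separation_px)
  lab <- EBImage::watershed(dm, tolerance = tol, ext = 1)
  relabel_raster_order(as.matrix(lab))
}

# deterministic labeling: ids assigned in raster order of centroids
relabel_raster_order <- function(lab) {
  n <- max(lab)
  if (n == 0) {
    return(matrix(0L, nrow(lab), ncol(lab)))
  }
  cent <- object_centroids(lab)
  ord <- order(round(cent[, "row"]), round(cent[, "col"]))
  remap <- integer(n)
  remap[cent[ord, "id"]] <- seq_len(n)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

object_centroids <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  rows <- row(lab)[lab > 0]
  cols <- col(lab)[lab > 0]
  vals <- lab[lab > 0]
  cbind(
    id = ids,
    row = tapply(rows, vals, mean)[as.character(ids)],
    col = tapply(cols, vals, mean)[as.character(ids)],
    area = tapply(rows, vals, length)[as.character(ids)]
  )
}

#' Segment, classify and count cells and particles
#'
#' End of the counting pipeline: runs [classify_pixels()],
#' [clean_and_binarize()] and [split_touching()] per class, merges the
#' label images and tallies the survivors.
#'
#' @param amplitude_image Numeric matrix (recovered amplitude).
#' @param class_thresholds See [classify_pixels()].
#' @param min_area_px,border_policy See [clean_and_binarize()].
#' @param min_separation_px See [split_touching()].
#' @return An object of class `count_report`: `n_cells`, `n_particles`,
#'   `n_removed_edge`, `n_removed_small`, a `per_object` data.frame
#'   (id, class, centroid_row, centroid_col, area_px) and the merged
#'   `labels` matrix with a class map attribute.
#' @export
count_objects <- function(amplitude_image, class_thresholds = NULL,
                          min_area_px = 20L,
                          border_policy = "remove",
                          min_separation_px = 7) {
  cm <- classify_pixels(amplitude_image, class_thresholds)
  masks <- clean_and_binarize(cm, min_area_px, border_policy)
  count_from_masks(masks, min_separation_px)
}

#' Count objects from cleaned class masks
#'
#' Lower-level entry used by [count_objects()]; takes the `clean_masks`
#' directly so tests can bypass classification.
#'
#' @param masks A `clean_masks` list.
#' @param min_separation_px See [split_touching()].
#' @return A `count_report`; see [count_objects()].
#' @export
count_from_masks <- function(masks, min_separation_px = 7) {
  lab_cell <- split_touching(masks$cell, min_separation_px)
  lab_part <- split_touching(masks$particle, min_separation_px)
  n_cell <- max(lab_cell)
  n_part <- max(lab_part)

  labels <- lab_cell
  labels[lab_part > 0] <- lab_part[lab_part > 0] + n_cell
  classes <- c(rep("cell", n_cell), rep("particle", n_part))

  # final deterministic ordering across both classes
  if (max(labels) > 0) {
    cent <- object_centroids(labels)
    ord <- order(round(cent[, "row"]), round(cent[, "col"]))
    remap <- integer(max(labels))
    remap[cent[ord, "id"]] <- seq_len(max(labels))
    out <- matrix(0L, nrow(labels), ncol(labels))
    nz <- labels > 0
    out[nz] <- remap[labels[nz]]
    classes <- classes[cent[ord, "id"]]
    labels <- out
    cent <- object_centroids(labels)
    per_object <- data.frame(
      id = as.integer(cent[, "id"]),
      class = classes,
      centroid_row = as.numeric(cent[, "row"]),
      centroid_col = as.numeric(cent[, "col"]),
      area_px = as.integer(cent[, "area"]),
      stringsAsFactors = FALSE
    )
  } else {
    per_object <- data.frame(
      id = integer(0), class = character(0),
      centroid_row = numeric(0), centroid_col = numeric(0),
      area_px = integer(0), stringsAsFactors = FALSE
    )
  }

  structure(
    list(
      n_cells = n_cell, n_particles = n_part,
      n_removed_edge = masks$n_removed_edge,
      n_removed_small = masks$n_removed_small,
      per_object = per_object,
      labels = labels
    ),
    class = "count_report"
  )
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf(
    "<count_report> %d cell(s), %d particle(s); removed: %d border, %d small\n",
    x$n_cells, x$n_particles, x$n_removed_edge, x$n_removed_small
  ))
  invisible(x)
}
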