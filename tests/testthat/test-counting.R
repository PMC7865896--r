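test_that("pixel classification separates the two classes by intensity", {
  img <- disc_amplitude(
    cell_centers = rbind(c(60, 60), c(150, 80)),
    particle_centers = rbind(c(100, 180)),
    radius_px = 7, n = 256
  )
  cm <- classify_pixels(img)
  truth_cell <- disc_mask(rbind(c(60, 60), c(150, 80)), 7, 256)
  truth_part <- disc_mask(rbind(c(100, 180)), 7, 256)
  obj <- truth_cell | truth_part
  truth <- matrix(0L, 256, 256)
  truth[truth_cell] <- 1L
  truth[truth_part] <- 2L
  expect_gte(mean(cm[obj] == truth[obj]), 0.95)
  expect_true(all(cm[!obj] == 0L))

  # swapping the two named thresholds swaps the classes exactly
  thr <- attr(cm, "thresholds")
  swapped <- c(cell = unname(thr["particle"]), particle = unname(thr["cell"]))
  cm2 <- classify_pixels(img, swapped)
  expect_true(all((cm == 1L) == (cm2 == 2L)))
  expect_true(all((cm == 2L) == (cm2 == 1L)))

  # uniform image: all background under explicit thresholds, error for Otsu
  flat <- matrix(1, 64, 64)
  expect_true(all(classify_pixels(flat, c(cell = 0.8, particle = 0.5)) == 0L))
  expect_error(classify_pixels(flat), "degenerate")
})

test_that("cleaning removes border and small objects and fills holes", {
  n <- 128
  cm <- matrix(0L, n, n)
  cm[disc_mask(rbind(c(64, 64)), 10, n)] <- 1L # interior cell
  cm[disc_mask(rbind(c(3, 40)), 8, n)] <- 1L # border-clipped cell
  cm[disc_mask(rbind(c(100, 100)), 2, n)] <- 1L # tiny speck
  # annulus: disc with a hole
  ann <- disc_mask(rbind(c(40, 100)), 9, n) & !disc_mask(rbind(c(40, 100)), 4, n)
  cm[ann] <- 1L

  masks <- clean_and_binarize(cm, min_area_px = 20)
  expect_identical(masks$n_removed_edge, 1L)
  expect_identical(masks$n_removed_small, 1L)
  lab <- EBImage::bwlabel(masks$cell * 1)
  expect_equal(max(lab), 2)

  # the annulus hole was filled: area grew to the full disc
  filled_area <- sum(masks$cell & disc_mask(rbind(c(40, 100)), 9, n))
  expect_gte(filled_area, sum(disc_mask(rbind(c(40, 100)), 9, n)) * 0.999)
  expect_gt(filled_area, sum(ann))

  # border policy keep retains the clipped object
  masks_keep <- clean_and_binarize(cm, min_area_px = 20, border_policy = "keep")
  expect_identical(masks_keep$n_removed_edge, 0L)

  # empty input
  empty <- clean_and_binarize(matrix(0L, 32, 32))
  expect_false(any(empty$cell) || any(empty$particle))
  expect_identical(empty$n_removed_edge + empty$n_removed_small, 0L)
})

test_that("watershed splits touching discs but never over-splits singles", {
  # two discs overlapping by 30% of the radius (centers 1.7 r apart)
  r <- 7
  fused <- disc_mask(rbind(c(100, 100), c(100, 100 + 1.7 * r)), r, 256)
  expect_identical(max(split_touching(fused, r)), 2L)

  # 50 seeded single discs: always exactly one label
  set.seed(33)
  for (i in 1:50) {
    ctr <- matrix(c(runif(1, 30, 220), runif(1, 30, 220)), 1)
    lab <- split_touching(disc_mask(ctr, r, 256), r)
    expect_identical(max(lab), 1L)
  }

  expect_identical(max(split_touching(matrix(FALSE, 32, 32))), 0L)
})

test_that("object ids are assigned in raster order of centroids", {
  img <- disc_amplitude(
    cell_centers = rbind(c(200, 30), c(50, 200), c(50, 30)),
    particle_centers = NULL, radius_px = 7, n = 256
  )
  rep <- count_objects(img, c(cell = 0.9, particle = 0.1))
  ord <- order(
    round(rep$per_object$centroid_row),
    round(rep$per_object$centroid_col)
  )
  expect_identical(rep$per_object$id, rep$per_object$id[ord])
  expect_identical(rep$per_object$id, seq_len(nrow(rep$per_object)))
})

test_that("counting is exact on clean non-touching phantom images", {
  # ground-truth amplitude images across 20 seeds
  g <- optical_geometry(grid_rows = 256, grid_cols = 256)
  for (s in 1:20) {
    ph <- make_disc_phantom(g, n_cells = 6, n_particles = 4, seed = s)
    rep <- count_objects(Mod(ph$transmittance))
    expect_identical(rep$n_cells, 6L)
    expect_identical(rep$n_particles, 4L)
  }

  # empty image
  rep0 <- count_objects(matrix(1, 64, 64), c(cell = 0.9, particle = 0.1))
  expect_identical(rep0$n_cells + rep0$n_particles, 0L)
  expect_identical(nrow(rep0$per_object), 0L)
})

test_that("border-straddling objects are removed and reported", {
  n <- 256
  img <- disc_amplitude(
    cell_centers = rbind(c(60, 60), c(120, 120), c(180, 60), c(2, 128),
      c(128, 254), c(250, 200)),
    particle_centers = rbind(c(60, 180), c(200, 140)),
    radius_px = 7, n = n
  )
  # 3 of the 6 cells straddle the border
  rep <- count_objects(img, c(cell = 0.9, particle = 0.5))
  expect_identical(rep$n_cells, 3L)
  expect_identical(rep$n_particles, 2L)
  expect_identical(rep$n_removed_edge, 3L)
  expect_identical(rep$n_cells + rep$n_particles, nrow(rep$per_object))
})

test_that("count error stays within 5% with 20% touching objects", {
  # 20 objects per image, 2 deliberately touching pairs (4 objects = 20%)
  r <- 7
  n <- 320
  for (s in 1:20) {
    set.seed(100 + s)
    centers <- matrix(NA_real_, 0, 2)
    while (nrow(centers) < 16) {
      cand <- c(runif(1, 30, n - 30), runif(1, 30, n - 30))
      if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) > 4 * r) {
        centers <- rbind(centers, cand)
      }
    }
    # turn the first two singles into touching pairs (centers 1.7 r apart)
    pairs <- rbind(
      centers[1, ] + c(0, 1.7 * r),
      centers[2, ] + c(1.7 * r, 0)
    )
    all_centers <- rbind(centers, pairs)
    img <- disc_amplitude(all_centers, NULL, r, n)
    rep <- count_objects(img, c(cell = 0.9, particle = 0.1),
      min_separation_px = r
    )
    expect_identical(rep$n_removed_edge + rep$n_removed_small, 0L)
    expect_lte(abs(rep$n_cells + rep$n_particles - 18L), ceiling(0.05 * 18))
  }
})
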