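test_that("hologram normalization modes behave as documented", {
  g <- small_geometry(64)
  B <- record_background(g, illumination_amplitude = 2)$intensity
  expect_true(all(normalize_hologram(B, B, "divide") == 1))
  expect_equal(normalize_hologram(B, B, "subtract"), B)
  expect_identical(normalize_hologram(B, mode = "none"), B)

  expect_error(normalize_hologram(B, B[1:10, 1:10], "divide"), "dimensions")
  expect_error(normalize_hologram(B, B * 0, "divide"), "zero")

  # simulated hologram normalized by its own background is ~1 off the rings
  g2 <- optical_geometry(grid_rows = 256, grid_cols = 256)
  ph <- make_disc_phantom(g2, n_cells = 1, seed = 4)
  I <- record_hologram(ph, g2)$intensity
  norm <- normalize_hologram(I, record_background(g2)$intensity, "divide")
  ctr <- c(ph$objects$center_row[1], ph$objects$center_col[1])
  ri <- matrix(seq_len(256), 256, 256)
  ci <- t(ri)
  far <- sqrt((ri - ctr[1])^2 + (ci - ctr[2])^2) > 80
  expect_lt(abs(mean(norm[far]) - 1), 1e-3)
})

test_that("backpropagation decodes the object position", {
  g <- optical_geometry(grid_rows = 256, grid_cols = 256)

  # uniform intensity backpropagates to a uniform plane wave
  flat <- backpropagate_hologram(matrix(4, 256, 256), g)
  expect_lt(max(abs(Mod(flat$values) - 2)), 1e-10)
  expect_identical(flat$plane, "object")

  # single-disc hologram: the dark spot localizes the object. The global
  # modulus minimum falls inside the disc (diffraction ringing makes the
  # rim darkest) and the centroid of the darkest 0.5% of pixels recovers
  # the true center to sub-pixel accuracy.
  ph <- make_disc_phantom(g, n_cells = 1, cell_transmittance = 0.2, seed = 21)
  I <- normalize_hologram(
    record_hologram(ph, g)$intensity,
    record_background(g)$intensity, "divide"
  )
  U <- backpropagate_hologram(I, g)
  modulus <- Mod(U$values)
  idx <- arrayInd(which.min(modulus), dim(modulus))
  truth <- c(ph$objects$center_row[1], ph$objects$center_col[1])
  r_px <- ph$objects$radius_m[1] / g$pixel_pitch
  expect_lte(sqrt(sum((idx - truth)^2)), r_px)
  dark <- which(modulus <= stats::quantile(modulus, 0.005), arr.ind = TRUE)
  expect_lt(sqrt(sum((colMeans(dark) - truth)^2)), 2)

  expect_error(backpropagate_hologram(matrix(-1, 256, 256), g), "non-negative")
})

test_that("support estimation finds every disc and covers it", {
  g <- optical_geometry(grid_rows = 256, grid_cols = 256)
  ph <- make_disc_phantom(g, n_cells = 5, n_particles = 3, seed = 31)
  I <- normalize_hologram(
    record_hologram(ph, g)$intensity,
    record_background(g)$intensity, "divide"
  )
  sup <- estimate_support(backpropagate_hologram(I, g))
  lab <- EBImage::bwlabel(sup$mask * 1)
  expect_equal(max(lab), 8)

  # each component overlaps exactly one ground-truth disc, and the support
  # covers each disc's area (dilation guarantee)
  r_px <- ph$objects$radius_m[1] / g$pixel_pitch
  for (k in seq_len(8)) {
    ctr <- round(c(ph$objects$center_row[k], ph$objects$center_col[k]))
    comp <- lab[ctr[1], ctr[2]]
    expect_gt(comp, 0)
    disc <- disc_mask(matrix(ctr, 1), r_px, 256)
    expect_gte(sum(sup$mask & disc), sum(disc) * 0.999)
  }

  # constant field: empty support, flagged
  expect_warning(
    sup0 <- estimate_support(complex_field(matrix(1 + 0i, 16, 16),
      small_geometry(16), "object"
    )),
    "empty support"
  )
  expect_false(any(sup0$mask))
})

test_that("iterative recovery converges and suppresses the twin image", {
  g <- optical_geometry(grid_rows = 256, grid_cols = 256)
  ph <- make_disc_phantom(g,
    n_cells = 10, cell_transmittance = 0.3, seed = 42,
    min_separation_m = 25e-6
  )
  holo <- record_hologram(ph, g)
  bg <- record_background(g)
  res <- iterate_phase_recovery(holo, bg, g, recovery_config())

  expect_true(res$converged)
  expect_lte(res$iterations_run, 15)
  expect_identical(length(res$residual_history), res$iterations_run)
  expect_true(all(res$residual_history >= 0))
  expect_lte(
    res$residual_history[length(res$residual_history)],
    res$residual_history[1]
  )

  # sensor-plane modulus constraint holds exactly on the returned state
  I_norm <- normalize_hologram(holo$intensity, bg$intensity, "divide")
  expect_lt(max(abs(Mod(res$sensor_field$values) - sqrt(I_norm))), 1e-12)

  # twin-image suppression: iterative beats naive in full-field RMSE, and
  # in modulus variance outside the true support
  truth <- Mod(ph$transmittance)
  amp <- recovered_amplitude(res)
  namp <- recovered_amplitude(res, naive = TRUE)
  expect_lt(sqrt(mean((amp - truth)^2)), sqrt(mean((namp - truth)^2)))
  outside <- !phantom_mask(ph)
  expect_lt(stats::var(amp[outside]), stats::var(namp[outside]))

  # determinism: bit-identical rerun
  res2 <- iterate_phase_recovery(holo, bg, g, recovery_config())
  expect_identical(res$object_field$values, res2$object_field$values)
  expect_identical(res$residual_history, res2$residual_history)
})

test_that("empty phantom recovers a uniform field in one iteration", {
  g <- small_geometry(64)
  ph <- make_disc_phantom(g, n_cells = 0)
  holo <- record_hologram(ph, g)
  bg <- record_background(g)
  res <- NULL
  wrns <- capture_warnings(
    res <- iterate_phase_recovery(holo, bg, g, recovery_config())
  )
  expect_match(wrns, "empty support", all = FALSE)
  expect_true(res$converged)
  expect_identical(res$iterations_run, 1L)
  amp <- recovered_amplitude(res)
  expect_lt(diff(range(amp)), 1e-6)
})

test_that("missing background falls back to the hologram mean with a warning", {
  g <- optical_geometry(grid_rows = 128, grid_cols = 128)
  ph <- make_disc_phantom(g, n_cells = 2, seed = 3)
  holo <- record_hologram(ph, g)
  expect_warning(
    res <- iterate_phase_recovery(holo, NULL, g, recovery_config()),
    "uniform field"
  )
  expect_s3_class(res, "recovery_result")
  expect_gte(res$iterations_run, 1L)
})

test_that("recovered modulus rank-orders with ground-truth transmittance", {
  g <- optical_geometry(grid_rows = 256, grid_cols = 256)
  # three distinct transmittance levels: 0.7 (cell), 0.3 (particle) plus a
  # hand-placed disc at 0.5
  ph <- make_disc_phantom(g, n_cells = 1, n_particles = 1,
    cell_transmittance = 0.7, particle_transmittance = 0.3, seed = 12
  )
  t_map <- ph$transmittance
  ctr <- c(200, 200)
  r_px <- 7.5e-6 / g$pixel_pitch
  extra <- disc_mask(matrix(ctr, 1), r_px, 256)
  stopifnot(all(t_map[extra] == 1 + 0i))
  t_map[extra] <- 0.5 + 0i
  ph$transmittance <- t_map
  ph$objects <- rbind(ph$objects, data.frame(
    center_row = ctr[1], center_col = ctr[2], radius_m = 7.5e-6,
    class = "cell", amplitude_transmittance = 0.5, phase_shift = 0
  ))

  res <- iterate_phase_recovery(
    record_hologram(ph, g), record_background(g), g, recovery_config()
  )
  amp <- recovered_amplitude(res)
  per_obj <- vapply(seq_len(nrow(ph$objects)), function(k) {
    d <- disc_mask(matrix(round(c(
      ph$objects$center_row[k],
      ph$objects$center_col[k]
    )), 1), r_px * 0.7, 256)
    mean(amp[d])
  }, numeric(1))
  expect_equal(
    stats::cor(per_obj, ph$objects$amplitude_transmittance, method = "spearman"),
    1
  )
})
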