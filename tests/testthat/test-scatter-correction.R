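test_that("shadow-center columns follow the projected rod position", {
  g <- beam_geometry()
  rod <- blocker_positions(25, g)
  pc <- pixel_centers(g)
  # central position: the 3 columns straddle the detector center
  cols <- shadow_center_pixels(rod, 13, g, k_center = 3)
  expect_length(cols, 3)
  expect_equal(mean(pc[cols]), 0, tolerance = 0.51)
  expect_false(attr(cols, "truncated"))
  # k = 1: the single column nearest the projected center
  c1 <- shadow_center_pixels(rod, 5, g, k_center = 1)
  expect_length(c1, 1)
  expect_equal(pc[c1], rod$projected_centers[5], tolerance = 0.51)
  # the outermost shadow is half off the detector: reduced set, flagged
  cedge <- shadow_center_pixels(rod, 1, g, k_center = 9)
  expect_lt(length(cedge), 9)
  expect_true(attr(cedge, "truncated"))
})

test_that("shadow sampling rescales 1/n-kerma frames to the full-kerma level", {
  g <- small_geom()
  fr <- constant_scatter_frames(g, scatter_level = 120)
  smp <- sample_scatter(fr, k_center = 3, median_window = 0)
  expect_equal(max(abs(smp$le - 120)), 0, tolerance = 1e-12)
  expect_equal(max(abs(smp$he - 60)), 0, tolerance = 1e-12)
  # the median pre-filter leaves a constant field untouched
  smp5 <- sample_scatter(fr, k_center = 3, median_window = 5)
  expect_equal(smp5$le, smp$le, tolerance = 1e-12)
})

test_that("rod-transmitted leakage into shadow samples is negligible", {
  g <- beam_geometry()
  s <- test_spectrum()
  det <- detector_model()
  ph <- build_phantom("standard", g)
  primary <- project_primary(ph, s, g)
  rod <- blocker_positions(25, g)
  # zero-scatter acquisition: shadow samples contain only leakage, bounded by
  # the shadow-center transmission times the primary level
  zero_sc <- pcdexr:::new_eri(
    array(0, dim(primary$data)), primary$energy, "scatter",
    primary$x_coords, g)
  nf <- acquire_frame_set(ph, s, g, det, rod, seed = 1, scatter = zero_sc,
                          primary = primary, sample = FALSE)
  smp <- sample_scatter(nf, k_center = 3, median_window = 0)
  pmap <- pcdexr:::collapse_to_bins(primary, det)
  # bound: the worst shadow-center transmission over the spectrum (the rod is
  # only ~5 optical depths at the 120 kVp endpoint) times the primary level
  w <- material_table("w")
  t_max <- exp(-lookup_mu(w, 120) * w$density / 10 * rod$thickness_mm)
  expect_lt(max(smp$le), t_max * max(pmap$le) * 1.01)
  expect_lt(max(smp$he), t_max * max(pmap$he) * 1.01)
  expect_lt(max(smp$le) / max(pmap$le), 1e-4)
})

test_that("reconstruction is exact for constants and linear ramps", {
  g <- small_geom()
  n <- g$n_pixels
  x <- (1:25 - 13) * 4   # sample columns, mm
  samples <- structure(list(
    x_mm = x,
    le = matrix(7, n, 25),
    he = matrix(3, n, 25),
    n_frames = 25, truncated = rep(FALSE, 25)), class = "scatter_sample_set")
  map <- reconstruct_scatter_map(samples, g, sigma_mm = 5)
  expect_equal(max(abs(map$le - 7)), 0, tolerance = 1e-9)
  expect_equal(max(abs(map$he - 3)), 0, tolerance = 1e-9)

  # linear ramp, no smoothing: cubic interpolation reproduces degree-1 exactly
  ramp <- samples
  ramp$le <- matrix(rep(60 + 0.5 * x, each = n), n, 25)
  ramp$he <- ramp$le
  m0 <- reconstruct_scatter_map(ramp, g, sigma_mm = 0)
  pc <- pixel_centers(g)
  interior <- pc >= min(x) & pc <= max(x)
  expect_equal(m0$le[5, interior], 60 + 0.5 * pc[interior], tolerance = 1e-9)
  # clamped (not extrapolated) beyond the outermost samples
  expect_equal(m0$le[5, pc < min(x)],
               rep(60 + 0.5 * min(x), sum(pc < min(x))), tolerance = 1e-9)
  expect_error(reconstruct_scatter_map(
    structure(list(x_mm = x[1:3], le = matrix(1, n, 3), he = matrix(1, n, 3)),
              class = "scatter_sample_set"), g), ">= 4")
})

test_that("a smooth sinusoidal field is reconstructed to better than 1%", {
  g <- beam_geometry()
  n <- g$n_pixels
  rod <- blocker_positions(25, g)
  x <- rod$projected_centers
  f <- function(x) 2 + sin(2 * pi * x / 100)
  samples <- structure(list(
    x_mm = x,
    le = matrix(rep(f(x), each = n), n, 25),
    he = matrix(1, n, 25),
    n_frames = 25, truncated = rep(FALSE, 25)), class = "scatter_sample_set")
  m <- reconstruct_scatter_map(samples, g, sigma_mm = 0)
  pc <- pixel_centers(g)
  interior <- pc >= min(x) & pc <= max(x)
  oracle <- matrix(rep(f(pc[interior]), each = n), n, sum(interior))
  rel_err <- abs(m$le[, interior] - oracle) / oracle
  expect_lt(max(rel_err), 0.01)
})

test_that("per-bin independence and smoothing neutrality hold", {
  g <- small_geom()
  n <- g$n_pixels
  x <- (1:25 - 13) * 4
  set.seed(42)
  base <- structure(list(
    x_mm = x,
    le = matrix(100 + stats::rnorm(n * 25), n, 25),
    he = matrix(50 + stats::rnorm(n * 25), n, 25),
    n_frames = 25, truncated = rep(FALSE, 25)), class = "scatter_sample_set")
  m1 <- reconstruct_scatter_map(base, g, sigma_mm = 5)
  messed <- base
  messed$he <- messed$he * 10 + 3
  m2 <- reconstruct_scatter_map(messed, g, sigma_mm = 5)
  expect_identical(m1$le, m2$le)

  # smoothing changes the interior mean by less than the boundary bound
  m0 <- reconstruct_scatter_map(base, g, sigma_mm = 0)
  interior <- 25:75
  expect_lt(abs(mean(m1$le[interior, interior]) -
                mean(m0$le[interior, interior])),
            0.02 * mean(m0$le))
})

test_that("scatter subtraction floors, flags, and respects linearity", {
  img <- pcdexr:::new_binned_image(matrix(100, 10, 10), matrix(50, 10, 10), 1)
  zero <- list(le = matrix(0, 10, 10), he = matrix(0, 10, 10))
  expect_equal(subtract_scatter(img, zero)$le, img$le)
  map <- list(le = matrix(30, 10, 10), he = matrix(20, 10, 10))
  out <- subtract_scatter(img, map)
  expect_equal(out$le, matrix(70, 10, 10))
  expect_equal(unname(attr(out, "n_floored")), c(0, 0))
  # ROI means commute with subtraction when nothing is floored
  roi <- matrix(FALSE, 10, 10); roi[2:5, 2:5] <- TRUE
  expect_equal(mean(out$le[roi]), mean(img$le[roi]) - mean(map$le[roi]))
  # exceeding map: floored pixels counted
  big <- list(le = matrix(200, 10, 10), he = matrix(0, 10, 10))
  out2 <- subtract_scatter(img, big, epsilon = 1e-3)
  expect_equal(unname(attr(out2, "n_floored")["le"]), 100)
  expect_true(all(out2$le == 1e-3))
  expect_error(subtract_scatter(img, list(le = matrix(0, 3, 3),
                                          he = matrix(0, 3, 3))), "mismatch")
})

test_that("error metrics: identity, uniform scaling, zero-truth rejection", {
  g <- small_geom()
  ph <- build_phantom("standard", g)
  tr <- list(le = matrix(200, 100, 100), he = matrix(80, 100, 100))
  m0 <- scatter_error_metrics(tr, tr, g, ph)
  expect_equal(m0$mean_pct, 0)
  expect_equal(m0$max_pct, 0)
  est <- list(le = tr$le * 1.01, he = tr$he * 1.01)
  m1 <- scatter_error_metrics(tr, est, g, ph)
  expect_equal(m1$mean_pct, 1, tolerance = 1e-9)
  expect_equal(m1$max_pct, 1, tolerance = 1e-9)
  bad <- tr; bad$le[50, 50] <- 0
  expect_error(scatter_error_metrics(bad, est, g, ph), "zero-valued truth")
})
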