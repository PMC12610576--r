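test_that("ROI statistics use sample moments and reject empty/overlapping ROIs", {
  roi <- list(fg = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
              bg = matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  img <- matrix(5, 2, 2)
  st <- roi_stats(img, roi)
  expect_equal(st$fg_mean, 5); expect_equal(st$fg_var, 0)

  # checkerboard of {0, 2}: mean 1, sample variance n/(n-1) by enumeration
  n <- 10
  roi2 <- list(fg = matrix(TRUE, n, n), bg = matrix(TRUE, n, n))
  img2 <- matrix(rep(c(0, 2), length.out = n * n), n, n)
  st2 <- roi_stats(img2, roi2)
  vals <- img2[roi2$fg]
  oracle_var <- sum((vals - mean(vals))^2) / (length(vals) - 1)
  expect_equal(st2$fg_mean, 1)
  expect_equal(st2$fg_var, oracle_var)
  expect_equal(oracle_var, n * n / (n * n - 1))

  # construction-time rejection of bad ROIs
  fw <- mid_forward()
  expect_error(roi_spec(fw$phantom, fw$geometry, 1, fg_radius_mm = 20),
               "beyond the insert")
  expect_error(roi_spec(fw$phantom, fw$geometry, 1, bg_offset_mm = 10),
               "overlaps an insert")
})

test_that("DEC reproduces the hand-arithmetic case and its symmetries", {
  # fg - bg = 2 in both realizations, all four variances exactly 1 -> DEC = 1
  n_fg <- 50; n_bg <- 50
  a <- sqrt((n_fg - 1) / n_fg)   # +/- a gives sample variance exactly 1
  fg_vals <- rep(c(10 - a, 10 + a), n_fg / 2)
  bg_vals <- rep(c(8 - a, 8 + a), n_bg / 2)
  img <- matrix(0, 10, 10)
  roi <- list(fg = matrix(FALSE, 10, 10), bg = matrix(FALSE, 10, 10),
              material = "al", thickness = 1)
  roi$fg[1:5, ] <- TRUE; roi$bg[6:10, ] <- TRUE
  img[roi$fg] <- fg_vals; img[roi$bg] <- bg_vals
  rec <- compute_dec(img, img, roi)
  expect_equal(rec$dec, 1, tolerance = 1e-12)

  # duplicated realization: 2d / (2 sqrt(2 (v_fg + v_bg))) by the formula
  st <- roi_stats(img, roi)
  d <- st$fg_mean - st$bg_mean
  expect_equal(rec$dec, d / sqrt(2 * (st$fg_var + st$bg_var)),
               tolerance = 1e-12)

  # label symmetry (1) <-> (2)
  img2 <- img + matrix(stats::rnorm(100, sd = 0.1), 10, 10)
  expect_equal(compute_dec(img, img2, roi)$dec,
               compute_dec(img2, img, roi)$dec, tolerance = 1e-15)
  expect_error(compute_dec(matrix(1, 10, 10), matrix(1, 10, 10), roi),
               "zero total ROI variance")
})

test_that("DSE equals DEC at 1 mGy and follows the chosen denominator", {
  expect_identical(compute_dse(3.7, ka = 1)$dse, 3.7)
  expect_equal(compute_dse(3.7, ka = 4, denominator = "sqrt_ka")$dse, 3.7 / 2)
  expect_equal(compute_dse(3.7, ka = 4, denominator = "ka")$dse, 3.7 / 4)
  expect_error(compute_dse(1, ka = 0), "positive")
  rec <- compute_dse(2, ka = 2)
  expect_identical(rec$denominator, "ka")
})

test_that("DEC scales with the square root of dose (scatter-free pipeline)", {
  fw <- mid_forward()
  idx <- which(fw$phantom$inserts$thickness %in% c(2.5, 10))
  rois <- lapply(idx, function(i) roi_spec(fw$phantom, fw$geometry, i))
  dec_at <- function(scale, seed0) {
    imgs <- lapply(1:2, function(r)
      apply_detector(fw$primary, detector = fw$detector, kerma_scale = scale,
                     seed = seed0 + r))
    lps <- lapply(imgs, function(im) {
      ref <- fw$reference
      ref$le <- ref$le * scale; ref$he <- ref$he * scale
      open_beam_log(im, ref)
    })
    w <- calibrate_weights(lps[[1]], fw$phantom, fw$geometry)
    des <- lapply(lps, de_subtract, weights = w)
    # each insert is measured in the image that targets its material
    vapply(rois, function(roi) {
      img <- if (roi$material == "al") "i_b" else "i_s"
      compute_dec(des[[1]][[img]], des[[2]][[img]], roi)$dec
    }, numeric(1))
  }
  d1 <- dec_at(1, 500)
  d4 <- dec_at(4, 700)
  expect_equal(unname(d4 / d1), rep(2, length(d1)), tolerance = 0.12)
})

test_that("the experiment report has the full matrix with target flags", {
  ex <- acceptance_experiment()
  rep <- dec_report(ex)
  expect_equal(nrow(rep), 180)
  expect_setequal(unique(rep$state), c("none", "uncorrected", "corrected"))
  expect_equal(sum(rep$target), 90)
  # DSE = DEC at the 1 mGy run kerma
  expect_equal(rep$dse, rep$dec)
  # target DEC magnitude grows monotonically with thickness (corrected state)
  for (size in names(ex$sizes)) {
    d <- rep[rep$size == size & rep$state == "corrected" & rep$target &
               rep$image == "b", ]
    d <- d[order(d$thickness), ]
    expect_equal(stats::cor(abs(d$dec), d$thickness, method = "spearman"), 1)
  }
  # non-target stays below target for thicknesses >= 1 mm (corrected)
  for (size in names(ex$sizes)) {
    d <- rep[rep$size == size & rep$state == "corrected" & rep$image == "b", ]
    tg <- d[d$target & d$thickness >= 1, ]
    nt <- d[!d$target, ]
    expect_lt(max(abs(nt$dec)), min(abs(tg$dec)))
  }
})
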