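# Dual-energy subtraction: open-beam log correction, cancellation-weight
# calibration on the 1.5 mm Al and 6 mm PMMA inserts, and the weighted log
# subtraction producing the PMMA-enhanced and Al-enhanced images.

#' Open-beam logarithmic correction
#'
#' Converts count images to log-attenuation relative to a reference
#' acquisition (a uniform PMMA slab, simulated noise- and scatter-free at
#' matched kerma): `value = ln(reference / image)` per pixel and bin, so
#' thicker material gives larger values.
#'
#' @param image a `binned_image`.
#' @param reference a `binned_image` (noise-free expected counts) on the same
#'   grid.
#' @return A `log_pair`: list with `le`/`he` log-attenuation matrices.
#' @export
open_beam_log <- function(image, reference) {
  if (!all(dim(image$le) == dim(reference$le))) stop("grid mismatch")
  if (any(image$le <= 0) || any(image$he <= 0) ||
      any(reference$le <= 0) || any(reference$he <= 0))
    stop("nonpositive counts; apply the epsilon floor upstream")
  structure(list(le = log(reference$le / image$le),
                 he = log(reference$he / image$he)),
            class = "log_pair")
}

# Projected detector-plane center (mm) of insert row i.
project_insert_center <- function(phantom, geometry, i) {
  ins <- phantom$inserts[i, ]
  M <- geometry$sdd_mm / ((ins$z0 + ins$z1) / 2)
  c(x = ins$cx * M, y = ins$cy * M, r = ins$diameter / 2 * M)
}

# Logical masks for a disc and for pixels inside any projected insert
# footprint (+ margin).
disc_mask <- function(geometry, cx, cy, r) {
  pc <- pixel_centers(geometry)
  outer((pc - cy)^2, (pc - cx)^2, `+`) <= r^2
}

any_insert_mask <- function(phantom, geometry, margin_mm = 2) {
  n <- geometry$n_pixels
  m <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(phantom$inserts))) {
    p <- project_insert_center(phantom, geometry, i)
    m <- m | disc_mask(geometry, p["x"], p["y"], p["r"] + margin_mm)
  }
  m
}

# Foreground-minus-background ROI mean of one log image over an insert:
# foreground = fg_radius disc, background = 15-20 mm annulus clipped against
# all insert footprints.
insert_log_contrast <- function(img, phantom, geometry, insert_i,
                                fg_radius_mm = 8) {
  p <- project_insert_center(phantom, geometry, insert_i)
  fg <- disc_mask(geometry, p["x"], p["y"], fg_radius_mm)
  ann <- disc_mask(geometry, p["x"], p["y"], 20) &
    !disc_mask(geometry, p["x"], p["y"], 15)
  bg <- ann & !any_insert_mask(phantom, geometry)
  if (!any(fg) || !any(bg)) stop("empty calibration ROI")
  mean(img[fg]) - mean(img[bg])
}

#' Calibrate dual-energy cancellation weights
#'
#' `w_pmma` is chosen to null the 1.5 mm Al insert in the PMMA-enhanced image
#' and `w_al` to null the 6 mm PMMA insert in the Al-enhanced image, from the
#' foreground-minus-background log contrasts of the calibration inserts:
#' `w_pmma = dL(Al 1.5)/dH(Al 1.5)` and `w_al = dH(PMMA 6)/dL(PMMA 6)`.
#'
#' @param log_pair a [open_beam_log()] result for the imaging phantom.
#' @param phantom the imaged [build_phantom()] (supplies insert positions).
#' @param geometry a [beam_geometry()].
#' @param tol minimum |denominator contrast| accepted.
#' @return A `weight_pair`: list with `w_pmma`, `w_al`, and the calibration
#'   contrasts.
#' @export
calibrate_weights <- function(log_pair, phantom, geometry, tol = 1e-6) {
  ins <- phantom$inserts
  i_al <- which(ins$material == "al" & abs(ins$thickness - 1.5) < 1e-9)
  i_pm <- which(ins$material == "pmma" & abs(ins$thickness - 6) < 1e-9)
  if (length(i_al) != 1 || length(i_pm) != 1)
    stop("phantom must contain the 1.5 mm Al and 6 mm PMMA calibration inserts")
  d_l_al <- insert_log_contrast(log_pair$le, phantom, geometry, i_al)
  d_h_al <- insert_log_contrast(log_pair$he, phantom, geometry, i_al)
  d_l_pm <- insert_log_contrast(log_pair$le, phantom, geometry, i_pm)
  d_h_pm <- insert_log_contrast(log_pair$he, phantom, geometry, i_pm)
  if (abs(d_h_al) < tol || abs(d_l_pm) < tol)
    stop("degenerate calibration contrast")
  structure(list(w_pmma = d_l_al / d_h_al, w_al = d_h_pm / d_l_pm,
                 contrasts = c(le_al = d_l_al, he_al = d_h_al,
                               le_pmma = d_l_pm, he_pmma = d_h_pm)),
            class = "weight_pair")
}

#' @export
print.weight_pair <- function(x, ...) {
  cat(sprintf("<weight_pair> w_pmma = %.4f, w_al = %.4f\n", x$w_pmma, x$w_al))
  invisible(x)
}

#' Dual-energy weighted log subtraction
#'
#' Computes the PMMA-enhanced (soft-tissue) image `i_s = I_L - w_pmma * I_H`
#' and the Al-enhanced (bone) image `i_b = I_H - w_al * I_L` from the
#' log-corrected bin images.
#'
#' @param log_pair a [open_beam_log()] result.
#' @param weights a [calibrate_weights()] result (or list with `w_pmma`,
#'   `w_al`).
#' @param scatter_state label recorded in the result: `"none"`,
#'   `"uncorrected"`, or `"corrected"`.
#' @return A `de_result`: list with `i_s`, `i_b`, `weights`, `scatter_state`.
#' @export
de_subtract <- function(log_pair, weights, scatter_state = "none") {
  stopifnot(inherits(log_pair, "log_pair"))
  structure(list(i_s = log_pair$le - weights$w_pmma * log_pair$he,
                 i_b = log_pair$he - weights$w_al * log_pair$le,
                 weights = weights, scatter_state = scatter_state),
            class = "de_result")
}
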