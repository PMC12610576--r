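# Moving-blocker scatter estimation: sample the scatter field in the rod
# shadows, reconstruct a full-field per-bin scatter map by cubic
# interpolation plus Gaussian smoothing, and subtract it.

#' Central pixel columns of a rod shadow
#'
#' Returns the `k_center` detector columns closest to the projected shadow
#' center whose pixel centers lie inside the projected shadow, restricting to
#' the central core minimizes contamination from rod-transmitted photons and
#' penumbra.
#'
#' @param rod a [blocker_positions()] result.
#' @param position_index rod position in `1..n`.
#' @param geometry a [beam_geometry()].
#' @param k_center number of central columns to use.
#' @return Integer vector of column indices, with attributes `center_mm`
#'   (projected shadow center) and `truncated` (`TRUE` if part of the
#'   requested core fell off the detector).
#' @export
shadow_center_pixels <- function(rod, position_index, geometry, k_center = 3) {
  if (position_index < 1 || position_index > length(rod$positions))
    stop("position index out of range")
  center <- rod$projected_centers[position_index]
  pc <- pixel_centers(geometry)
  inside <- abs(pc - center) <= rod$shadow_width_mm / 2
  ord <- order(abs(pc - center))
  cand <- ord[inside[ord]]
  cols <- sort(utils::head(cand, k_center))
  truncated <- length(cols) < k_center
  if (!length(cols)) stop("shadow entirely off the detector")
  structure(cols, center_mm = center, truncated = truncated)
}

#' Sample the scatter field from blocker-frame shadows
#'
#' For every frame, averages the counts over the central shadow columns, per
#' detector row and energy bin, and rescales by the frame count so the
#' samples are on the full-kerma scale.  An optional running-median filter
#' along rows suppresses outliers before interpolation.
#'
#' @param frames a [acquire_frame_set()] result.
#' @param k_center number of central shadow columns to average.
#' @param median_window odd window length of the along-row median pre-filter;
#'   `0` disables it.
#' @return A `scatter_sample_set`: `x_mm` (projected sample column
#'   positions), `le`/`he` (rows x positions sample matrices at full kerma),
#'   `n_frames`, and `truncated` flags.
#' @export
sample_scatter <- function(frames, k_center = 3, median_window = 5) {
  stopifnot(inherits(frames, "frame_set"))
  n <- frames$n_frames
  nr <- nrow(frames$frames[[1]]$le)
  le <- matrix(0, nr, n); he <- matrix(0, nr, n)
  x_mm <- numeric(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    cols <- shadow_center_pixels(frames$rod, i, frames$geometry, k_center)
    if (!length(cols)) stop("empty shadow column set for frame ", i)
    le[, i] <- rowMeans(frames$frames[[i]]$le[, cols, drop = FALSE]) * n
    he[, i] <- rowMeans(frames$frames[[i]]$he[, cols, drop = FALSE]) * n
    x_mm[i] <- attr(cols, "center_mm")
    trunc[i] <- attr(cols, "truncated")
  }
  if (median_window >= 3) {
    for (i in seq_len(n)) {
      le[, i] <- stats::runmed(le[, i], median_window, endrule = "median")
      he[, i] <- stats::runmed(he[, i], median_window, endrule = "median")
    }
  }
  structure(list(x_mm = x_mm, le = le, he = he, n_frames = n,
                 truncated = trunc),
            class = "scatter_sample_set")
}

#' Reconstruct the full-field scatter map
#'
#' Per detector row and energy bin, natural cubic interpolation across the
#' sample columns onto every pixel column (clamped, not extrapolated, beyond
#' the outermost samples), followed by 2-D Gaussian smoothing with
#' `sigma_mm`; the result is clipped at zero.
#'
#' @param samples a [sample_scatter()] result (needs >= 4 sample columns).
#' @param geometry a [beam_geometry()].
#' @param sigma_mm Gaussian smoothing standard deviation, mm.
#' @return A `scatter_map`: full-kerma `le`/`he` count maps on the pixel
#'   grid, plus `sigma_mm` and the sample positions.
#' @export
reconstruct_scatter_map <- function(samples, geometry, sigma_mm = 5) {
  if (length(samples$x_mm) < 4) stop("cubic interpolation needs >= 4 sample columns")
  op <- spline_operator(samples$x_mm, pixel_centers(geometry))
  s_px <- sigma_mm / geometry$effective_pitch_mm
  mk <- function(m) {
    recon <- m %*% t(op)          # [rows, all columns]
    pmax(gaussian_smooth(recon, s_px), 0)
  }
  structure(list(le = mk(samples$le), he = mk(samples$he),
                 sigma_mm = sigma_mm, x_mm = samples$x_mm),
            class = "scatter_map")
}

#' Subtract a scatter map from a binned image
#'
#' Per-bin subtraction, floored at a small positive epsilon so downstream
#' logarithms stay finite; the number of floored pixels is reported.
#'
#' @param image a `binned_image`.
#' @param map a `scatter_map` on the same grid (or a list with `le`/`he`).
#' @param epsilon positive count floor.
#' @return The corrected `binned_image`, with attribute `n_floored` (named,
#'   per bin).
#' @export
subtract_scatter <- function(image, map, epsilon = 1e-3) {
  if (!all(dim(image$le) == dim(map$le))) stop("image/map grid mismatch")
  le <- image$le - map$le
  he <- image$he - map$he
  n_floored <- c(le = sum(le < epsilon), he = sum(he < epsilon))
  out <- new_binned_image(pmax(le, epsilon), pmax(he, epsilon),
                          image$kerma_mgy, image$seed)
  attr(out, "n_floored") <- n_floored
  out
}

#' Percentage-error metrics between two scatter maps
#'
#' Per-pixel percentage error `|estimate - truth| / truth * 100` evaluated
#' inside a region of interest (by default the phantom-covered field of view
#' minus an edge margin), reported per energy bin.
#'
#' @param truth,estimate lists with `le`/`he` matrices on the same grid.
#' @param geometry a [beam_geometry()].
#' @param phantom the imaged [build_phantom()]; with `mask = NULL` the
#'   evaluation region is the full lateral projection of the phantom stack
#'   minus `margin_mm`.
#' @param margin_mm edge margin excluded from the evaluation region.
#' @param mask optional logical matrix overriding the default region.
#' @return A list with `mean_pct`/`max_pct` (over both bins) and per-bin
#'   sublists carrying `mean_pct`, `max_pct`, and the per-pixel error `map`.
#' @export
scatter_error_metrics <- function(truth, estimate, geometry, phantom = NULL,
                                  margin_mm = 10, mask = NULL) {
  if (!all(dim(truth$le) == dim(estimate$le))) stop("grid mismatch")
  if (is.null(mask)) {
    if (is.null(phantom)) stop("need a phantom (or explicit mask) to define the region")
    mat <- phantom$layers[phantom$layers$material != "air", , drop = FALSE]
    half <- phantom$lateral_half_mm * geometry$sdd_mm / max(mat$z1) - margin_mm
    pc <- pixel_centers(geometry)
    mask <- outer(abs(pc) <= half, abs(pc) <= half, `&`)
  }
  per_bin <- lapply(c(le = "le", he = "he"), function(b) {
    tr <- truth[[b]]; es <- estimate[[b]]
    if (any(tr[mask] <= 0)) stop("zero-valued truth pixels inside the evaluation region")
    err <- abs(es - tr) / tr * 100
    list(mean_pct = mean(err[mask]), max_pct = max(err[mask]),
         map = err * ifelse(mask, 1, NA))
  })
  list(mean_pct = mean(vapply(per_bin, `[[`, numeric(1), "mean_pct")),
       max_pct = max(vapply(per_bin, `[[`, numeric(1), "max_pct")),
       le = per_bin$le, he = per_bin$he, mask = mask)
}
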