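# Acquisition geometry: source/detector distances, detector pixel grid,
# the photon-counting detector response model, and the moving-blocker rod.

#' Beam and detector geometry
#'
#' @param sdd_cm source-to-detector distance, cm.
#' @param sid_cm source-to-isocenter distance, cm.
#' @param detector_cm detector side length, cm (square detector).
#' @param native_pitch_mm native detector pixel pitch, mm.
#' @param binning pixel binning factor; the effective pitch is
#'   `native_pitch_mm * binning`.
#' @param blocker_plane_cm distance from the source to the blocker plane, cm.
#' @return A `beam_geometry`: distances in mm (`sdd_mm`, `sid_mm`,
#'   `blocker_plane_mm`), `detector_mm`, `effective_pitch_mm`, and the number
#'   of effective pixels per side `n_pixels`.
#' @details The detector pixel grid uses the 0-based, pixel-center convention
#'   with the origin at the detector center on the beam axis; [pixel_centers()]
#'   returns the lateral pixel-center coordinates.
#' @export
beam_geometry <- function(sdd_cm = 180, sid_cm = 150, detector_cm = 40,
                          native_pitch_mm = 0.1, binning = 10L,
                          blocker_plane_cm = 20) {
  stopifnot(sdd_cm > sid_cm, sid_cm > blocker_plane_cm, blocker_plane_cm > 0)
  eff <- native_pitch_mm * binning
  n <- detector_cm * 10 / eff
  if (abs(n - round(n)) > 1e-9) stop("detector size must be a whole number of effective pixels")
  structure(list(sdd_mm = sdd_cm * 10, sid_mm = sid_cm * 10,
                 detector_mm = detector_cm * 10,
                 native_pitch_mm = native_pitch_mm, binning = as.integer(binning),
                 effective_pitch_mm = eff, n_pixels = as.integer(round(n)),
                 blocker_plane_mm = blocker_plane_cm * 10),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> SDD %g cm, SID %g cm, %g x %g cm detector, %d px of %g mm\n",
              x$sdd_mm / 10, x$sid_mm / 10, x$detector_mm / 10, x$detector_mm / 10,
              x$n_pixels, x$effective_pitch_mm))
  invisible(x)
}

#' Lateral pixel-center coordinates of the effective detector grid
#'
#' @param geometry a [beam_geometry()].
#' @return Numeric vector of length `n_pixels`, mm, centered on the beam axis.
#' @export
pixel_centers <- function(geometry) {
  n <- geometry$n_pixels
  p <- geometry$effective_pitch_mm
  (seq_len(n) - (n + 1) / 2) * p
}

#' Geometric magnification of a plane onto the detector
#'
#' @param geometry a [beam_geometry()].
#' @param plane_dist_cm distance from the source to the object plane, cm.
#' @return `sdd / plane_dist` (dimensionless).
#' @export
magnification <- function(geometry, plane_dist_cm) {
  if (plane_dist_cm <= 0 || plane_dist_cm * 10 > geometry$sdd_mm)
    stop("plane distance must be in (0, sdd]")
  geometry$sdd_mm / (plane_dist_cm * 10)
}

#' Moving-blocker rod positions
#'
#' A tungsten rod of rectangular cross-section (width across the translation
#' axis, thickness along the beam) spanning the full detector height, placed
#' at the blocker plane and translated laterally so that the projected shadow
#' centers uniformly span the detector width.
#'
#' @param n number of rod positions (>= 2).
#' @param geometry a [beam_geometry()].
#' @param width_mm physical rod width, mm.
#' @param thickness_mm rod thickness along the source-detector axis, mm.
#' @return A `blocker_rod`: list with `positions` (lateral offsets at the
#'   blocker plane, mm), `projected_centers` (shadow centers at the detector,
#'   mm), `step_mm` (blocker-plane step), `projected_step_mm`,
#'   `shadow_width_mm` (projected), `width_mm`, `thickness_mm`,
#'   `plane_dist_mm`, and `magnification`.
#' @export
blocker_positions <- function(n = 25, geometry = beam_geometry(),
                              width_mm = 1, thickness_mm = 2) {
  if (n < 2) stop("need at least 2 blocker positions")
  M <- geometry$sdd_mm / geometry$blocker_plane_mm
  projected_step <- geometry$detector_mm / (n - 1)
  step <- projected_step / M
  offsets <- (seq_len(n) - (n + 1) / 2) * step
  structure(list(positions = offsets, projected_centers = offsets * M,
                 step_mm = step, projected_step_mm = projected_step,
                 span_mm = step * (n - 1),
                 shadow_width_mm = width_mm * M,
                 width_mm = width_mm, thickness_mm = thickness_mm,
                 plane_dist_mm = geometry$blocker_plane_mm, magnification = M),
            class = "blocker_rod")
}

#' @export
print.blocker_rod <- function(x, ...) {
  cat(sprintf(
    "<blocker_rod> %d positions, span %.3g cm at blocker plane (step %.3g mm), projected step %.3g cm, shadow %.3g mm\n",
    length(x$positions), x$span_mm / 10, x$step_mm, x$projected_step_mm / 10,
    x$shadow_width_mm))
  invisible(x)
}

#' Photon-counting detector model
#'
#' Two-threshold CdTe photon-counting detector: absorption efficiency of the
#' sensor thickness, Gaussian blur of the recorded energy, and count
#' assignment to the low-energy bin (recorded energy in `[thr1, thr2)`) or
#' high-energy bin (`>= thr2`).
#'
#' @param thresholds_kev two strictly increasing energy thresholds, keV.
#' @param sigma_kev electronic-noise standard deviation of the recorded
#'   energy, keV.
#' @param thickness_mm sensor thickness, mm.
#' @param material sensor material table name.
#' @return A `detector_model`.
#' @export
detector_model <- function(thresholds_kev = c(30, 70), sigma_kev = 1.6,
                           thickness_mm = 0.75, material = "cdte") {
  stopifnot(length(thresholds_kev) == 2, diff(thresholds_kev) > 0,
            sigma_kev >= 0, thickness_mm > 0)
  structure(list(thresholds_kev = thresholds_kev, sigma_kev = sigma_kev,
                 thickness_mm = thickness_mm, material = material),
            class = "detector_model")
}

# Expected LE/HE detection probability per incident photon at each energy:
# absorption efficiency times the Gaussian-blur probability of the recorded
# energy falling in each bin.  Returns a length(energies) x 2 matrix.
bin_weights <- function(detector, energies) {
  tab <- material_table(detector$material)
  eff <- 1 - exp(-mu_linear_mm(tab, energies) * detector$thickness_mm)
  s <- detector$sigma_kev
  t1 <- detector$thresholds_kev[1]; t2 <- detector$thresholds_kev[2]
  if (s > 0) {
    p_ge1 <- stats::pnorm((energies - t1) / s)
    p_ge2 <- stats::pnorm((energies - t2) / s)
  } else {
    p_ge1 <- as.numeric(energies >= t1)
    p_ge2 <- as.numeric(energies >= t2)
  }
  cbind(le = eff * (p_ge1 - p_ge2), he = eff * p_ge2)
}
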