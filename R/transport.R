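# Transport simulator: analytic primary projection (Beer-Lambert over ray
# path lengths), Monte Carlo scatter transport, the photon-counting detector
# model, and blocker-frame acquisition.

# --- energy-resolved images -------------------------------------------------

new_eri <- function(data, energy, component, x_coords, geometry,
                    upsample_op = NULL) {
  structure(list(data = data, energy = energy, component = component,
                 x_coords = x_coords, geometry = geometry,
                 upsample_op = upsample_op),
            class = "energy_resolved_image")
}

#' @export
print.energy_resolved_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<energy_resolved_image> %s: %d x %d pixels, %d energy bins [%g, %g] keV%s\n",
              x$component, d[1], d[2], d[3], min(x$energy), max(x$energy),
              if (!is.null(x$upsample_op)) " (coarse grid)" else ""))
  invisible(x)
}

# --- primary projection -----------------------------------------------------

#' Analytic primary projection
#'
#' Beer-Lambert forward projection of the spectrum through the phantom:
#' `fluence(E, pixel) = S(E) * cos^3(theta) * exp(-sum_m mu_m(E) path_m)`.
#' The `cos^3` factor carries the inverse-square and obliquity falloff
#' relative to the central pixel, where the kerma normalization is defined.
#'
#' @param phantom a [build_phantom()] result (or [reference_phantom()]).
#' @param spectrum a normalized [generate_spectrum()] beam.
#' @param geometry a [beam_geometry()].
#' @return An `energy_resolved_image` (component `"primary"`) whose `data` is
#'   an `n_pixels x n_pixels x n_energy` array of photons/mm^2; image planes
#'   are indexed `[y, x]`.
#' @export
project_primary <- function(phantom, spectrum, geometry = beam_geometry()) {
  paths <- material_path_lengths(phantom, geometry)
  pc <- pixel_centers(geometry)
  n <- geometry$n_pixels
  D <- geometry$sdd_mm
  x <- matrix(rep(pc, each = n), n, n)
  y <- matrix(rep(pc, times = n), n, n)
  cos3 <- (D / sqrt(x^2 + y^2 + D^2))^3
  tabs <- lapply(stats::setNames(nm = names(paths)), material_table)
  nE <- length(spectrum$energy)
  out <- array(0, c(n, n, nE))
  for (e in seq_len(nE)) {
    if (spectrum$fluence[e] == 0) next
    att <- 0
    for (m in names(paths))
      att <- att + mu_linear_mm(tabs[[m]], spectrum$energy[e]) * paths[[m]]
    out[, , e] <- spectrum$fluence[e] * cos3 * exp(-att)
  }
  new_eri(out, spectrum$energy, "primary", pc, geometry)
}

# --- Monte Carlo scatter ----------------------------------------------------

# Fine-grid linear attenuation matrices (1/mm) for the transport kernel.
fine_mu_tables <- function(materials, e0 = 5, e1 = 150, de = 0.25) {
  eg <- seq(e0, e1, by = de)
  mk <- function(kind) vapply(materials, function(m)
    mu_linear_mm(material_table(m), eg, kind), numeric(length(eg)))
  list(energy = eg, total = mk("total"), compton = mk("compton"),
       rayleigh = mk("rayleigh"), e0 = e0, de = de)
}

#' Monte Carlo scattered-fluence image
#'
#' Samples photons from the spectrum, transports them through the background
#' slab stack (photoelectric absorption by implicit capture, Klein-Nishina
#' Compton scattering, optional Thomson-shaped Rayleigh scattering, up to
#' `max_order` interactions), and scores the scattered fluence reaching the
#' detector plane by next-event estimation onto a coarse node grid.  The
#' coarse maps are optionally smoothed across nodes and upsampled to the
#' effective pixel grid with cubic-spline operators.
#'
#' @param phantom,spectrum,geometry as in [project_primary()].
#' @param n_photons number of photon histories.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @param max_order maximum number of interactions per history.
#' @param rayleigh include coherent scattering (Thomson angular shape).
#' @param coarse_n nodes per side of the scoring grid.
#' @param coarse_smooth_nodes Gaussian smoothing sigma across scoring nodes
#'   (in node spacings) applied before upsampling; suppresses residual Monte
#'   Carlo variance in the smooth scatter field.
#' @param expand if `TRUE` return the full pixel-grid image; if `FALSE`
#'   return the coarse-grid image with the upsampling operator attached
#'   (linear collapse and upsampling commute, so downstream code can work at
#'   either resolution).
#' @return An `energy_resolved_image` (component `"scatter"`), photons/mm^2.
#' @export
simulate_scatter <- function(phantom, spectrum, geometry = beam_geometry(),
                             n_photons = 2e6, seed = NULL, max_order = 3,
                             rayleigh = FALSE, coarse_n = 25,
                             coarse_smooth_nodes = 1.5, expand = TRUE) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  lay <- phantom$layers[phantom$layers$material != "air", , drop = FALSE]
  mats <- unique(lay$material)
  mu <- fine_mu_tables(mats)
  half <- geometry$detector_mm / 2
  node_x <- (seq_len(coarse_n) - (coarse_n + 1) / 2) * (geometry$detector_mm / coarse_n)
  cell <- (geometry$detector_mm / coarse_n)^2
  keep <- spectrum$fluence > 0
  arr <- with_seed(seed, .mc_scatter_cpp(
    as.integer(n_photons),
    spectrum$energy[keep], spectrum$fluence[keep],
    sum(spectrum$fluence), half, geometry$sdd_mm,
    as.matrix(lay[, c("z0", "z1")]),
    match(lay$material, mats) - 1L,
    phantom$lateral_half_mm,
    mu$total, mu$compton, mu$rayleigh, mu$e0, mu$de,
    node_x, cell,
    as.integer(min(spectrum$energy)), length(spectrum$energy),
    as.integer(max_order), isTRUE(rayleigh)))
  # [x, y, E] -> image convention [y, x, E]
  arr <- aperm(arr, c(2, 1, 3))
  if (coarse_smooth_nodes > 0) {
    K <- gaussian_operator(coarse_n, coarse_smooth_nodes)
    for (e in seq_len(dim(arr)[3])) arr[, , e] <- K %*% arr[, , e] %*% t(K)
  }
  op <- spline_operator(node_x, pixel_centers(geometry))
  if (expand) {
    n <- geometry$n_pixels
    full <- array(0, c(n, n, dim(arr)[3]))
    for (e in seq_len(dim(arr)[3]))
      full[, , e] <- pmax(op %*% arr[, , e] %*% t(op), 0)
    new_eri(full, spectrum$energy, "scatter", pixel_centers(geometry), geometry)
  } else {
    new_eri(arr, spectrum$energy, "scatter", node_x, geometry, upsample_op = op)
  }
}

#' Sample Compton scattering angles and energies
#'
#' Klein-Nishina rejection sampler used by the transport kernel, exposed for
#' validation against quadrature of the differential cross-section.
#'
#' @param energy_kev incident photon energy, keV.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return A matrix with columns `cos_theta` and `energy_kev` (scattered).
#' @export
compton_sample <- function(energy_kev, n, seed = NULL) {
  with_seed(seed, .kn_sample_cpp(energy_kev, as.integer(n)))
}

# --- detector model ---------------------------------------------------------

# Collapse an energy-resolved image to expected LE/HE count maps on the full
# pixel grid (counts per effective pixel; pixel area = pitch^2).
collapse_to_bins <- function(eri, detector) {
  w <- bin_weights(detector, eri$energy) * eri$geometry$effective_pitch_mm^2
  d <- dim(eri$data)
  flat <- matrix(eri$data, d[1] * d[2], d[3])
  le <- matrix(flat %*% w[, "le"], d[1], d[2])
  he <- matrix(flat %*% w[, "he"], d[1], d[2])
  if (!is.null(eri$upsample_op)) {
    op <- eri$upsample_op
    le <- pmax(op %*% le %*% t(op), 0)
    he <- pmax(op %*% he %*% t(op), 0)
  }
  list(le = le, he = he)
}

new_binned_image <- function(le, he, kerma_mgy, seed = NULL) {
  structure(list(le = le, he = he, kerma_mgy = kerma_mgy, seed = seed),
            class = "binned_image")
}

#' @export
print.binned_image <- function(x, ...) {
  cat(sprintf("<binned_image> %d x %d px; kerma %.4g mGy; mean counts LE %.4g / HE %.4g\n",
              nrow(x$le), ncol(x$le), x$kerma_mgy, mean(x$le), mean(x$he)))
  invisible(x)
}

#' Apply the photon-counting detector model
#'
#' Converts energy-resolved fluence (primary plus optional scatter) into
#' low/high-energy-bin count images: counts per effective pixel are fluence
#' times pixel area times the CdTe absorption efficiency, with the recorded
#' energy blurred by a Gaussian of `sigma_kev` before threshold assignment;
#' counts are then Poisson-sampled.
#'
#' @param primary an `energy_resolved_image` (component `"primary"`).
#' @param scatter optional scatter `energy_resolved_image` on the same grid
#'   (either full-resolution or coarse with its upsampling operator).
#' @param detector a [detector_model()].
#' @param kerma_scale multiplier applied to the expected counts (e.g. `1/25`
#'   for a single blocker frame).
#' @param seed RNG seed for the Poisson draw.
#' @param sample if `FALSE`, return the noise-free expected counts.
#' @return A `binned_image` with `le` and `he` count matrices.
#' @export
apply_detector <- function(primary, scatter = NULL, detector = detector_model(),
                           kerma_scale = 1, seed = NULL, sample = TRUE) {
  exp_maps <- collapse_to_bins(primary, detector)
  if (!is.null(scatter)) {
    if (!identical(dim(scatter$data)[3], dim(primary$data)[3]))
      stop("primary and scatter energy grids differ")
    sm <- collapse_to_bins(scatter, detector)
    if (!all(dim(sm$le) == dim(exp_maps$le)))
      stop("primary and scatter pixel grids differ")
    exp_maps$le <- exp_maps$le + sm$le
    exp_maps$he <- exp_maps$he + sm$he
  }
  le <- exp_maps$le * kerma_scale
  he <- exp_maps$he * kerma_scale
  if (sample) {
    d <- dim(le)
    drawn <- with_seed(seed, list(
      le = matrix(stats::rpois(length(le), le), d[1], d[2]),
      he = matrix(stats::rpois(length(he), he), d[1], d[2])))
    le <- drawn$le; he <- drawn$he
  }
  new_binned_image(le, he, kerma_mgy = kerma_scale, seed = seed)
}

# --- blocker ----------------------------------------------------------------

# Chord length (mm, along z) of the source->pixel-column ray through the rod
# rectangle, per detector x coordinate; zero away from the shadow.
rod_chord_dz <- function(rod, position_index, geometry, x_mm) {
  c0 <- rod$positions[position_index]
  zb <- rod$plane_dist_mm
  z0 <- zb - rod$thickness_mm / 2
  z1 <- zb + rod$thickness_mm / 2
  sx <- x_mm / geometry$sdd_mm
  lo <- c0 - rod$width_mm / 2
  hi <- c0 + rod$width_mm / 2
  dz <- numeric(length(x_mm))
  flat <- abs(sx) < 1e-12
  dz[flat] <- ifelse(lo <= 0 & 0 <= hi, z1 - z0, 0)
  i <- which(!flat)
  if (length(i)) {
    za <- lo / sx[i]; zb2 <- hi / sx[i]
    zmin <- pmin(za, zb2); zmax <- pmax(za, zb2)
    dz[i] <- pmax(0, pmin(zmax, z1) - pmax(zmin, z0))
  }
  dz
}

#' Attenuate the primary image by the blocker rod
#'
#' Multiplies the primary fluence, per pixel and energy, by the Beer-Lambert
#' transmission of the ray's chord through the tungsten rod at the given
#' position.  Scatter images are by contract untouched by the blocker.
#'
#' @param primary a primary `energy_resolved_image`.
#' @param rod a [blocker_positions()] result.
#' @param position_index rod position index in `1..n`.
#' @param geometry a [beam_geometry()].
#' @return The attenuated `energy_resolved_image`.
#' @export
apply_blocker <- function(primary, rod, position_index, geometry = primary$geometry) {
  if (position_index < 1 || position_index > length(rod$positions))
    stop("position index out of range")
  pc <- primary$x_coords
  dz <- rod_chord_dz(rod, position_index, geometry, pc)
  cols <- which(dz > 0)
  if (!length(cols)) return(primary)
  w <- material_table("w")
  n <- length(pc)
  D <- geometry$sdd_mm
  # full 3-D secant factor per (row, shadow column)
  sec <- outer(pc, pc[cols], function(y, x) sqrt(x^2 + y^2 + D^2)) / D
  path <- sweep(sec, 2, dz[cols], `*`)   # mm through W per [row, col]
  mu_w <- mu_linear_mm(w, primary$energy)
  out <- primary$data
  for (e in seq_along(primary$energy)) {
    if (mu_w[e] * min(dz[cols]) > 60) { out[, cols, e] <- 0; next }
    out[, cols, e] <- out[, cols, e] * exp(-mu_w[e] * path)
  }
  new_eri(out, primary$energy, primary$component, primary$x_coords,
          primary$geometry, primary$upsample_op)
}

# --- frame acquisition ------------------------------------------------------

#' Acquire a moving-blocker frame set
#'
#' Simulates the full moving-blocker acquisition: `n` low-dose frames (one
#' per rod position, each at `1/n` of the total kerma, independent Poisson
#' seeds) plus the blocker-free expected primary and scatter truth maps at
#' full kerma.
#'
#' @param phantom,spectrum,geometry as in [project_primary()].
#' @param detector a [detector_model()].
#' @param rod a [blocker_positions()] result; its position count sets the
#'   number of frames.
#' @param mc list of [simulate_scatter()] options (`n_photons`, `max_order`,
#'   `rayleigh`, `coarse_n`, `coarse_smooth_nodes`).
#' @param seed master seed; per-frame Poisson seeds and the transport seed
#'   are fanned out deterministically with [stage_seed()].
#' @param scatter optional precomputed scatter `energy_resolved_image`
#'   (avoids re-running the transport when several frame sets share one
#'   phantom).
#' @param primary optional precomputed primary `energy_resolved_image`.
#' @param sample if `FALSE`, frames carry the noise-free expected counts.
#' @return A `frame_set`: list with `frames` (list of `binned_image`), `rod`,
#'   `truth` (expected full-kerma `primary` and `scatter` LE/HE maps),
#'   `detector`, `geometry`, and `n_frames`.
#' @export
acquire_frame_set <- function(phantom, spectrum, geometry = beam_geometry(),
                              detector = detector_model(),
                              rod = blocker_positions(25, geometry),
                              mc = list(), seed = 1L,
                              scatter = NULL, primary = NULL, sample = TRUE) {
  n_frames <- length(rod$positions)
  if (is.null(primary)) primary <- project_primary(phantom, spectrum, geometry)
  if (is.null(scatter))
    scatter <- do.call(simulate_scatter, c(
      list(phantom = phantom, spectrum = spectrum, geometry = geometry,
           seed = stage_seed(seed, "mc"), expand = FALSE), mc))
  prim_maps <- collapse_to_bins(primary, detector)
  scat_maps <- collapse_to_bins(scatter, detector)
  w <- bin_weights(detector, primary$energy) * geometry$effective_pitch_mm^2
  mu_w <- mu_linear_mm(material_table("w"), primary$energy)
  pc <- primary$x_coords
  D <- geometry$sdd_mm
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    dz <- rod_chord_dz(rod, i, geometry, pc)
    cols <- which(dz > 0)
    le <- prim_maps$le; he <- prim_maps$he
    if (length(cols)) {
      sec <- outer(pc, pc[cols], function(y, x) sqrt(x^2 + y^2 + D^2)) / D
      path <- sweep(sec, 2, dz[cols], `*`)
      sub <- primary$data[, cols, , drop = FALSE]
      d <- dim(sub)
      for (e in seq_along(primary$energy))
        sub[, , e] <- sub[, , e] * exp(-pmin(mu_w[e] * path, 700))
      flat <- matrix(sub, d[1] * d[2], d[3])
      le[, cols] <- matrix(flat %*% w[, "le"], d[1], d[2])
      he[, cols] <- matrix(flat %*% w[, "he"], d[1], d[2])
    }
    exp_le <- (le + scat_maps$le) / n_frames
    exp_he <- (he + scat_maps$he) / n_frames
    fs <- stage_seed(seed, paste0("frame", i))
    counts <- if (sample) with_seed(fs, list(
      le = matrix(stats::rpois(length(exp_le), exp_le), nrow(exp_le)),
      he = matrix(stats::rpois(length(exp_he), exp_he), nrow(exp_he))))
    else list(le = exp_le, he = exp_he)
    frames[[i]] <- new_binned_image(counts$le, counts$he,
                                    kerma_mgy = 1 / n_frames,
                                    seed = if (sample) fs else NULL)
  }
  structure(list(frames = frames, rod = rod,
                 truth = list(primary = prim_maps, scatter = scat_maps),
                 detector = detector, geometry = geometry,
                 n_frames = n_frames),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames at 1/%d kerma each, %d x %d px\n",
              x$n_frames, x$n_frames, nrow(x$frames[[1]]$le),
              ncol(x$frames[[1]]$le)))
  invisible(x)
}
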