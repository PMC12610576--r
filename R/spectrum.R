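# X-ray beam spectrum: analytic tungsten-anode bremsstrahlung model
# (Kramers-type with anode self-filtration and K-characteristic lines),
# added filtration, and air-kerma normalization at the detector entrance.

#' Generate a tungsten-anode X-ray spectrum
#'
#' Analytic spectrum model: Kramers photon-fluence shape `(kVp - E)/E`,
#' hardened by tungsten anode self-filtration, with the four W K lines
#' (58.0, 59.3, 67.2, 69.1 keV) added when the tube potential exceeds the W
#' K-edge, then filtered by the requested aluminium thickness.  The returned
#' fluence is unnormalized; use [normalize_to_kerma()] to set the dose scale.
#'
#' @param kvp tube potential in kV (40-150).
#' @param filtration_mm_al added aluminium filtration in mm.
#' @param self_filtration_mm_w effective tungsten self-filtration path in mm.
#' @param characteristic_fraction K-line fluence as a fraction of the
#'   bremsstrahlung fluence (before added filtration).
#' @return A `beam_spectrum`: list with `energy` (keV, 1 keV bins from 5 to
#'   `max(120, kvp)`), `fluence` (photons/mm^2 per bin, zero above `kvp`),
#'   `kvp`, and `filtration_mm_al`.
#' @examples
#' s <- generate_spectrum(120, 4)
#' sum(s$fluence * s$energy) / sum(s$fluence)  # mean energy, keV
#' @export
generate_spectrum <- function(kvp = 120, filtration_mm_al = 4,
                              self_filtration_mm_w = 0.003,
                              characteristic_fraction = 0.08) {
  if (kvp < 40 || kvp > 150) stop("kvp must be within [40, 150]")
  energy <- seq(5L, max(120L, as.integer(ceiling(kvp))))
  w <- material_table("w")
  fl <- pmax(kvp - energy, 0) / energy
  fl <- fl * exp(-mu_linear_mm(w, energy) * self_filtration_mm_w)
  if (kvp > 69.53 && characteristic_fraction > 0) {
    lines <- c(`58` = 0.28, `59` = 0.50, `67` = 0.17, `69` = 0.05)
    amp <- characteristic_fraction * sum(fl)
    for (le in names(lines)) {
      i <- match(as.integer(le), energy)
      fl[i] <- fl[i] + amp * lines[[le]]
    }
  }
  spec <- structure(list(energy = energy, fluence = fl, kvp = kvp,
                         filtration_mm_al = 0), class = "beam_spectrum")
  if (filtration_mm_al > 0) spec <- apply_filtration(spec, filtration_mm_al)
  validate_spectrum(spec)
}

# Multiplicative Beer-Lambert aluminium filtration.
apply_filtration <- function(spectrum, mm_al) {
  al <- material_table("al")
  spectrum$fluence <- spectrum$fluence * exp(-mu_linear_mm(al, spectrum$energy) * mm_al)
  spectrum$filtration_mm_al <- spectrum$filtration_mm_al + mm_al
  spectrum
}

validate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "beam_spectrum"))
  if (any(diff(spec$energy) != 1)) stop("spectrum bins must have 1 keV spacing")
  if (any(spec$fluence < 0)) stop("negative fluence")
  if (any(spec$fluence[spec$energy > spec$kvp] > 0))
    stop("nonzero fluence above kvp")
  spec
}

#' @export
print.beam_spectrum <- function(x, ...) {
  k <- compute_air_kerma(x)
  cat(sprintf(
    "<beam_spectrum> %g kVp, %.3g mm Al; mean energy %.1f keV; air kerma %.4g mGy\n",
    x$kvp, x$filtration_mm_al,
    sum(x$fluence * x$energy) / sum(x$fluence), k))
  invisible(x)
}

#' Read a spectrum from a two-column text file
#'
#' Plain-text format: whitespace-separated columns `energy_keV fluence`,
#' comment lines starting with `#`.  The energy grid must have 1 keV spacing.
#'
#' @param path file path.
#' @return A `beam_spectrum` (see [generate_spectrum()]); `kvp` is taken as
#'   the highest energy with nonzero fluence.
#' @export
read_spectrum <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("energy", "fluence"))
  kvp <- max(d$energy[d$fluence > 0])
  validate_spectrum(structure(
    list(energy = as.integer(d$energy), fluence = d$fluence, kvp = kvp,
         filtration_mm_al = NA_real_), class = "beam_spectrum"))
}

#' Air kerma of a beam spectrum
#'
#' `K = sum_E fluence(E) * E * (mu_en/rho)_air(E) * c`, the kinetic energy
#' released per unit mass of air at the detector-entrance plane.
#'
#' @param spectrum a `beam_spectrum` with fluence in photons/mm^2.
#' @return Air kerma in mGy.
#' @export
compute_air_kerma <- function(spectrum) {
  air <- material_table("air")
  mu_en <- lookup_mu(air, spectrum$energy, "mu_en")
  sum(spectrum$fluence * spectrum$energy * mu_en) * .KERMA_PER_FLUENCE
}

#' Rescale a spectrum to a target air kerma
#'
#' Scales the fluence uniformly (spectral shape unchanged) so that
#' [compute_air_kerma()] of the result equals `target_mgy`.
#'
#' @param spectrum a `beam_spectrum`.
#' @param target_mgy target air kerma in mGy.
#' @return The rescaled `beam_spectrum`.
#' @export
normalize_to_kerma <- function(spectrum, target_mgy = 1) {
  k <- compute_air_kerma(spectrum)
  if (k <= 0) stop("cannot normalize a zero-kerma spectrum")
  spectrum$fluence <- spectrum$fluence * (target_mgy / k)
  spectrum
}
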