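# Material attenuation data: compact compiled photon cross-section tables for
# the five materials the simulation touches (PMMA, Al, air, W, CdTe), with
# log-log interpolation between tabulated nodes.  The air table additionally
# carries the mass energy-absorption coefficient needed for kerma.

.materials_cache <- new.env(parent = emptyenv())

#' Load a material attenuation table
#'
#' Reads one of the bundled cross-section tables (or a user-supplied file in
#' the same plain-text format).  Tables tabulate, per energy node, the
#' photoelectric, Compton (incoherent), and Rayleigh (coherent) mass
#' attenuation coefficients plus their total, all in cm^2/g; the air table has
#' an extra `mu_en` column (mass energy-absorption coefficient).
#'
#' @param material one of `"pmma"`, `"al"`, `"air"`, `"w"`, `"cdte"`, or a
#'   path to a table file.
#' @return An object of class `material_table`: a list with `material`,
#'   `density` (g/cm^3), `z_over_a`, `energy` (keV, strictly increasing), and
#'   coefficient vectors `photoelectric`, `compton`, `rayleigh`, `total`, and
#'   optionally `mu_en`.
#' @examples
#' al <- material_table("al")
#' lookup_mu(al, 60, "total")
#' @export
material_table <- function(material) {
  key <- tolower(material)
  if (key %in% ls(.materials_cache)) return(get(key, envir = .materials_cache))
  path <- if (file.exists(material)) material else
    system.file("extdata", "xsect", paste0(key, ".txt"), package = "pcdexr")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown material or missing table: ", material)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getf <- function(tag) {
    ln <- grep(paste0("^# ", tag, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    trimws(sub(paste0("^# ", tag, ":"), "", ln[1]))
  }
  cols <- strsplit(trimws(sub("^#", "", hdr[length(hdr)])), "\\s+")[[1]]
  d <- utils::read.table(path, comment.char = "#", col.names = cols)
  tab <- structure(list(
    material = getf("material"),
    density = as.numeric(getf("density_g_cm3")),
    z_over_a = as.numeric(getf("z_over_a")),
    energy = d$energy_kev,
    photoelectric = d$photoelectric,
    compton = d$compton,
    rayleigh = d$rayleigh,
    total = d$total,
    mu_en = if ("mu_en" %in% names(d)) d$mu_en else NULL
  ), class = "material_table")
  validate_material_table(tab)
  if (!file.exists(material)) assign(key, tab, envir = .materials_cache)
  tab
}

validate_material_table <- function(tab) {
  with(tab, {
    if (is.unsorted(energy, strictly = TRUE))
      stop("energy grid must be strictly increasing")
    if (min(energy) > 5 || max(energy) < 120)
      stop("energy grid must cover [5, 120] keV")
    for (k in c("photoelectric", "compton", "rayleigh", "total"))
      if (any(tab[[k]] <= 0)) stop("nonpositive coefficient in column ", k)
    if (any(total < photoelectric - 1e-12) || any(total < compton - 1e-12) ||
        any(total < rayleigh - 1e-12))
      stop("total must be >= each partial coefficient")
    if (!is.finite(density) || density <= 0) stop("invalid density")
  })
  invisible(tab)
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table> %s  density %.4g g/cm^3  %d nodes [%.3g, %.3g] keV\n",
              x$material, x$density, length(x$energy), min(x$energy), max(x$energy)))
  invisible(x)
}

#' Look up a mass attenuation coefficient
#'
#' Log-log linear interpolation of the tabulated coefficients; exact at the
#' tabulated nodes, exact for power-law segments in between.  No
#' extrapolation: energies outside the tabulated range are an error.
#'
#' @param table a [material_table()].
#' @param energy_kev photon energy in keV (vectorized).
#' @param kind one of `"total"`, `"photoelectric"`, `"compton"`, `"rayleigh"`,
#'   `"mu_en"`.
#' @return Coefficient(s) in cm^2/g.
#' @export
lookup_mu <- function(table, energy_kev,
                      kind = c("total", "photoelectric", "compton",
                               "rayleigh", "mu_en")) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "material_table"))
  y <- table[[kind]]
  if (is.null(y)) stop("table for ", table$material, " has no ", kind, " column")
  e <- table$energy
  if (any(energy_kev < e[1] - 1e-9) || any(energy_kev > e[length(e)] + 1e-9))
    stop(sprintf("energy out of tabulated range [%.4g, %.4g] keV for %s",
                 e[1], e[length(e)], table$material))
  ev <- pmin(pmax(energy_kev, e[1]), e[length(e)])
  exp(stats::approx(log(e), log(y), xout = log(ev), ties = "ordered")$y)
}

# Linear attenuation coefficient in 1/mm at the material's nominal density.
mu_linear_mm <- function(table, energy_kev, kind = "total") {
  lookup_mu(table, energy_kev, kind) * table$density / 10
}

#' @rdname material_table
#' @export
list_materials <- function() c("pmma", "al", "air", "w", "cdte")
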