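# LucAl-style chest phantom: PMMA + 4.1 mm Al slab stack with a 190 mm air
# gap toward the detector, in three sizes, plus ten 25 mm cylindrical inserts
# (five PMMA, five Al) mounted on the detector-side face of the Al layer.

PMMA_INSERT_MM <- c(2, 4, 6, 8, 10)
AL_INSERT_MM <- c(0.5, 1.0, 1.5, 2.0, 2.5)

#' Build a LucAl-style chest phantom
#'
#' The background stack is, from source to detector: a PMMA slab (53, 73, or
#' 93 mm for the small/standard/large size), a 4.1 mm Al layer, and a 190 mm
#' air gap.  Ten cylindrical inserts (diameter 25 mm; PMMA 2-10 mm, Al
#' 0.5-2.5 mm) sit on a 2 x 5 grid with 50 mm center spacing on the
#' detector-side face of the Al layer: the Al row at y = +25 mm and the PMMA
#' row at y = -25 mm, ordered by thickness along x.
#'
#' @param size_class `"small"`, `"standard"`, or `"large"`.
#' @param geometry a [beam_geometry()]; the phantom assembly (slab stack plus
#'   its air gap, 247/267/287 mm total) is centered on the beam axis at the
#'   source-to-isocenter distance.
#' @param air_gap_mm air gap on the detector side of the slab stack, mm (part
#'   of the phantom assembly).
#' @param lateral_mm lateral slab size, mm (square).
#' @param insert_spacing_mm center spacing of the insert grid, mm.
#' @return A `phantom_model`: `size_class`, `layers` (data frame with
#'   material, thickness, and source-distance interval `z0`/`z1` in mm),
#'   `inserts` (data frame with material, thickness, diameter, center
#'   `cx`/`cy`, `z0`/`z1`), `lateral_half_mm`, and `air_gap_mm`.
#' @examples
#' ph <- build_phantom("standard")
#' subset(ph$layers, material != "air")
#' @export
build_phantom <- function(size_class = c("standard", "small", "large"),
                          geometry = beam_geometry(), air_gap_mm = 190,
                          lateral_mm = 300, insert_spacing_mm = 50) {
  size_class <- match.arg(size_class)
  pmma_mm <- c(small = 53, standard = 73, large = 93)[[size_class]]
  al_mm <- 4.1
  total_mm <- pmma_mm + al_mm + air_gap_mm
  # assembly (slabs + air gap) centered at the isocenter
  z_exit <- geometry$sid_mm + total_mm / 2 - air_gap_mm  # detector-side face of Al
  layers <- data.frame(
    material = c("pmma", "al", "air"),
    thickness = c(pmma_mm, al_mm, air_gap_mm),
    z1 = c(z_exit - al_mm, z_exit, z_exit + air_gap_mm)
  )
  layers$z0 <- layers$z1 - layers$thickness
  layers <- layers[, c("material", "thickness", "z0", "z1")]

  cx <- (seq_len(5) - 3) * insert_spacing_mm
  inserts <- rbind(
    data.frame(material = "al", thickness = AL_INSERT_MM, cx = cx,
               cy = insert_spacing_mm / 2),
    data.frame(material = "pmma", thickness = PMMA_INSERT_MM, cx = cx,
               cy = -insert_spacing_mm / 2)
  )
  inserts$diameter <- 25
  inserts$z0 <- z_exit
  inserts$z1 <- z_exit + inserts$thickness
  structure(list(size_class = size_class, layers = layers, inserts = inserts,
                 lateral_half_mm = lateral_mm / 2, air_gap_mm = air_gap_mm,
                 pmma_mm = pmma_mm, al_mm = al_mm),
            class = "phantom_model")
}

#' Uniform reference slab for the open-beam correction
#'
#' A plain PMMA slab (no Al layer, no inserts) used as the logarithmic
#' open-beam reference; placed with its exit face at the same plane as the
#' imaging phantoms.
#'
#' @param thickness_mm slab thickness, mm.
#' @inheritParams build_phantom
#' @return A `phantom_model` with a single PMMA layer and no inserts.
#' @export
reference_phantom <- function(thickness_mm = 60, geometry = beam_geometry(),
                              air_gap_mm = 190, lateral_mm = 300) {
  z_exit <- geometry$sid_mm + (thickness_mm + air_gap_mm) / 2 - air_gap_mm
  layers <- data.frame(material = c("pmma", "air"),
                       thickness = c(thickness_mm, air_gap_mm),
                       z0 = c(z_exit - thickness_mm, z_exit),
                       z1 = c(z_exit, z_exit + air_gap_mm))
  structure(list(size_class = "reference", layers = layers,
                 inserts = data.frame(), lateral_half_mm = lateral_mm / 2,
                 air_gap_mm = air_gap_mm, pmma_mm = thickness_mm, al_mm = 0),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  mat <- subset(x$layers, x$layers$material != "air")
  cat(sprintf("<phantom_model> %s: %s; %d inserts; air gap %g mm\n",
              x$size_class,
              paste(sprintf("%g mm %s", mat$thickness, toupper(mat$material)),
                    collapse = " + "),
              nrow(x$inserts), x$air_gap_mm))
  invisible(x)
}

#' Per-material ray path lengths through a phantom
#'
#' Traces the ray from the source through every slab layer (with its lateral
#' extent) and every cylindrical insert (exact finite-cylinder chord, axis
#' along the beam axis), for the detector position(s) requested.  Rays that
#' miss the phantom return zero paths.
#'
#' @param phantom a [build_phantom()] result.
#' @param geometry a [beam_geometry()].
#' @param x_mm,y_mm detector-plane coordinates of the ray(s), mm.  If both are
#'   `NULL`, the full effective pixel grid is traced and matrices are
#'   returned.
#' @return A named list, one element per material present (`pmma`, `al`),
#'   with path lengths in mm: vectors for explicit coordinates, or
#'   `n_pixels x n_pixels` matrices (rows = y, columns = x) for the grid.
#' @export
material_path_lengths <- function(phantom, geometry, x_mm = NULL, y_mm = NULL) {
  grid <- is.null(x_mm) && is.null(y_mm)
  if (grid) {
    pc <- pixel_centers(geometry)
    x <- rep(pc, each = length(pc))   # column-major [y, x]
    y <- rep(pc, times = length(pc))
  } else {
    stopifnot(length(x_mm) == length(y_mm))
    x <- x_mm; y <- y_mm
  }
  D <- geometry$sdd_mm
  sec <- sqrt(x^2 + y^2 + D^2) / D
  lat <- phantom$lateral_half_mm
  # furthest z at which the ray is still inside the lateral slab bounds
  amax <- pmax(abs(x), abs(y))
  z_lat <- ifelse(amax > 0, lat * D / amax, Inf)

  mats <- setdiff(unique(phantom$layers$material), "air")
  out <- stats::setNames(vector("list", length(mats)), mats)
  for (m in mats) out[[m]] <- numeric(length(x))
  for (i in seq_len(nrow(phantom$layers))) {
    m <- phantom$layers$material[i]
    if (m == "air") next
    dz <- pmax(0, pmin(phantom$layers$z1[i], z_lat) - phantom$layers$z0[i])
    out[[m]] <- out[[m]] + dz * sec
  }
  if (nrow(phantom$inserts) > 0) {
    sx <- x / D; sy <- y / D
    for (i in seq_len(nrow(phantom$inserts))) {
      ins <- phantom$inserts[i, ]
      r <- ins$diameter / 2
      # |(sx*z - cx, sy*z - cy)| <= r  =>  a z^2 + b z + c <= 0
      a <- sx^2 + sy^2
      b <- -2 * (sx * ins$cx + sy * ins$cy)
      cc <- ins$cx^2 + ins$cy^2 - r^2
      dz <- numeric(length(x))
      deg <- a < 1e-14
      if (any(deg)) dz[deg] <- ifelse(cc <= 0, ins$z1 - ins$z0, 0)
      nd <- which(!deg)
      if (length(nd)) {
        disc <- b[nd]^2 - 4 * a[nd] * cc
        hit <- disc > 0
        if (any(hit)) {
          j <- nd[hit]
          sq <- sqrt(disc[hit])
          za <- (-b[j] - sq) / (2 * a[j])
          zb <- (-b[j] + sq) / (2 * a[j])
          dz[j] <- pmax(0, pmin(zb, ins$z1) - pmax(za, ins$z0))
        }
      }
      out[[ins$material]] <- out[[ins$material]] + dz * sec
    }
  }
  if (grid) {
    n <- geometry$n_pixels
    out <- lapply(out, function(v) matrix(v, n, n))
  } else if (length(x) == 1) {
    out <- vapply(out, identity, numeric(1))
  }
  out
}

#' Write a plain-text phantom description
#'
#' Key-value provenance record of the layer stack and insert list, written
#' alongside simulation outputs.
#'
#' @param phantom a `phantom_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phantom_description <- function(phantom, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("size_class: %s", phantom$size_class), con)
  writeLines(sprintf("lateral_mm: %g", 2 * phantom$lateral_half_mm), con)
  for (i in seq_len(nrow(phantom$layers)))
    writeLines(sprintf("layer: %s %g mm [z %g..%g]",
                       phantom$layers$material[i], phantom$layers$thickness[i],
                       phantom$layers$z0[i], phantom$layers$z1[i]), con)
  for (i in seq_len(nrow(phantom$inserts)))
    writeLines(sprintf("insert: %s %g mm d=%g at (%g, %g)",
                       phantom$inserts$material[i], phantom$inserts$thickness[i],
                       phantom$inserts$diameter[i], phantom$inserts$cx[i],
                       phantom$inserts$cy[i]), con)
  invisible(path)
}
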