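# IEC 62220-2-1 style evaluation: per-insert dual-energy contrast (DEC) from
# two independent noise realizations, and the kerma-normalized dual-energy
# subtraction efficiency (DSE).

#' Region-of-interest specification for one insert
#'
#' Foreground: a disc centered on the projected insert; background: four
#' square regions flanking the insert at a fixed center offset along +/-x and
#' +/-y.  Construction fails if the foreground leaves the insert footprint or
#' any background pixel falls inside an insert footprint.
#'
#' @param phantom a [build_phantom()] result.
#' @param geometry a [beam_geometry()].
#' @param insert_index row index into `phantom$inserts`.
#' @param fg_radius_mm foreground disc radius, mm at the detector plane.
#' @param bg_offset_mm center offset of the four background squares, mm.
#' @param bg_size_mm side length of each background square, mm.
#' @return A `roi_spec`: logical `fg`/`bg` pixel masks plus the insert's
#'   material and thickness.
#' @export
roi_spec <- function(phantom, geometry, insert_index, fg_radius_mm = 8,
                     bg_offset_mm = 25, bg_size_mm = 10) {
  p <- project_insert_center(phantom, geometry, insert_index)
  if (fg_radius_mm > p["r"])
    stop("foreground disc extends beyond the insert footprint")
  fg <- disc_mask(geometry, p["x"], p["y"], fg_radius_mm)
  pc <- pixel_centers(geometry)
  square <- function(cx, cy)
    outer(abs(pc - cy) <= bg_size_mm / 2, abs(pc - cx) <= bg_size_mm / 2, `&`)
  bg <- square(p["x"] + bg_offset_mm, p["y"]) |
    square(p["x"] - bg_offset_mm, p["y"]) |
    square(p["x"], p["y"] + bg_offset_mm) |
    square(p["x"], p["y"] - bg_offset_mm)
  if (any(bg & any_insert_mask(phantom, geometry, margin_mm = 0)))
    stop("background region overlaps an insert footprint")
  if (!any(fg) || !any(bg)) stop("empty ROI")
  structure(list(fg = fg, bg = bg,
                 material = phantom$inserts$material[insert_index],
                 thickness = phantom$inserts$thickness[insert_index]),
            class = "roi_spec")
}

#' ROI means and variances
#'
#' Sample mean and sample variance (n-1 denominator) of an image over the
#' foreground and background pixel sets of an ROI.
#'
#' @param image numeric matrix.
#' @param roi a [roi_spec()] (or list with logical `fg`/`bg` masks).
#' @return List with `fg_mean`, `fg_var`, `bg_mean`, `bg_var`.
#' @export
roi_stats <- function(image, roi) {
  if (!any(roi$fg) || !any(roi$bg)) stop("empty ROI")
  list(fg_mean = mean(image[roi$fg]), fg_var = stats::var(image[roi$fg]),
       bg_mean = mean(image[roi$bg]), bg_var = stats::var(image[roi$bg]))
}

#' Dual-energy contrast (DEC) of one insert
#'
#' From two independent realizations of the same tissue-subtracted image
#' type:
#' `DEC = (d1 + d2) / (2 * sqrt(v1f + v1b + v2f + v2b))`,
#' where `d_i` is the foreground-minus-background ROI mean of realization `i`
#' and the `v` are the four ROI variances.  Dimensionless; the sign is
#' preserved.
#'
#' @param img1,img2 matrices: the two realizations (identical kerma and
#'   scatter state, independent noise seeds).
#' @param roi a [roi_spec()].
#' @return A `dec_record`: list with `dec`, the per-realization differences,
#'   and the variance sum.
#' @export
compute_dec <- function(img1, img2, roi) {
  s1 <- roi_stats(img1, roi)
  s2 <- roi_stats(img2, roi)
  vsum <- s1$fg_var + s1$bg_var + s2$fg_var + s2$bg_var
  if (vsum <= 0) stop("zero total ROI variance")
  d1 <- s1$fg_mean - s1$bg_mean
  d2 <- s2$fg_mean - s2$bg_mean
  structure(list(dec = (d1 + d2) / (2 * sqrt(vsum)), d1 = d1, d2 = d2,
                 var_sum = vsum, material = roi$material,
                 thickness = roi$thickness),
            class = "dec_record")
}

#' Dual-energy subtraction efficiency (DSE)
#'
#' Kerma normalization of a DEC value.  The printed defining formula divides
#' by the air kerma `Ka`; its stated units (mGy^-1/2) instead imply division
#' by `sqrt(Ka)`.  Both are available; the default follows the printed
#' formula, and the record labels which denominator was used.  At
#' `Ka = 1 mGy` the two coincide and DSE equals DEC numerically.
#'
#' @param dec a [compute_dec()] record or a bare numeric DEC value.
#' @param ka entrance air kerma, mGy (> 0).
#' @param denominator `"ka"` (printed formula) or `"sqrt_ka"` (units-implied).
#' @return A `dse_record`: list with `dse`, `dec`, `ka`, `denominator`.
#' @export
compute_dse <- function(dec, ka = 1, denominator = c("ka", "sqrt_ka")) {
  denominator <- match.arg(denominator)
  if (ka <= 0) stop("ka must be positive")
  d <- if (inherits(dec, "dec_record")) dec$dec else dec
  structure(list(dse = d / if (denominator == "ka") ka else sqrt(ka),
                 dec = d, ka = ka, denominator = denominator),
            class = "dse_record")
}

#' Tabulate DEC/DSE across an experiment
#'
#' Builds the tidy result table from a [run_experiment()] result: one row per
#' (phantom size, scatter state, image type, feature material, insert
#' thickness) with the DEC, the DSE at the run kerma, whether the feature is
#' the image's target material, and the relative DEC change of the corrected
#' versus the uncorrected state.
#'
#' @param experiment a [run_experiment()] result.
#' @return A data frame (180 rows for the full 3-size matrix).
#' @export
dec_report <- function(experiment) {
  rows <- list()
  for (size in names(experiment$sizes)) {
    res <- experiment$sizes[[size]]
    for (state in names(res$dec)) {
      tab <- res$dec[[state]]
      tab$size <- size
      tab$state <- state
      rows[[length(rows) + 1]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  out$target <- (out$image == "s" & out$material == "pmma") |
    (out$image == "b" & out$material == "al")
  out$dse <- vapply(out$dec, function(d)
    compute_dse(d, experiment$config$total_mgy)$dse, numeric(1))
  # relative change corrected vs uncorrected
  out$rel_change_pct <- NA_real_
  key <- function(d) paste(d$size, d$image, d$material, d$thickness)
  unc <- out[out$state == "uncorrected", ]
  idx <- match(key(out), key(unc))
  out$rel_change_pct <- ifelse(
    out$state == "corrected" & !is.na(idx),
    (out$dec - unc$dec[idx]) / unc$dec[idx] * 100, NA_real_)
  missing_states <- setdiff(c("none", "uncorrected", "corrected"),
                            unique(out$state))
  if (length(missing_states))
    warning("incomplete run matrix; missing states: ",
            paste(missing_states, collapse = ", "))
  rownames(out) <- NULL
  out[, c("size", "state", "image", "material", "thickness", "target",
          "dec", "dse", "rel_change_pct")]
}

#' Plot DEC against insert thickness
#'
#' One panel per image type, target and non-target curves per scatter state.
#'
#' @param report a [dec_report()] data frame (one phantom size).
#' @param size phantom size to plot.
#' @return Invisibly, the subset plotted.
#' @export
plot_dec <- function(report, size = report$size[1]) {
  d <- report[report$size == size, ]
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (img in c("b", "s")) {
    di <- d[d$image == img, ]
    graphics::plot(range(di$thickness), range(di$dec), type = "n",
                   xlab = "insert thickness (mm)", ylab = "DEC",
                   main = sprintf("%s-enhanced image (%s phantom)",
                                  if (img == "b") "Al" else "PMMA", size))
    cols <- c(none = "grey40", uncorrected = "red3", corrected = "blue3")
    for (state in unique(di$state)) for (tg in c(TRUE, FALSE)) {
      dd <- di[di$state == state & di$target == tg, ]
      dd <- dd[order(dd$thickness), ]
      if (nrow(dd))
        graphics::lines(dd$thickness, dd$dec, col = cols[[state]],
                        lty = if (tg) 1 else 2, type = "b",
                        pch = if (tg) 19 else 1)
    }
    graphics::legend("topleft", bty = "n", cex = 0.8,
                     legend = c(paste(names(cols), "(target)"), "non-target"),
                     col = c(cols, "grey40"), lty = c(1, 1, 1, 2))
  }
  invisible(d)
}
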