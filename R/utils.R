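# Internal numerical helpers shared across modules.
# Unit conventions (package-wide): energies keV, lengths mm, densities g/cm^3,
# mass attenuation cm^2/g, fluence photons/mm^2, kerma mGy.

#' @useDynLib pcdexr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage random seed from a master seed
#'
#' Deterministic fan-out of one master seed into independent per-stage seeds,
#' so that every stochastic stage of a run is reproducible from a single knob.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- 0
  for (ch in utf8ToInt(paste0(stage))) h <- (h * 131 + ch) %% 2147483629
  v <- ((abs(master) %% 2147483629) * 69069 + h) %% 2147483629
  as.integer(v) + 1L
}

# Row-normalized Gaussian smoothing operator for an n-point 1-D grid.
# Truncated at 4 sigma; row renormalization makes the operator exact for
# constant fields including at the boundaries.
gaussian_operator <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  idx <- seq_len(n)
  d <- outer(idx, idx, function(i, j) abs(i - j))
  K <- exp(-0.5 * (d / sigma_px)^2)
  K[d > ceiling(4 * sigma_px)] <- 0
  K / rowSums(K)
}

#' Gaussian smoothing of an image matrix
#'
#' Separable Gaussian filter with kernel renormalization at the image
#' boundaries, so constant fields are reproduced exactly.
#'
#' @param img numeric matrix.
#' @param sigma_px kernel standard deviation in pixels; `0` returns `img`.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(img, sigma_px) {
  stopifnot(is.matrix(img))
  if (sigma_px <= 0) return(img)
  Kr <- gaussian_operator(nrow(img), sigma_px)
  Kc <- gaussian_operator(ncol(img), sigma_px)
  Kr %*% img %*% t(Kc)
}

# Linear operator mapping values at `from_x` to natural-cubic-spline values at
# `to_x`, with clamp-to-nearest-sample behaviour outside [min(from_x),
# max(from_x)] (no extrapolation).  Returns a length(to_x) x length(from_x)
# matrix; exact for constant and linear fields in the interior.
spline_operator <- function(from_x, to_x) {
  m <- length(from_x)
  stopifnot(m >= 4, !is.unsorted(from_x, strictly = TRUE))
  tx <- pmin(pmax(to_x, min(from_x)), max(from_x))
  op <- matrix(0, length(to_x), m)
  for (j in seq_len(m)) {
    basis <- numeric(m); basis[j] <- 1
    op[, j] <- stats::splinefun(from_x, basis, method = "natural")(tx)
  }
  op
}

# Physics constants
.KERMA_PER_FLUENCE <- 1.602176634e-8  # mGy per (photon/mm^2 * keV * cm^2/g)
.ELECTRON_REST_KEV <- 510.99895
.R_E_CM <- 2.8179403e-13
.N_AVOGADRO <- 6.02214076e23

#' Total Klein-Nishina cross-section
#'
#' Closed-form integrated Compton cross-section per electron.
#'
#' @param energy_kev photon energy in keV (vectorized).
#' @return Cross-section in cm^2 per electron.
#' @export
klein_nishina_sigma <- function(energy_kev) {
  k <- energy_kev / .ELECTRON_REST_KEV
  t1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  t2 <- log(1 + 2 * k) / (2 * k)
  t3 <- (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * .R_E_CM^2 * (t1 + t2 - t3)
}

#' Klein-Nishina differential cross-section
#'
#' Differential Compton cross-section per electron per steradian at scattering
#' angle `theta` with `cos(theta) = cos_theta`.
#'
#' @param energy_kev incident photon energy in keV.
#' @param cos_theta cosine of the scattering angle (vectorized).
#' @return dsigma/dOmega in cm^2/sr.
#' @export
klein_nishina_dcs <- function(energy_kev, cos_theta) {
  k <- energy_kev / .ELECTRON_REST_KEV
  kappa <- 1 / (1 + k * (1 - cos_theta))   # E'/E
  0.5 * .R_E_CM^2 * kappa^2 * (kappa + 1 / kappa - (1 - cos_theta^2))
}
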