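## Dosiomics: scale-invariant 3D dose moments, DVH Vx/Dx metrics, and
## original-image dose texture inside the esophagus mask.

#' The 63 scale-invariant dose moment indices
#'
#' All (p, q, r) with each order in 0..3, excluding (0, 0, 0) whose invariant
#' is identically 1: 4^3 - 1 = 63 combinations.
#'
#' @return 63 x 3 integer matrix with columns p, q, r.
#' @export
moment_indices <- function() {
  g <- as.matrix(expand.grid(p = 0:3, q = 0:3, r = 0:3))
  g[rowSums(g) > 0L, , drop = FALSE]
}

#' Scale-invariant 3D dose moments
#'
#' Central geometric moments of the dose field about its dose-weighted
#' centroid in physical mm coordinates, normalized by the zeroth moment:
#' `eta_pqr = mu_pqr / mu_000^(1 + (p+q+r)/3)`. The exponent makes `eta`
#' invariant under spatial rescaling of the grid, and the `mu_000` ratio makes
#' it invariant under multiplying the dose by a constant.
#'
#' @param dose Dose [volume_grid()] (Gy, non-negative).
#' @param mask Binary [volume_grid()] sharing the dose geometry.
#' @return Named numeric vector of 63 features `dose_moment_eta_pqr`.
#' @export
dose_moments <- function(dose, mask) {
  stopifnot(inherits(dose, "volume_grid"), inherits(mask, "volume_grid"))
  if (!same_geometry(dose, mask)) stop("dose and mask must share grid geometry")
  m <- mask$values > 0.5
  if (!any(m)) stop("mask is empty")
  d <- dose$values[m]
  if (any(d < 0)) stop("dose must be non-negative")
  tot <- sum(d)
  if (tot <= 0) stop("undefined centroid: total in-mask dose is zero")
  w <- which(m, arr.ind = TRUE)
  x <- (w[, 1] - 1) * dose$spacing_mm[1]
  y <- (w[, 2] - 1) * dose$spacing_mm[2]
  z <- (w[, 3] - 1) * dose$spacing_mm[3]
  cx <- sum(x * d) / tot; cy <- sum(y * d) / tot; cz <- sum(z * d) / tot
  # voxel volume weight keeps mu_000 a physical integral (Gy mm^3): required
  # for scale invariance under resampling
  vv <- prod(dose$spacing_mm)
  xp <- outer(x - cx, 0:3, `^`)
  yp <- outer(y - cy, 0:3, `^`)
  zp <- outer(z - cz, 0:3, `^`)
  # all 64 raw central moments in one product: W[, 4q+p+1] = D x^p y^q,
  # crossprod(W, zp)[4q+p+1, r+1] = sum D x^p y^q z^r
  W <- (d * xp)[, rep(1:4, times = 4)] * yp[, rep(1:4, each = 4)]
  M <- crossprod(W, zp) * vv
  idx <- moment_indices()
  mu000 <- tot * vv
  mu <- M[cbind(idx[, 2] * 4 + idx[, 1] + 1, idx[, 3] + 1)]
  eta <- mu / mu000^(1 + rowSums(idx) / 3)
  names(eta) <- sprintf("dose_moment_eta_%d%d%d", idx[, 1], idx[, 2], idx[, 3])
  eta
}

#' Cumulative dose-volume histogram
#'
#' @param dose Dose [volume_grid()].
#' @param mask Binary [volume_grid()] sharing the dose geometry.
#' @param bin_gy Dose bin width in Gy (default 0.01).
#' @return Object of class `dvh_curve`: dose grid (Gy), cumulative volume in
#'   cc and in % of the mask volume (volume receiving >= each dose level).
#' @export
dvh <- function(dose, mask, bin_gy = 0.01) {
  stopifnot(inherits(dose, "volume_grid"), inherits(mask, "volume_grid"))
  if (!same_geometry(dose, mask)) stop("dose and mask must share grid geometry")
  m <- mask$values > 0.5
  if (!any(m)) stop("mask is empty")
  d <- dose$values[m]
  vox_cc <- voxel_volume_cc(dose)
  grid <- seq(0, max(d) + bin_gy, by = bin_gy)
  # volume receiving a dose >= each grid level (right-continuous step curve)
  n_ge <- length(d) - findInterval(grid - 1e-12, sort(d))
  cc <- n_ge * vox_cc
  structure(list(dose_gy = grid, volume_cc = cc,
                 volume_pct = 100 * n_ge / length(d),
                 total_cc = length(d) * vox_cc, bin_gy = bin_gy),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %.1f cc structure, dose 0 to %.2f Gy (%d bins of %.3g Gy)\n",
              x$total_cc, max(x$dose_gy), length(x$dose_gy), x$bin_gy))
  invisible(x)
}

#' Vx: volume receiving more than x Gy
#'
#' Linear interpolation of the cumulative DVH at dose `x_gy`. Below the
#' minimum in-mask dose this is 100% of the structure.
#'
#' @param curve A [dvh()] curve.
#' @param x_gy Dose threshold in Gy.
#' @return Named vector: `pct` (% of mask volume) and `cc`.
#' @export
vx <- function(curve, x_gy) {
  stopifnot(inherits(curve, "dvh_curve"))
  pct <- stats::approx(curve$dose_gy, curve$volume_pct, xout = x_gy,
                       yleft = 100, yright = 0, ties = "ordered")$y
  cc <- stats::approx(curve$dose_gy, curve$volume_cc, xout = x_gy,
                      yleft = curve$total_cc, yright = 0, ties = "ordered")$y
  c(pct = pct, cc = cc)
}

#' Dx: minimum dose to the hottest x% of the volume
#'
#' Inverse DVH query with linear interpolation: the largest dose `d` such
#' that the relative volume receiving at least `d` is still `>= x_percent`.
#' `dx(curve, 100)` is the minimum in-mask dose (to within one dose bin).
#'
#' @param curve A [dvh()] curve.
#' @param x_percent Relative volume in \[0, 100\].
#' @return Dose in Gy.
#' @export
dx <- function(curve, x_percent) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (x_percent < 0 || x_percent > 100) stop("x_percent must be in [0, 100]")
  v <- curve$volume_pct
  g <- curve$dose_gy
  n <- length(v)
  if (x_percent <= v[n]) return(g[n])
  # v is non-increasing; last index where volume is still >= x
  k <- max(which(v >= x_percent))
  if (k == n || v[k] == v[k + 1]) return(g[k])
  g[k] + (g[k + 1] - g[k]) * (v[k] - x_percent) / (v[k] - v[k + 1])
}

#' Dosiomics extraction configuration
#'
#' @param vx_grid_gy Dose thresholds (Gy) for Vx queries; default
#'   `c(0.99, seq(1, 70, by = 5))` — the sub-Gy V0.99 plus a 5-Gy grid.
#' @param dx_grid_pct Relative-volume queries (%) for Dx; default
#'   `c(2, 5, 50, 95, 98)`.
#' @param bin_counts Bin counts for the dose texture block (original image
#'   only); default `c(20, 50)`.
#' @param texture_families Subset of `c("glcm", "glrlm")`.
#' @param vx_as_pct If TRUE (default) Vx features are reported as % volume,
#'   otherwise in cc.
#' @return A list of class `dosiomics_config`.
#' @export
dosiomics_config <- function(vx_grid_gy = c(0.99, seq(1, 70, by = 5)),
                             dx_grid_pct = c(2, 5, 50, 95, 98),
                             bin_counts = c(20, 50),
                             texture_families = c("glcm", "glrlm"),
                             vx_as_pct = TRUE) {
  if (any(vx_grid_gy < 0)) stop("Vx thresholds must be non-negative")
  if (any(dx_grid_pct < 0 | dx_grid_pct > 100)) stop("Dx queries must be in [0, 100]")
  structure(list(vx_grid_gy = vx_grid_gy, dx_grid_pct = dx_grid_pct,
                 bin_counts = as.integer(bin_counts),
                 texture_families = match.arg(tolower(texture_families),
                                              c("glcm", "glrlm"), several.ok = TRUE),
                 vx_as_pct = isTRUE(vx_as_pct)),
            class = "dosiomics_config")
}

#' Expected dosiomics feature count for a configuration
#'
#' `63 moments + |vx grid| + |dx grid| + 12 + |bins| * (1 + 6 [glcm] + 7 [glrlm])`.
#'
#' @param config A [dosiomics_config()].
#' @return Integer feature count.
#' @export
dosiomics_feature_count <- function(config) {
  per_bin <- 1 + 6 * ("glcm" %in% config$texture_families) +
    7 * ("glrlm" %in% config$texture_families)
  as.integer(63 + length(config$vx_grid_gy) + length(config$dx_grid_pct) +
               12 + length(config$bin_counts) * per_bin)
}

#' Dose texture features
#'
#' Reuses the radiomics first-order and texture operators on the dose grid
#' (original image only, no filtered variants). Names carry the `dose_`
#' prefix so they never collide with CT features.
#'
#' @param dose Dose [volume_grid()].
#' @param mask Binary [volume_grid()].
#' @param bin_counts Discretization bin counts.
#' @param texture_families Subset of `c("glcm", "glrlm")`.
#' @return Named numeric vector.
#' @export
dose_texture <- function(dose, mask, bin_counts = c(20, 50),
                         texture_families = c("glcm", "glrlm")) {
  cfg <- radiomics_config(bin_counts = bin_counts, image_filters = "original",
                          texture_families = texture_families)
  f <- extract_radiomics(dose, mask, cfg)
  names(f) <- paste0("dose_", names(f))
  f
}

#' Extract the dosiomics feature vector
#'
#' Concatenates the 63 scale-invariant dose moments, the configured DVH
#' Vx/Dx grid, and the original-image dose texture block. Deterministic and
#' name-stable.
#'
#' @param dose Dose [volume_grid()].
#' @param mask Binary [volume_grid()], typically HU-refined.
#' @param config A [dosiomics_config()].
#' @return Named numeric vector of length [dosiomics_feature_count()].
#' @export
extract_dosiomics <- function(dose, mask, config = dosiomics_config()) {
  eta <- dose_moments(dose, mask)
  curve <- dvh(dose, mask)
  vxs <- vapply(config$vx_grid_gy, function(x)
    unname(vx(curve, x)[if (config$vx_as_pct) "pct" else "cc"]), numeric(1))
  names(vxs) <- sprintf("dose_dvh_v%ggy_%s", config$vx_grid_gy,
                        if (config$vx_as_pct) "pct" else "cc")
  dxs <- vapply(config$dx_grid_pct, function(x) dx(curve, x), numeric(1))
  names(dxs) <- sprintf("dose_dvh_d%gpct_gy", config$dx_grid_pct)
  tex <- dose_texture(dose, mask, config$bin_counts, config$texture_families)
  c(eta, vxs, dxs, tex)
}
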