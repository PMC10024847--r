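## CT radiomics: first-order and texture features inside a refined mask,
## over equal-width discretizations at several bin counts and over filtered
## image variants (undecimated Haar wavelet sub-bands, Laplacian-of-Gaussian).

#' Radiomics extraction configuration
#'
#' @param bin_counts Integer vector of discretization bin counts (equal-width
#'   bins over the in-mask intensity range). Default is the ten-count grid
#'   `c(20, 30, 40, 50, 80, 100, 150, 200, 250, 300)`.
#' @param image_filters Subset of `c("original", "wavelet", "log_sigma")`.
#' @param log_sigmas_mm Gaussian scales (mm) for the Laplacian-of-Gaussian
#'   filter; default `c(1, 2, 3)`.
#' @param texture_families Subset of `c("glcm", "glrlm")`.
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(bin_counts = c(20, 30, 40, 50, 80, 100, 150, 200, 250, 300),
                             image_filters = c("original", "wavelet", "log_sigma"),
                             log_sigmas_mm = c(1, 2, 3),
                             texture_families = c("glcm", "glrlm")) {
  bin_counts <- as.integer(bin_counts)
  if (any(bin_counts < 2L)) stop("bin counts must be >= 2")
  image_filters <- match.arg(image_filters, c("original", "wavelet", "log_sigma"),
                             several.ok = TRUE)
  texture_families <- match.arg(tolower(texture_families), c("glcm", "glrlm"),
                                several.ok = TRUE)
  if (any(log_sigmas_mm <= 0)) stop("LoG sigmas must be positive")
  structure(list(bin_counts = bin_counts, image_filters = image_filters,
                 log_sigmas_mm = as.numeric(log_sigmas_mm),
                 texture_families = texture_families),
            class = "radiomics_config")
}

#' Expected radiomics feature count for a configuration
#'
#' Count formula: `n_variants * (12 + |bins| * (1 + 6 [glcm] + 7 [glrlm]))`
#' where `n_variants = 1 [original] + 8 [wavelet] + |sigmas| [log_sigma]`,
#' 12 is the bin-free first-order block and the per-bin block is entropy plus
#' the texture families.
#'
#' @param config A [radiomics_config()].
#' @return Integer feature count.
#' @export
radiomics_feature_count <- function(config) {
  nv <- sum(c("original" %in% config$image_filters,
              8 * ("wavelet" %in% config$image_filters),
              length(config$log_sigmas_mm) * ("log_sigma" %in% config$image_filters)))
  per_bin <- 1 + 6 * ("glcm" %in% config$texture_families) +
    7 * ("glrlm" %in% config$texture_families)
  as.integer(nv * (12 + length(config$bin_counts) * per_bin))
}

#' Discretize intensities into equal-width bins
#'
#' Equal-width bins over `[min, max]` of the supplied values; the maximum maps
#' to `bin_count`; a constant region occupies bin 1 only.
#'
#' @param values Numeric vector of in-mask intensities.
#' @param bin_count Number of bins (>= 2).
#' @return Integer bin labels in `1..bin_count`.
#' @export
discretize <- function(values, bin_count) {
  if (length(values) == 0L) stop("empty value set")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  w <- (rng[2] - rng[1]) / bin_count
  pmin(as.integer(floor((values - rng[1]) / w)) + 1L, as.integer(bin_count))
}

#' First-order intensity statistics
#'
#' Population-moment conventions: variance uses the `n` denominator, skewness
#' is the third standardized moment, kurtosis the (non-excess) fourth; both
#' are defined as 0 for a constant region. Entropy is computed separately per
#' discretization (see [extract_radiomics()]).
#'
#' @param values Numeric vector of in-mask intensities (>= 1 voxel).
#' @return Named numeric vector: mean, median, variance, skewness, kurtosis,
#'   energy, min, max, range, p10, p90, iqr.
#' @export
first_order_features <- function(values) {
  if (length(values) == 0L) stop("first-order features need at least one voxel")
  m <- mean(values)
  v <- mean((values - m)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((values - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((values - m)^4) / s^4 else 0
  q <- unname(stats::quantile(values, c(0.1, 0.25, 0.75, 0.9)))
  c(mean = m, median = stats::median(values), variance = v, skewness = skew,
    kurtosis = kurt, energy = sum(values^2), min = min(values),
    max = max(values), range = diff(range(values)), p10 = q[1], p90 = q[4],
    iqr = q[3] - q[2])
}

# Shannon entropy (bits) of discretized labels
bin_entropy <- function(labels) {
  p <- tabulate(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# the 13 unique 3D direction offsets (one of each +/- pair)
offsets_13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# slice ranges for an offset so that voxel and voxel+offset are both in-grid;
# empty when the grid is thinner than the offset
offset_slices <- function(d, off) {
  lapply(1:3, function(a) {
    if (off[a] >= 0) seq_len(max(d[a] - off[a], 0L))
    else if (1 - off[a] > d[a]) integer(0)
    else (1 - off[a]):d[a]
  })
}

#' Grey-level co-occurrence matrix for one direction
#'
#' Counts ordered in-mask voxel pairs at the given integer offset, symmetrized
#' (both orderings) and normalized to sum 1.
#'
#' @param bins Integer 3D array of bin labels, 0 outside the mask.
#' @param n_levels Number of grey levels.
#' @param offset Integer length-3 voxel offset.
#' @return `n_levels x n_levels` matrix summing to 1, or NULL if no pairs.
#' @export
glcm_matrix <- function(bins, n_levels, offset = c(1, 0, 0)) {
  d <- dim(bins)
  sl <- offset_slices(d, offset)
  a <- bins[sl[[1]], sl[[2]], sl[[3]]]
  b <- bins[sl[[1]] + offset[1], sl[[2]] + offset[2], sl[[3]] + offset[3]]
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(NULL)
  counts <- tabulate((a[ok] - 1L) * n_levels + b[ok], nbins = n_levels^2)
  M <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  M <- M + t(M)
  M / sum(M)
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 1
  nz <- P > 0
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    energy = sum(P^2),
    joint_entropy = -sum(P[nz] * log2(P[nz])),
    idm = sum(P / (1 + (i - j)^2)),
    correlation = corr)
}

# per-patient texture context: for each of the 13 directions, the linear
# index pairs of in-mask neighbours (GLCM) and the mask-restricted line
# traversal with run-break flags (GLRLM); depends only on the mask, so it is
# computed once and reused across image variants and bin counts
.ctx_cache <- new.env(parent = emptyenv())

texture_context <- function(mask, need_runs = TRUE) {
  d <- dim(mask)
  cached <- .ctx_cache$ctx
  if (!is.null(cached) && identical(.ctx_cache$dim, d) &&
      identical(.ctx_cache$mask, mask) &&
      (!need_runs || !is.null(cached$runs)))
    return(cached)
  step3 <- c(1L, d[1], d[1] * d[2])
  pairs <- vector("list", nrow(offsets_13))
  runs <- if (need_runs) vector("list", nrow(offsets_13)) else NULL
  mv <- as.vector(mask)
  for (k in seq_len(nrow(offsets_13))) {
    off <- offsets_13[k, ]
    sl <- offset_slices(d, off)
    nb <- array(FALSE, d)
    nb[sl[[1]], sl[[2]], sl[[3]]] <-
      mask[sl[[1]] + off[1], sl[[2]] + off[2], sl[[3]] + off[3]]
    i1 <- which(mask & nb)
    pairs[[k]] <- list(i1 = i1, i2 = i1 + sum(off * step3))
    if (need_runs) {
      ln <- glrlm_lines(d, off)
      sel <- mv[ln$ord]
      ord_m <- ln$ord[sel]
      line_id <- cumsum(ln$new_line)[sel]
      pos <- seq_along(ln$ord)[sel]
      n <- length(ord_m)
      brk <- if (n > 1)
        c(TRUE, line_id[-1] != line_id[-n] | pos[-1] != pos[-n] + 1L) else TRUE
      runs[[k]] <- list(ord = ord_m, brk = brk)
    }
  }
  ctx <- list(pairs = pairs, runs = runs, n_voxels = sum(mask))
  .ctx_cache$ctx <- ctx; .ctx_cache$dim <- d; .ctx_cache$mask <- mask
  ctx
}

glcm_features_ctx <- function(bins_vec, n_levels, ctx) {
  acc <- NULL; nd <- 0L
  for (k in seq_along(ctx$pairs)) {
    pr <- ctx$pairs[[k]]
    if (length(pr$i1) == 0L) next
    counts <- tabulate((bins_vec[pr$i1] - 1L) * n_levels + bins_vec[pr$i2],
                       nbins = n_levels^2)
    M <- matrix(counts, n_levels, n_levels, byrow = TRUE)
    M <- M + t(M)
    f <- glcm_features_one(M / sum(M))
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("undefined texture: no in-mask voxel pairs in any direction")
  acc / nd
}

glrlm_features_ctx <- function(bins_vec, n_levels, ctx) {
  acc <- NULL
  for (k in seq_along(ctx$runs)) {
    rn <- ctx$runs[[k]]
    v <- bins_vec[rn$ord]
    n <- length(v)
    start <- rn$brk | c(TRUE, v[-1] != v[-n])
    lens <- tabulate(cumsum(start))
    vals <- v[start]
    max_len <- max(lens)
    counts <- tabulate((vals - 1L) * max_len + lens, nbins = n_levels * max_len)
    R <- matrix(counts, n_levels, max_len, byrow = TRUE)
    f <- glrlm_features_one(R, ctx$n_voxels)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / length(ctx$runs)
}

#' Direction-averaged GLCM features
#'
#' Accumulates a symmetric, normalized co-occurrence matrix for each of the 13
#' unique 3D direction offsets at distance 1 and averages the derived features
#' (contrast, dissimilarity, energy, joint entropy, inverse difference moment,
#' correlation) over directions.
#'
#' @param bins Integer 3D array of bin labels, 0 outside the mask.
#' @param n_levels Number of grey levels used by the discretization.
#' @return Named numeric vector of 6 features.
#' @export
glcm_features <- function(bins, n_levels) {
  if (sum(bins > 0L) < 2L) stop("undefined texture: mask has fewer than 2 voxels")
  ctx <- texture_context(bins > 0L)
  glcm_features_ctx(as.integer(bins), n_levels, ctx)
}

.glrlm_cache <- new.env(parent = emptyenv())

# line decomposition of a grid for one direction: voxel visit order plus
# line-start flags; depends only on (shape, offset), so cached
glrlm_lines <- function(d, offset) {
  ckey <- paste(c(d, offset), collapse = ",")
  hit <- .glrlm_cache[[ckey]]
  if (!is.null(hit)) return(hit)
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  t_par <- ix * offset[1] + iy * offset[2] + iz * offset[3]
  step <- sum(offset^2)
  tq <- t_par %/% step
  # anchor: coordinates projected back to t = 0 identify the line
  a1 <- ix - tq * offset[1]; a2 <- iy - tq * offset[2]; a3 <- iz - tq * offset[3]
  # collapse anchor to a single key (values bounded by grid size + max |t|);
  # numeric arithmetic to avoid 32-bit overflow on the mixed-radix encoding
  span <- as.numeric(max(d) * 4L)
  key <- (a1 + span) + (2 * span) * ((a2 + span) + (2 * span) * (a3 + span))
  # consecutive voxels along a line differ in t_par by exactly `step`
  ord <- order(key, t_par)
  k <- key[ord]
  res <- list(ord = ord, new_line = c(TRUE, k[-1] != k[-length(k)]))
  if (length(ls(.glrlm_cache)) > 256L) rm(list = ls(.glrlm_cache), envir = .glrlm_cache)
  .glrlm_cache[[ckey]] <- res
  res
}

#' Grey-level run-length matrix for one direction
#'
#' Decomposes the grid into the maximal lines along `offset`, splits each line
#' into runs of consecutive in-mask voxels with equal bin label, and counts
#' runs by (grey level, run length).
#'
#' @param bins Integer 3D array of bin labels, 0 outside the mask.
#' @param n_levels Number of grey levels.
#' @param offset Integer length-3 voxel step.
#' @return `n_levels x max_run_length` count matrix.
#' @export
glrlm_matrix <- function(bins, n_levels, offset = c(1, 0, 0)) {
  d <- dim(bins)
  ln <- glrlm_lines(d, offset)
  v <- as.integer(bins)[ln$ord]
  start <- ln$new_line | c(TRUE, v[-1] != v[-length(v)])
  run_id <- cumsum(start)
  lens <- tabulate(run_id)
  vals <- v[start]
  keep <- vals > 0L
  lens <- lens[keep]; vals <- vals[keep]
  max_len <- max(lens, 1L)
  counts <- tabulate((vals - 1L) * max_len + lens, nbins = n_levels * max_len)
  matrix(counts, n_levels, max_len, byrow = TRUE)
}

glrlm_features_one <- function(R, n_voxels) {
  Nr <- sum(R)
  lev <- seq_len(nrow(R)); len <- seq_len(ncol(R))
  ri <- rowSums(R); rl <- colSums(R)
  c(sre = sum(rl / len^2) / Nr,
    lre = sum(rl * len^2) / Nr,
    gln = sum(ri^2) / Nr,
    rln = sum(rl^2) / Nr,
    rp = Nr / n_voxels,
    lglre = sum(ri / lev^2) / Nr,
    hglre = sum(ri * lev^2) / Nr)
}

#' Direction-averaged GLRLM features
#'
#' Run-length matrices over the 13 unique 3D directions, features averaged
#' across directions: short/long run emphasis, grey-level and run-length
#' non-uniformity, run percentage, low/high grey-level run emphasis.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 7 features.
#' @export
glrlm_features <- function(bins, n_levels) {
  if (sum(bins > 0L) < 2L) stop("undefined texture: mask has fewer than 2 voxels")
  ctx <- texture_context(bins > 0L)
  glrlm_features_ctx(as.integer(bins), n_levels, ctx)
}

## ---- image filters ----

# shift array along one axis with edge replication
shift_axis <- function(a, axis, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# separable 1D convolution along an axis with edge-replicated boundaries,
# as one banded-matrix product (out[i] = sum_k kernel[k] * a[clamp(i+k-r-1)])
conv_axis <- function(a, axis, kernel) {
  d <- dim(a); n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    src <- pmin(pmax(seq_len(n) + (k - 1L - r), 1L), n)
    ij <- cbind(seq_len(n), src)
    K[ij] <- K[ij] + kernel[k]
  }
  if (axis == 1L) {
    array(K %*% matrix(a, n), d)
  } else if (axis == 2L) {
    p <- aperm(a, c(2, 1, 3))
    aperm(array(K %*% matrix(p, n), d[c(2, 1, 3)]), c(2, 1, 3))
  } else {
    array(matrix(a, ncol = n) %*% t(K), d)
  }
}

#' Single-level undecimated 3D Haar wavelet decomposition
#'
#' Applies the 2-tap orthonormal Haar low/high-pass pair `(1, 1)/sqrt(2)` and
#' `(1, -1)/sqrt(2)` along each axis without decimation, yielding 8 sub-band
#' volumes of the input shape named `LLL ... HHH` (letters give the filter on
#' the x, y, z axes in order). A constant volume maps to a constant `LLL`
#' with gain `2^(3/2)` and (numerically) zero high-pass bands.
#'
#' @param values 3D numeric array (each dimension >= 2).
#' @return Named list of 8 arrays.
#' @export
wavelet_bands <- function(values) {
  if (any(dim(values) < 2L)) stop("volume too small for wavelet filtering")
  s2 <- 1 / sqrt(2)
  lo <- function(a, ax) s2 * (a + shift_axis(a, ax, 1L))
  hi <- function(a, ax) s2 * (a - shift_axis(a, ax, 1L))
  out <- list()
  for (fx in c("L", "H")) {
    ax1 <- if (fx == "L") lo(values, 1L) else hi(values, 1L)
    for (fy in c("L", "H")) {
      ax2 <- if (fy == "L") lo(ax1, 2L) else hi(ax1, 2L)
      for (fz in c("L", "H"))
        out[[paste0(fx, fy, fz)]] <- if (fz == "L") lo(ax2, 3L) else hi(ax2, 3L)
    }
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Laplacian-of-Gaussian filter
#'
#' Separable Gaussian smoothing at physical scale `sigma_mm` followed by the
#' 6-neighbour discrete Laplacian (second differences divided by the squared
#' spacing per axis). Interior response on a constant volume is zero.
#'
#' @param values 3D numeric array.
#' @param sigma_mm Gaussian scale in mm.
#' @param spacing_mm Voxel spacing (length 3, mm).
#' @return Filtered array of the input shape.
#' @export
log_filter <- function(values, sigma_mm, spacing_mm = c(1, 1, 1)) {
  if (sigma_mm <= 0) stop("sigma must be positive")
  if (any(dim(values) < 3L)) stop("volume too small for LoG filtering")
  sm <- values
  for (ax in 1:3)
    sm <- conv_axis(sm, ax, gaussian_kernel(sigma_mm / spacing_mm[ax]))
  lap <- array(0, dim(values))
  for (ax in 1:3)
    lap <- lap + (shift_axis(sm, ax, 1L) - 2 * sm + shift_axis(sm, ax, -1L)) /
      spacing_mm[ax]^2
  lap
}

## ---- full extraction ----

# features for one image variant: in-mask values, shared texture context,
# linear mask indices and total box length to scatter bin labels into
variant_features <- function(vals, ctx, mask_idx, box_len, config, prefix) {
  out <- first_order_features(vals)
  names(out) <- paste0(prefix, "_firstorder_", names(out))
  for (b in config$bin_counts) {
    lab <- discretize(vals, b)
    blk <- stats::setNames(bin_entropy(lab),
                           paste0(prefix, "_firstorder_entropy_b", b))
    bins_vec <- integer(box_len)
    bins_vec[mask_idx] <- lab
    if ("glcm" %in% config$texture_families) {
      f <- glcm_features_ctx(bins_vec, b, ctx)
      names(f) <- paste0(prefix, "_glcm_", names(f), "_b", b)
      blk <- c(blk, f)
    }
    if ("glrlm" %in% config$texture_families) {
      f <- glrlm_features_ctx(bins_vec, b, ctx)
      names(f) <- paste0(prefix, "_glrlm_", names(f), "_b", b)
      blk <- c(blk, f)
    }
    out <- c(out, blk)
  }
  out
}

#' Extract the CT radiomics feature vector
#'
#' Concatenates first-order and texture features over the configured image
#' variants (original, 8 wavelet sub-bands, LoG scales) and bin counts, inside
#' the (refined) mask. Deterministic and name-stable: two identical patients
#' yield identical vectors and any two patients share the same name set.
#'
#' @param ct CT [volume_grid()] (HU).
#' @param mask Binary [volume_grid()], typically from [refine_mask_by_hu()].
#' @param config A [radiomics_config()].
#' @return Named numeric vector of length [radiomics_feature_count()].
#' @export
extract_radiomics <- function(ct, mask, config = radiomics_config()) {
  stopifnot(inherits(ct, "volume_grid"), inherits(mask, "volume_grid"))
  if (!same_geometry(ct, mask)) stop("ct and mask must share grid geometry")
  pad <- if ("log_sigma" %in% config$image_filters)
    ceiling(3 * max(config$log_sigmas_mm) / min(ct$spacing_mm)) + 1L else 2L
  cr <- crop_to_mask(mask, list(ct = ct), pad = pad)
  m <- cr$mask
  if (sum(m) < 2L && length(intersect(c("glcm", "glrlm"), config$texture_families)))
    stop("undefined texture: mask has fewer than 2 voxels")
  ctx <- texture_context(m, need_runs = "glrlm" %in% config$texture_families)
  mask_idx <- which(m)
  variants <- list()
  if ("original" %in% config$image_filters) variants$original <- cr$volumes$ct
  if ("wavelet" %in% config$image_filters) {
    wb <- wavelet_bands(cr$volumes$ct)
    names(wb) <- paste0("wavelet.", names(wb))
    variants <- c(variants, wb)
  }
  if ("log_sigma" %in% config$image_filters)
    for (s in config$log_sigmas_mm)
      variants[[sprintf("log.sigma.%g.mm", s)]] <-
        log_filter(cr$volumes$ct, s, cr$spacing)
  out <- numeric(0)
  for (nm in names(variants)) {
    f <- tryCatch(
      variant_features(variants[[nm]][m], ctx, mask_idx, length(m), config, nm),
      error = function(e)
        stop(sprintf("radiomics variant '%s': %s", nm, conditionMessage(e))))
    out <- c(out, f)
  }
  out
}
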