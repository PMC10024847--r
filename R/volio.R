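#' Construct a volume grid
#'
#' A `volume_grid` is a 3D scalar array with voxel spacing and physical origin
#' in millimetres. Axis order is fixed as (x, y, z) with z the slice axis;
#' voxel centres sit at `origin + (index - 1) * spacing`.
#'
#' @param values 3D numeric array.
#' @param spacing_mm Numeric length-3 voxel spacing in mm, all > 0.
#' @param origin_mm Numeric length-3 physical origin in mm.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive finite numbers")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite numbers")
  if (any(!is.finite(values))) stop("volume contains non-finite values")
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, value range [%.4g, %.4g]\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume in cc
#' @param v A `volume_grid`.
#' @return Volume of one voxel in cubic centimetres.
#' @export
voxel_volume_cc <- function(v) prod(v$spacing_mm) / 1000

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

## ---- NRRD (minimal NRRD0004, 3D, raw or gzip, little endian) ----

nrrd_type_map <- c(
  "double" = "double", "float" = "float", "uchar" = "uint8",
  "unsigned char" = "uint8", "uint8" = "uint8", "uint8_t" = "uint8",
  "short" = "int16", "int16" = "int16", "int" = "int32", "int32" = "int32"
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop(sprintf("malformed NRRD header in '%s': bad magic '%s'", path, magic))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop(sprintf("malformed NRRD '%s': no end of header", path))
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed NRRD header line in '%s': '%s'", path, line))
    hdr[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  need <- function(field) {
    if (is.null(hdr[[field]]))
      stop(sprintf("malformed NRRD '%s': missing field '%s'", path, field))
    hdr[[field]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop(sprintf("NRRD '%s': only 3D volumes supported (field 'dimension')", path))
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  rtype <- nrrd_type_map[[tolower(need("type"))]]
  if (is.null(rtype)) stop(sprintf("NRRD '%s': unsupported type '%s'", path, hdr$type))
  enc <- tolower(need("encoding"))
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  if (!is.null(hdr[["space directions"]])) {
    vecs <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  } else if (!is.null(hdr[["spacings"]])) {
    spacing <- as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(hdr[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  bytes <- switch(rtype, double = 8L, float = 4L, uint8 = 1L, int16 = 2L, int32 = 4L)
  raw_data <- readBin(con, "raw", n = n * bytes + 64L)
  if (enc == "gzip" || enc == "gz") raw_data <- memDecompress(raw_data, type = "gzip")
  if (length(raw_data) < n * bytes)
    stop(sprintf("malformed NRRD '%s': data shorter than sizes imply", path))
  vals <- switch(rtype,
    double = readBin(raw_data, "double", n = n, size = 8, endian = "little"),
    float  = readBin(raw_data, "double", n = n, size = 4, endian = "little"),
    uint8  = as.numeric(readBin(raw_data, "integer", n = n, size = 1,
                                signed = FALSE, endian = "little")),
    int16  = as.numeric(readBin(raw_data, "integer", n = n, size = 2, endian = "little")),
    int32  = as.numeric(readBin(raw_data, "integer", n = n, size = 4, endian = "little")))
  volume_grid(array(vals, dim = sizes), spacing, origin)
}

write_nrrd <- function(v, path, dtype = "double") {
  stopifnot(dtype %in% c("double", "uint8"))
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(v$values)
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (dtype == "uint8") "uint8" else "double"),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            v$spacing_mm[1], v$spacing_mm[2], v$spacing_mm[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            v$origin_mm[1], v$origin_mm[2], v$origin_mm[3]),
    "")
  writeLines(hdr, con, sep = "\n")
  if (dtype == "uint8")
    writeBin(as.integer(round(v$values)), con, size = 1, endian = "little")
  else
    writeBin(as.numeric(v$values), con, size = 8, endian = "little")
  invisible(path)
}

## ---- NIfTI via RNifti ----

read_nifti_grid <- function(path) {
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop(sprintf("malformed NIfTI file '%s': %s", path, conditionMessage(e))))
  spacing <- RNifti::pixdim(img)[1:3]
  org <- as.numeric(RNifti::xform(img)[1:3, 4])
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]), spacing, org)
}

write_nifti_grid <- function(v, path, dtype = "double") {
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$spacing_mm
  xf <- structure(diag(c(v$spacing_mm, 1)), code = 2L)
  xf[1:3, 4] <- v$origin_mm
  img <- RNifti::`qform<-`(img, xf)
  RNifti::writeNifti(img, path, datatype = if (dtype == "uint8") "uint8" else "double")
  invisible(path)
}

#' Read a medical image volume
#'
#' Supports NRRD (`.nrrd`) and NIfTI-1 (`.nii`, `.nii.gz`). Spacing is
#' preserved to 1e-6 mm across a write/read round trip.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format One of `"auto"`, `"nrrd"`, `"nifti"`.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else stop(sprintf("unrecognized volume extension on '%s' (need .nrrd or .nii[.gz])", path))
  }
  if (format == "nrrd") read_nrrd(path) else read_nifti_grid(path)
}

#' Write a medical image volume
#'
#' @param v A [volume_grid()].
#' @param path Output path ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @param dtype `"double"` for scalar volumes or `"uint8"` for label masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, dtype = c("double", "uint8")) {
  dtype <- match.arg(dtype)
  stopifnot(inherits(v, "volume_grid"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) write_nrrd(v, path, dtype)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) write_nifti_grid(v, path, dtype)
  else stop(sprintf("unrecognized volume extension on '%s' (need .nrrd or .nii[.gz])", path))
}

## ---- resampling ----

#' Resample a volume to an isotropic grid
#'
#' Trilinear (scalar volumes) or nearest-neighbour (masks) resampling onto a
#' grid of `target_mm` spacing covering the same physical extent (to within
#' one voxel). Resampling an already-matching grid is an exact identity.
#'
#' @param v A [volume_grid()].
#' @param target_mm Length-3 target spacing in mm (default 1 mm isotropic).
#' @param mode `"linear"` for intensities, `"nearest"` for masks (keeps values
#'   strictly binary).
#' @return A resampled [volume_grid()].
#' @export
resample_isotropic <- function(v, target_mm = c(1, 1, 1), mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "volume_grid"))
  target_mm <- rep_len(as.numeric(target_mm), 3L)
  if (any(target_mm <= 0)) stop("target spacing must be positive")
  d <- dim(v$values)
  if (any(d == 0L)) stop("empty volume")
  out_d <- pmax(1L, as.integer(round(d * v$spacing_mm / target_mm)))
  if (all(out_d == d) && all(abs(v$spacing_mm - target_mm) < 1e-12))
    return(v)
  # continuous input index of each output voxel centre along each axis
  ax_idx <- lapply(1:3, function(a) {
    phys <- (seq_len(out_d[a]) - 1) * target_mm[a]       # relative to origin
    1 + phys / v$spacing_mm[a]
  })
  if (mode == "nearest") {
    near <- lapply(1:3, function(a) pmin(pmax(round(ax_idx[[a]]), 1L), d[a]))
    out <- v$values[near[[1]], near[[2]], near[[3]], drop = FALSE]
    dim(out) <- out_d
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(ax_idx[[a]]), 1L), d[a]))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
    w <- lapply(1:3, function(a) pmin(pmax(ax_idx[[a]] - lo[[a]], 0), 1))
    out <- array(0, out_d)
    # 8-corner accumulation, separable weights
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- if (cx) hi[[1]] else lo[[1]]
      iy <- if (cy) hi[[2]] else lo[[2]]
      iz <- if (cz) hi[[3]] else lo[[3]]
      wx <- if (cx) w[[1]] else 1 - w[[1]]
      wy <- if (cy) w[[2]] else 1 - w[[2]]
      wz <- if (cz) w[[3]] else 1 - w[[3]]
      wt <- outer(outer(wx, wy), wz)
      if (any(wt > 0)) out <- out + wt * v$values[ix, iy, iz, drop = FALSE]
    }
  }
  volume_grid(out, target_mm, v$origin_mm)
}

#' Refine an esophagus mask by a Hounsfield window
#'
#' Keeps a voxel iff it is inside the input mask and its CT number lies in the
#' closed interval `hu_range` (default \[-150, 180\]), removing non-esophagus
#' content such as intraluminal air cavities before feature extraction.
#'
#' @param ct CT [volume_grid()] in HU.
#' @param mask Binary [volume_grid()] sharing the CT geometry.
#' @param hu_range Closed HU interval, default `c(-150, 180)`.
#' @return A binary [volume_grid()] that is a subset of `mask`.
#' @export
refine_mask_by_hu <- function(ct, mask, hu_range = c(-150, 180)) {
  stopifnot(inherits(ct, "volume_grid"), inherits(mask, "volume_grid"))
  if (!same_geometry(ct, mask)) stop("ct and mask must share grid geometry")
  keep <- (mask$values > 0.5) & ct$values >= hu_range[1] & ct$values <= hu_range[2]
  if (!any(keep)) stop("refined mask is empty: no voxels left for feature extraction")
  volume_grid(array(as.numeric(keep), dim(keep)), mask$spacing_mm, mask$origin_mm)
}

# crop a set of co-registered volumes to the mask bounding box (+pad voxels);
# returns list(values = list of arrays, mask = logical array, spacing)
crop_to_mask <- function(mask, volumes = list(), pad = 0L) {
  m <- mask$values > 0.5
  if (!any(m)) stop("mask is empty")
  d <- dim(m)
  rng <- lapply(1:3, function(a) {
    pr <- apply(m, a, any)
    range(which(pr))
  })
  sl <- lapply(1:3, function(a)
    max(1L, rng[[a]][1] - pad):min(d[a], rng[[a]][2] + pad))
  list(
    mask = m[sl[[1]], sl[[2]], sl[[3]], drop = FALSE],
    volumes = lapply(volumes, function(v) v$values[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]),
    spacing = mask$spacing_mm
  )
}
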