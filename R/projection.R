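# Scout-like 2D projections from 3D volumes, mask co-projection,
# normalization/resizing with exact row-to-z bookkeeping, and the
# magnification distortion used to emulate real scout acquisition geometry.

#' Scout-like 2D projection
#'
#' A 2D image whose rows run craniocaudally, together with the affine
#' mapping from row index to patient z: `z(r) = z0 + (r - 1) * dz`.
#'
#' @param pixels numeric matrix, rows craniocaudal (row 1 most superior).
#' @param view `"AP"` or `"LAT"`.
#' @param row_to_z numeric `c(z0, dz)` with `dz > 0`.
#' @param normalization `NULL`, or a record (list) of the normalization
#'   applied, e.g. `list(method = "minmax", min = ..., max = ...)`.
#' @param provenance `"summed"` (synthesized from a volume) or `"scout"`
#'   (a real localizer).
#' @return An object of class `projection2d`.
#' @export
projection2d <- function(pixels, view = c("AP", "LAT"), row_to_z,
                         normalization = NULL,
                         provenance = c("summed", "scout")) {
  view <- match.arg(view); provenance <- match.arg(provenance)
  stopifnot(is.matrix(pixels))
  if (any(!is.finite(pixels))) stop("projection pixels must be finite")
  row_to_z <- as.numeric(row_to_z)
  if (length(row_to_z) != 2L || row_to_z[2] <= 0)
    stop("row_to_z must be c(z0, dz) with dz > 0")
  if (!is.null(normalization)) {
    rng <- range(pixels)
    if (rng[1] < 0 || rng[2] > 1)
      stop("normalized pixel values must lie in [0, 1]")
  }
  structure(list(pixels = pixels, view = view, row_to_z = row_to_z,
                 normalization = normalization, provenance = provenance),
            class = "projection2d")
}

#' Binary 2D lung mask paired with a projection
#'
#' @param pixels logical matrix, congruent with its paired projection.
#' @param row_to_z affine `c(z0, dz)`, same as the paired projection.
#' @return An object of class `mask2d`.
#' @export
mask2d <- function(pixels, row_to_z) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "logical"
  row_to_z <- as.numeric(row_to_z)
  if (length(row_to_z) != 2L || row_to_z[2] <= 0)
    stop("row_to_z must be c(z0, dz) with dz > 0")
  structure(list(pixels = pixels, row_to_z = row_to_z), class = "mask2d")
}

#' Map image rows to patient z (mm) and back
#'
#' @param obj a [projection2d()] or [mask2d()].
#' @param row row index (may be fractional).
#' @param z patient z in mm.
#' @return `row_to_z()`: z in mm; `z_to_row()`: (fractional) row index.
#' @export
row_to_z <- function(obj, row) {
  obj$row_to_z[1] + (row - 1) * obj$row_to_z[2]
}

#' @rdname row_to_z
#' @export
z_to_row <- function(obj, z) {
  (z - obj$row_to_z[1]) / obj$row_to_z[2] + 1
}

#' Project a CT volume into a scout-like 2D image
#'
#' Line integral of the attenuation proxy `max(HU + 1000, 0)` along the AP
#' or lateral direction, scaled by the ray step (voxel spacing along the
#' projection axis), so air contributes zero and total attenuation is
#' conserved. Image rows correspond one-to-one to slices.
#'
#' @param volume a [ct_volume()].
#' @param view `"AP"` (rays along the anterior-posterior axis) or `"LAT"`.
#' @return A [projection2d()] with `provenance = "summed"`, un-normalized.
#' @export
project_volume <- function(volume, view = c("AP", "LAT")) {
  stopifnot(inherits(volume, "ct_volume"))
  view <- match.arg(view)
  att <- pmax(volume$voxels + 1000, 0)
  if (view == "AP") {
    px <- t(colSums(att)) * volume$spacing[1]           # [slice, column]
  } else {
    px <- t(colSums(aperm(att, c(2, 1, 3)))) * volume$spacing[2]  # [slice, row]
  }
  dz <- volume$spacing[3]
  projection2d(px, view = view, row_to_z = c(0.5 * dz, dz),
               provenance = "summed")
}

#' Project a 3D lung mask onto a scout view
#'
#' A 2D pixel is lung if any voxel along its ray is lung, so the set of
#' occupied image rows equals the set of slices containing lung exactly.
#'
#' @param mask a [lung_mask3d()].
#' @param view `"AP"` or `"LAT"`.
#' @return A [mask2d()]; an empty 3D mask yields an empty 2D mask with a
#'   warning.
#' @export
project_mask <- function(mask, view = c("AP", "LAT")) {
  stopifnot(inherits(mask, "lung_mask3d"))
  view <- match.arg(view)
  v <- mask$voxels
  if (view == "AP") {
    px <- t(colSums(v) > 0)
  } else {
    px <- t(colSums(aperm(v, c(2, 1, 3))) > 0)
  }
  if (!any(px)) warning("projected mask is empty")
  dz <- mask$spacing[3]
  mask2d(px, row_to_z = c(0.5 * dz, dz))
}

#' Normalize and resize a projection (and its mask)
#'
#' Min-max scales intensities to `[0, 1]`, resizes the image with bilinear
#' interpolation and the mask with nearest-neighbour sampling to a square
#' `size x size` matrix (anisotropically for non-square inputs), and
#' updates the row-to-z affine so every resampled row maps to the same
#' patient z as the original grid.
#'
#' @param p a [projection2d()].
#' @param m optionally, the paired [mask2d()].
#' @param size output matrix size (>= 32).
#' @return A list with elements `projection` and `mask` (`NULL` when no
#'   mask was supplied). A constant-intensity image degenerates to all
#'   zeros with a warning.
#' @export
normalize_resize <- function(p, m = NULL, size = 256) {
  stopifnot(inherits(p, "projection2d"), size >= 32)
  px <- p$pixels
  rng <- range(px)
  if (diff(rng) == 0) {
    warning("constant-intensity image: normalization degenerates to zeros")
    norm <- matrix(0, nrow(px), ncol(px))
  } else {
    norm <- (px - rng[1]) / diff(rng)
  }
  R <- nrow(px)
  if (R != size || ncol(px) != size) {
    norm <- EBImage::resize(norm, w = size, h = size, filter = "bilinear")
    # interpolation smooths the extremes; rescale so min = 0, max = 1 holds
    if (diff(range(norm)) > 0)
      norm <- (norm - min(norm)) / diff(range(norm))
  }
  dz <- p$row_to_z[2]
  dz2 <- dz * R / size
  z0_2 <- (p$row_to_z[1] - dz / 2) + dz2 / 2
  out_p <- projection2d(norm, view = p$view, row_to_z = c(z0_2, dz2),
                        normalization = list(method = "minmax",
                                             min = rng[1], max = rng[2],
                                             original_dim = dim(px)),
                        provenance = p$provenance)
  out_m <- NULL
  if (!is.null(m)) {
    stopifnot(inherits(m, "mask2d"), all(dim(m$pixels) == dim(px)))
    mp <- m$pixels * 1
    if (nrow(mp) != size || ncol(mp) != size)
      mp <- EBImage::resize(mp, w = size, h = size, filter = "none")
    out_m <- mask2d(mp > 0.5, row_to_z = c(z0_2, dz2))
  }
  list(projection = out_p, mask = out_m)
}

#' Scout acquisition geometry
#'
#' @param source_detector_distance_mm distance from x-ray source to
#'   detector (SDD, mm).
#' @param source_isocenter_distance_mm distance from source to isocenter
#'   (SID, mm); must satisfy `0 < SID < SDD`.
#' @param table_height_offset_mm offset of the imaged plane from the
#'   isocenter along the beam axis (mm, positive toward the source).
#' @return An object of class `scout_geometry`.
#' @export
scout_geometry <- function(source_detector_distance_mm = 1040,
                           source_isocenter_distance_mm = 570,
                           table_height_offset_mm = 0) {
  sdd <- source_detector_distance_mm; sid <- source_isocenter_distance_mm
  if (!(sid > 0 && sid < sdd))
    stop("require 0 < source_isocenter_distance < source_detector_distance")
  structure(list(sdd = sdd, sid = sid, offset = table_height_offset_mm),
            class = "scout_geometry")
}

#' Apply scout magnification distortion
#'
#' Scales transverse (column) coordinates about the image center by the
#' magnification `M = SDD / (SDD - y)`, where `y` is the imaged plane's
#' offset from the isocenter along the beam axis. Craniocaudal rows are
#' unchanged: scout acquisition translates the table along z, which is
#' therefore undistorted. Intensities are resampled with linear
#' interpolation, masks with nearest-neighbour sampling.
#'
#' @param p a [projection2d()].
#' @param m the paired [mask2d()] (or `NULL`).
#' @param geom a [scout_geometry()].
#' @return A list with elements `projection` (provenance `"scout"`) and
#'   `mask`.
#' @export
apply_magnification <- function(p, m = NULL, geom = scout_geometry()) {
  stopifnot(inherits(p, "projection2d"), inherits(geom, "scout_geometry"))
  y <- geom$offset
  if (y >= geom$sid) stop("imaged plane lies at or beyond the source")
  M <- geom$sdd / (geom$sdd - y)
  px <- p$pixels
  C <- ncol(px); ctr <- (C + 1) / 2
  src <- ctr + (seq_len(C) - ctr) / M
  lo <- floor(src); w <- src - lo
  out <- matrix(0, nrow(px), C)
  ok_lo <- lo >= 1 & lo <= C
  ok_hi <- (lo + 1) >= 1 & (lo + 1) <= C
  if (any(ok_lo))
    out[, ok_lo] <- out[, ok_lo] +
      sweep(px[, lo[ok_lo], drop = FALSE], 2, 1 - w[ok_lo], "*")
  if (any(ok_hi))
    out[, ok_hi] <- out[, ok_hi] +
      sweep(px[, lo[ok_hi] + 1, drop = FALSE], 2, w[ok_hi], "*")
  out_p <- projection2d(if (!is.null(p$normalization)) pmin(pmax(out, 0), 1) else out,
                        view = p$view, row_to_z = p$row_to_z,
                        normalization = p$normalization, provenance = "scout")
  out_m <- NULL
  if (!is.null(m)) {
    stopifnot(inherits(m, "mask2d"), all(dim(m$pixels) == dim(px)))
    nn <- round(src)
    keep <- nn >= 1 & nn <= C
    mpx <- matrix(FALSE, nrow(px), C)
    mpx[, keep] <- m$pixels[, nn[keep]]
    out_m <- mask2d(mpx, row_to_z = m$row_to_z)
  }
  list(projection = out_p, mask = out_m)
}
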