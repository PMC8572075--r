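# Standard-format I/O: NIfTI volumes/masks, 16-bit PNG projections with
# JSON sidecars carrying the row-to-z mapping, CSV/JSON tables, and a
# minimal DICOM series reader for uncompressed explicit-VR little-endian
# axial series (the only DICOM flavour this package ingests).

#' Write / read a CT volume as NIfTI
#'
#' The voxel array is stored with correct spacing in the NIfTI header; the
#' acquisition metadata the pipeline needs (CTDIvol, kVp, TCM profile,
#' patient meta) goes into a JSON sidecar next to the image.
#'
#' @param volume a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param sidecar write the JSON metadata sidecar (`<path>.json`).
#' @return `write_ct_volume()` returns `path` invisibly;
#'   `read_ct_volume()` returns a [ct_volume()].
#' @export
write_ct_volume <- function(volume, path, sidecar = TRUE) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  if (sidecar) {
    meta <- list(ctdi_vol = volume$ctdi_vol, kvp = volume$kvp,
                 patient_meta = volume$patient_meta)
    if (!is.null(volume$tcm))
      meta$tcm <- list(ma = volume$tcm$ma, slice_z = volume$tcm$slice_z)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  vox <- array(as.numeric(img), dim = dim(img))
  side <- paste0(path, ".json")
  ctdi <- NA_real_; kvp <- 120; tcm <- NULL
  pm <- list(age = NA_real_, sex = "unknown")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$ctdi_vol)) ctdi <- meta$ctdi_vol
    if (!is.null(meta$kvp)) kvp <- meta$kvp
    if (!is.null(meta$patient_meta)) pm <- meta$patient_meta
    if (!is.null(meta$tcm)) tcm <- tcm_profile(meta$tcm$ma, meta$tcm$slice_z)
  }
  ct_volume(vox, spacing, ctdi_vol = ctdi, kvp = kvp, tcm = tcm,
            patient_meta = pm)
}

#' Write / read a 3D lung mask as NIfTI
#'
#' @param mask a [lung_mask3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_lung_mask()` returns `path` invisibly;
#'   `read_lung_mask()` returns a [lung_mask3d()].
#' @export
write_lung_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lung_mask3d"))
  arr <- array(as.integer(mask$voxels), dim = dim(mask$voxels))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_lung_mask
#' @export
read_lung_mask <- function(path) {
  img <- RNifti::readNifti(path)
  lung_mask3d(array(as.numeric(img) > 0.5, dim = dim(img)),
              RNifti::pixdim(img)[1:3])
}

#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI files are read through [read_ct_volume()]. Directories are treated
#' as DICOM series: slices are sorted most-superior-first from the slice
#' position metadata, spacing is populated from the header, and per-slice
#' tube current (when present) becomes the TCM profile; a missing tube
#' current yields a constant fallback profile with a warning.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of DICOM files.
#' @return A [ct_volume()].
#' @export
read_ct <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (grepl("\\.nii(\\.gz)?$", path)) return(read_ct_volume(path))
  stop("input must be a NIfTI file or a DICOM series directory")
}

# ---- minimal DICOM (explicit VR little endian, uncompressed) ------------

.dcm_u16 <- function(raw) sum(as.integer(raw) * c(1L, 256L))
.dcm_u32 <- function(raw) sum(as.numeric(raw) * c(1, 256, 65536, 16777216))

# parse one file; returns the tags the pipeline needs
.read_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132)
  if (length(preamble) < 132 || rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  repeat {
    hdr <- readBin(con, "raw", 8)
    if (length(hdr) < 8) break
    group <- .dcm_u16(hdr[1:2]); elem <- .dcm_u16(hdr[3:4])
    vr <- rawToChar(hdr[5:6])
    if (vr %in% long_vrs) {
      len <- .dcm_u32(readBin(con, "raw", 4))
    } else {
      len <- .dcm_u16(hdr[7:8])
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    key <- sprintf("%04x,%04x", group, elem)
    wanted <- key %in% c("0008,0060", "0018,1151", "0018,9345", "0020,000e",
                         "0020,0032", "0028,0010", "0028,0011", "0028,0030",
                         "0028,0100", "0028,0103", "0028,1052", "0028,1053",
                         "7fe0,0010")
    if (wanted) {
      val <- readBin(con, "raw", len)
      tags[[key]] <- list(vr = vr, raw = val)
    } else {
      seek(con, len, origin = "current")
    }
    if (key == "7fe0,0010") break
  }
  tags
}

.dcm_str <- function(tag) {
  if (is.null(tag)) return(NULL)
  r <- tag$raw
  r <- r[r != as.raw(0)]           # strip DICOM nul padding
  trimws(rawToChar(r))
}

.dcm_num <- function(tag) {
  s <- .dcm_str(tag)
  if (is.null(s) || s == "") return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

#' Read an uncompressed explicit-VR little-endian DICOM series
#'
#' @param dir directory containing one axial DICOM series.
#' @return A [ct_volume()] with slices ordered most-superior-first.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  parsed <- lapply(files, .read_dicom_file)

  uids <- unique(vapply(parsed, function(t) .dcm_str(t[["0020,000e"]]) %||% "?",
                        character(1)))
  if (length(uids) > 1)
    stop("directory mixes multiple series UIDs: ", paste(uids, collapse = ", "))

  info <- lapply(parsed, function(t) {
    rows <- .dcm_u16(t[["0028,0010"]]$raw)
    cols <- .dcm_u16(t[["0028,0011"]]$raw)
    ps <- .dcm_num(t[["0028,0030"]])
    ipp <- .dcm_num(t[["0020,0032"]])
    if (is.null(ps) || is.null(ipp)) stop("missing pixel spacing or slice position")
    bits <- .dcm_u16(t[["0028,0100"]]$raw)
    if (bits != 16) stop("only 16-bit DICOM pixel data is supported")
    signed <- !is.null(t[["0028,0103"]]) && .dcm_u16(t[["0028,0103"]]$raw) == 1
    slope <- (.dcm_num(t[["0028,1053"]]) %||% 1)
    inter <- (.dcm_num(t[["0028,1052"]]) %||% 0)
    raw <- t[["7fe0,0010"]]$raw
    px <- readBin(raw, "integer", n = rows * cols, size = 2,
                  signed = signed, endian = "little")
    ma <- .dcm_num(t[["0018,1151"]])
    list(rows = rows, cols = cols, ps = ps, z = ipp[3],
         hu = slope * px + inter, ma = if (is.null(ma)) NA_real_ else ma)
  })

  # DICOM patient z increases toward the head: most superior slice first
  ord <- order(vapply(info, `[[`, numeric(1), "z"), decreasing = TRUE)
  info <- info[ord]
  rows <- info[[1]]$rows; cols <- info[[1]]$cols
  nk <- length(info)
  vox <- array(0, dim = c(rows, cols, nk))
  for (k in seq_len(nk))
    vox[, , k] <- matrix(info[[k]]$hu, rows, cols, byrow = TRUE)
  zs <- vapply(info, `[[`, numeric(1), "z")
  dz <- if (nk > 1) abs(stats::median(diff(zs))) else 1
  if (dz <= 0) stop("cannot determine slice spacing from positions")
  spacing <- c(info[[1]]$ps[1], info[[1]]$ps[2], dz)

  ma <- vapply(info, `[[`, numeric(1), "ma")
  if (any(is.na(ma))) {
    warning("per-slice tube current missing; using a constant 100 mA profile")
    ma <- rep(100, nk)
  }
  vox[vox < -1024] <- -1024; vox[vox > 3071] <- 3071
  vol <- ct_volume(vox, spacing)
  vol$tcm <- tcm_profile(ma, slice_z_positions(vol))
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- 2D projections and masks: 16-bit PNG + JSON sidecar ----------------

#' Write / read a projection as grayscale PNG with JSON sidecar
#'
#' The sidecar (`<path>.json`) carries the view, the row-to-z affine, the
#' normalization record and the PNG scaling, and is required to
#' reconstruct the projection for range conversion.
#'
#' @param p a [projection2d()].
#' @param path output path (`.png`).
#' @return `write_projection()` returns `path` invisibly;
#'   `read_projection()` returns a [projection2d()].
#' @export
write_projection <- function(p, path) {
  stopifnot(inherits(p, "projection2d"))
  px <- p$pixels
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  png::writePNG(scaled, path, dpi = NULL)
  side <- list(view = p$view, row_to_z = p$row_to_z,
               provenance = p$provenance, png_min = rng[1], png_max = rng[2],
               normalization = p$normalization)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px <- px * (side$png_max - side$png_min) + side$png_min
  norm <- side$normalization
  if (!is.null(norm)) {
    norm <- as.list(norm)
    px <- pmin(pmax(px, 0), 1)
  }
  projection2d(px, view = side$view, row_to_z = as.numeric(side$row_to_z),
               normalization = norm, provenance = side$provenance)
}

#' Write / read a 2D mask as PNG with JSON sidecar
#'
#' @param m a [mask2d()].
#' @param path output path (`.png`).
#' @return `write_mask2d()` returns `path` invisibly; `read_mask2d()`
#'   returns a [mask2d()].
#' @export
write_mask2d <- function(m, path) {
  stopifnot(inherits(m, "mask2d"))
  png::writePNG(m$pixels * 1, path)
  jsonlite::write_json(list(row_to_z = m$row_to_z), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask2d
#' @export
read_mask2d <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  mask2d(px > 0.5, as.numeric(side$row_to_z))
}

# ---- ranges, TCM profiles ----------------------------------------------

#' Write / read scan ranges as a cohort CSV
#'
#' Columns: `patient_id`, `provenance`, `superior_z`, `inferior_z`.
#'
#' @param ranges a named list of [scan_range()] (names become patient ids,
#'   recycled across provenances) or a data.frame in the same layout.
#' @param path CSV path.
#' @return `write_ranges_csv()` returns `path` invisibly;
#'   `read_ranges_csv()` returns the data.frame.
#' @export
write_ranges_csv <- function(ranges, path) {
  df <- if (is.data.frame(ranges)) ranges else ranges_to_df(ranges)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranges_csv
#' @export
read_ranges_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Convert scan ranges to a cohort data.frame
#'
#' @param ranges named (by patient id) list of [scan_range()] objects, or a
#'   list of such lists.
#' @return data.frame with columns `patient_id`, `provenance`,
#'   `superior_z`, `inferior_z`.
#' @export
ranges_to_df <- function(ranges) {
  rows <- list()
  for (pid in names(ranges)) {
    entry <- ranges[[pid]]
    if (inherits(entry, "scan_range")) entry <- list(entry)
    for (r in entry) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, provenance = r$provenance,
        superior_z = r$superior_z, inferior_z = r$inferior_z)
    }
  }
  do.call(rbind, rows)
}

#' Write / read a scan range as JSON
#'
#' @param range a [scan_range()].
#' @param path JSON path.
#' @return `write_range_json()` returns `path` invisibly;
#'   `read_range_json()` returns a [scan_range()].
#' @export
write_range_json <- function(range, path) {
  stopifnot(inherits(range, "scan_range"))
  jsonlite::write_json(unclass(range), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_range_json
#' @export
read_range_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scan_range(x$superior_z, x$inferior_z, x$provenance)
}

#' Write / read a TCM profile as CSV
#'
#' Columns: `slice_index`, `z_mm`, `ma`.
#'
#' @param tcm a [tcm_profile()].
#' @param path CSV path.
#' @return `write_tcm_csv()` returns `path` invisibly; `read_tcm_csv()`
#'   returns a [tcm_profile()].
#' @export
write_tcm_csv <- function(tcm, path) {
  stopifnot(inherits(tcm, "tcm_profile"))
  write.csv(data.frame(slice_index = seq_along(tcm$ma), z_mm = tcm$slice_z,
                       ma = tcm$ma),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tcm_csv
#' @export
read_tcm_csv <- function(path) {
  df <- read.csv(path)
  tcm_profile(df$ma, df$z_mm)
}
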