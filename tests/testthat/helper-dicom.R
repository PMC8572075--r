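# Byte-level construction of minimal explicit-VR little-endian DICOM
# slices, independent of the package's reader.

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcm_even <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

.dcm_el_short <- function(g, e, vr, val) {
  c(.u16(g), .u16(e), charToRaw(vr), .u16(length(val)), val)
}

.dcm_el_long <- function(g, e, vr, val) {
  c(.u16(g), .u16(e), charToRaw(vr), as.raw(c(0, 0)), .u32(length(val)), val)
}

# one axial slice; hu is a rows x cols matrix
write_fake_dicom_slice <- function(path, hu, z, ma, spacing = c(2, 2),
                                   series_uid = "1.2.826.0.1.999999.1") {
  rows <- nrow(hu); cols <- ncol(hu)
  stored <- as.integer(round(t(hu))) + 1024L     # row-major, intercept -1024
  px_raw <- writeBin(as.vector(stored), raw(), size = 2, endian = "little")
  body <- c(
    .dcm_el_short(0x0008, 0x0060, "CS", .dcm_even("CT")),
    .dcm_el_short(0x0018, 0x1151, "IS", .dcm_even(as.character(ma))),
    .dcm_el_short(0x0020, 0x000E, "UI", .dcm_even(series_uid)),
    .dcm_el_short(0x0020, 0x0032, "DS",
                  .dcm_even(sprintf("0\\0\\%g", z))),
    .dcm_el_short(0x0028, 0x0010, "US", .u16(rows)),
    .dcm_el_short(0x0028, 0x0011, "US", .u16(cols)),
    .dcm_el_short(0x0028, 0x0030, "DS",
                  .dcm_even(sprintf("%g\\%g", spacing[1], spacing[2]))),
    .dcm_el_short(0x0028, 0x0100, "US", .u16(16)),
    .dcm_el_short(0x0028, 0x0103, "US", .u16(0)),
    .dcm_el_short(0x0028, 0x1052, "DS", .dcm_even("-1024")),
    .dcm_el_short(0x0028, 0x1053, "DS", .dcm_even("1")),
    .dcm_el_long(0x7FE0, 0x0010, "OW", px_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}
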