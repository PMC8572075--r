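# Scan ranges, mask post-processing, mask-to-range conversion and signed
# overscan quantification.

#' Craniocaudal scan range
#'
#' Superior and inferior z-limits in patient millimetres (slice-center
#' convention, z increasing caudally, inclusive limits) with a provenance
#' tag recording how the range was selected.
#'
#' @param superior_z superior (cranial) limit, mm.
#' @param inferior_z inferior (caudal) limit, mm; must exceed `superior_z`.
#' @param provenance one of `"exact"`, `"human"`, `"DL_AP"`, `"DL_Lat"`,
#'   `"DL_Both"`.
#' @return An object of class `scan_range`.
#' @export
scan_range <- function(superior_z, inferior_z,
                       provenance = c("exact", "human", "DL_AP", "DL_Lat", "DL_Both")) {
  provenance <- match.arg(provenance)
  superior_z <- as.numeric(superior_z); inferior_z <- as.numeric(inferior_z)
  if (!is.finite(superior_z) || !is.finite(inferior_z))
    stop("scan range limits must be finite")
  if (superior_z >= inferior_z)
    stop("superior_z must be strictly above (less than) inferior_z")
  structure(list(superior_z = superior_z, inferior_z = inferior_z,
                 provenance = provenance),
            class = "scan_range")
}

#' @export
print.scan_range <- function(x, ...) {
  cat(sprintf("<scan_range %s> [%.2f, %.2f] mm (length %.2f mm)\n",
              x$provenance, x$superior_z, x$inferior_z,
              x$inferior_z - x$superior_z))
  invisible(x)
}

#' Length of a scan range in mm
#' @param range a [scan_range()].
#' @return Length in mm.
#' @export
range_length_mm <- function(range) {
  stopifnot(inherits(range, "scan_range"))
  range$inferior_z - range$superior_z
}

#' Remove small segmented regions from a 2D mask
#'
#' Drops connected components smaller than `min_pixels` while always keeping
#' the largest component (even if itself below the cutoff). Idempotent.
#'
#' @param m a [mask2d()].
#' @param min_pixels minimum component size in pixels.
#' @return The filtered [mask2d()].
#' @export
postprocess_mask <- function(m, min_pixels = 50) {
  stopifnot(inherits(m, "mask2d"), min_pixels >= 0)
  px <- m$pixels
  if (!any(px)) {
    warning("post-processing an empty mask")
    return(m)
  }
  lbl <- EBImage::bwlabel(px * 1)
  sizes <- tabulate(lbl[lbl > 0])
  keep <- union(which(sizes >= min_pixels), which.max(sizes))
  m$pixels <- matrix(lbl %in% keep, nrow(px), ncol(px)) & px
  m
}

#' Convert a 2D lung mask to a craniocaudal scan range
#'
#' The first occupied row in the craniocaudal direction defines the
#' superior limit and the last occupied row the inferior limit; a safety
#' margin of `margin_voxels` rows is added in each direction (clipped to
#' the image extent) and rows are mapped to patient z through the mask's
#' affine row-to-z mapping.
#'
#' @param m a [mask2d()].
#' @param margin_voxels margin in rows added cranially and caudally.
#' @param provenance provenance tag for the resulting range.
#' @return A [scan_range()].
#' @export
mask_to_range <- function(m, margin_voxels = 1, provenance = "exact") {
  stopifnot(inherits(m, "mask2d"), margin_voxels >= 0)
  occ <- which(rowSums(m$pixels) > 0)
  if (length(occ) == 0L) stop("no lung found in mask")
  r1 <- max(1L, min(occ) - margin_voxels)
  r2 <- min(nrow(m$pixels), max(occ) + margin_voxels)
  scan_range(row_to_z(m, r1), row_to_z(m, r2), provenance = provenance)
}

#' Combine AP- and lateral-view scan ranges
#'
#' @param ap range derived from the AP view.
#' @param lat range derived from the lateral view.
#' @param rule `"average"` (limit-wise mean), `"union"` (most superior top,
#'   most inferior bottom) or `"intersection"` (the opposite).
#' @return A [scan_range()] with provenance `"DL_Both"`.
#' @export
combine_ranges <- function(ap, lat, rule = c("average", "union", "intersection")) {
  stopifnot(inherits(ap, "scan_range"), inherits(lat, "scan_range"))
  rule <- match.arg(rule)
  lim <- switch(rule,
    average      = c(mean(c(ap$superior_z, lat$superior_z)),
                     mean(c(ap$inferior_z, lat$inferior_z))),
    union        = c(min(ap$superior_z, lat$superior_z),
                     max(ap$inferior_z, lat$inferior_z)),
    intersection = c(max(ap$superior_z, lat$superior_z),
                     min(ap$inferior_z, lat$inferior_z)))
  scan_range(lim[1], lim[2], provenance = "DL_Both")
}

#' Signed overscan errors of a selected range
#'
#' Positive errors indicate overscanning (coverage beyond the lung);
#' negative errors indicate exclusion of lung slices.
#'
#' @param selected the evaluated [scan_range()].
#' @param truth the ground-truth (exact lung coverage) [scan_range()].
#' @return An object of class `overscan_report` with elements
#'   `superior_error_mm`, `inferior_error_mm`, `overscan_superior`,
#'   `overscan_inferior` and `provenance`.
#' @export
overscan_error <- function(selected, truth) {
  stopifnot(inherits(selected, "scan_range"), inherits(truth, "scan_range"))
  sup <- truth$superior_z - selected$superior_z
  inf <- selected$inferior_z - truth$inferior_z
  structure(list(superior_error_mm = sup, inferior_error_mm = inf,
                 overscan_superior = sup > 0, overscan_inferior = inf > 0,
                 provenance = selected$provenance),
            class = "overscan_report")
}

#' @export
print.overscan_report <- function(x, ...) {
  cat(sprintf("<overscan_report %s> superior %+.2f mm, inferior %+.2f mm\n",
              x$provenance, x$superior_error_mm, x$inferior_error_mm))
  invisible(x)
}

#' Summarize overscan errors across a cohort
#'
#' @param reports list of [overscan_error()] reports (or a data.frame with
#'   columns `superior_error_mm`, `inferior_error_mm`).
#' @return A data.frame with one row per direction and columns `mean`,
#'   `sd`, `min`, `q1`, `median`, `q3`, `max` and `frac_overscan`
#'   (fraction of cases with error > 0).
#' @export
summarize_cohort <- function(reports) {
  if (is.data.frame(reports)) {
    df <- reports
  } else {
    if (length(reports) == 0L) stop("empty report list")
    df <- data.frame(
      superior_error_mm = vapply(reports, `[[`, numeric(1), "superior_error_mm"),
      inferior_error_mm = vapply(reports, `[[`, numeric(1), "inferior_error_mm"))
  }
  if (nrow(df) == 0L) stop("empty report list")
  one <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
               min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x),
               frac_overscan = mean(x > 0))
  }
  out <- rbind(one(df$superior_error_mm), one(df$inferior_error_mm))
  cbind(direction = c("superior", "inferior"), out)
}
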