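# Synthetic chest phantom: body + two lungs (tapered apices, slanted
# costophrenic recesses) in Hounsfield units, with per-slice tube-current
# modulation and simulated operator-selected scan ranges.

#' CT volume container
#'
#' A 3D grid of Hounsfield units plus geometry and acquisition metadata.
#' Axis convention: `voxels[i, j, k]` with `i` anterior-to-posterior rows,
#' `j` left-to-right columns, `k` slices; slice 1 is the most superior and
#' z (mm, slice centers) increases caudally.
#'
#' @param voxels 3D numeric array of HU values in `[-1024, 3071]`.
#' @param spacing numeric length-3, voxel spacing in mm (row, column, slice);
#'   all components positive.
#' @param ctdi_vol volumetric CT dose index of the acquisition (mGy).
#' @param kvp tube voltage (kV).
#' @param tcm optional [tcm_profile()] with one mA value per slice.
#' @param patient_meta list with elements `age` (years) and `sex`
#'   (`"M"`, `"F"` or `"unknown"`).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, ctdi_vol = NA_real_, kvp = 120,
                      tcm = NULL, patient_meta = list(age = NA_real_, sex = "unknown")) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (row, column, slice mm)")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop("HU values must lie within [-1024, 3071]")
  n_slices <- dim(voxels)[3]
  if (!is.null(tcm)) {
    stopifnot(inherits(tcm, "tcm_profile"))
    if (length(tcm$ma) != n_slices)
      stop("tcm profile length must equal the number of slices")
  }
  structure(list(voxels = voxels, spacing = spacing, n_slices = n_slices,
                 ctdi_vol = ctdi_vol, kvp = kvp, tcm = tcm,
                 patient_meta = patient_meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ (%.2f, %.2f, %.2f) mm, CTDIvol %.2f mGy\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$ctdi_vol))
  invisible(x)
}

#' 3D lung mask congruent with a CT volume
#'
#' @param voxels 3D logical (or 0/1) array, same shape as the parent volume.
#' @param spacing voxel spacing in mm, same as the parent volume.
#' @return An object of class `lung_mask3d`.
#' @export
lung_mask3d <- function(voxels, spacing) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(voxels = voxels, spacing = spacing),
            class = "lung_mask3d")
}

#' Per-slice tube-current profile
#'
#' One mA value per slice together with the slice-center z coordinate (mm),
#' so that z-defined scan regions can be resolved to slices.
#'
#' @param ma numeric vector of tube-current values (mA), all positive.
#' @param slice_z numeric vector of slice-center z positions (mm), same
#'   length as `ma`, increasing caudally.
#' @return An object of class `tcm_profile`.
#' @export
tcm_profile <- function(ma, slice_z) {
  ma <- as.numeric(ma); slice_z <- as.numeric(slice_z)
  if (length(ma) != length(slice_z)) stop("ma and slice_z must have equal length")
  if (any(!is.finite(ma)) || any(ma <= 0)) stop("all mA values must be positive")
  structure(list(ma = ma, slice_z = slice_z), class = "tcm_profile")
}

#' Effective tube current-time product of a TCM profile
#'
#' mAs/pitch scalar derived from the mean modulated current.
#'
#' @param tcm a [tcm_profile()].
#' @param rotation_time gantry rotation time (s).
#' @param pitch helical pitch factor.
#' @return Effective mAs (mAs divided by pitch).
#' @export
effective_mas <- function(tcm, rotation_time = 0.5, pitch = 1) {
  stopifnot(inherits(tcm, "tcm_profile"), rotation_time > 0, pitch > 0)
  mean(tcm$ma) * rotation_time / pitch
}

#' Phantom configuration
#'
#' Geometry, tissue HU values and noise level for the synthetic chest
#' phantom. Defaults emulate an adult chest on a desk-scale grid: body
#' diameters are the cohort means of a typical clinical center, tissue HU
#' values are typical clinical magnitudes, and a moderate amount of
#' basal-predominant consolidation stands in for the pathology spectrum of
#' a pandemic-era referral population.
#'
#' @param body_ap_cm anterior-posterior body diameter (cm).
#' @param body_lat_cm lateral body diameter (cm).
#' @param apex_taper_mm craniocaudal length over which the lung apices taper
#'   to a point (mm).
#' @param costophrenic_slant_mm craniocaudal drop of the posterior
#'   costophrenic recess below the anterior lung base (mm); the most
#'   inferior lung slices therefore contain only a narrow posterior sliver.
#' @param hu named list of tissue HU values
#'   (`air`, `lung`, `soft_tissue`, `bone`, `consolidation`).
#' @param pathology_fraction target fraction of lung voxels replaced by
#'   consolidation-density tissue, in `[0, 1]`.
#' @param noise_sd additive Gaussian HU noise standard deviation.
#' @param matrix grid size (rows, columns, slices), each at least
#'   (64, 64, 40).
#' @param spacing voxel spacing in mm (row, column, slice).
#' @param ctdi_vol CTDIvol reported for the simulated acquisition (mGy).
#' @param kvp tube voltage (kV).
#' @param lung_top_frac fraction of the slice stack above the lung apex.
#' @param lung_len_frac lung length as a fraction of the slice stack.
#' @param lung_scale relative lung size; values that push the lungs outside
#'   the body are a configuration error.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(body_ap_cm = 23.3, body_lat_cm = 31.1,
                           apex_taper_mm = 30, costophrenic_slant_mm = 25,
                           hu = list(air = -1000, lung = -800, soft_tissue = 40,
                                     bone = 700, consolidation = -100),
                           pathology_fraction = 0.1, noise_sd = 20,
                           matrix = c(96, 96, 64),
                           spacing = c(3.75, 3.75, 2.5),
                           ctdi_vol = 6.0, kvp = 120,
                           lung_top_frac = 0.18, lung_len_frac = 0.62,
                           lung_scale = 1.0) {
  matrix <- as.integer(matrix); spacing <- as.numeric(spacing)
  if (length(matrix) != 3L || any(matrix < c(64L, 64L, 40L)))
    stop("matrix must be at least (64, 64, 40)")
  if (any(spacing <= 0)) stop("spacing components must be positive")
  if (body_ap_cm <= 0 || body_lat_cm <= 0) stop("body diameters must be positive")
  if (pathology_fraction < 0 || pathology_fraction > 1)
    stop("pathology_fraction must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  needed <- c("air", "lung", "soft_tissue", "bone", "consolidation")
  if (!all(needed %in% names(hu))) stop("hu must name: ", paste(needed, collapse = ", "))
  cfg <- structure(list(body_ap_cm = body_ap_cm, body_lat_cm = body_lat_cm,
                        apex_taper_mm = apex_taper_mm,
                        costophrenic_slant_mm = costophrenic_slant_mm,
                        hu = hu, pathology_fraction = pathology_fraction,
                        noise_sd = noise_sd, matrix = matrix, spacing = spacing,
                        ctdi_vol = ctdi_vol, kvp = kvp,
                        lung_top_frac = lung_top_frac,
                        lung_len_frac = lung_len_frac, lung_scale = lung_scale),
                   class = "phantom_config")
  # body must fit in the field of view
  if (body_ap_cm * 10 > matrix[1] * spacing[1] || body_lat_cm * 10 > matrix[2] * spacing[2])
    stop("body does not fit inside the reconstruction field of view")
  # lung must fit inside the body
  a <- body_ap_cm * 10 / 2; b <- body_lat_cm * 10 / 2
  if (0.55 * a * lung_scale > a || (0.50 * b + 0.42 * b * lung_scale) > b)
    stop("configured lungs are larger than the body")
  cfg
}

#' Slice-center z coordinates of a volume
#'
#' @param volume a [ct_volume()] or [lung_mask3d()].
#' @return Numeric vector of slice-center z positions (mm), slice 1 most
#'   superior.
#' @export
slice_z_positions <- function(volume) {
  dz <- volume$spacing[3]
  k <- seq_len(dim(volume$voxels)[3])
  (k - 0.5) * dz
}

#' Ground-truth scan range of a 3D lung mask
#'
#' Brute-force slice scan: the superior limit is the center z of the first
#' slice containing lung, the inferior limit that of the last.
#'
#' @param mask a [lung_mask3d()].
#' @return A [scan_range()] with provenance `"exact"`.
#' @export
range_from_mask3d <- function(mask) {
  stopifnot(inherits(mask, "lung_mask3d"))
  occ <- which(apply(mask$voxels, 3, any))
  if (length(occ) == 0L) stop("mask contains no lung voxels")
  z <- slice_z_positions(mask)
  scan_range(z[min(occ)], z[max(occ)], provenance = "exact")
}

#' Generate a synthetic chest phantom
#'
#' Builds an elliptical soft-tissue body containing two lungs with tapered
#' apices and slanted costophrenic recesses (the posterior recess extends
#' more caudally, so the most inferior lung slices hold only a thin
#' posterior sliver), a vertebral bone column, optional basal-predominant
#' consolidation, and additive Gaussian HU noise. The ground-truth lung mask
#' is the anatomical lung region before noise; a tube-current-modulation
#' profile is derived from the finished volume.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; identical (config, seed) pairs give
#'   bit-identical phantoms.
#' @param base_ma baseline tube current for the simulated TCM profile (mA).
#' @param tcm_exponent modulation strength passed to [simulate_tcm()].
#' @return A list with elements `volume` ([ct_volume()]), `mask`
#'   ([lung_mask3d()]) and `range` (the ground-truth [scan_range()]).
#' @examples
#' ph <- generate_phantom(phantom_config(noise_sd = 0, pathology_fraction = 0), seed = 1)
#' ph$range
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1,
                             base_ma = 150, tcm_exponent = 0.5) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(as.integer(seed), {
    nr <- config$matrix[1]; nc <- config$matrix[2]; nk <- config$matrix[3]
    s <- config$spacing
    a <- config$body_ap_cm * 10 / 2   # AP semi-axis, mm
    b <- config$body_lat_cm * 10 / 2  # lateral semi-axis, mm
    ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
    x <- (seq_len(nr) - ci) * s[1]    # AP coordinate per row, mm
    y <- (seq_len(nc) - cj) * s[2]    # lateral coordinate per column, mm

    X <- matrix(x, nr, nc); Y <- matrix(y, nr, nc, byrow = TRUE)
    body2d <- (X / a)^2 + (Y / b)^2 <= 1
    spine2d <- (X - 0.62 * a)^2 + Y^2 <= 14^2

    # lung geometry (mm), proportional to the body
    rx <- 0.55 * a * config$lung_scale
    ry <- 0.42 * b * config$lung_scale
    off <- 0.50 * b
    xc <- -0.10 * a
    k_top <- max(2L, round(config$lung_top_frac * nk))
    len_k <- round(config$lung_len_frac * nk)
    k_bot <- min(nk - 2L, k_top + len_k - 1L)
    taper_k <- max(1L, round(config$apex_taper_mm / s[3]))
    slant_k <- max(1L, min(round(config$costophrenic_slant_mm / s[3]), k_bot - k_top - taper_k))
    k_bot_ant <- k_bot - slant_k    # anterior lung base slice

    ellip <- function(scale, sgn) {
      ((X - xc) / (rx * scale))^2 + ((Y - sgn * off) / (ry * scale))^2 <= 1
    }

    mask <- array(FALSE, dim = c(nr, nc, nk))
    for (k in k_top:k_bot) {
      sc <- min(1, (k - k_top + 1) / taper_k)
      m2 <- ellip(sc, 1) | ellip(sc, -1)
      if (k > k_bot_ant) {
        # slanted recess: at slice k only voxels posterior to x_thr keep lung
        x_thr <- (xc - rx) + (k - k_bot_ant) / slant_k * (2 * rx)
        m2[X < x_thr] <- FALSE
      }
      mask[, , k] <- m2 & body2d
    }

    vox <- array(config$hu$air, dim = c(nr, nc, nk))
    for (k in seq_len(nk)) {
      sl <- vox[, , k]
      sl[body2d] <- config$hu$soft_tissue
      sl[mask[, , k]] <- config$hu$lung
      sl[spine2d & body2d & !mask[, , k]] <- config$hu$bone
      vox[, , k] <- sl
    }

    # basal/peripheral-predominant consolidation inside the lungs
    if (config$pathology_fraction > 0) {
      lung_idx <- which(mask)
      n_lung <- length(lung_idx)
      target <- config$pathology_fraction * n_lung
      cons <- array(FALSE, dim = dim(mask))
      dd <- dim(mask)
      kz <- ((lung_idx - 1) %/% (nr * nc)) + 1
      w <- (kz - min(kz) + 1)^2            # bias blob seeds toward the base
      tries <- 0L
      while (sum(cons) < target && tries < 25L) {
        tries <- tries + 1L
        ctr <- lung_idx[sample.int(n_lung, 1L, prob = w)]
        ck <- ((ctr - 1) %/% (nr * nc)) + 1
        cjj <- ((ctr - 1) %% (nr * nc)) %/% nr + 1
        cii <- ((ctr - 1) %% nr) + 1
        r_mm <- runif(1, 10, 22)
        di <- pmax(1, cii - ceiling(r_mm / s[1])):pmin(nr, cii + ceiling(r_mm / s[1]))
        dj <- pmax(1, cjj - ceiling(r_mm / s[2])):pmin(nc, cjj + ceiling(r_mm / s[2]))
        dk <- pmax(1, ck - ceiling(r_mm / s[3])):pmin(nk, ck + ceiling(r_mm / s[3]))
        for (k in dk) {
          d2 <- outer(((di - cii) * s[1])^2, ((dj - cjj) * s[2])^2, "+") + ((k - ck) * s[3])^2
          blob <- d2 <= r_mm^2
          sub <- cons[di, dj, k] | (blob & mask[di, dj, k])
          cons[di, dj, k] <- sub
        }
      }
      vox[cons] <- config$hu$consolidation
    }

    if (config$noise_sd > 0)
      vox <- vox + rnorm(length(vox), 0, config$noise_sd)
    vox[vox < -1024] <- -1024
    vox[vox > 3071] <- 3071

    vol <- ct_volume(vox, s, ctdi_vol = config$ctdi_vol, kvp = config$kvp)
    vol$tcm <- simulate_tcm(vol, base_ma = base_ma, exponent = tcm_exponent)
    msk <- lung_mask3d(mask, s)
    list(volume = vol, mask = msk, range = range_from_mask3d(msk))
  })
}

#' Simulate tube-current modulation from slice attenuation
#'
#' Each slice receives `ma = base_ma * (A / mean(A))^exponent`, where `A` is
#' the slice sum of `max(HU + 1000, 0)`, clipped to
#' `[0.2 * base_ma, 3 * base_ma]`. For `exponent > 0` the profile is
#' monotone in slice attenuation before clipping.
#'
#' @param volume a [ct_volume()].
#' @param base_ma baseline tube current (mA), positive.
#' @param exponent modulation exponent; 0 gives a flat profile.
#' @return A [tcm_profile()].
#' @export
simulate_tcm <- function(volume, base_ma = 150, exponent = 0.5) {
  stopifnot(inherits(volume, "ct_volume"), base_ma > 0)
  att <- pmax(volume$voxels + 1000, 0)
  d <- dim(att)
  A <- colSums(matrix(att, nrow = d[1] * d[2], ncol = d[3]))
  if (all(A == 0)) stop("volume is empty (no attenuating material)")
  ma <- base_ma * (A / mean(A))^exponent
  ma <- pmin(pmax(ma, 0.2 * base_ma), 3 * base_ma)
  tcm_profile(ma, slice_z_positions(volume))
}

#' Operator overscan simulation settings
#'
#' Normal-distributed extensions of the true lung range in each direction,
#' parameterized by the mean and SD of the overscan length (mm). By default
#' draws are truncated at zero, matching the near-universal overscan
#' reported in clinical audits; `allow_negative = TRUE` permits missed-lung
#' draws (used for distributional parameter recovery).
#'
#' @param superior_mean,superior_sd mean and SD of superior overscan (mm).
#' @param inferior_mean,inferior_sd mean and SD of inferior overscan (mm).
#' @param allow_negative logical; permit negative (missed-lung) draws.
#' @return An object of class `human_range_sim_config`.
#' @export
human_range_sim_config <- function(superior_mean = 26.0, superior_sd = 9.2,
                                   inferior_mean = 38.1, inferior_sd = 21.0,
                                   allow_negative = FALSE) {
  if (superior_sd < 0 || inferior_sd < 0) stop("standard deviations must be >= 0")
  structure(list(superior_mean = superior_mean, superior_sd = superior_sd,
                 inferior_mean = inferior_mean, inferior_sd = inferior_sd,
                 allow_negative = isTRUE(allow_negative)),
            class = "human_range_sim_config")
}

#' Draw simulated operator overscan lengths
#'
#' @param config a [human_range_sim_config()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return A data.frame with columns `superior` and `inferior` (mm).
#' @export
simulate_overscan_draws <- function(config = human_range_sim_config(), n = 1, seed = 1) {
  stopifnot(inherits(config, "human_range_sim_config"), n >= 1)
  withr::with_seed(as.integer(seed), {
    sup <- rnorm(n, config$superior_mean, config$superior_sd)
    inf <- rnorm(n, config$inferior_mean, config$inferior_sd)
    if (!config$allow_negative) { sup <- pmax(sup, 0); inf <- pmax(inf, 0) }
    data.frame(superior = sup, inferior = inf)
  })
}

#' Simulate an operator-selected ("human") scan range
#'
#' Moves the superior limit cranially and the inferior limit caudally by
#' draws from the configured overscan distributions.
#'
#' @param true_range ground-truth [scan_range()].
#' @param config a [human_range_sim_config()].
#' @param seed integer seed; deterministic per seed.
#' @return A [scan_range()] with provenance `"human"`.
#' @export
simulate_human_range <- function(true_range, config = human_range_sim_config(), seed = 1) {
  stopifnot(inherits(true_range, "scan_range"))
  d <- simulate_overscan_draws(config, n = 1, seed = seed)
  scan_range(true_range$superior_z - d$superior,
             true_range$inferior_z + d$inferior,
             provenance = "human")
}
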