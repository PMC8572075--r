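# Scout-view synthesis: sum projections, mask co-projection,
# normalization/resizing with z bookkeeping, magnification distortion.

test_that("air-only volumes project to zero and single voxels to one term", {
  vol <- ct_volume(array(-1000, c(64, 64, 40)), c(1, 1, 1))
  expect_true(all(project_volume(vol, "AP")$pixels == 0))
  expect_true(all(project_volume(vol, "LAT")$pixels == 0))

  vox <- array(-1000, c(64, 64, 40))
  vox[10, 20, 30] <- 0              # attenuation 1000, ray step 1 mm
  vol1 <- ct_volume(vox, c(1, 1, 1))
  ap <- project_volume(vol1, "AP")
  expect_equal(ap$pixels[30, 20], 1000)
  expect_equal(sum(ap$pixels), 1000)
  lat <- project_volume(vol1, "LAT")
  expect_equal(lat$pixels[30, 10], 1000)
})

test_that("projection conserves total attenuation", {
  ph <- generate_phantom(random_phantom_config(), seed = 9)
  att <- pmax(ph$volume$voxels + 1000, 0)
  for (v in c("AP", "LAT")) {
    p <- project_volume(ph$volume, v)
    step <- ph$volume$spacing[if (v == "AP") 1 else 2]
    expect_lt(abs(sum(p$pixels) - sum(att) * step) / (sum(att) * step), 1e-9)
  }
})

test_that("mask projection reproduces the 3D slice occupancy exactly", {
  # constructed case: lung in slices 30-90 only
  vox <- array(FALSE, c(32, 32, 100))
  vox[10:20, 10:20, 30:90] <- TRUE
  m3 <- lung_mask3d(vox, c(2, 2, 2))
  m2 <- project_mask(m3, "AP")
  expect_identical(which(rowSums(m2$pixels) > 0), 30:90)

  # property: row set == slice set on random phantoms
  set.seed(7)
  for (i in 1:10) {
    ph <- generate_phantom(random_phantom_config(), seed = 100 + i)
    occ3 <- which(apply(ph$mask$voxels, 3, any))
    for (v in c("AP", "LAT")) {
      m <- project_mask(ph$mask, v)
      expect_identical(which(rowSums(m$pixels) > 0), occ3)
    }
  }
})

test_that("range from the projected mask equals the 3D range at native resolution", {
  ph <- generate_phantom(random_phantom_config(), seed = 21)
  for (v in c("AP", "LAT")) {
    m <- project_mask(ph$mask, v)
    r <- mask_to_range(m, margin_voxels = 0)
    expect_identical(r$superior_z, ph$range$superior_z)
    expect_identical(r$inferior_z, ph$range$inferior_z)
  }
})

test_that("normalization scales to [0,1] and resizing preserves the z mapping", {
  ph <- generate_phantom(random_phantom_config(), seed = 2)
  p <- project_volume(ph$volume, "AP")
  m <- project_mask(ph$mask, "AP")
  nr <- normalize_resize(p, m, 256)
  expect_equal(min(nr$projection$pixels), 0)
  expect_equal(max(nr$projection$pixels), 1)
  expect_equal(dim(nr$projection$pixels), c(256L, 256L))
  expect_type(nr$mask$pixels[1], "logical")

  # native-size call on a square image changes only the intensity scale
  rows <- nrow(p$pixels)
  sq <- matrix(runif(128 * 128, 10, 90), 128, 128)
  psq <- projection2d(sq, "AP", c(0.5, 1))
  same <- normalize_resize(psq, NULL, 128)
  expect_equal(same$projection$pixels,
               (sq - min(sq)) / diff(range(sq)), tolerance = 1e-12)

  # row -> z -> row round trip is exact under the affine
  r <- c(1, 57, 200, 256)
  z <- row_to_z(nr$projection, r)
  expect_equal(z_to_row(nr$projection, z), r, tolerance = 1e-12)
  # resampled rows address the same z interval as the native grid
  z_native_extent <- c(row_to_z(p, 1) - p$row_to_z[2] / 2,
                       row_to_z(p, rows) + p$row_to_z[2] / 2)
  z_resized_extent <- c(row_to_z(nr$projection, 1) - nr$projection$row_to_z[2] / 2,
                        row_to_z(nr$projection, 256) + nr$projection$row_to_z[2] / 2)
  expect_equal(z_native_extent, z_resized_extent, tolerance = 1e-12)
})

test_that("resizing maps mask rows through the expected affine", {
  px <- matrix(0, 512, 512)
  mk <- matrix(FALSE, 512, 512)
  mk[100:180, 200:300] <- TRUE
  px[mk] <- 1; px[1, 1] <- 2        # non-constant image
  p <- projection2d(px, "AP", c(0.5, 1))
  m <- mask2d(mk, c(0.5, 1))
  nr <- normalize_resize(p, m, 256)
  occ <- which(rowSums(nr$mask$pixels) > 0)
  expect_lte(abs(min(occ) - 50), 1)
  expect_lte(abs(max(occ) - 90), 1)
})

test_that("constant-intensity images degenerate to zeros with a warning", {
  p <- projection2d(matrix(5, 64, 64), "AP", c(0.5, 1))
  expect_warning(nr <- normalize_resize(p, NULL, 64), "constant")
  expect_true(all(nr$projection$pixels == 0))
})

test_that("magnification follows M = SDD/(SDD - y) on column offsets", {
  px <- matrix(0, 64, 101)
  mk <- matrix(FALSE, 64, 101)
  ctr <- 51
  mk[30, ctr + 20] <- TRUE          # point 20 columns off-center
  mk[31, ctr] <- TRUE               # point at the isocenter column
  px[mk] <- 1; px[2, 2] <- 2
  p <- projection2d(px, "AP", c(0.5, 1))
  m <- mask2d(mk, c(0.5, 1))

  # y = 100 mm closer to the source, SDD 1040 -> offsets scaled by 1040/940
  g <- scout_geometry(1040, 570, 100)
  out <- apply_magnification(p, m, g)
  hit <- which(out$mask$pixels[30, ])
  expect_lte(abs(hit - (ctr + 20 * 1040 / 940)), 1)
  expect_true(out$mask$pixels[31, ctr])   # isocenter column unmoved

  # y = 0: M = 1, everything unchanged
  id <- apply_magnification(p, m, scout_geometry(1040, 570, 0))
  expect_equal(id$projection$pixels, px)
  expect_identical(id$mask$pixels, mk)

  # parallel-beam limit: distances -> infinity with fixed offset
  par <- apply_magnification(p, m, scout_geometry(1e12, 1e11, 100))
  expect_equal(par$projection$pixels, px, tolerance = 1e-6)

  # object at or beyond the source is rejected
  expect_error(apply_magnification(p, m, scout_geometry(1040, 570, 600)),
               "beyond the source")
})

test_that("magnification never changes which rows are occupied", {
  set.seed(3)
  for (i in 1:5) {
    ph <- generate_phantom(random_phantom_config(), seed = 300 + i)
    m <- project_mask(ph$mask, "AP")
    p <- project_volume(ph$volume, "AP")
    out <- apply_magnification(p, m, scout_geometry(1040, 570, runif(1, -80, 120)))
    expect_identical(which(rowSums(out$mask$pixels) > 0),
                     which(rowSums(m$pixels) > 0))
  }
})
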