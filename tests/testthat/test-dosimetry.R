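# Effective diameter, AAPM-220 SSDE conversion, TCM region averaging, DLP,
# organ-dose surrogate and ICRP-103 effective dose.

# independent numeric oracle for the surrogate: midpoint rule on a fine grid
numeric_organ_dose <- function(field, z_start, z_end, ssde, lambda, n = 200000) {
  z <- seq(z_start, z_end, length.out = n)
  d <- ifelse(z < field[1], field[1] - z, ifelse(z > field[2], z - field[2], 0))
  mean(ifelse(d == 0, ssde, ssde * exp(-d / lambda)))
}

test_that("effective diameter is the geometric mean of the body diameters", {
  expect_equal(effective_diameter(10, 10), 10)
  expect_equal(effective_diameter(23.3, 31.1), sqrt(23.3 * 31.1))
  expect_lt(abs(effective_diameter(23.3, 31.1) - 26.92), 0.01)
  expect_error(effective_diameter(0, 30), "positive")
})

test_that("the SSDE conversion matches the published table and decreases in size", {
  # printed conversion factors for the 32-cm phantom at three diameters
  anchors <- c("8" = 2.76, "20" = 1.78, "30" = 1.23)
  for (d in names(anchors)) {
    f <- ssde_conversion_factor(as.numeric(d))
    expect_lt(abs(f - anchors[[d]]) / anchors[[d]], 0.01)
  }
  grid <- seq(6, 55, by = 0.5)
  expect_true(all(diff(ssde_conversion_factor(grid)) < 0))
  expect_error(ssde_conversion_factor(5), "domain")
  expect_error(ssde_conversion_factor(60), "domain")
  expect_equal(ssde(0, 25), 0)
  expect_gt(ssde(10, 20), ssde(10, 30))
})

test_that("body diameters are measured within a voxel on known geometry", {
  ph <- generate_phantom(quiet_config(body_ap_cm = 22, body_lat_cm = 30), seed = 4)
  dm <- measure_body_diameters(ph$volume, ph$mask)
  expect_lt(abs(dm["d_ap"] - 22), ph$volume$spacing[1] / 10)
  expect_lt(abs(dm["d_lat"] - 30), ph$volume$spacing[2] / 10)

  # isotropic cylinder: both diameters equal 2r within a voxel
  vox <- array(-1000, c(80, 80, 40))
  x <- (seq_len(80) - 40.5) * 2
  X <- matrix(x, 80, 80); Y <- t(X)
  cyl <- X^2 + Y^2 <= 60^2
  for (k in 1:40) vox[, , k][cyl] <- 40
  cylv <- ct_volume(vox, c(2, 2, 3))
  dm2 <- measure_body_diameters(cylv)
  expect_lt(abs(dm2["d_ap"] - 12), 0.2)
  expect_lt(abs(dm2["d_lat"] - 12), 0.2)

  expect_error(measure_body_diameters(
    ct_volume(array(-1000, c(64, 64, 40)), c(2, 2, 2))), "no body")
})

test_that("TCM region averages resolve slices by z against both ranges", {
  tcm <- tcm_profile(rep(100, 40), (1:40 - 0.5) * 2.5)
  truth <- scan_range(20, 80, "exact")
  sel <- scan_range(5, 95, "human")
  expect_equal(tcm_region_average(tcm, truth, sel),
               c(lung = 100, superior = 100, inferior = 100))
  # selected == truth: no slices outside the lung
  same <- tcm_region_average(tcm, truth, scan_range(20, 80, "DL_AP"))
  expect_true(is.na(same["superior"]) && is.na(same["inferior"]))

  # mA equal to the 0-based slice index on 10 slices; lung slices 3-6
  tcm2 <- tcm_profile(pmax(0:9, 1e-9), (1:10 - 0.5))
  tr <- scan_range(3.5, 6.5, "exact")
  sl <- scan_range(0.5, 9.5, "human")
  avg <- tcm_region_average(tcm2, tr, sl)
  expect_equal(unname(avg["lung"]), 4.5)
  expect_equal(unname(avg["superior"]), 1, tolerance = 1e-6)
  expect_equal(unname(avg["inferior"]), 8)
})

test_that("DLP is the CTDI-length product and rejects negative lengths", {
  expect_equal(dlp(10, 30), 300)
  expect_equal(dlp(10, 0), 0)
  expect_equal(dlp(c(5, 10), c(2, 3)), 40)
  expect_error(dlp(10, -1), "non-negative")
})

test_that("reference-lung normalization scales overscan by the length ratio", {
  truth <- scan_range(100, 400, "exact")          # 300 mm lung
  sel <- scan_range(70, 430, "human")             # 30 mm overscan each side
  ref <- normalize_to_reference_lung(sel, truth, 240)
  expect_equal(ref$superior_z, -24)
  expect_equal(ref$inferior_z, 264)

  # equal lengths leave overscan unchanged
  truth2 <- scan_range(0, 240, "exact")
  sel2 <- scan_range(-15, 260, "human")
  ref2 <- normalize_to_reference_lung(sel2, truth2, 240)
  expect_equal(ref2$superior_z, -15)
  expect_equal(ref2$inferior_z, 260)

  # zero overscan maps to the reference boundaries
  ref3 <- normalize_to_reference_lung(truth, truth, 240)
  expect_equal(c(ref3$superior_z, ref3$inferior_z), c(0, 240))
})

test_that("the organ-dose surrogate matches closed forms and decays off-field", {
  field <- c(0, 240)
  lam <- 30
  organs <- data.frame(organ = c("inside", "far", "half"),
                       z_start_mm = c(50, 240 + 10 * lam, 240 - lam),
                       z_end_mm = c(150, 240 + 12 * lam, 240 + lam))
  d <- organ_dose_surrogate(field, organs, 8, scatter_length = lam)
  expect_equal(unname(d["inside"]), 8)
  expect_lt(unname(d["far"]), 1e-4 * 8)
  expect_equal(unname(d["half"]), 8 * (0.5 + 0.5 * (1 - exp(-1))),
               tolerance = 1e-9)
  # closed form vs numeric integration on all three organs
  for (i in 1:3) {
    num <- numeric_organ_dose(field, organs$z_start_mm[i], organs$z_end_mm[i],
                              8, lam)
    expect_equal(unname(d[i]), num, tolerance = 1e-4)
  }
  expect_true(all(d <= 8 + 1e-12))
  expect_error(organ_dose_surrogate(field, organs[0, ], 8), "empty")
})

test_that("ICRP-103 weights load, sum to one, and define the effective dose", {
  w <- icrp103_weights()
  expect_lt(abs(sum(w$w_t) - 1), 1e-9)
  geom <- reference_organ_geometry()
  expect_setequal(geom$organ, w$organ)

  # uniform organ dose d gives ED == d
  uniform <- setNames(rep(7.5, nrow(w)), w$organ)
  expect_equal(effective_dose(uniform, w), 7.5)
  # a single organ contributes w_T * D_T
  lung_only <- c(lung = 10)
  expect_equal(effective_dose(lung_only, w), 10 * 0.12)
  expect_equal(effective_dose(setNames(rep(0, nrow(w)), w$organ), w), 0)
  expect_error(effective_dose(c(flux_capacitor = 1), w), "unknown organ")
})

test_that("scenario dose reports satisfy the DLP and ED identities", {
  ph <- generate_phantom(quiet_config(), seed = 13)
  truth <- ph$range
  human <- scan_range(truth$superior_z - 26, truth$inferior_z + 38.1, "human")
  dm <- measure_body_diameters(ph$volume, ph$mask)
  inp <- dose_inputs(dm["d_ap"], dm["d_lat"], ctdi_vol = 6,
                     tcm = ph$volume$tcm)

  # TCM mode: scenario DLP equals the sum of independently computed
  # regional CTDI x length products
  rep_h <- scenario_dose(human, truth, inp, "human", tcm_mode = TRUE)
  reg <- tcm_region_average(inp$tcm, truth, human)
  z <- inp$tcm$slice_z
  in_scan <- z >= human$superior_z & z <= human$inferior_z
  scan_ma <- mean(inp$tcm$ma[in_scan])
  lens <- c(lung = range_length_mm(truth),
            superior = truth$superior_z - human$superior_z,
            inferior = human$inferior_z - truth$inferior_z) / 10
  manual <- sum(6 * reg / scan_ma * lens)
  expect_lt(abs(rep_h$dlp - manual) / manual, 1e-9)

  # constant-current mode: fractional DLP reduction == fractional length
  # reduction, exactly
  rc_h <- scenario_dose(human, truth, inp, "human", tcm_mode = FALSE)
  rc_e <- scenario_dose(truth, truth, inp, "exact", tcm_mode = FALSE)
  expect_equal((rc_h$dlp - rc_e$dlp) / rc_h$dlp,
               (rc_h$scan_length_cm - rc_e$scan_length_cm) / rc_h$scan_length_cm,
               tolerance = 1e-12)

  # ED ordering: exact <= DL (nested) <= human
  dl <- scan_range(truth$superior_z - 2, truth$inferior_z + 5, "DL_Both")
  rc_d <- scenario_dose(dl, truth, inp, "DL", tcm_mode = FALSE)
  expect_lte(rc_e$ed, rc_d$ed)
  expect_lte(rc_d$ed, rc_h$ed)
})

test_that("scenario comparison decomposes the human ED and reports reductions", {
  ph <- generate_phantom(quiet_config(), seed = 19)
  truth <- ph$range
  dm <- measure_body_diameters(ph$volume, ph$mask)
  inp <- dose_inputs(dm["d_ap"], dm["d_lat"], ctdi_vol = 6)
  human <- scan_range(truth$superior_z - 26, truth$inferior_z + 38.1, "human")
  dl <- scan_range(truth$superior_z - 1, truth$inferior_z + 2, "DL_Both")
  r_e <- scenario_dose(truth, truth, inp, "exact", tcm_mode = FALSE)
  r_h <- scenario_dose(human, truth, inp, "human", tcm_mode = FALSE)
  r_d <- scenario_dose(dl, truth, inp, "DL", tcm_mode = FALSE)
  cmp <- compare_scenarios(r_e, r_h, r_d)
  expect_equal(cmp$ed_reduction_percent, 100 * (r_h$ed - r_d$ed) / r_h$ed)
  # additional superior + inferior ED reconstructs the human ED
  expect_lt(abs(r_e$ed + cmp$additional_ed_superior +
                  cmp$additional_ed_inferior - r_h$ed) / r_h$ed, 1e-6)
  # identical human and DL scenarios: no reduction
  cmp0 <- compare_scenarios(r_e, r_h, r_h)
  expect_equal(cmp0$ed_reduction_percent, 0)
})
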