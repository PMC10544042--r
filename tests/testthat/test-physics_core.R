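test_that("mixture mass attenuation follows the weighted sum rule", {
  raw <- raw_elements()
  egrid <- as.numeric(raw$energy_kev)
  # pure element at a tabulated grid point reproduces the table exactly
  iH <- which(raw$elements$symbol == "H")
  tot_H <- raw$elements$mu_rho_pe[[iH]] + raw$elements$mu_rho_coh[[iH]] +
    raw$elements$mu_rho_inc[[iH]]
  mH <- material("hydrogen", 0.001, c(H = 1))
  expect_equal(mass_attenuation(mH, egrid[3]), tot_H[3], tolerance = 1e-12)

  # 50/50 by mass is the arithmetic mean of the two elemental values
  mC <- material("carbon", 2, c(C = 1))
  mix <- material("mix", 1, c(H = 0.5, C = 0.5))
  expect_equal(mass_attenuation(mix, 80),
               (mass_attenuation(mH, 80) + mass_attenuation(mC, 80)) / 2,
               tolerance = 1e-12)

  # water at 60 keV against an independent hand-sum from the raw table
  # (own log-log spline per element, weights 2*1.008/18.015 and 16/18.015)
  hand <- function(sym) {
    i <- which(raw$elements$symbol == sym)
    tot <- raw$elements$mu_rho_pe[[i]] + raw$elements$mu_rho_coh[[i]] +
      raw$elements$mu_rho_inc[[i]]
    exp(spline(log(egrid), log(tot), xout = log(60), method = "fmm")$y)
  }
  w_H <- 2 * 1.008 / (2 * 1.008 + 15.999)
  expected <- w_H * hand("H") + (1 - w_H) * hand("O")
  expect_equal(mass_attenuation(water_mat(), 60), expected, tolerance = 2e-3)

  expect_error(mass_attenuation(water_mat(), 10), "outside")
  expect_error(material("x", 1, c(Qq = 1)), "unknown element")
})

test_that("relative linear attenuation is normalized to water", {
  w <- water_mat()
  expect_equal(linear_attenuation_rel_water(w, c(40, 74, 140)), rep(1, 3))
  bone <- phantom_inserts()[["bone_800"]]
  expect_gt(linear_attenuation_rel_water(bone, 60), 1)
  thin <- material("near-vacuum", 1e-9, c(H = 0.1119, O = 0.8881))
  expect_lt(linear_attenuation_rel_water(thin, 60), 1e-8)
})

test_that("ground-truth RED, ln(I) and EAN behave as defined", {
  w <- water_mat()
  expect_equal(true_red(w), 1.0, tolerance = 1e-12)
  w2 <- material("dense water", 2.0, c(H = 0.1119, O = 0.8881))
  expect_equal(true_red(w2), 2.0, tolerance = 1e-12)

  # hand computation for a muscle-like packaged material
  m <- phantom_inserts()[["muscle"]]
  tab <- dect_elements()$elements
  za <- vapply(names(m$w), function(s) tab[[s]]$Z / tab[[s]]$A, 0)
  expect_equal(true_red(m),
               m$rho * sum(m$w * za) / (0.1119 * 1 / 1.008 + 0.8881 * 8 / 15.999),
               tolerance = 1e-10)

  # single element and equal-electron-fraction mean
  mO <- material("oxygen", 1, c(O = 1))
  expect_equal(true_lnI(mO), log(tab$O$I_ev))
  # water ln I in the physical band and matching the hand formula
  lnI_w <- true_lnI(w)
  expect_gt(lnI_w, log(70)); expect_lt(lnI_w, log(80))
  lamH <- 0.1119 * (1 / 1.008)
  lamO <- 0.8881 * (8 / 15.999)
  expect_equal(lnI_w, (lamH * log(tab$H$I_ev) + lamO * log(tab$O$I_ev)) /
                 (lamH + lamO), tolerance = 1e-12)

  expect_gt(true_ean(phantom_inserts()[["bone_1250"]], 3.1), 10)
  expect_equal(true_ean(mO, 3.1), 8)
})

test_that("Bethe stopping-power ratio has its fixed points and monotonicity", {
  k <- bethe_constants()
  expect_equal(spr_bethe(1.0, 78.73, k), 1.0, tolerance = 1e-12)
  expect_equal(spr_bethe(1.05, 78.73, k), 1.05, tolerance = 1e-12)
  # frozen value from an independent evaluation (beta^2 from 100 MeV
  # protons, proton rest energy 938.272 MeV)
  expect_equal(spr_bethe(1.0, 75.0, k), 1.00622, tolerance = 1e-4)
  # strictly decreasing in I at fixed RED
  iv <- seq(60, 120, by = 5)
  s <- spr_bethe(rep(1, length(iv)), iv, k)
  expect_true(all(diff(s) < 0))
  expect_error(spr_bethe(1, 1e9, k), "non-positive")
})

test_that("two-branch ln(I) parametrization matches its printed constants", {
  expect_equal(yang_lnI(7.0), 0.120 * 7 + 3.407)
  expect_equal(yang_lnI(13.0), 0.081 * 13 + 3.514)
  # branch boundary belongs to the upper branch; discontinuity preserved
  expect_equal(yang_lnI(8.5), 4.2025)
  expect_gt(yang_lnI(8.5 - 1e-9), yang_lnI(8.5))
})

test_that("HU to relative attenuation conversion", {
  expect_equal(hu_to_rel_atten(c(0, -1000, 800)), c(1, 0, 1.8))
  expect_warning(out <- hu_to_rel_atten(-1500), "clamped")
  expect_equal(out, 0)
  expect_equal(rel_atten_to_hu(hu_to_rel_atten(123.4)), 123.4)
})
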