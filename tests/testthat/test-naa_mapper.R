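test_that("inversion round-trips exact forward-model voxels", {
  b <- test_basis()
  set.seed(7)
  zs <- runif(40, 4, 54)
  rs <- runif(40, 0.2, 2)
  for (pr in list(c(50, 60), c(44, 54), c(70, 120))) {
    mu1 <- jh_forward_rel_water(b, zs, rs, pr[1])
    mu2 <- jh_forward_rel_water(b, zs, rs, pr[2])
    inv <- invert_zeff(mu1, mu2, pr[1], pr[2], b)
    rd <- red_from_pair(mu1, mu2, pr[1], pr[2], inv$zeff, b)
    expect_lt(max(abs(inv$zeff - zs)), 1e-3)
    expect_lt(max(abs(rd$red - rs)), 1e-4)
    expect_false(any(inv$flagged))
  }
})

test_that("solver agrees with an exhaustive grid-search oracle", {
  b <- test_basis()
  set.seed(11)
  n <- 100
  zs <- runif(n, 4.5, 53.5)
  rs <- runif(n, 0.3, 1.9)
  e1 <- 49; e2 <- 52
  mu1 <- jh_forward_rel_water(b, zs, rs, e1)
  mu2 <- jh_forward_rel_water(b, zs, rs, e2)
  inv <- invert_zeff(mu1, mu2, e1, e2, b)
  # oracle: 0.001-step exhaustive scan of the squared residual
  zg <- seq(4, 54, by = 0.001)
  fg1 <- jh_fg(b, zg, e1); fg2 <- jh_fg(b, zg, e2)
  a1 <- zg^4 * fg1$F + fg1$G
  a2 <- zg^4 * fg2$F + fg2$G
  muw1 <- 1 * mass_attenuation(water_mat(), e1)
  muw2 <- 1 * mass_attenuation(water_mat(), e2)
  for (i in seq_len(n)) {
    r2 <- (mu2[i] * muw2 * a1 - mu1[i] * muw1 * a2)^2
    expect_lt(abs(inv$zeff[i] - zg[which.min(r2)]), 1.1e-3)
  }
})

test_that("a pure element and water invert to sensible parameters", {
  b <- test_basis()
  ca <- material("calcium", 1.55, c(Ca = 1))
  mu <- sapply(c(60, 100), function(e) linear_attenuation_rel_water(ca, e))
  inv <- invert_zeff(mu[1], mu[2], 60, 100, b)
  expect_equal(inv$zeff, 20, tolerance = 0.05 / 20)
  muw <- sapply(c(49, 52), function(e) linear_attenuation_rel_water(water_mat(), e))
  invw <- invert_zeff(muw[1], muw[2], 49, 52, b)
  rdw <- red_from_pair(muw[1], muw[2], 49, 52, invw$zeff, b)
  expect_equal(rdw$red, 1.0, tolerance = 0.005)
})

test_that("the two-energy relations are homogeneous in attenuation", {
  b <- test_basis()
  mu1 <- jh_forward_rel_water(b, 12, 1.1, 60)
  mu2 <- jh_forward_rel_water(b, 12, 1.1, 90)
  i1 <- invert_zeff(mu1, mu2, 60, 90, b)
  i2 <- invert_zeff(2 * mu1, 2 * mu2, 60, 90, b)
  expect_equal(i1$zeff, i2$zeff, tolerance = 1e-6)
  r1 <- red_from_pair(mu1, mu2, 60, 90, i1$zeff, b)$red
  r2 <- red_from_pair(2 * mu1, 2 * mu2, 60, 90, i2$zeff, b)$red
  expect_equal(r2, 2 * r1, tolerance = 1e-6)
})

test_that("segmentation partitions every voxel with closed soft bounds", {
  th <- tissue_class_thresholds()
  expect_equal(as.integer(segment_tissue_classes(c(-500, 0, 500), th)),
               c(1L, 2L, 3L))
  # boundary values belong to the soft class
  expect_equal(as.integer(segment_tissue_classes(c(-200, 150), th)),
               c(2L, 2L))
  set.seed(2)
  v <- runif(1000, -1000, 2000)
  lab <- segment_tissue_classes(v, th)
  expect_true(all(lab %in% 1:3))
})

test_that("mapping a noise-free stack recovers ground truth", {
  b <- test_basis()
  phan <- build_phantom(phantom_spec("Body", spacing = c(2, 2, 2.5), z_mm = 10))
  sub <- crop_phantom(phan, insert_centers(phan)["breast", ], c(36, 36))
  acq <- default_acquisition("Body", sigma_ref = c(low = 0, high = 0))
  stack <- simulate_acquisition(sub, acq)
  maps <- map_spr_naa(stack, pair_assignment(), basis = b)
  mask <- cylinder_roi_mask(sub$labels, c(0, 0, 0), 20, 8)
  spr_true <- spr_bethe(true_red(phantom_inserts()[["breast"]]),
                        exp(true_lnI(phantom_inserts()[["breast"]])))
  expect_equal(mean(maps$spr$data[mask]), spr_true, tolerance = 0.01)
  # water body region maps to SPR 1 within 0.5%
  body <- sub$labels$data == 1L
  expect_lt(max(abs(maps$spr$data[body] - 1)), 0.005)
  # missing assigned energy is a configuration error
  stack2 <- stack[names(stack) != "40"]
  class(stack2) <- "vmi_stack"
  expect_error(map_spr_naa(stack2, pair_assignment(), basis = b), "missing")
})
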