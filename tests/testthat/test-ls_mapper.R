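
test_that("calibration recovers parameters from exact forward data", {
  mats <- phantom_inserts()
  true_par <- list(A = 0.05, B = 1.0, C = 0.02, m = 3.3,
                   alpha = 0.6, a = 1.0, b = 1.0)
  ct <- do.call(ls_forward, c(list(mats), true_par))
  cal <- calibrate_ls(ct$ct_low, ct$ct_high, mats, phantom_id = "Body")
  for (p in names(true_par))
    expect_equal(cal[[p]], true_par[[p]], tolerance = 0.01,
                 label = paste("parameter", p))
  expect_lt(max(abs(cal$residuals_red)), 1e-8)
})

test_that("degenerate and noisy designs behave as specified", {
  w <- water_mat()
  mats <- lapply(1:6, function(i) w)
  expect_error(calibrate_ls(rep(0, 6), rep(0, 6), mats), "degenerate")
  expect_error(calibrate_ls(1:3, 1:3, phantom_inserts()[1:3]), "at least 5")

  # 0.5% gaussian noise on CT numbers: held-out RED prediction within 1%
  mats <- phantom_inserts()
  ct <- ls_forward(mats, 0.05, 1.0, 0.02, 3.3, 0.6, 1.0, 1.0)
  set.seed(1)
  noisy_low <- ct$ct_low + rnorm(9, 0, 5)
  noisy_high <- ct$ct_high + rnorm(9, 0, 5)
  cal <- calibrate_ls(noisy_low[-4], noisy_high[-4], mats[-4])
  pred <- unname(red_ls(ct$ct_low[4], ct$ct_high[4], cal))
  expect_equal(pred, true_red(mats[[4]]), tolerance = 0.01)
})

test_that("the ln(I) lookup is monotone, total and clamped", {
  lut <- build_lnI_lut(reference_tissues(), m = 3.3)
  xg <- seq(-10, 600, length.out = 500)
  y <- lookup_lnI(lut, xg)
  expect_true(all(diff(y) >= 0))
  expect_true(all(is.finite(y)))
  expect_equal(lookup_lnI(lut, -5), min(lut$lnI))
  # query at a reference tissue's own x stays inside the residual band
  m <- 3.3
  t1 <- reference_tissues()[["liver"]]
  x1 <- true_ean(t1, m)^(m - 1)
  band <- max(abs(lut$lnI - lookup_lnI(lut, lut$x))) + 0.06
  expect_lt(abs(lookup_lnI(lut, x1) - true_lnI(t1)), band)
  expect_error(build_lnI_lut(reference_tissues()[1:2], 3.3), "at least 3")
})

test_that("the RED model is linear with the printed zero point", {
  cal <- structure(list(alpha = 0.6, a = 1.0, b = 1.0), class = "ls_calibration")
  expect_equal(red_ls(0, 0, cal), 1.0)
  expect_equal(red_ls(50, 40, cal), 1.034)
  # superposition
  expect_equal(red_ls(10 + 20, 5 + 7, cal) - red_ls(0, 0, cal),
               (red_ls(10, 5, cal) - red_ls(0, 0, cal)) +
                 (red_ls(20, 7, cal) - red_ls(0, 0, cal)), tolerance = 1e-12)
})

test_that("volume mapping closes the loop and survives unphysical voxels", {
  fix <- insert_native_hu()
  cal <- calibrate_ls(fix$ct_low, fix$ct_high, fix$materials, "Body")
  lut <- build_lnI_lut(reference_tissues(), cal$m)
  lo <- image_volume(array(fix$ct_low, c(9, 1, 1)), c(1, 1, 1))
  hi <- image_volume(array(fix$ct_high, c(9, 1, 1)), c(1, 1, 1))
  maps <- map_spr_ls(lo, hi, cal, lut)
  spr_true <- vapply(fix$materials, function(m)
    spr_bethe(true_red(m), exp(true_lnI(m))), 0)
  soft <- classify_tissues(fix$materials) == "soft"
  expect_lt(max(abs(maps$spr$data[soft] / spr_true[soft] - 1)), 0.015)

  # wildly unphysical voxels map to finite SPR through the clamped lookup
  lo2 <- image_volume(array(c(-900, 4000), c(2, 1, 1)), c(1, 1, 1))
  hi2 <- image_volume(array(c(200, -900), c(2, 1, 1)), c(1, 1, 1))
  expect_silent(m2 <- map_spr_ls(lo2, hi2, cal, lut))
  expect_true(all(is.finite(m2$spr$data)))
  hi3 <- image_volume(array(0, c(3, 1, 1)), c(1, 1, 1))
  expect_error(map_spr_ls(lo2, hi3, cal, lut), "grid")
})

test_that("noise in native channels is amplified into the SPR map", {
  fix <- insert_native_hu()
  cal <- calibrate_ls(fix$ct_low, fix$ct_high, fix$materials, "Body")
  lut <- build_lnI_lut(reference_tissues(), cal$m)
  set.seed(5)
  n <- 20000
  sig <- c(33, 32)  # HU, matching the matched-acquisition condition
  cl <- fix$ct_low[["breast"]] + rnorm(n, 0, sig[1])
  ch <- fix$ct_high[["breast"]] + rnorm(n, 0, sig[2])
  maps <- map_spr_ls(image_volume(array(cl, c(n, 1, 1)), c(1, 1, 1)),
                     image_volume(array(ch, c(n, 1, 1)), c(1, 1, 1)), cal, lut)
  in_rel <- max(sd(hu_to_rel_atten(cl)) / mean(hu_to_rel_atten(cl)),
                sd(hu_to_rel_atten(ch)) / mean(hu_to_rel_atten(ch)))
  out_rel <- sd(maps$spr$data) / mean(maps$spr$data)
  expect_gt(out_rel, in_rel)
})
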