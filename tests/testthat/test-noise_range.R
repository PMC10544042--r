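test_that("cylindrical ROI masks match the analytic voxel count", {
  v <- image_volume(array(0, c(40, 40, 16)), c(1, 1, 2.5))
  m <- cylinder_roi_mask(v, c(0, 0, 0), 20, 30)
  analytic <- pi * 10^2 / (1 * 1) * (30 / 2.5)
  expect_lt(abs(sum(m) - analytic), pi * 100)  # within one slice layer
  # 90-degree in-plane rotation symmetry
  sl <- m[, , 8]
  expect_identical(sl, t(sl)[, rev(seq_len(ncol(sl)))])
  expect_error(cylinder_roi_mask(v, c(0, 0, 0), 0, 30), "positive")
  expect_error(cylinder_roi_mask(v, c(0, 0, 0), 200, 30), "outside")
})

test_that("ROI statistics report the documented conventions", {
  v <- array(5, c(4, 4, 2)); mask <- array(TRUE, dim(v))
  rec <- roi_statistics(v, mask, "x", "spr")
  expect_equal(rec$rel_sd_pct, 0)
  expect_equal(rec$skewness, 0)
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  set.seed(123)
  x <- rnorm(1e5)
  expect_lt(abs(sample_skewness(x)), 0.03)
  # CI87 is exactly 1.5x the relative SD
  v2 <- array(abs(rnorm(1000, 10, 1)), c(10, 10, 10))
  r2 <- roi_statistics(v2, array(TRUE, dim(v2)), "x", "spr")
  expect_equal(r2$ci87_pct, 1.5 * r2$rel_sd_pct)
  # near-zero mean flags relative quantities
  r3 <- roi_statistics(array(c(-1, 1), c(2, 1, 1)),
                       array(TRUE, c(2, 1, 1)), "x", "hu")
  expect_true(r3$rel_flag)
})

test_that("aggregation over repeats averages statistics", {
  rec <- roi_statistics(array(1:8, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), "a", "q")
  agg <- aggregate_repeats(list(rec, rec, rec))
  expect_equal(agg$mean, rec$mean)
  expect_equal(agg$repeats, 3L)
  r1 <- rec; r1$ci87_pct <- 1
  r2 <- rec; r2$ci87_pct <- 3
  expect_equal(aggregate_repeats(list(r1, r2))$ci87_pct, 2)
  expect_equal(aggregate_repeats(list(r1, r2))$ci87_pct,
               aggregate_repeats(list(r2, r1))$ci87_pct)
  rq <- rec; rq$quantity <- "other"
  expect_error(aggregate_repeats(list(rec, rq)), "mixed")
})

test_that("the range-energy power law evaluates and scales", {
  beam <- beam_spec()
  expect_equal(r80_water(105, beam), 83.16, tolerance = 1e-3)
  beam2 <- beam_spec(alpha_bk = 2 * beam$alpha_bk)
  expect_equal(r80_water(105, beam2), 2 * r80_water(105, beam))
  e <- seq(70, 200, by = 10)
  expect_true(all(diff(r80_water(e, beam)) > 0))
})

test_that("WEPL range integration matches the water identity", {
  for (s in c(0.2, 0.5, 1, 2)) {
    nz <- ceiling(1.2 * 83.2 / s)
    v <- image_volume(array(s, c(24, 24, nz)), c(2, 2, 1))
    r <- simulate_range(v)
    expect_equal(length(r), 81)
    expect_lt(max(abs(r - r80_water(105) / s)), 0.5)
  }
  # beam exits before R80: flagged lines
  short <- image_volume(array(1, c(24, 24, 20)), c(2, 2, 1))
  expect_true(all(is.na(simulate_range(short))))
})

test_that("range statistics aggregate lines and repeats", {
  rs <- range_statistics(list(c(80, 82, 84)), "x")
  expect_equal(rs$mean, 82)
  expect_equal(rs$skewness, 0)
  # noise-free repeats: zero spread
  rs2 <- range_statistics(list(rep(83, 81), rep(83, 81)), "x")
  expect_equal(rs2$rel_sd_pct, 0)
  expect_equal(rs2$repeats, 2L)
  rs3 <- range_statistics(list(c(80, NA, 84), c(NA, 82, 84)), "x")
  expect_equal(rs3$n_flagged, 2L)
})

test_that("coverage of +/-1.5 SD on a normal sample is near 87%", {
  set.seed(99)
  x <- rnorm(1e5)
  cover <- mean(abs(x - mean(x)) <= 1.5 * sd(x))
  expect_equal(cover, 2 * pnorm(1.5) - 1, tolerance = 0.003 / 0.8664)
})
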