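test_that("phantom rasterization places all labels inside the body", {
  spec <- phantom_spec("Body", spacing = c(2, 2, 2.5), z_mm = 10)
  phan <- build_phantom(spec)
  labs <- sort(unique(as.integer(phan$labels$data)))
  expect_equal(labs, 0:10)   # air, body, nine inserts
  # head: all insert centers stay within the head radius
  head <- phantom_spec("Head")
  r <- vapply(head$inserts, function(i) sqrt(sum(i$center^2)), 0)
  expect_true(all(r + 15 <= head$diameter_mm / 2))
  # body-only phantom
  empty <- phantom_spec("Body", insert_materials = list(),
                        spacing = c(2, 2, 2.5), z_mm = 10)
  expect_equal(sort(unique(as.integer(build_phantom(empty)$labels$data))), 0:1)
  # oversized inserts overlap on the ring
  expect_error(phantom_spec("Head", insert_diameter_mm = 45), "overlap")
})

test_that("ground-truth maps look up the right per-material values", {
  phan <- build_phantom(phantom_spec("Body", spacing = c(2, 2, 2.5), z_mm = 10))
  gt <- ground_truth_maps(phan, energies = 74)
  body <- phan$labels$data == 1L
  expect_lt(max(abs(gt$spr$data[body] - 1)), 1e-6)
  expect_lt(max(abs(gt$mu_rel[["74"]]$data[body] - 1)), 1e-12)
  lab_of <- function(nm) {
    idx <- which(vapply(phan$materials, function(m) m$name == nm, TRUE))
    as.integer(names(phan$materials)[idx])
  }
  spr_at <- function(nm) unique(gt$spr$data[phan$labels$data == lab_of(nm)])
  expect_gt(spr_at("bone_800"), spr_at("muscle"))
  expect_gt(spr_at("muscle"), spr_at("lung_exhale"))
})

test_that("acquisitions are deterministic and exact at zero noise", {
  phan <- build_phantom(phantom_spec("Body", spacing = c(2, 2, 2.5), z_mm = 10))
  sub <- crop_phantom(phan, insert_centers(phan)["muscle", ], c(36, 36))
  gt <- ground_truth_maps(sub, energies = c(44, 74))
  acq0 <- default_acquisition("Body", sigma_ref = c(low = 0, high = 0))
  acq0$energies <- c(44, 74)
  s0 <- simulate_acquisition(sub, acq0, 1, gt = gt)
  expect_equal(stack_get(s0, 74)$data,
               rel_atten_to_hu(gt$mu_rel[["74"]]$data), tolerance = 1e-12)
  acq <- default_acquisition("Body", base_seed = 5L)
  acq$energies <- c(44, 74)
  s1 <- simulate_acquisition(sub, acq, 3, gt = gt)
  s2 <- simulate_acquisition(sub, acq, 3, gt = gt)
  expect_identical(stack_get(s1, 44)$data, stack_get(s2, 44)$data)
})

test_that("channel noise is correlated across energies and larger at low keV", {
  phan <- build_phantom(phantom_spec("Body", spacing = c(2, 2, 2.5), z_mm = 10))
  sub <- crop_phantom(phan, c(45, 0), c(40, 40))
  acq <- default_acquisition("Body", base_seed = 13L)
  acq$energies <- c(40, 44, 47, 74, 89)
  gt <- ground_truth_maps(sub, energies = acq$energies)
  st <- simulate_acquisition(sub, acq, 1, gt = gt)
  noise <- function(e) stack_get(st, e)$data -
    rel_atten_to_hu(gt$mu_rel[[format(e, trim = TRUE)]]$data)
  expect_gt(cor(as.numeric(noise(44)), as.numeric(noise(47))), 0.9)
  expect_gt(sd(noise(40)), sd(noise(74)))
  # native channels reproduce their reference SDs (in HU)
  expect_equal(sd(noise(89)) / 1000, 0.032, tolerance = 0.05)
})

test_that("dose scaling of noise follows the inverse square root", {
  phan <- build_phantom(phantom_spec("Body", spacing = c(2, 2, 2.5), z_mm = 10))
  sub <- crop_phantom(phan, c(45, 0), c(40, 40))
  gt <- ground_truth_maps(sub, energies = 74)
  sds <- vapply(c(5, 15), function(d) {
    acq <- default_acquisition("Body", ctdi_mgy = d, base_seed = 17L)
    acq$energies <- 74
    st <- simulate_acquisition(sub, acq, 1, gt = gt)
    sd(stack_get(st, 74)$data - rel_atten_to_hu(gt$mu_rel[["74"]]$data))
  }, 0)
  expect_equal(sds[2], sds[1] / sqrt(3), tolerance = 0.05)
})

test_that("the noise-reduction surrogate smooths without shifting means", {
  expect_error(apply_noise_reduction(image_volume(array(0, c(2, 2, 2)),
                                                  c(1, 1, 1)), 9), "unknown")
  set.seed(4)
  v <- image_volume(array(rnorm(40 * 40 * 8), c(40, 40, 8)), c(1, 1, 2.5))
  expect_identical(apply_noise_reduction(v, 0)$data, v$data)
  sm <- apply_noise_reduction(v, 2)
  expect_lt(sd(sm$data), sd(v$data))
  expect_lt(abs(mean(sm$data) - mean(v$data)), 1e-3)
  const <- image_volume(array(7, c(10, 10, 4)), c(1, 1, 1))
  expect_equal(apply_noise_reduction(const, 2)$data, const$data,
               tolerance = 1e-12)
})
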