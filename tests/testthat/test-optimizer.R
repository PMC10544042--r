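test_that("pair enumeration follows the k(k-1)/2 combinatorics", {
  expect_equal(nrow(enumerate_pairs(40, 42, 1)), 3)
  for (k in c(2, 5, 11)) {
    p <- enumerate_pairs(40, 40 + k - 1, 1)
    expect_equal(nrow(p), k * (k - 1) / 2)
    expect_true(all(p$E1 < p$E2))
    expect_false(any(duplicated(paste(p$E1, p$E2))))
  }
  expect_error(enumerate_pairs(60, 60, 1), "two points")
})

test_that("tissue classification rule and forward table are coherent", {
  tt <- tissue_forward_table(reference_tissues())
  expect_equal(length(tt$class), 73)
  expect_true(all(c("lung", "soft", "bone") %in% tt$class))
  lungs <- names(tt$class)[tt$class == "lung"]
  expect_true(all(vapply(reference_tissues()[lungs], `[[`, 0, "rho") < 0.6))
  expect_equal(dim(tt$mu_rel), c(73, 101))
})

test_that("theoretical pair RMSE is symmetric and matched by the fast path", {
  b <- test_basis()
  tt <- tissue_forward_table(reference_tissues())
  r1 <- pair_rmse_theoretical(c(50, 80), tt, "soft", b)
  r2 <- pair_rmse_theoretical(c(80, 50), tt, "soft", b)
  expect_equal(r1, r2)
  grid <- jh_basis_grid(b, c(50, 60, 80, 110))
  pairs <- data.frame(E1 = c(50, 50, 60), E2 = c(80, 110, 80))
  sel <- tt$class == "soft"
  fast <- score_pairs(pairs, tt$mu_rel[sel, as.character(c(50, 60, 80, 110))],
                      tt$spr_true[sel], grid)
  exact <- mapply(function(a, bb) pair_rmse_theoretical(c(a, bb), tt, "soft", b),
                  pairs$E1, pairs$E2)
  expect_equal(fast, exact, tolerance = 1e-5)
  expect_error(pair_rmse_theoretical(c(50, 80), tt, "nope", b), "no tissues")
})

test_that("measured RMSE reduces to the theoretical one without noise", {
  b <- test_basis()
  phan <- build_phantom(phantom_spec("Body", spacing = c(2, 2, 2.5), z_mm = 10))
  ctrs <- insert_centers(phan)
  acq <- default_acquisition("Body", sigma_ref = c(low = 0, high = 0))
  acq$energies <- c(44, 54, 74)
  mats <- phantom_inserts()
  soft <- names(mats)[classify_tissues(mats) == "soft"]
  rois <- list(); mus <- NULL
  stacks <- list()
  for (nm in soft) {
    sub <- crop_phantom(phan, ctrs[nm, ], c(36, 36))
    stacks[[nm]] <- simulate_acquisition(sub, acq)
    rois[[nm]] <- cylinder_roi_mask(sub$labels, c(0, 0, 0), 20, 8)
  }
  spr_true <- vapply(mats[soft], function(m)
    spr_bethe(true_red(m), exp(true_lnI(m))), 0)
  # assemble one per-insert stack list into combined ROI means
  mu_rmse <- local({
    v1 <- vapply(soft, function(nm)
      mean(stack_get(stacks[[nm]], 44)$data[rois[[nm]]]), 0)
    v2 <- vapply(soft, function(nm)
      mean(stack_get(stacks[[nm]], 54)$data[rois[[nm]]]), 0)
    mu1 <- hu_to_rel_atten(v1); mu2 <- hu_to_rel_atten(v2)
    inv <- invert_zeff(mu1, mu2, 44, 54, b)
    rd <- red_from_pair(mu1, mu2, 44, 54, inv$zeff, b)
    spr <- spr_bethe(pmax(rd$red, 0), exp(yang_lnI(inv$zeff)))
    100 * sqrt(mean(((spr - spr_true) / spr_true)^2))
  })
  # theoretical RMSE restricted to the same inserts
  tab <- tissue_forward_table(mats[soft], energies = c(44, 54))
  theo <- pair_rmse_theoretical(c(44, 54), tab, "soft", b)
  expect_lt(abs(mu_rmse - theo), 0.1)
})

test_that("noisy acquisitions surface stochasticity deterministically", {
  phan <- build_phantom(phantom_spec("Body", spacing = c(2, 2, 2.5), z_mm = 10))
  sub <- crop_phantom(phan, insert_centers(phan)["breast", ], c(36, 36))
  acq <- default_acquisition("Body", repeats = 2, base_seed = 77L)
  acq$energies <- c(44, 54)
  mask <- cylinder_roi_mask(sub$labels, c(0, 0, 0), 20, 8)
  s1 <- simulate_acquisition(sub, acq, 1)
  s1b <- simulate_acquisition(sub, acq, 1)
  s2 <- simulate_acquisition(sub, acq, 2)
  m <- function(s) mean(stack_get(s, 44)$data[mask])
  expect_identical(m(s1), m(s1b))
  expect_false(isTRUE(all.equal(m(s1), m(s2))))
})

test_that("per-class selection ranks, excludes and accounts correctly", {
  theo <- data.frame(E1 = c(50, 60, 70), E2 = c(80, 90, 100),
                     class = "soft", rmse = c(0.5, 1.0, 3.0))
  measured <- do.call(rbind, lapply(1:4, function(r)
    data.frame(phantom = rep(c("Body", "Head"), each = 3),
               repeat_id = r, E1 = c(50, 60, 70), E2 = c(80, 90, 100),
               class = "soft",
               rmse = c(0.5, 1.0, 3.0) + 0.01 * r + c(0, 0, 0.1))))
  sel <- select_optimal(theo, measured)
  expect_equal(sel$assignment$soft, c(50, 80))
  s <- sel$summary
  expect_equal(nrow(s), 2)           # the 3% pair is excluded
  expect_equal(sum(s$times_first), 4)  # one first place per repeat
  expect_true(all(sort(s$rank) == 1:2))
  # exclusion monotonicity: tightening the threshold only removes pairs
  sel_tight <- select_optimal(theo, measured, exclude_above = 0.7)
  keys <- function(x) paste(x$summary$E1, x$summary$E2)
  expect_true(all(keys(sel_tight) %in% keys(sel)))
  expect_error(select_optimal(theo, measured, exclude_above = 0.1), "excluded")
})

test_that("the EAN normality screen rejects collapsed distributions", {
  set.seed(21)
  expect_true(ean_normality_screen(rnorm(2000)))
  spikes <- sample(c(4, 54), 2000, replace = TRUE)   # bound-pinned spikes
  expect_false(ean_normality_screen(spikes))
  # screen plugs into selection as an additional exclusion condition
  theo <- data.frame(E1 = c(50, 60), E2 = c(80, 90), class = "soft",
                     rmse = c(0.5, 0.6))
  measured <- data.frame(phantom = "Body", repeat_id = 1,
                         E1 = c(50, 60), E2 = c(80, 90), class = "soft",
                         rmse = c(0.5, 0.6))
  ok <- c("50/80" = FALSE, "60/90" = TRUE)
  sel <- select_optimal(theo, measured, normality_ok = ok)
  expect_equal(sel$assignment$soft, c(60, 90))
})
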