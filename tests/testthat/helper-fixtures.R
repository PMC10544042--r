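# shared fixtures, built once per test run
.fix <- new.env()

test_basis <- function() {
  if (is.null(.fix$basis)) .fix$basis <- build_jh_basis()
  .fix$basis
}

water_mat <- function() material("water", 1.0, c(H = 0.1119, O = 0.8881))

# noise-free native CT numbers of the packaged inserts
insert_native_hu <- function() {
  if (is.null(.fix$native_hu)) {
    nat <- native_surrogate_energies()
    ins <- phantom_inserts()
    .fix$native_hu <- list(
      materials = ins,
      ct_low = vapply(ins, function(m)
        rel_atten_to_hu(linear_attenuation_rel_water(m, nat[["low"]])), 0),
      ct_high = vapply(ins, function(m)
        rel_atten_to_hu(linear_attenuation_rel_water(m, nat[["high"]])), 0))
  }
  .fix$native_hu
}

# raw packaged element table, read directly from the JSON (for oracles)
raw_elements <- function() {
  if (is.null(.fix$raw)) {
    path <- system.file("extdata", "elements_synthetic.json", package = "dectspr")
    .fix$raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .fix$raw
}

# forward-generate native CT numbers exactly consistent with the EAN
# ratio model and the weighted-difference RED model at given parameters
ls_forward <- function(materials, A, B, C, m, alpha, a, b) {
  z <- vapply(materials, true_ean, 0, exponent = m)^(m - 1)
  r <- (1 + A * z) / (B + C * z)
  red <- vapply(materials, true_red, 0)
  v <- ((red - b) / a + 1) / ((1 + alpha) - alpha * r)  # CT_high/1000 + 1
  u <- r * v
  list(ct_low = 1000 * (u - 1), ct_high = 1000 * (v - 1))
}

# forward-generate native CT numbers exactly consistent with both
# superposition equations at given alpha factors
direct_forward <- function(materials, alpha_red, alpha_ean) {
  red <- vapply(materials, true_red, 0)
  ean <- vapply(materials, true_ean, 0, exponent = 3.1)
  ean_w <- true_ean(material("water", 1, c(H = 0.1119, O = 0.8881)), 3.1)
  t(vapply(seq_along(materials), function(i) {
    # alpha_red ctl + (1 - alpha_red) cth = (red - 1) * 1000
    # (aE/1000) ctl + ((eanw^3.1 - aE)/1000) cth = ean^3.1 red - eanw^3.1
    Amat <- rbind(c(alpha_red, 1 - alpha_red),
                  c(alpha_ean / 1000, (ean_w^3.1 - alpha_ean) / 1000))
    rhs <- c((red[i] - 1) * 1000, ean[i]^3.1 * red[i] - ean_w^3.1)
    solve(Amat, rhs)
  }, numeric(2)))
}
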