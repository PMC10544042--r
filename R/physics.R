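# Ground-truth photon and proton physics shared by every mapping method.

.N_A <- 6.02214076e23

# log-log cubic interpolants of the elemental partial coefficients, cached
.element_interp <- function(symbol, partial = c("pe", "coh", "inc")) {
  partial <- match.arg(partial)
  key <- paste0("interp_", symbol, "_", partial)
  f <- .dect_cache[[key]]
  if (!is.null(f)) return(f)
  tab <- dect_elements()
  el <- tab$elements[[symbol]]
  if (is.null(el)) stop("unknown element symbol: ", symbol)
  f <- splinefun(log(tab$energy_kev), log(el[[partial]]), method = "fmm")
  .dect_cache[[key]] <- f
  f
}

.check_energy <- function(energy) {
  grid <- dect_elements()$energy_kev
  if (any(energy < grid[1] | energy > grid[length(grid)]))
    stop("energy outside the tabulated grid [", grid[1], ", ",
         grid[length(grid)], "] keV")
  invisible(energy)
}

#' Mass attenuation coefficient of a material
#'
#' Mixture rule over the packaged elemental tables,
#' \eqn{(\mu/\rho)(E) = \sum_i w_i (\mu/\rho)_i(E)}, with per-element values
#' log-log cubic interpolated in energy.
#'
#' @param mat a [material()].
#' @param energy photon energy in keV (vectorized); must lie inside the
#'   tabulated 30--150 keV grid.
#' @param partial one of `"total"`, `"pe"`, `"coh"`, `"inc"`.
#' @return mass attenuation coefficient(s) in cm^2/g.
#' @export
mass_attenuation <- function(mat, energy, partial = "total") {
  stopifnot(inherits(mat, "dect_material"))
  .check_energy(energy)
  parts <- if (identical(partial, "total")) c("pe", "coh", "inc") else partial
  out <- numeric(length(energy))
  for (sym in names(mat$w)) {
    for (p in parts)
      out <- out + mat$w[[sym]] * exp(.element_interp(sym, p)(log(energy)))
  }
  out
}

#' Linear attenuation relative to water
#'
#' \eqn{\mu/\mu_{H2O}} at the given energy:
#' \eqn{\rho (\mu/\rho) / (\rho_w (\mu/\rho)_w)} with \eqn{\rho_w} = 1 g/cm^3.
#'
#' @inheritParams mass_attenuation
#' @return dimensionless relative linear attenuation (vectorized in energy).
#' @export
linear_attenuation_rel_water <- function(mat, energy) {
  w <- .water_material()
  mat$rho * mass_attenuation(mat, energy) /
    (1.0 * mass_attenuation(w, energy))
}

.water_material <- function() {
  if (is.null(.dect_cache$water))
    .dect_cache$water <- material("water", 1.0, c(H = 0.11190, O = 0.88810))
  .dect_cache$water
}

.electron_fractions <- function(mat) {
  tab <- dect_elements()$elements
  za <- vapply(names(mat$w), function(s) tab[[s]]$Z / tab[[s]]$A, 0)
  lam <- mat$w * za
  lam / sum(lam)
}

.electrons_per_gram <- function(mat) {
  tab <- dect_elements()$elements
  za <- vapply(names(mat$w), function(s) tab[[s]]$Z / tab[[s]]$A, 0)
  .N_A * sum(mat$w * za)
}

#' Ground-truth relative electron density
#'
#' Electron density relative to water at 1 g/cm^3:
#' \eqn{\rho \sum_i w_i Z_i/A_i} over the same expression for water.
#'
#' @param mat a [material()].
#' @return dimensionless RED.
#' @export
true_red <- function(mat) {
  stopifnot(inherits(mat, "dect_material"))
  mat$rho * .electrons_per_gram(mat) / (1.0 * .electrons_per_gram(.water_material()))
}

#' Ground-truth mean excitation energy (Bragg additivity)
#'
#' \eqn{\ln I = \sum_i \lambda_i \ln I_i} with \eqn{\lambda_i} the electron
#' fractions \eqn{w_i Z_i/A_i / \sum_j w_j Z_j/A_j}.
#'
#' @param mat a [material()].
#' @return `ln(I)` with I in eV.
#' @export
true_lnI <- function(mat) {
  stopifnot(inherits(mat, "dect_material"))
  tab <- dect_elements()$elements
  lam <- .electron_fractions(mat)
  lnI <- vapply(names(lam), function(s) {
    iv <- tab[[s]]$I_ev
    if (is.null(iv) || !is.finite(iv)) stop("element ", s, " lacks an I-value")
    log(iv)
  }, 0)
  sum(lam * lnI)
}

#' Ground-truth effective atomic number (power-law mean)
#'
#' The exponent-n power-law electron-fraction mean
#' \eqn{Z_{eff} = (\sum_i \lambda_i Z_i^n)^{1/n}}. The default exponent 3.1
#' is the convention used by the alpha-blending superposition method.
#'
#' @param mat a [material()].
#' @param exponent power-law exponent (default 3.1).
#' @return dimensionless EAN.
#' @export
true_ean <- function(mat, exponent = 3.1) {
  stopifnot(inherits(mat, "dect_material"))
  tab <- dect_elements()$elements
  lam <- .electron_fractions(mat)
  z <- vapply(names(lam), function(s) tab[[s]]$Z, 0)
  sum(lam * z^exponent)^(1 / exponent)
}

#' Proton kinematics constants for the Bethe stopping-power ratio
#'
#' @param energy_mev proton kinetic energy in MeV (default 100).
#' @param i_water_ev water mean excitation energy in eV (default 78.73).
#' @return list with `beta2` (from relativistic kinematics, proton rest
#'   energy 938.272 MeV), `two_me_c2_ev` and `i_water_ev`.
#' @export
bethe_constants <- function(energy_mev = 100, i_water_ev = 78.73) {
  stopifnot(energy_mev > 0, i_water_ev > 0)
  m_p <- 938.272       # MeV
  gamma <- 1 + energy_mev / m_p
  beta2 <- 1 - 1 / gamma^2
  list(energy_mev = energy_mev, proton_rest_mev = m_p, beta2 = beta2,
       two_me_c2_ev = 2 * 0.51099895e6, i_water_ev = i_water_ev)
}

#' Stopping-power ratio from RED and I-value (Bethe)
#'
#' \deqn{SPR = \rho_e \frac{\ln(2 m_e c^2 \beta^2 / ((1-\beta^2) I)) - \beta^2}
#'                    {\ln(2 m_e c^2 \beta^2 / ((1-\beta^2) I_w)) - \beta^2}}
#'
#' @param red relative electron density (vectorized).
#' @param i_ev mean excitation energy in eV (vectorized or scalar).
#' @param constants from [bethe_constants()].
#' @return dimensionless SPR.
#' @export
spr_bethe <- function(red, i_ev, constants = bethe_constants()) {
  stopifnot(all(red >= 0, na.rm = TRUE), all(i_ev > 0, na.rm = TRUE))
  arg <- constants$two_me_c2_ev * constants$beta2 / (1 - constants$beta2)
  num <- log(arg / i_ev) - constants$beta2
  den <- log(arg / constants$i_water_ev) - constants$beta2
  if (any(num <= 0, na.rm = TRUE))
    stop("I-value too large: Bethe bracket is non-positive")
  red * num / den
}

#' Yang parametrization constants for ln(I) from EAN
#'
#' @return list with slopes/intercepts of the two linear branches and the
#'   branch boundary (EAN 8.5, assigned to the upper branch).
#' @export
yang_constants <- function() {
  list(a1 = 0.120, b1 = 3.407, a2 = 0.081, b2 = 3.514, z_break = 8.5)
}

#' ln(I) from effective atomic number (two-branch linear parametrization)
#'
#' `a1*zeff + b1` below the branch point, `a2*zeff + b2` at or above it.
#' The discontinuity at the branch point is preserved as printed.
#'
#' @param zeff effective atomic number (vectorized, > 0).
#' @param constants from [yang_constants()].
#' @return `ln(I)` with I in eV.
#' @export
yang_lnI <- function(zeff, constants = yang_constants()) {
  stopifnot(all(zeff > 0, na.rm = TRUE))
  ifelse(zeff < constants$z_break,
         constants$a1 * zeff + constants$b1,
         constants$a2 * zeff + constants$b2)
}

#' CT number to linear attenuation relative to water
#'
#' `(CT# + 1000) / 1000`. Values below -1000 HU are clamped to 0 with a
#' warning (relative attenuation cannot be negative).
#'
#' @param ct_number CT number(s) in HU.
#' @return dimensionless relative attenuation.
#' @export
hu_to_rel_atten <- function(ct_number) {
  if (any(ct_number < -1000, na.rm = TRUE)) {
    warning("CT numbers below -1000 HU clamped to zero relative attenuation")
    ct_number <- pmax(ct_number, -1000)
  }
  (ct_number + 1000) / 1000
}

#' Linear attenuation relative to water to CT number
#' @param mu_rel dimensionless relative attenuation.
#' @return CT number(s) in HU.
#' @export
rel_atten_to_hu <- function(mu_rel) 1000 * (mu_rel - 1)
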