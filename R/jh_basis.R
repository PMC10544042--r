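# Jackson-Hawkes two-function parametrization of the per-electron
# attenuation cross section: e(Z, E) = Z^4 F(Z, E) + G(Z, E), where the
# Z^4 F term carries photoelectric absorption and G carries coherent plus
# incoherent scattering.

#' Build the Jackson-Hawkes F/G basis from the packaged elemental tables
#'
#' For every tabulated element with Z in the requested range the
#' per-electron partial cross sections are computed as
#' \eqn{e = (\mu/\rho) A / (Z N_A)} and split into
#' \eqn{F = e_{pe} / Z^4} and \eqn{G = e_{coh} + e_{inc}}
#' (cm^2/electron). Evaluation interpolates log-log cubic in energy and
#' monotone piecewise-cubic in Z.
#'
#' @param z_range atomic-number domain, default `c(4, 54)`.
#' @param energy_grid energies (keV) at which to tabulate; defaults to the
#'   packaged grid.
#' @return An object of class `jh_basis` with matrices `F` and `G`
#'   (rows = elements, columns = energies), `zs` and `energies`.
#' @export
build_jh_basis <- function(z_range = c(4, 54), energy_grid = NULL) {
  tab <- dect_elements()
  if (is.null(energy_grid)) energy_grid <- tab$energy_kev
  .check_energy(energy_grid)
  els <- Filter(function(e) e$Z >= z_range[1] && e$Z <= z_range[2],
                tab$elements)
  if (length(els) < 4)
    stop("not enough tabulated elements in Z range [",
         z_range[1], ", ", z_range[2], "]")
  zs <- vapply(els, `[[`, 0, "Z")
  ord <- order(zs)
  els <- els[ord]; zs <- zs[ord]
  nE <- length(energy_grid)
  Fm <- matrix(NA_real_, length(zs), nE)
  Gm <- matrix(NA_real_, length(zs), nE)
  for (i in seq_along(els)) {
    e <- els[[i]]
    per_e <- e$A / (e$Z * .N_A)   # g/electron
    sym <- e$symbol
    pe  <- exp(.element_interp(sym, "pe")(log(energy_grid))) * per_e
    sc  <- exp(.element_interp(sym, "coh")(log(energy_grid))) * per_e +
           exp(.element_interp(sym, "inc")(log(energy_grid))) * per_e
    Fm[i, ] <- pe / e$Z^4
    Gm[i, ] <- sc
  }
  stopifnot(all(Fm > 0), all(Gm > 0))
  structure(list(F = Fm, G = Gm, zs = zs, energies = energy_grid,
                 interpolation = "log-log cubic in E, monotone cubic in Z",
                 cache = new.env(parent = emptyenv())),
            class = "jh_basis")
}

#' @export
print.jh_basis <- function(x, ...) {
  cat(sprintf("<jh_basis  Z in [%g, %g] (%d elements), E in [%g, %g] keV>\n",
              min(x$zs), max(x$zs), length(x$zs),
              min(x$energies), max(x$energies)))
  invisible(x)
}

# Cached F/G interpolants in Z at a fixed energy. F and G are interpolated
# in log space; both are monotone in Z so monoH.FC keeps them positive and
# shape-preserving.
.basis_slice <- function(basis, energy) {
  stopifnot(inherits(basis, "jh_basis"), length(energy) == 1L)
  key <- format(energy, digits = 12)
  sl <- basis$cache[[key]]
  if (!is.null(sl)) return(sl)
  if (energy < min(basis$energies) || energy > max(basis$energies))
    stop("energy ", energy, " keV outside basis domain")
  le <- log(basis$energies)
  fE <- apply(basis$F, 1, function(row) exp(splinefun(le, log(row),
                                                     method = "fmm")(log(energy))))
  gE <- apply(basis$G, 1, function(row) exp(splinefun(le, log(row),
                                                     method = "fmm")(log(energy))))
  sl <- list(Fz = splinefun(basis$zs, log(fE), method = "monoH.FC"),
             Gz = splinefun(basis$zs, log(gE), method = "monoH.FC"))
  basis$cache[[key]] <- sl
  sl
}

#' Evaluate the Jackson-Hawkes basis functions
#'
#' @param basis a [build_jh_basis()] object.
#' @param zeff effective atomic number(s) within the basis Z domain
#'   (clamped to it).
#' @param energy a single energy in keV.
#' @return list with vectors `F` and `G` (cm^2/electron).
#' @export
jh_fg <- function(basis, zeff, energy) {
  sl <- .basis_slice(basis, energy)
  z <- pmin(pmax(zeff, min(basis$zs)), max(basis$zs))
  list(F = exp(sl$Fz(z)), G = exp(sl$Gz(z)))
}

#' Forward Jackson-Hawkes attenuation relative to water
#'
#' Synthesizes \eqn{\mu/\mu_w(E)} for a hypothetical material with the given
#' effective atomic number and relative electron density:
#' \eqn{\mu = \rho_e n_w (Z_{eff}^4 F + G)} normalized by water's linear
#' attenuation. Used to generate exact-model voxels for round-trip tests.
#'
#' @inheritParams jh_fg
#' @param red relative electron density.
#' @return dimensionless \eqn{\mu/\mu_w} at `energy`.
#' @export
jh_forward_rel_water <- function(basis, zeff, red, energy) {
  fg <- jh_fg(basis, zeff, energy)
  n_w <- .electrons_per_gram(.water_material())   # electrons/cm^3 for rho_w = 1
  mu_w <- mass_attenuation(.water_material(), energy)
  red * n_w * (zeff^4 * fg$F + fg$G) / mu_w
}
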