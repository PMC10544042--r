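# Fast bulk scorer for the pair optimizer: the Jackson-Hawkes basis is
# pre-evaluated on a fine Zeff grid for every candidate energy, so the
# per-voxel bisection can run vectorized across thousands of
# (pair, material) combinations with mixed energies. Linear interpolation
# on a 0.005-step Zeff grid; agreement with the spline path is well below
# the ranking resolution.

#' Pre-evaluate the basis on a fine Zeff grid for a set of energies
#'
#' @param basis a [build_jh_basis()] object.
#' @param energies energies (keV) that will be scored.
#' @param dz Zeff grid step (default 0.005).
#' @return object of class `jh_basis_grid`.
#' @export
jh_basis_grid <- function(basis, energies = 40:140, dz = 0.005) {
  zg <- seq(min(basis$zs), max(basis$zs), by = dz)
  nE <- length(energies)
  Fm <- matrix(NA_real_, nE, length(zg))
  Gm <- matrix(NA_real_, nE, length(zg))
  muw <- numeric(nE)
  for (i in seq_len(nE)) {
    fg <- jh_fg(basis, zg, energies[i])
    Fm[i, ] <- fg$F
    Gm[i, ] <- fg$G
    muw[i] <- mass_attenuation(.water_material(), energies[i])
  }
  structure(list(z0 = zg[1], dz = dz, nz = length(zg), zmax = zg[length(zg)],
                 Fm = Fm, Gm = Gm, energies = energies, mu_w = muw),
            class = "jh_basis_grid")
}

.grid_fg <- function(grid, eidx, z) {
  pos <- (z - grid$z0) / grid$dz
  i0 <- pmin(pmax(floor(pos), 0), grid$nz - 2)
  fr <- pos - i0
  j1 <- cbind(eidx, i0 + 1L)
  j2 <- cbind(eidx, i0 + 2L)
  list(F = grid$Fm[j1] * (1 - fr) + grid$Fm[j2] * fr,
       G = grid$Gm[j1] * (1 - fr) + grid$Gm[j2] * fr)
}

# vectorized bisection on the gridded basis; mu are relative attenuation
.invert_zeff_grid <- function(mu1, mu2, e1_idx, e2_idx, grid, n_iter = 45) {
  m1 <- mu1 * grid$mu_w[e1_idx]
  m2 <- mu2 * grid$mu_w[e2_idx]
  resid <- function(z) {
    fg1 <- .grid_fg(grid, e1_idx, z)
    fg2 <- .grid_fg(grid, e2_idx, z)
    m2 * (z^4 * fg1$F + fg1$G) - m1 * (z^4 * fg2$F + fg2$G)
  }
  lo <- rep(grid$z0, length(m1))
  hi <- rep(grid$zmax, length(m1))
  rl <- resid(lo)
  rh <- resid(hi)
  bracket <- sign(rl) != sign(rh)
  l <- lo; h <- hi
  for (it in seq_len(n_iter)) {
    mid <- 0.5 * (l + h)
    rm <- resid(mid)
    left <- sign(rm) == sign(rl)
    l <- ifelse(bracket & left, mid, l)
    rl <- ifelse(bracket & left, rm, rl)
    h <- ifelse(bracket & !left, mid, h)
  }
  z <- 0.5 * (l + h)
  # non-bracketed: pin to the boundary with the smaller |residual|
  nb <- !bracket
  if (any(nb))
    z[nb] <- ifelse(abs(rl[nb]) < abs(rh[nb]), grid$z0, grid$zmax)
  list(zeff = z, flagged = nb)
}

.spr_chain_grid <- function(mu1, mu2, e1_idx, e2_idx, grid, constants) {
  inv <- .invert_zeff_grid(mu1, mu2, e1_idx, e2_idx, grid)
  z <- inv$zeff
  fg1 <- .grid_fg(grid, e1_idx, z)
  fg2 <- .grid_fg(grid, e2_idx, z)
  m1 <- mu1 * grid$mu_w[e1_idx]
  m2 <- mu2 * grid$mu_w[e2_idx]
  den <- (fg2$F * fg1$G - fg1$F * fg2$G) * .electrons_per_gram(.water_material())
  red <- (m1 * fg2$F - m2 * fg1$F) / den
  spr_bethe(pmax(red, 0), exp(yang_lnI(pmax(z, 1e-6))), constants)
}

#' Score many VMI pairs at once against reference values
#'
#' Runs the full VMI inversion chain for every (pair, material)
#' combination in one vectorized pass and returns the percent SPR RMSE per
#' pair. Used both for the theoretical sweep (materials = reference
#' tissues, noise-free attenuation) and the measured sweep (materials =
#' insert ROI means from a noisy acquisition).
#'
#' @param pairs data.frame with `E1`, `E2` (from [enumerate_pairs()]).
#' @param mu_mat matrix of relative attenuation, rows = materials,
#'   columns = energies in the order of `grid$energies`.
#' @param spr_true ground-truth SPR per material (row order of `mu_mat`).
#' @param grid a [jh_basis_grid()] covering all pair energies.
#' @param constants from [bethe_constants()].
#' @return numeric vector of percent RMSE, one per pair.
#' @export
score_pairs <- function(pairs, mu_mat, spr_true, grid,
                        constants = bethe_constants()) {
  np <- nrow(pairs)
  ni <- nrow(mu_mat)
  stopifnot(length(spr_true) == ni)
  e1_idx <- match(pairs$E1, grid$energies)
  e2_idx <- match(pairs$E2, grid$energies)
  if (anyNA(e1_idx) || anyNA(e2_idx))
    stop("pair energies missing from the basis grid")
  ii <- rep(seq_len(ni), times = np)
  pp <- rep(seq_len(np), each = ni)
  mu1 <- mu_mat[cbind(ii, e1_idx[pp])]
  mu2 <- mu_mat[cbind(ii, e2_idx[pp])]
  spr <- .spr_chain_grid(pmax(mu1, 1e-6), pmax(mu2, 1e-6),
                         e1_idx[pp], e2_idx[pp], grid, constants)
  rel2 <- ((spr - spr_true[ii]) / spr_true[ii])^2
  100 * sqrt(colMeans(matrix(rel2, ni, np)))
}
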