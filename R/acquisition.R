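# Repeated noisy DECT acquisitions of a phantom. Channel means are exact
# ground-truth attenuation. Noise is a rank-2 Gaussian model carried by
# the two native source channels (a dual-source scanner's low and high
# acquisitions are independent measurements); every synthesized VMI
# channel is their exact linear recombination via the two-material
# (water / cortical-bone) decomposition, so VMIs at different energies
# carry strongly correlated noise and low-keV VMIs are noisier. Noise
# magnitude scales as 1/sqrt(dose).

#' Acquisition specification
#'
#' @param ctdi_mgy dose level (CTDIvol, mGy, > 0).
#' @param energies channel energies in keV (VMIs and/or the native-kV
#'   surrogates, see [native_surrogate_energies()]).
#' @param nr_level noise-reduction level (0 = off, 1, 2).
#' @param repeats number of repeated acquisitions (default 30).
#' @param base_seed integer seed; repeat `k` uses `base_seed + k`.
#' @param dose_ref_mgy reference dose at which `sigma_ref` applies.
#' @param sigma_ref length-2 noise SDs (relative-attenuation units) of the
#'   native low and high source channels at the reference dose.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(ctdi_mgy, energies, nr_level = 0, repeats = 30,
                             base_seed = 1L, dose_ref_mgy = 10,
                             sigma_ref = c(low = 0.033, high = 0.032)) {
  stopifnot(ctdi_mgy > 0, repeats >= 1, dose_ref_mgy > 0,
            length(sigma_ref) == 2, all(sigma_ref >= 0))
  structure(list(ctdi_mgy = ctdi_mgy, energies = sort(unique(energies)),
                 nr_level = nr_level, repeats = repeats,
                 base_seed = as.integer(base_seed),
                 dose_ref_mgy = dose_ref_mgy, sigma_ref = sigma_ref),
            class = "acquisition_spec")
}

#' Default acquisition for a phantom size
#'
#' Body phantom: doses 5/10/15 mGy with reference 10 mGy; Head phantom:
#' 30/40/50 mGy with reference 40 mGy and half the Body reference noise
#' (the smaller object attenuates less).
#'
#' @param phantom_name `"Body"` or `"Head"`.
#' @param ctdi_mgy dose level; defaults to the phantom's medium dose.
#' @param sigma_ref override of the phantom's reference noise SDs.
#' @param ... passed to [acquisition_spec()].
#' @return an [acquisition_spec()].
#' @export
default_acquisition <- function(phantom_name = c("Body", "Head"),
                                ctdi_mgy = NULL, sigma_ref = NULL, ...) {
  phantom_name <- match.arg(phantom_name)
  if (phantom_name == "Body") {
    if (is.null(ctdi_mgy)) ctdi_mgy <- 10
    if (is.null(sigma_ref)) sigma_ref <- c(low = 0.033, high = 0.032)
    acquisition_spec(ctdi_mgy, energies = c(40, 41, 50, 56, 74, 84, 89),
                     dose_ref_mgy = 10, sigma_ref = sigma_ref, ...)
  } else {
    if (is.null(ctdi_mgy)) ctdi_mgy <- 40
    if (is.null(sigma_ref)) sigma_ref <- c(low = 0.0165, high = 0.016)
    acquisition_spec(ctdi_mgy, energies = c(40, 41, 50, 56, 74, 84, 89),
                     dose_ref_mgy = 40, sigma_ref = sigma_ref, ...)
  }
}

#' Effective energies of the native-kV surrogate channels
#'
#' The simulator has no tube spectra; native low/high kV images are
#' represented by VMIs at nominal effective energies (56 keV for the low
#' tube, 89 keV for the Sn-filtered high tube).
#'
#' @return named numeric vector `c(low = 56, high = 89)`.
#' @export
native_surrogate_energies <- function() c(low = 56, high = 89)

# bone basis shape: relative attenuation of cortical bone, cached
.bone_basis_rel <- function(energy) {
  key <- paste0("bone_basis_", format(energy, digits = 12))
  v <- .dect_cache[[key]]
  if (is.null(v)) {
    v <- linear_attenuation_rel_water(reference_tissues()[["cortical_bone"]],
                                      energy)
    .dect_cache[[key]] <- v
  }
  v
}

#' Simulate one repeated acquisition
#'
#' Produces one HU volume per requested channel energy. Each voxel's mean
#' is the exact ground-truth relative attenuation of its material. Noise
#' in the two native source channels is iid zero-mean Gaussian with SDs
#' `sigma_ref * sqrt(dose_ref / dose)` and independent between the two; a
#' synthesized channel at energy E receives the linear recombination
#' `g_l(E) eps_low + g_h(E) eps_high` determined by the water/bone
#' two-material decomposition (so the native channels reproduce their own
#' noise exactly and nearby VMIs are strongly correlated). Deterministic
#' given `base_seed + repeat_index`; the noise fields do not depend on the
#' channel list.
#'
#' @param phantom a [build_phantom()] result.
#' @param acq an [acquisition_spec()].
#' @param repeat_index which repeat (1-based).
#' @param gt optional precomputed [ground_truth_maps()] for this phantom
#'   (must include all channel energies); avoids recomputation in loops.
#' @return a [vmi_stack()] of HU channel volumes.
#' @export
simulate_acquisition <- function(phantom, acq, repeat_index = 1L, gt = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(acq, "acquisition_spec"))
  .check_energy(acq$energies)
  if (is.null(gt)) gt <- ground_truth_maps(phantom, energies = acq$energies)
  if (!all(format(acq$energies, trim = TRUE) %in% names(gt$mu_rel)))
    stop("precomputed ground truth lacks some channel energies")
  dims <- dim(phantom$labels$data)
  scale <- sqrt(acq$dose_ref_mgy / acq$ctdi_mgy)
  seed <- (acq$base_seed + as.integer(repeat_index)) %% .Machine$integer.max
  set.seed(seed)
  eps_l <- array(rnorm(prod(dims), 0, acq$sigma_ref[[1]] * scale), dims)
  eps_h <- array(rnorm(prod(dims), 0, acq$sigma_ref[[2]] * scale), dims)
  nat <- native_surrogate_energies()
  b_l <- .bone_basis_rel(nat[["low"]])
  b_h <- .bone_basis_rel(nat[["high"]])
  vols <- lapply(acq$energies, function(e) {
    b_e <- .bone_basis_rel(e)
    g_l <- (b_h - b_e) / (b_h - b_l)
    g_h <- (b_e - b_l) / (b_h - b_l)
    mu <- gt$mu_rel[[format(e, trim = TRUE)]]$data +
      g_l * eps_l + g_h * eps_h
    v <- image_volume(rel_atten_to_hu(mu), phantom$labels$spacing,
                      energy_kev = e, units = "HU")
    if (acq$nr_level > 0) v <- apply_noise_reduction(v, acq$nr_level)
    v
  })
  vmi_stack(vols)
}

# kernel weights for one noise-reduction level (SD in voxels)
.nr_sigma_vox <- function(level) {
  sig <- c("0" = 0, "1" = 0.75, "2" = 1.5)[as.character(level)]
  if (is.na(sig)) stop("unknown noise-reduction level: ", level)
  unname(sig)
}

.gauss_smooth_dim <- function(arr, sd_vox, along) {
  if (sd_vox <= 0) return(arr)
  r <- ceiling(3 * sd_vox)
  off <- -r:r
  w <- exp(-off^2 / (2 * sd_vox^2))
  d <- dim(arr)
  out <- array(0, d)
  wsum <- array(0, d)
  n <- d[along]
  for (k in seq_along(off)) {
    src <- seq_len(n) + off[k]
    ok <- src >= 1 & src <= n
    dst_idx <- which(ok)
    src_idx <- src[ok]
    sel <- function(a, i) switch(along,
                                 a[i, , , drop = FALSE],
                                 a[, i, , drop = FALSE],
                                 a[, , i, drop = FALSE])
    if (!length(dst_idx)) next
    piece <- sel(arr, src_idx) * w[k]
    if (along == 1) {
      out[dst_idx, , ] <- out[dst_idx, , , drop = FALSE] + piece
      wsum[dst_idx, , ] <- wsum[dst_idx, , , drop = FALSE] + w[k]
    } else if (along == 2) {
      out[, dst_idx, ] <- out[, dst_idx, , drop = FALSE] + piece
      wsum[, dst_idx, ] <- wsum[, dst_idx, , drop = FALSE] + w[k]
    } else {
      out[, , dst_idx] <- out[, , dst_idx, drop = FALSE] + piece
      wsum[, , dst_idx] <- wsum[, , dst_idx, drop = FALSE] + w[k]
    }
  }
  out / wsum
}

#' Noise-reduction surrogate
#'
#' Stands in for the scanners' iterative/deep-learning reconstruction
#' filters: separable Gaussian spatial smoothing whose kernel width maps
#' from the level (0 = identity, 1 = 0.75 voxel SD, 2 = 1.5). Edge kernels
#' are renormalized, so constants (and large-ROI means) are preserved.
#'
#' @param volume an [image_volume()].
#' @param level noise-reduction level in `{0, 1, 2}`.
#' @return the smoothed [image_volume()].
#' @export
apply_noise_reduction <- function(volume, level) {
  sig <- .nr_sigma_vox(level)
  if (sig == 0) return(volume)
  a <- volume$data
  for (dd in 1:3) if (dim(a)[dd] > 1) a <- .gauss_smooth_dim(a, sig, dd)
  out <- volume
  out$data <- a
  out
}
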