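# Simplified proton range model: the treatment-planning dose engine is
# replaced by water-equivalent path length (WEPL) integration along
# parallel beam lines plus a Bragg-Kleeman range-energy power law for the
# distal-80% depth in water. Absolute ranges are a proxy; the quantity of
# interest is noise-induced range variation.

#' Beam specification for the range simulation
#'
#' @param energy_mev proton energy (default 105).
#' @param grid_mm dose-grid spacing (x, y, z), default 2 x 2 x 1 mm with
#'   the beam along +z.
#' @param alpha_bk,p_bk Bragg-Kleeman constants, range = alpha * E^p in cm
#'   (defaults 0.0022 and 1.77).
#' @param roi_diameter_mm diameter of the circular ROI the lines cross.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(energy_mev = 105, grid_mm = c(2, 2, 1),
                      alpha_bk = 0.0022, p_bk = 1.77, roi_diameter_mm = 20) {
  stopifnot(energy_mev > 0, all(grid_mm > 0), alpha_bk > 0, p_bk > 0)
  structure(list(energy_mev = energy_mev, grid_mm = grid_mm,
                 alpha_bk = alpha_bk, p_bk = p_bk,
                 roi_diameter_mm = roi_diameter_mm),
            class = "beam_spec")
}

#' Proton range in water (Bragg-Kleeman)
#'
#' \eqn{R = \alpha E^p} (cm, converted to mm), taken as the distal-80%
#' depth in water.
#'
#' @param energy_mev proton energy in MeV (vectorized).
#' @param beam a [beam_spec()] supplying the power-law constants.
#' @return range in mm.
#' @export
r80_water <- function(energy_mev = 105, beam = beam_spec()) {
  stopifnot(all(energy_mev > 0))
  10 * beam$alpha_bk * energy_mev^beam$p_bk
}

# the 81 lateral lattice points (beam lines) nearest the ROI center
.beam_lattice <- function(volume, beam, roi_center_mm = c(0, 0), n_lines = 81) {
  d <- dim(volume$data)
  x <- .grid_coords(d[1], volume$spacing[1])
  y <- .grid_coords(d[2], volume$spacing[2])
  gx <- seq(ceiling(min(x) / beam$grid_mm[1]), floor(max(x) / beam$grid_mm[1])) *
    beam$grid_mm[1]
  gy <- seq(ceiling(min(y) / beam$grid_mm[2]), floor(max(y) / beam$grid_mm[2])) *
    beam$grid_mm[2]
  pts <- expand.grid(x = gx, y = gy)
  pts$d2 <- (pts$x - roi_center_mm[1])^2 + (pts$y - roi_center_mm[2])^2
  pts <- pts[order(pts$d2, pts$x, pts$y), ]
  if (nrow(pts) < n_lines)
    stop("volume too small: only ", nrow(pts), " lattice lines available")
  pts[seq_len(n_lines), c("x", "y")]
}

#' Simulate distal-80% proton range along parallel beam lines
#'
#' The beam travels along +z. The SPR volume is sampled on the dose grid:
#' the 81 lateral lattice points (2 mm pitch) nearest the ROI center define
#' the lines; along each line SPR is linearly interpolated to the dose-grid
#' z step and integrated (trapezoid) into cumulative WEPL. The range is the
#' geometric depth from the entry face where cumulative WEPL reaches the
#' water distal-80% range, linearly interpolated. Lines whose WEPL never
#' reaches it are returned as `NA` (flagged).
#'
#' @param spr_volume an [image_volume()] of SPR values.
#' @param beam a [beam_spec()].
#' @param roi_center_mm lateral (x, y) ROI center in grid coordinates.
#' @param n_lines number of beam lines (default 81).
#' @return numeric vector of per-line ranges in mm (length `n_lines`).
#' @export
simulate_range <- function(spr_volume, beam = beam_spec(),
                           roi_center_mm = c(0, 0), n_lines = 81) {
  stopifnot(inherits(spr_volume, "image_volume"))
  d <- dim(spr_volume$data)
  if (d[3] < 2) stop("SPR volume needs at least 2 slices along the beam")
  target <- r80_water(beam$energy_mev, beam)
  lines <- .beam_lattice(spr_volume, beam, roi_center_mm, n_lines)
  x <- .grid_coords(d[1], spr_volume$spacing[1])
  y <- .grid_coords(d[2], spr_volume$spacing[2])
  # depth coordinate: 0 at the entry face of the first slice
  zc <- (seq_len(d[3]) - 0.5) * spr_volume$spacing[3]
  z_len <- d[3] * spr_volume$spacing[3]
  tz <- seq(0, z_len, by = beam$grid_mm[3])
  out <- numeric(nrow(lines))
  for (i in seq_len(nrow(lines))) {
    ix <- which.min(abs(x - lines$x[i]))
    iy <- which.min(abs(y - lines$y[i]))
    prof <- spr_volume$data[ix, iy, ]
    spr_t <- approx(zc, prof, xout = tz, rule = 2)$y
    dw <- diff(tz) * (spr_t[-1] + spr_t[-length(spr_t)]) / 2
    wepl <- c(0, cumsum(dw))
    if (max(wepl) < target) { out[i] <- NA_real_; next }
    k <- which(wepl >= target)[1]
    if (k == 1) { out[i] <- 0; next }
    f <- (target - wepl[k - 1]) / (wepl[k] - wepl[k - 1])
    out[i] <- tz[k - 1] + f * (tz[k] - tz[k - 1])
  }
  out
}

#' Per-repeat range statistics, aggregated over repeats
#'
#' For each repeat: mean range, relative SD and skewness over the beam
#' lines (flagged `NA` lines excluded, count reported); statistics are then
#' averaged over the repeats and CI87 = 1.5 x relative SD.
#'
#' @param ranges_per_repeat list of per-line range vectors, one per repeat.
#' @param insert label carried into the record.
#' @return a one-row record as in [roi_statistics()], plus `n_flagged`.
#' @export
range_statistics <- function(ranges_per_repeat, insert = NA_character_) {
  if (is.numeric(ranges_per_repeat))
    ranges_per_repeat <- list(ranges_per_repeat)
  stopifnot(length(ranges_per_repeat) >= 1)
  n_flagged <- sum(vapply(ranges_per_repeat, function(r) sum(is.na(r)), 0))
  recs <- lapply(ranges_per_repeat, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) stop("all lines flagged in a repeat")
    m <- mean(r)
    s <- if (length(r) > 1) sd(r) else 0
    data.frame(insert = insert, quantity = "range", mean = m,
               rel_sd_pct = 100 * s / m, ci87_pct = 150 * s / m,
               skewness = as.numeric(sample_skewness(r)),
               n_voxels = length(r), repeats = 1L, rel_flag = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- aggregate_repeats(recs)
  out$n_flagged <- n_flagged
  out
}
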