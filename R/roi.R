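# ROI noise statistics: cylindrical insert ROIs, per-repeat sample
# statistics, and aggregation over repeated acquisitions. The reported
# confidence interval convention is CI87 = +/- 1.5 standard deviations
# (~87% coverage under normality), expressed in % of the ROI mean.

#' Cylindrical ROI mask
#'
#' Voxels whose centers lie inside a z-aligned cylinder.
#'
#' @param volume an [image_volume()] (defines grid and spacing).
#' @param center_mm cylinder center (x, y, z) in grid coordinates
#'   (origin at the volume center).
#' @param diameter_mm,height_mm cylinder dimensions (d = 20, z = 30 by
#'   default, the insert ROI).
#' @return logical array of the volume's shape.
#' @export
cylinder_roi_mask <- function(volume, center_mm = c(0, 0, 0),
                              diameter_mm = 20, height_mm = 30) {
  stopifnot(inherits(volume, "image_volume"))
  if (diameter_mm <= 0 || height_mm <= 0)
    stop("ROI dimensions must be positive")
  d <- dim(volume$data)
  x <- .grid_coords(d[1], volume$spacing[1]) - center_mm[1]
  y <- .grid_coords(d[2], volume$spacing[2]) - center_mm[2]
  z <- .grid_coords(d[3], volume$spacing[3]) - center_mm[3]
  if (abs(center_mm[1]) + diameter_mm / 2 > d[1] * volume$spacing[1] / 2 ||
      abs(center_mm[2]) + diameter_mm / 2 > d[2] * volume$spacing[2] / 2 ||
      abs(center_mm[3]) + height_mm / 2 > d[3] * volume$spacing[3] / 2)
    stop("ROI extends outside the volume")
  in_xy <- outer(x^2, y^2, `+`) <= (diameter_mm / 2)^2
  in_z <- abs(z) <= height_mm / 2
  mask <- array(FALSE, d)
  for (k in which(in_z)) mask[, , k] <- in_xy
  if (!any(mask)) stop("empty ROI mask")
  mask
}

#' Adjusted Fisher-Pearson sample skewness
#' @param x numeric sample (n >= 3).
#' @return bias-corrected skewness; 0 (with attribute `degenerate`) for a
#'   constant sample.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(structure(0, degenerate = TRUE))
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' ROI sample statistics
#'
#' Sample mean, relative SD (% of mean), CI87 (= 1.5 x relative SD) and
#' adjusted Fisher-Pearson skewness over the masked voxels. If the mean is
#' near zero the relative quantities are flagged (`rel_flag`); the pipeline
#' therefore converts HU channels to relative attenuation first.
#'
#' @param volume an [image_volume()] or numeric array.
#' @param mask logical array (e.g. from [cylinder_roi_mask()]).
#' @param insert,quantity labels carried into the record.
#' @return a one-row `data.frame` (an ROI stats record) with columns
#'   `insert`, `quantity`, `mean`, `rel_sd_pct`, `ci87_pct`, `skewness`,
#'   `n_voxels`, `repeats`, `rel_flag`.
#' @export
roi_statistics <- function(volume, mask, insert = NA_character_,
                           quantity = NA_character_) {
  x <- if (inherits(volume, "image_volume")) volume$data else volume
  v <- x[mask]
  v <- v[is.finite(v)]
  if (!length(v)) stop("mask selects no finite voxels")
  m <- mean(v)
  s <- sd(v)
  rel_flag <- abs(m) < 1e-9
  rel_sd <- if (rel_flag) NA_real_ else 100 * s / abs(m)
  sk <- sample_skewness(v)
  data.frame(insert = insert, quantity = quantity, mean = m,
             rel_sd_pct = rel_sd, ci87_pct = 1.5 * rel_sd,
             skewness = as.numeric(sk), n_voxels = length(v),
             repeats = 1L, rel_flag = rel_flag,
             stringsAsFactors = FALSE)
}

#' Aggregate per-repeat ROI records
#'
#' Arithmetic mean of each statistic over the repeats (the convention used
#' for the repeated-acquisition tables). All records must describe the
#' same insert and quantity.
#'
#' @param records a `data.frame` of per-repeat records ([roi_statistics()]
#'   rows) or a list of them.
#' @return a one-row aggregated record.
#' @export
aggregate_repeats <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  stopifnot(nrow(records) >= 1)
  if (length(unique(records$quantity)) != 1L ||
      length(unique(records$insert)) != 1L)
    stop("cannot aggregate records of mixed insert/quantity")
  out <- records[1, , drop = FALSE]
  for (col in c("mean", "rel_sd_pct", "ci87_pct", "skewness"))
    out[[col]] <- mean(records[[col]])
  out$repeats <- nrow(records)
  out$rel_flag <- any(records$rel_flag)
  rownames(out) <- NULL
  out
}
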