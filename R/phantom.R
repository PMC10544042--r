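# Synthetic cylindrical multi-insert phantom (Head/Body) and its
# ground-truth maps. Voxels take the single material of their center
# (no partial-volume mixing).

#' Cylindrical phantom specification
#'
#' A water-equivalent cylinder in two sizes with tissue-surrogate insert
#' rods: eight on a ring plus one at the center, 30 mm diameter each,
#' running the full z extent. Default voxel spacing 1 x 1 x 2.5 mm.
#'
#' @param name `"Body"` (300 mm diameter, ring radius 100 mm) or `"Head"`
#'   (180 mm diameter, ring radius 55 mm).
#' @param insert_materials named list of [material()]s (default the nine
#'   packaged surrogates); at most 9 are placed.
#' @param spacing voxel spacing in mm.
#' @param z_mm phantom length along the cylinder axis.
#' @param insert_diameter_mm insert rod diameter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(name = c("Body", "Head"),
                         insert_materials = phantom_inserts(),
                         spacing = c(1, 1, 2.5), z_mm = 40,
                         insert_diameter_mm = 30) {
  name <- match.arg(name)
  geom <- switch(name,
                 Body = list(diameter = 300, ring = 100),
                 Head = list(diameter = 180, ring = 55))
  n <- length(insert_materials)
  if (n > 9) stop("at most 9 inserts fit the default layout")
  centers <- list()
  if (n == 1) centers[[1]] <- c(0, 0)
  else for (i in seq_len(n)) {
    if (i < n || n < 9) {
      ang <- 2 * pi * (i - 1) / max(n - (n == 9), 1)
      centers[[i]] <- geom$ring * c(cos(ang), sin(ang))
    } else centers[[i]] <- c(0, 0)
  }
  if (n == 9) {
    centers <- c(lapply(0:7, function(k)
      geom$ring * c(cos(2 * pi * k / 8), sin(2 * pi * k / 8))), list(c(0, 0)))
  }
  inserts <- lapply(seq_len(n), function(i)
    list(material = insert_materials[[i]], center = centers[[i]],
         diameter = insert_diameter_mm))
  # validity: inside body and non-overlapping
  for (i in seq_len(n)) {
    ci <- inserts[[i]]
    if (sqrt(sum(ci$center^2)) + ci$diameter / 2 > geom$diameter / 2)
      stop("insert '", ci$material$name, "' extends outside the phantom body")
    for (j in seq_len(i - 1L)) {
      cj <- inserts[[j]]
      if (sqrt(sum((ci$center - cj$center)^2)) < (ci$diameter + cj$diameter) / 2)
        stop("inserts '", ci$material$name, "' and '", cj$material$name,
             "' overlap")
    }
  }
  structure(list(name = name, diameter_mm = geom$diameter,
                 ring_radius_mm = geom$ring, inserts = inserts,
                 spacing = spacing, z_mm = z_mm),
            class = "phantom_spec")
}

.grid_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Rasterize a phantom specification
#'
#' @param spec a [phantom_spec()].
#' @param margin_mm background margin around the body cylinder.
#' @return object of class `phantom`: an integer label volume (`labels`,
#'   0 = background air, 1 = water body, 2.. = inserts) and the
#'   label -> material table (`materials`, a named list; names are labels).
#' @export
build_phantom <- function(spec, margin_mm = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  sx <- spec$spacing[1]; sy <- spec$spacing[2]; sz <- spec$spacing[3]
  ext <- spec$diameter_mm + 2 * margin_mm
  nx <- ceiling(ext / sx); ny <- ceiling(ext / sy)
  nz <- max(1L, round(spec$z_mm / sz))
  x <- .grid_coords(nx, sx); y <- .grid_coords(ny, sy)
  r2 <- outer(x^2, y^2, `+`)
  lab2d <- matrix(0L, nx, ny)
  lab2d[r2 <= (spec$diameter_mm / 2)^2] <- 1L
  mats <- list("1" = .water_material())
  for (i in seq_along(spec$inserts)) {
    ins <- spec$inserts[[i]]
    d2 <- outer((x - ins$center[1])^2, (y - ins$center[2])^2, `+`)
    lab2d[d2 <= (ins$diameter / 2)^2] <- i + 1L
    mats[[as.character(i + 1L)]] <- ins$material
  }
  labels <- array(lab2d, dim = c(nx, ny, nz))
  structure(list(labels = image_volume(labels, spec$spacing, units = "label"),
                 materials = mats, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s  %s voxels  %d inserts>\n", x$spec$name,
              paste(dim(x$labels$data), collapse = "x"),
              length(x$spec$inserts)))
  invisible(x)
}

#' Crop a phantom to a box around a point
#'
#' Used to restrict simulation and mapping to an analysis subvolume (e.g.
#' an insert ROI column); with spatially white noise this is exact for ROI
#' statistics.
#'
#' @param phantom a [build_phantom()] result.
#' @param center_mm box center (x, y) in phantom coordinates.
#' @param size_mm box lateral size (x, y) in mm.
#' @return a cropped `phantom`.
#' @export
crop_phantom <- function(phantom, center_mm, size_mm) {
  lab <- phantom$labels
  d <- dim(lab$data)
  x <- .grid_coords(d[1], lab$spacing[1])
  y <- .grid_coords(d[2], lab$spacing[2])
  ix <- which(abs(x - center_mm[1]) <= size_mm[1] / 2)
  iy <- which(abs(y - center_mm[2]) <= size_mm[2] / 2)
  if (!length(ix) || !length(iy)) stop("crop box outside the phantom grid")
  sub <- lab$data[ix, iy, , drop = FALSE]
  out <- phantom
  out$labels <- image_volume(sub, lab$spacing, units = "label")
  out$offset_mm <- c(mean(x[ix]), mean(y[iy]))
  out
}

#' Insert center coordinates
#' @param phantom a [build_phantom()] result.
#' @return matrix with one row per insert (x, y in mm), rownames are
#'   insert material names.
#' @export
insert_centers <- function(phantom) {
  ctr <- t(vapply(phantom$spec$inserts, `[[`, numeric(2), "center"))
  rownames(ctr) <- vapply(phantom$spec$inserts,
                          function(i) i$material$name, "")
  ctr
}

# per-label ground-truth scalar, background air gets `bg`
.label_values <- function(phantom, fun, bg = 0) {
  labs <- sort(unique(as.integer(phantom$labels$data)))
  vals <- setNames(rep(bg, max(labs) + 1L), as.character(0:max(labs)))
  for (l in labs) {
    if (l == 0L) next
    vals[as.character(l)] <- fun(phantom$materials[[as.character(l)]])
  }
  vals
}

#' Ground-truth maps of a phantom
#'
#' Per-voxel ground truth by label lookup: SPR (Bethe at the configured
#' proton energy), RED, EAN (exponent 3.1) and, optionally, relative
#' attenuation \eqn{\mu/\mu_w} at requested energies. Background air is
#' assigned a nominal relative attenuation of 0.001 and SPR/RED of 0.001.
#'
#' @param phantom a [build_phantom()] result.
#' @param energies optional energies (keV) for \eqn{\mu/\mu_w} volumes.
#' @param constants from [bethe_constants()].
#' @return list with `spr`, `red`, `ean` [image_volume()]s and `mu_rel`,
#'   a list of volumes keyed by energy.
#' @export
ground_truth_maps <- function(phantom, energies = NULL,
                              constants = bethe_constants()) {
  lab <- phantom$labels$data
  idx <- as.integer(lab) + 1L
  mk <- function(vals) image_volume(array(vals[idx], dim(lab)),
                                    phantom$labels$spacing,
                                    units = "dimensionless")
  spr_v <- .label_values(phantom, function(m)
    spr_bethe(true_red(m), exp(true_lnI(m)), constants), bg = 0.001)
  red_v <- .label_values(phantom, true_red, bg = 0.001)
  ean_v <- .label_values(phantom, true_ean, bg = NA_real_)
  mu <- list()
  for (e in energies) {
    v <- .label_values(phantom, function(m)
      linear_attenuation_rel_water(m, e), bg = 0.001)
    vol <- mk(v)
    vol$energy_kev <- e
    mu[[format(e, trim = TRUE)]] <- vol
  }
  list(spr = mk(spr_v), red = mk(red_v), ean = mk(ean_v), mu_rel = mu)
}
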