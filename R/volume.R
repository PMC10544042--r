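# Minimal 3-D image container used throughout: a voxel array plus spacing
# and an optional energy/channel label, with NIfTI round-trip I/O.

#' Construct an image volume
#'
#' @param data numeric 3-D array (a matrix or vector is promoted).
#' @param spacing voxel spacing in mm, length 3.
#' @param energy_kev optional energy/channel label (keV) for VMI channels.
#' @param units value units, e.g. `"HU"` or `"dimensionless"`.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, energy_kev = NA_real_, units = "HU") {
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L, 1L)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing),
                 energy_kev = energy_kev, units = units),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s  %s mm  %s%s>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$units,
              if (is.finite(x$energy_kev)) sprintf("  %g keV", x$energy_kev) else ""))
  invisible(x)
}

#' Write an image volume to NIfTI
#'
#' The voxel array and spacing are stored losslessly (float64); the energy
#' label and units go into the NIfTI `descrip`/`intent_name` fields.
#'
#' @param volume an [image_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  arr <- volume$data
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  img$descrip <- sprintf("units=%s;energy_kev=%s", volume$units,
                         format(volume$energy_kev, digits = 12))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an image volume from NIfTI
#'
#' @param path NIfTI file written by [write_volume()] (or any scalar NIfTI).
#' @return an [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read volume '", path,
                                           "': ", conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  desc <- hdr$descrip
  units <- "HU"; energy <- NA_real_
  m <- regmatches(desc, regexec("units=([^;]+);energy_kev=([^;]+)", desc))[[1]]
  if (length(m) == 3L) {
    units <- m[2]
    energy <- suppressWarnings(as.numeric(m[3]))
  }
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  image_volume(arr, RNifti::pixdim(img)[1:3], energy_kev = energy, units = units)
}

#' Build a VMI stack from volumes
#'
#' A stack is a list of channel volumes keyed (as names) by their energy in
#' keV, e.g. `"74"`. Native-kV surrogate channels are keyed by their
#' effective energy like any other channel.
#'
#' @param volumes list of [image_volume()]s with finite `energy_kev`.
#' @return named list of class `vmi_stack`.
#' @export
vmi_stack <- function(volumes) {
  en <- vapply(volumes, `[[`, 0, "energy_kev")
  stopifnot(all(is.finite(en)))
  names(volumes) <- format(en, trim = TRUE)
  structure(volumes, class = "vmi_stack")
}

#' @rdname vmi_stack
#' @param stack a `vmi_stack`.
#' @return `stack_energies`: numeric vector of channel energies.
#' @export
stack_energies <- function(stack) {
  vapply(stack, `[[`, 0, "energy_kev")
}

#' @rdname vmi_stack
#' @param energy_kev channel energy to extract.
#' @return `stack_get`: the channel [image_volume()].
#' @export
stack_get <- function(stack, energy_kev) {
  i <- which(abs(stack_energies(stack) - energy_kev) < 1e-9)
  if (!length(i)) stop("stack has no channel at ", energy_kev, " keV")
  stack[[i[1]]]
}
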