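#' @importFrom stats splinefun approxfun rnorm sd lm coef residuals
#'   isoreg setNames pnorm approx aggregate
#' @importFrom utils write.csv
NULL

.dect_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "dectspr")
  if (!nzchar(path)) {
    # allow use from a source checkout (devtools::load_all)
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged data file not found: ", file)
  path
}

#' Packaged elemental photon data
#'
#' Loads the packaged table of nominal elemental data: atomic number and
#' mass, mean excitation energy (I-value, eV), and partial mass attenuation
#' coefficients (photoelectric, coherent, incoherent; cm^2/g) tabulated on a
#' 30--150 keV grid. The table is a documented synthetic stand-in generated
#' from standard analytic approximations; it contains no K-edges.
#'
#' @return A list with `energy_kev` (the tabulated grid) and `elements`,
#'   a named list (by symbol) each holding `Z`, `A`, `I_ev` and the three
#'   partial coefficient vectors.
#' @export
dect_elements <- function() {
  if (!is.null(.dect_cache$elements)) return(.dect_cache$elements)
  raw <- jsonlite::read_json(.extdata("elements_synthetic.json"),
                             simplifyVector = TRUE)
  el <- raw$elements
  out <- list(energy_kev = as.numeric(raw$energy_kev), elements = list())
  for (i in seq_len(nrow(el))) {
    e <- list(symbol = el$symbol[i], Z = el$Z[i], A = el$A[i],
              I_ev = el$I_ev[i],
              pe = as.numeric(el$mu_rho_pe[[i]]),
              coh = as.numeric(el$mu_rho_coh[[i]]),
              inc = as.numeric(el$mu_rho_inc[[i]]))
    stopifnot(e$Z >= 1, all(e$pe > 0), all(e$coh > 0), all(e$inc > 0))
    out$elements[[e$symbol]] <- e
  }
  stopifnot(!is.unsorted(out$energy_kev, strictly = TRUE),
            out$energy_kev[1] <= 30, out$energy_kev[length(out$energy_kev)] >= 150)
  .dect_cache$elements <- out
  out
}

#' Construct a material
#'
#' A material is a named chemical mixture: a mass density and elemental
#' mass fractions. Mass fractions must sum to one (tolerance 1e-6) and are
#' renormalized exactly on construction.
#'
#' @param name character label.
#' @param rho mass density in g/cm^3 (> 0).
#' @param mass_fractions named numeric vector of elemental mass fractions,
#'   names are element symbols present in [dect_elements()].
#' @return An object of class `dect_material`.
#' @export
material <- function(name, rho, mass_fractions) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("material density must be a single positive number")
  w <- mass_fractions
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("mass_fractions must be a named vector of element symbols")
  if (abs(sum(w) - 1) > 1e-6)
    stop("mass fractions of '", name, "' sum to ", sum(w), ", not 1")
  known <- names(dect_elements()$elements)
  bad <- setdiff(names(w), known)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, rho = rho, w = w / sum(w)),
            class = "dect_material")
}

#' @export
print.dect_material <- function(x, ...) {
  cat(sprintf("<material '%s'  rho = %.4g g/cm^3>\n", x$name, x$rho))
  print(round(x$w, 4))
  invisible(x)
}

.load_material_json <- function(file, key) {
  raw <- jsonlite::read_json(.extdata(file), simplifyVector = TRUE)
  tab <- raw[[key]]
  out <- list()
  for (i in seq_len(nrow(tab))) {
    w <- setNames(as.numeric(tab$mass_fractions[[i]]),
                  as.character(tab$elements[[i]]))
    out[[tab$name[i]]] <- material(tab$name[i], tab$rho[i], w)
  }
  out
}

#' Packaged reference tissue library
#'
#' The 73 named theoretical reference tissues used for VMI pair scoring.
#' The library is a nominal synthetic stand-in (ICRU-44/46-style
#' compositions plus deterministic blend series), documented as such.
#'
#' @return Named list of [material()] objects (length 73).
#' @export
reference_tissues <- function() {
  if (is.null(.dect_cache$tissues))
    .dect_cache$tissues <- .load_material_json("tissues_synthetic.json", "tissues")
  .dect_cache$tissues
}

#' Packaged phantom insert surrogates
#'
#' Nine nominal tissue-surrogate inserts for the cylindrical multi-insert
#' phantom (lung inhale/exhale, adipose, breast, muscle, liver and three
#' hydroxyapatite bone surrogates at 200/800/1250 mg/cm^3).
#'
#' @return Named list of [material()] objects.
#' @export
phantom_inserts <- function() {
  if (is.null(.dect_cache$inserts))
    .dect_cache$inserts <- .load_material_json("inserts_synthetic.json", "inserts")
  .dect_cache$inserts
}
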