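# Experiment runner: composes phantom simulation, calibration, the three
# mapping methods, ROI statistics and the range simulation into the
# repeated-acquisition study design, emitting tidy CSV tables and a
# manifest of all seeds.

#' Read or normalize an experiment configuration
#'
#' @param x path to a YAML file, or a list of fields. Recognized fields
#'   (with defaults): `phantom` ("Body"), `doses` (5/10/15 for Body,
#'   30/40/50 for Head), `nr_levels` (0), `methods`
#'   (`c("naa", "ls", "direct")`), `inserts` (all nine), `repeats` (30),
#'   `base_seed` (1), `pairs` (per-class VMI pairs; defaults to
#'   [pair_assignment()]), `spacing` (1 x 1 x 2.5 mm), `run_range` (TRUE),
#'   `out_dir` (NULL: don't write files).
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  cfg <- list(
    phantom = x$phantom %||% "Body",
    nr_levels = x$nr_levels %||% 0,
    methods = x$methods %||% c("naa", "ls", "direct"),
    inserts = x$inserts %||% names(phantom_inserts()),
    repeats = x$repeats %||% 30,
    base_seed = as.integer(x$base_seed %||% 1L),
    spacing = as.numeric(x$spacing %||% c(1, 1, 2.5)),
    run_range = x$run_range %||% TRUE,
    out_dir = x$out_dir %||% NULL)
  cfg$doses <- x$doses %||% (if (cfg$phantom == "Body") c(5, 10, 15)
                             else c(30, 40, 50))
  pr <- x$pairs
  cfg$pairs <- if (is.null(pr)) pair_assignment()
  else pair_assignment(lung = as.numeric(pr$lung), soft = as.numeric(pr$soft),
                       bone = as.numeric(pr$bone))
  if (!cfg$phantom %in% c("Body", "Head"))
    stop("config error: phantom must be 'Body' or 'Head'")
  bad <- setdiff(cfg$inserts, names(phantom_inserts()))
  if (length(bad))
    stop("config error: unknown inserts ", paste(bad, collapse = ", "))
  if (!all(cfg$methods %in% c("naa", "ls", "direct")))
    stop("config error: methods must be among naa/ls/direct")
  structure(cfg, class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a calibration as JSON
#'
#' @param calib an `ls_calibration` or `alpha_calibration`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_calibration <- function(calib, path) {
  type <- class(calib)[1]
  if (!type %in% c("ls_calibration", "alpha_calibration"))
    stop("unsupported calibration type: ", type)
  obj <- c(list(type = type), unclass(calib))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a calibration saved by [save_calibration()]
#' @param path JSON path.
#' @return the calibration object, with its class restored.
#' @export
load_calibration <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("calibration schema error in '",
                                           path, "': ", conditionMessage(e)))
  required <- switch(obj$type %||% "",
                     ls_calibration = c("A", "B", "C", "m", "alpha", "a", "b"),
                     alpha_calibration = c("alpha_red", "alpha_ean", "ean_water"),
                     stop("calibration schema error: unknown type in '", path, "'"))
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("calibration schema error: missing field(s) ",
         paste(missing, collapse = ", "))
  type <- obj$type
  obj$type <- NULL
  structure(obj, class = type)
}

# ROI column crop half-size (mm) around an insert center
.roi_box_mm <- 36

.calibrate_phantom <- function(phantom, cfg, gt_cache) {
  nat <- native_surrogate_energies()
  acq <- default_acquisition(cfg$phantom,
                             ctdi_mgy = if (cfg$phantom == "Body") 10 else 40,
                             nr_level = 0, repeats = 1,
                             base_seed = cfg$base_seed + 900000L)
  acq$energies <- sort(unname(nat))
  centers <- insert_centers(phantom)
  mats <- lapply(phantom$spec$inserts, `[[`, "material")
  names(mats) <- rownames(centers)
  ct_low <- ct_high <- numeric(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    sub <- crop_phantom(phantom, centers[i, ], c(.roi_box_mm, .roi_box_mm))
    stack <- simulate_acquisition(sub, acq, repeat_index = i)
    mask <- cylinder_roi_mask(sub$labels, c(0, 0, 0), 20, 30)
    ct_low[i] <- mean(stack_get(stack, nat[["low"]])$data[mask])
    ct_high[i] <- mean(stack_get(stack, nat[["high"]])$data[mask])
  }
  list(ls = calibrate_ls(ct_low, ct_high, mats, phantom_id = cfg$phantom),
       direct = calibrate_alphas(ct_low, ct_high, mats),
       ct_low = ct_low, ct_high = ct_high)
}

.method_stats_one_repeat <- function(stack, method, cfg, calib, lut, basis,
                                     cls, mask, insert, constants,
                                     want_stats = TRUE) {
  nat <- native_surrogate_energies()
  rec <- list()
  if (method == "naa") {
    pr <- cfg$pairs[[cls]]
    maps <- map_spr_naa(stack, cfg$pairs, basis = basis, constants = constants)
    if (want_stats) {
      in_lo <- hu_to_rel_atten(stack_get(stack, pr[1])$data)
      in_hi <- hu_to_rel_atten(stack_get(stack, pr[2])$data)
      rec$mu_low <- roi_statistics(in_lo, mask, insert, "mu_low")
      rec$mu_high <- roi_statistics(in_hi, mask, insert, "mu_high")
      rec$ean <- roi_statistics(maps$ean, mask, insert, "ean")
      rec$red <- roi_statistics(maps$red, mask, insert, "red")
      rec$spr <- roi_statistics(maps$spr, mask, insert, "spr")
    }
    rec$spr_vol <- maps$spr
  } else {
    lo <- stack_get(stack, nat[["low"]])
    hi <- stack_get(stack, nat[["high"]])
    if (want_stats) {
      rec$mu_low <- roi_statistics(hu_to_rel_atten(lo$data), mask, insert, "mu_low")
      rec$mu_high <- roi_statistics(hu_to_rel_atten(hi$data), mask, insert, "mu_high")
    }
    if (method == "ls") {
      maps <- map_spr_ls(lo, hi, calib$ls, lut, constants)
      if (want_stats) rec$red <- roi_statistics(maps$red, mask, insert, "red")
    } else {
      maps <- map_spr_direct(lo, hi, calib$direct, constants)
    }
    if (want_stats) rec$spr <- roi_statistics(maps$spr, mask, insert, "spr")
    rec$spr_vol <- maps$spr
  }
  rec
}

.range_z_mm <- function(spr_true, beam, slice_mm) {
  z <- 1.3 * r80_water(beam$energy_mev, beam) / max(spr_true, 0.05) + 20
  ceiling(min(z, 550) / slice_mm) * slice_mm
}

#' Run a repeated-acquisition noise experiment
#'
#' For each (insert, dose, noise-reduction level, repeat): simulate the
#' acquisition on an ROI column around the insert, map SPR with each
#' configured method, extract ROI statistics, optionally simulate proton
#' range along 81 beam lines through an extended insert column, and
#' aggregate over the repeats. Calibration for the two native-kV methods
#' uses one dedicated acquisition at the phantom's medium dose with no
#' noise reduction. Fully deterministic given the config.
#'
#' @param config an [experiment_config()] (or list/YAML path accepted by it).
#' @param basis optional prebuilt [build_jh_basis()].
#' @return list with `table` (aggregated data.frame, one row per insert x
#'   method x dose x noise level), `calibrations` and `manifest`. If
#'   `out_dir` is set, writes `report.csv`, `calibration_*.json` and
#'   `manifest.json` there.
#' @export
run_experiment <- function(config = experiment_config(), basis = NULL) {
  cfg <- if (inherits(config, "experiment_config")) config
         else experiment_config(config)
  if (is.null(basis)) basis <- build_jh_basis()
  constants <- bethe_constants()
  beam <- beam_spec()
  all_inserts <- phantom_inserts()
  spec <- phantom_spec(cfg$phantom, insert_materials = all_inserts,
                       spacing = cfg$spacing, z_mm = 40)
  phantom <- build_phantom(spec)
  calib <- .calibrate_phantom(phantom, cfg, NULL)
  lut <- build_lnI_lut(reference_tissues(), calib$ls$m)
  centers <- insert_centers(phantom)
  centers <- centers[rownames(centers) %in% cfg$inserts, , drop = FALSE]
  thresholds <- tissue_class_thresholds()
  nat <- native_surrogate_energies()
  seeds_used <- list()

  rows <- list()
  for (ii in seq_len(nrow(centers))) {
    insert <- rownames(centers)[ii]
    mat <- all_inserts[[insert]]
    spr_true <- spr_bethe(true_red(mat), exp(true_lnI(mat)), constants)
    cls <- classify_tissues(list(mat))[[1]]
    sub <- crop_phantom(phantom, centers[ii, ], c(.roi_box_mm, .roi_box_mm))
    energies <- sort(unique(c(unlist(cfg$pairs), thresholds$ref_energy_kev,
                              unname(nat))))
    gt <- ground_truth_maps(sub, energies = energies)
    mask <- cylinder_roi_mask(sub$labels, c(0, 0, 0), 20, 30)
    # dedicated long column for the range simulation
    if (cfg$run_range) {
      rng_spec <- phantom_spec(cfg$phantom, insert_materials = all_inserts[insert],
                               spacing = cfg$spacing,
                               z_mm = .range_z_mm(spr_true, beam, cfg$spacing[3]))
      rng_phantom <- build_phantom(rng_spec)
      rng_center <- insert_centers(rng_phantom)[1, ]
      rng_sub <- crop_phantom(rng_phantom, rng_center,
                              c(.roi_box_mm, .roi_box_mm))
      rng_gt <- ground_truth_maps(rng_sub, energies = energies)
    }
    for (di in seq_along(cfg$doses)) {
      for (ni in seq_along(cfg$nr_levels)) {
        seed0 <- cfg$base_seed +
          1000L * ((ii - 1L) * length(cfg$doses) * length(cfg$nr_levels) +
                     (di - 1L) * length(cfg$nr_levels) + (ni - 1L))
        seeds_used[[length(seeds_used) + 1L]] <-
          list(insert = insert, dose = cfg$doses[di],
               nr = cfg$nr_levels[ni], base = seed0)
        acq <- default_acquisition(cfg$phantom, ctdi_mgy = cfg$doses[di],
                                   nr_level = cfg$nr_levels[ni],
                                   repeats = cfg$repeats, base_seed = seed0)
        acq$energies <- energies
        per_method <- setNames(vector("list", length(cfg$methods)), cfg$methods)
        ranges <- setNames(vector("list", length(cfg$methods)), cfg$methods)
        for (r in seq_len(cfg$repeats)) {
          stack <- simulate_acquisition(sub, acq, repeat_index = r, gt = gt)
          if (cfg$run_range) {
            acq_rng <- acq
            acq_rng$base_seed <- seed0 + 500L
            rng_stack <- simulate_acquisition(rng_sub, acq_rng,
                                              repeat_index = r, gt = rng_gt)
          }
          for (mth in cfg$methods) {
            rec <- .method_stats_one_repeat(stack, mth, cfg, calib, lut,
                                            basis, cls, mask, insert, constants)
            per_method[[mth]][[r]] <- rec[setdiff(names(rec), "spr_vol")]
            if (cfg$run_range) {
              rrec <- .method_stats_one_repeat(rng_stack, mth, cfg, calib, lut,
                                               basis, cls, NULL,
                                               insert, constants,
                                               want_stats = FALSE)
              ranges[[mth]][[r]] <- simulate_range(rrec$spr_vol, beam,
                                                   roi_center_mm = c(0, 0))
            }
          }
        }
        for (mth in cfg$methods) {
          recs <- per_method[[mth]]
          qty <- names(recs[[1]])
          agg <- lapply(qty, function(q)
            aggregate_repeats(lapply(recs, `[[`, q)))
          names(agg) <- qty
          row <- data.frame(phantom = cfg$phantom, insert = insert,
                            tissue_class = cls, method = mth,
                            dose_mgy = cfg$doses[di],
                            nr_level = cfg$nr_levels[ni],
                            spr_true = spr_true, stringsAsFactors = FALSE)
          for (q in c("mu_low", "mu_high", "ean", "red", "spr")) {
            row[[paste0(q, "_ci_pct")]] <-
              if (q %in% qty) agg[[q]]$ci87_pct else NA_real_
            row[[paste0(q, "_skew")]] <-
              if (q %in% qty) agg[[q]]$skewness else NA_real_
          }
          row$spr_mean <- agg[["spr"]]$mean
          if (cfg$run_range) {
            rstat <- range_statistics(ranges[[mth]], insert = insert)
            row$range_mean_mm <- rstat$mean
            row$range_ci_pct <- rstat$ci87_pct
            row$range_skew <- rstat$skewness
            row$range_flagged <- rstat$n_flagged
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  cfg_plain <- unclass(cfg)
  cfg_plain$pairs <- lapply(unclass(cfg$pairs), as.numeric)
  manifest <- list(package_version = as.character(utils::packageVersion("dectspr")),
                   config = cfg_plain, seeds = seeds_used,
                   calibration = list(ls = unclass(calib$ls),
                                      direct = unclass(calib$direct)))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(table, file.path(cfg$out_dir, "report.csv"), row.names = FALSE)
    save_calibration(calib$ls, file.path(cfg$out_dir, "calibration_ls.json"))
    save_calibration(calib$direct,
                     file.path(cfg$out_dir, "calibration_direct.json"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = table, calibrations = calib[c("ls", "direct")],
       manifest = manifest)
}
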