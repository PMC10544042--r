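# VMI energy-pair optimization: enumerate candidate pairs, score each by
# SPR RMSE over reference tissues (theoretically, and as measured on noisy
# acquisitions), exclude pairs above the 2% theoretical threshold, rank
# per repeat, and select per-class optima pooled across phantoms.

#' Enumerate candidate VMI pairs
#'
#' All unordered pairs {E1 < E2} from the inclusive grid; the default
#' 40--140 keV grid in 1 keV steps yields 5050 pairs.
#'
#' @param e_min,e_max grid bounds in keV.
#' @param step grid step in keV.
#' @return data.frame with columns `E1`, `E2`.
#' @export
enumerate_pairs <- function(e_min = 40, e_max = 140, step = 1) {
  stopifnot(step > 0)
  grid <- seq(e_min, e_max, by = step)
  if (e_min >= e_max || length(grid) < 2)
    stop("energy grid must contain at least two points")
  idx <- which(upper.tri(matrix(0, length(grid), length(grid))), arr.ind = TRUE)
  data.frame(E1 = grid[idx[, "row"]], E2 = grid[idx[, "col"]])
}

#' Classify reference tissues into lung/soft/bone
#'
#' Rule (configurable): lung if mass density < `lung_rho`, bone if the
#' exponent-3.1 EAN exceeds `bone_ean`, soft otherwise.
#'
#' @param tissues list of [material()]s.
#' @param lung_rho density bound (g/cm^3, default 0.6).
#' @param bone_ean EAN bound (default 10).
#' @return character vector of classes, named by tissue.
#' @export
classify_tissues <- function(tissues, lung_rho = 0.6, bone_ean = 10) {
  vapply(tissues, function(m) {
    if (m$rho < lung_rho) "lung"
    else if (true_ean(m, 3.1) > bone_ean) "bone"
    else "soft"
  }, "")
}

#' Precompute tissue forward attenuation and ground truth for pair scoring
#'
#' @param tissues list of [material()]s.
#' @param energies energies (keV) to tabulate.
#' @param constants from [bethe_constants()].
#' @return list with matrix `mu_rel` (tissues x energies, dimnames set),
#'   `spr_true`, and `class` from [classify_tissues()].
#' @export
tissue_forward_table <- function(tissues, energies = 40:140,
                                 constants = bethe_constants()) {
  mu <- t(vapply(tissues, function(m)
    linear_attenuation_rel_water(m, energies), numeric(length(energies))))
  dimnames(mu) <- list(names(tissues), format(energies, trim = TRUE))
  spr <- vapply(tissues, function(m)
    spr_bethe(true_red(m), exp(true_lnI(m)), constants), 0)
  list(mu_rel = mu, spr_true = spr, class = classify_tissues(tissues),
       energies = energies)
}

.naa_spr_from_mu <- function(mu1, mu2, e1, e2, basis, constants) {
  inv <- invert_zeff(mu1, mu2, e1, e2, basis)
  rd <- red_from_pair(mu1, mu2, e1, e2, inv$zeff, basis)
  spr_bethe(pmax(rd$red, 0), exp(yang_lnI(inv$zeff)), constants)
}

#' Theoretical SPR RMSE of a VMI pair over reference tissues
#'
#' Forward \eqn{\mu/\mu_w} at the two energies for each tissue of the
#' class, run the VMI inversion chain to SPR, and report the percent RMSE
#' of the relative SPR error against the Bethe ground truth. Symmetric in
#' the pair order.
#'
#' @param pair length-2 energies (keV).
#' @param table a [tissue_forward_table()].
#' @param class one of `"lung"`, `"soft"`, `"bone"` or `"all"`.
#' @param basis a [build_jh_basis()] object.
#' @param constants from [bethe_constants()].
#' @return percent RMSE (scalar).
#' @export
pair_rmse_theoretical <- function(pair, table, class = "soft", basis,
                                  constants = bethe_constants()) {
  sel <- if (identical(class, "all")) rep(TRUE, length(table$class))
         else table$class == class
  if (!any(sel)) stop("no tissues in class '", class, "'")
  pair <- sort(pair)
  k1 <- format(pair[1], trim = TRUE); k2 <- format(pair[2], trim = TRUE)
  mu1 <- table$mu_rel[sel, k1]
  mu2 <- table$mu_rel[sel, k2]
  spr <- .naa_spr_from_mu(mu1, mu2, pair[1], pair[2], basis, constants)
  100 * sqrt(mean(((spr - table$spr_true[sel]) / table$spr_true[sel])^2))
}

#' Measured SPR RMSE of a VMI pair on a noisy acquisition
#'
#' Insert-ROI mean relative attenuation at the two energies is pushed
#' through the VMI inversion chain and compared with each insert's Bethe
#' ground truth.
#'
#' @param pair length-2 energies (keV).
#' @param stack a [vmi_stack()] acquisition containing both energies (HU).
#' @param rois list of logical ROI masks, one per insert.
#' @param spr_true ground-truth SPR per insert (same order as `rois`).
#' @param basis,constants as in [pair_rmse_theoretical()].
#' @return percent RMSE over the inserts.
#' @export
pair_rmse_measured <- function(pair, stack, rois, spr_true, basis,
                               constants = bethe_constants()) {
  pair <- sort(pair)
  v1 <- stack_get(stack, pair[1])$data
  v2 <- stack_get(stack, pair[2])$data
  mu1 <- vapply(rois, function(m) hu_to_rel_atten(mean(v1[m])), 0)
  mu2 <- vapply(rois, function(m) hu_to_rel_atten(mean(v2[m])), 0)
  spr <- .naa_spr_from_mu(mu1, mu2, pair[1], pair[2], basis, constants)
  100 * sqrt(mean(((spr - spr_true) / spr_true)^2))
}

#' D'Agostino-type EAN normality screen
#'
#' Standardized skewness and excess-kurtosis omnibus statistic
#' (K2 = Zs^2 + Zk^2, chi-squared with 2 df under normality) on an
#' insert-ROI EAN sample. Collapsed, spiky EAN distributions fail.
#'
#' @param x numeric sample (n >= 20).
#' @param alpha significance level (default 0.01).
#' @return logical: `TRUE` if the sample passes (is compatible with
#'   normality), with attribute `p_value`.
#' @export
ean_normality_screen <- function(x, alpha = 0.01) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) stop("need at least 20 samples for the normality screen")
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(structure(FALSE, p_value = 0))
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  zs <- g1 / sqrt(6 / n)
  zk <- g2 / sqrt(24 / n)
  k2 <- zs^2 + zk^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  structure(p >= alpha, p_value = p)
}

#' Select optimal VMI pairs per tissue class
#'
#' Per class: pairs with theoretical RMSE above `exclude_above` (%) are
#' excluded; per repeat the remaining pairs are ranked by measured RMSE
#' pooled across both phantoms (root mean of the two squared RMSEs); the
#' optimum minimizes the pooled RMSE aggregated (averaged) over repeats,
#' with lexicographic (RMSE, E1, E2) tie-break. The robustness summary
#' reports times-ranked-first, mean and SD of the pooled RMSE, and the
#' worst (largest) rank per pair.
#'
#' @param theoretical data.frame `E1, E2, class, rmse` (theoretical scores).
#' @param measured data.frame `phantom, repeat_id, E1, E2, class, rmse`.
#' @param exclude_above theoretical exclusion threshold in % (default 2).
#' @param normality_ok optional logical vector named `"E1/E2"` marking
#'   pairs that pass the EAN normality screen; when supplied, failing
#'   pairs are excluded as an additional condition.
#' @return list with `assignment` (a [pair_assignment()]-style list of the
#'   per-class optima) and `summary` (data.frame, one row per retained
#'   pair and class).
#' @export
select_optimal <- function(theoretical, measured, exclude_above = 2,
                           normality_ok = NULL) {
  key <- function(e1, e2) paste0(e1, "/", e2)
  out_sum <- list()
  assignment <- list()
  for (cls in unique(theoretical$class)) {
    th <- theoretical[theoretical$class == cls, ]
    keep <- th$rmse <= exclude_above
    if (!is.null(normality_ok))
      keep <- keep & normality_ok[key(th$E1, th$E2)] %in% TRUE
    th <- th[keep, ]
    if (!nrow(th)) stop("all pairs excluded for class '", cls, "'")
    me <- measured[measured$class == cls, ]
    me <- me[key(me$E1, me$E2) %in% key(th$E1, th$E2), ]
    if (!nrow(me)) stop("no measured scores for retained pairs, class '", cls, "'")
    # pool across phantoms per (repeat, pair)
    pooled <- aggregate(rmse ~ E1 + E2 + repeat_id, data = me,
                        FUN = function(r) sqrt(mean(r^2)))
    reps <- sort(unique(pooled$repeat_id))
    pk <- key(pooled$E1, pooled$E2)
    pair_keys <- sort(unique(pk))
    first <- setNames(rep(0L, length(pair_keys)), pair_keys)
    worst <- setNames(rep(1L, length(pair_keys)), pair_keys)
    for (r in reps) {
      pr <- pooled[pooled$repeat_id == r, ]
      pr <- pr[order(pr$rmse, pr$E1, pr$E2), ]
      rk <- seq_len(nrow(pr))
      kk <- key(pr$E1, pr$E2)
      first[kk[1]] <- first[kk[1]] + 1L
      worst[kk] <- pmax(worst[kk], rk)
    }
    agg_mean <- aggregate(rmse ~ E1 + E2, data = pooled, FUN = mean)
    agg_sd <- aggregate(rmse ~ E1 + E2, data = pooled,
                        FUN = function(x) if (length(x) > 1) sd(x) else 0)
    agg <- merge(agg_mean, agg_sd, by = c("E1", "E2"),
                 suffixes = c("_mean", "_sd"))
    kk <- key(agg$E1, agg$E2)
    agg$class <- cls
    agg$times_first <- as.integer(first[kk])
    agg$worst_rank <- as.integer(worst[kk])
    agg <- agg[order(agg$rmse_mean, agg$E1, agg$E2), ]
    agg$rank <- seq_len(nrow(agg))
    assignment[[cls]] <- c(agg$E1[1], agg$E2[1])
    out_sum[[cls]] <- agg
  }
  list(assignment = assignment, summary = do.call(rbind, out_sum))
}
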