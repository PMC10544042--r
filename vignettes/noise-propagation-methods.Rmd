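---
title: "Methods: simulating noise propagation in dual-energy CT stopping-power mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating noise propagation in dual-energy CT stopping-power mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`dectspr` studies how voxel noise in dual-energy CT (DECT) images
propagates into proton stopping-power-ratio (SPR) maps and, through a
simplified range model, into the precision of simulated proton range.
Three voxel-wise SPR mapping methods are implemented over a shared
physics core:

* **VMI inversion** (`map_spr_naa()`): two virtual monoenergetic images
  (VMIs) are inverted through the Jackson–Hawkes parametrization
  $\mu(E) = \rho_e\,(Z_\mathrm{eff}^4 F(Z_\mathrm{eff},E) +
  G(Z_\mathrm{eff},E))$ to an effective atomic number (EAN) and relative
  electron density (RED); the mean excitation energy follows the
  two-branch linear parametrization $\ln I = a_i Z_\mathrm{eff} + b_i$
  (slope change at $Z_\mathrm{eff} = 8.5$, assigned to the upper branch,
  discontinuity preserved); SPR follows from the Bethe ratio at 100 MeV
  with $I_w = 78.73$ eV. Voxels are segmented on a 74 keV reference VMI
  (lung $< -200$ HU, soft $[-200, 150]$ HU, bone $> 150$ HU; both
  boundary values are soft) and each class uses its own VMI pair.
* **Landry–Saito** (`map_spr_ls()`): an EAN ratio model
  $r = (1 + Az)/(B + Cz)$ with $z = Z_\mathrm{eff}^{m-1}$ and a RED
  model $\rho_e = a[(1+\alpha)\,CT_h - \alpha\,CT_l]/1000 + b$, both
  calibrated by least squares on the phantom inserts. The per-voxel
  EAN-to-$I$ step is bypassed: noisy voxels produce unphysical EAN, so
  $\ln I$ comes from a monotone (isotonic piecewise-linear) lookup from
  $z$ built over the reference-tissue library and clamped outside its
  domain. The lookup is total — every real $z$ maps to a finite $\ln I$.
* **Alpha superposition** (`map_spr_direct()`): RED and EAN as
  calibrated weighted superpositions of the native low/high CT numbers
  (the published equations behind the commercial DirectSPR product).
  Everything beyond those two equations is proprietary, so the $I$-value
  step reuses the two-branch parametrization, rescaled so the water EAN
  maps exactly onto $I_w$; the water voxel (0 HU in both channels) then
  maps to SPR exactly 1. No numerical equivalence with the commercial
  product is claimed.

## Packaged physics tables

Elemental partial mass attenuation coefficients (photoelectric,
coherent, incoherent) are packaged on a 30–150 keV grid for 26 elements
covering $Z \in \{1\} \cup [4, 54]$. They are **nominal, synthetic**
tables generated from standard analytic approximations — exact
Klein–Nishina incoherent scattering with a small binding correction, and
power-law photoelectric ($\propto Z^{4.6} E^{-3.1}$) and coherent
($\propto Z^{2.4} E^{-1.7}$) terms anchored to water's partial
attenuation at 30 keV. K-edges are not modeled, which matters only for
iodine/xenon below ~40 keV. Interpolation is log–log cubic in energy and
monotone piecewise-cubic in $Z$ (the smoothness the iterative EAN solve
requires). The Jackson–Hawkes split is exact at the table nodes by
construction: $Z^4 F + G$ reproduces the per-electron cross section to
better than $10^{-10}$ relative.

Elemental $I$-values are ICRU 37 values, except that the H, C, N, O, P,
Cl, Ca subset is rescaled by a common factor in $\ln I$ so that Bragg
additivity gives water exactly $I_w = 78.73$ eV — the water anchor the
Bethe ratio uses. The 73-tissue reference library and the nine phantom
insert surrogates (lung inhale/exhale, adipose, breast, muscle, liver,
and water–hydroxyapatite blends at 200/800/1250 mg/cm³) are likewise
nominal stand-ins with ICRU-44/46-style compositions; file names and
documentation label them synthetic. Consequently all quantitative
results characterize this documented synthetic system, not any specific
scanner or the vendor's insert chemistry.

## The EAN solver

The two-energy relation is solved in residual form,
$\mu_2 (z^4F_1 + G_1) - \mu_1 (z^4F_2 + G_2) = 0$, which avoids the
fourth root of a possibly negative ratio. Because $F_1/F_2$ is nearly
constant in $z$, the residual is monotone up to a mild scattering term,
and a vectorized safeguarded bisection on $[4, 54]$ (tolerance $10^{-8}$
on the interval) is equivalent to the bounded minimization of the
squared residual while vectorizing over whole volumes. Voxels whose
residual does not change sign across the bounds fall back to a 0.01-step
grid scan, are pinned near the better bound, and are flagged — but still
propagated to SPR, since the method computes SPR everywhere. The solver
is verified against an exhaustive 0.001-step grid search.

## The synthetic imaging chain

The phantom is a water-equivalent cylinder in two sizes (Body 300 mm,
Head 180 mm diameter) with 30 mm insert rods (eight on a ring, one
central), rasterized at 1×1×2.5 mm; each voxel takes the material of its
center (no partial volume). Acquisition means are the exact ground-truth
relative attenuations — the simulator models no beam hardening, scatter,
or projection physics.

Noise is a rank-2 zero-mean Gaussian model. The two *native* source
channels (surrogate effective energies 56 and 89 keV for the low and
Sn-filtered high tube) carry independent noise; every synthesized VMI at
energy $E$ receives the linear recombination of those two fields given
by the water/cortical-bone two-material decomposition. This choice —
noise diagonal in the native-channel basis rather than the material
basis — reflects that a dual-source scanner's two acquisitions are
independent measurements, and it yields the expected phenomenology:
nearby VMIs are correlated above 0.9, VMI noise grows steeply below the
low-tube energy, and native channels reproduce their own noise exactly.
Noise SD scales as $1/\sqrt{\mathrm{CTDI_{vol}}}$. The reference SDs
(relative-attenuation units 0.033/0.032 at 10 mGy for the Body phantom;
half that at 40 mGy for the Head) were calibrated once so the Body
soft-tissue input channels show CI87 of about ±5% — the scale reported
for repeated phantom acquisitions at that dose — and are documented
constants, not fit parameters. Noise reduction is a surrogate: separable
Gaussian smoothing (levels 0/1/2 map to kernel SDs of 0/0.75/1.5
voxels) with edge renormalization, so large-ROI means are preserved;
no claim is made about the internals of iterative or deep-learning
reconstruction.

A consequence worth stating plainly: with exactly rank-2 noise, every
well-calibrated two-channel mapper shares the same first-order RED
response, so differences between methods are carried by their $I$-value
pathways and nonlinearities. In this system the Landry–Saito SPR noise
exceeds its inputs (amplification) and the VMI method's SPR noise is
far below its own (much noisier, low-keV) inputs (compression), both as
observed on real scanners; the *cross-method* ordering, however, comes
out with the VMI method noisiest, because the real-world ingredients
that separate the methods — the commercial product's proprietary,
interpolating calibration and the scanner-specific VMI reconstruction
chains — are exactly the parts replaced by surrogates here. The test
suite asserts the real-world ordering anyway; those expectations fail
under this simulator by design, and we keep them failing rather than
re-tune the generator, while reporting the ratios the simulator does
produce.

## VMI pair optimization

All $\binom{101}{2} = 5050$ pairs from the 40–140 keV, 1 keV grid are
scored by percent SPR RMSE over the reference tissues per class; pairs
above 2% theoretical RMSE are excluded, the rest are re-ranked on each
of 30 noisy optimization acquisitions (medium dose, both phantoms,
pooled as the root mean of the two squared class RMSEs — a single
scalar for "lowest RMSE across both phantoms"), and the optimum
minimizes the repeat-averaged pooled RMSE with lexicographic (RMSE,
$E_1$, $E_2$) tie-break. The robustness summary reports times-ranked
first, mean ± SD RMSE, and worst rank, and an optional D'Agostino-type
skew/kurtosis screen (off by default) can reject pairs whose insert-ROI
EAN distribution collapses into spikes. Tissue classes use a documented,
configurable rule (lung: density < 0.6 g/cm³; bone: exponent-3.1 EAN
> 10; else soft), since no partition of the 73 tissues is standard. The
package defaults — lung 40/50, soft 40/41, bone 40/84 keV, selected by
`analysis/01_optimize_vmi_pairs.R` with seed 101 — are properties of
this synthetic chain, as scanner-reported optima are properties of
theirs.

## ROI statistics and the range model

Insert statistics use cylindrical ROIs (d = 20 mm, z = 30 mm) at insert
centers: sample mean, relative SD (% of mean), CI87 = ±1.5 SD (86.6%
coverage under normality), and adjusted Fisher–Pearson skewness, each
computed per repeat and averaged over the 30 repeats. CT channels are
converted to attenuation relative to water, $(CT\# + 1000)/1000$, before
relative statistics, so near-zero HU means cannot inflate them.

The treatment-planning dose engine is replaced by water-equivalent path
length (WEPL) integration: a 105 MeV beam parallel to the insert axis on
a 2×2×1 mm dose grid, 81 lattice lines (the 2 mm lattice points nearest
the ROI center; exactly 81 fall within a d = 20 mm circle), trapezoidal
cumulative WEPL at 1 mm steps, and range defined as the depth where
cumulative WEPL reaches the Bragg–Kleeman water range
$R = \alpha E^p$ ($\alpha = 0.0022$ cm·MeV$^{-p}$, $p = 1.77$, i.e.
83.16 mm at 105 MeV). This proxy shifts absolute ranges relative to a
dose engine — there is no straggling, scattering, or nuclear physics —
but the studied quantity is noise-induced range *variation*, for which
relative statistics are the comparable output. Lines whose WEPL never
reaches the target (e.g. low-density inserts in a short volume) are
flagged and excluded with a reported count.

## Experiment design and problem sizes

`run_experiment()` mirrors the repeated-acquisition design: per (insert,
dose, noise-reduction level), 30 repeats are simulated, mapped with all
three methods, reduced to ROI records, and aggregated; the native-kV
calibrations use one dedicated acquisition at the medium dose with no
noise reduction; every output row is traceable to a recorded seed in the
manifest, and identical configs produce byte-identical CSVs. Since the
noise is spatially white and the mappers voxel-wise, simulation is
restricted to a 36 mm column around each analyzed insert (exact for ROI
statistics) and to a long single-insert column for the range lines; the
shipped analyses use 30 repeats, the full 5050-pair grid with the
73-tissue library, and 10⁴–10⁵-voxel ROIs for distributional checks —
sizes at which the Monte-Carlo error is well below the effects studied.

## Known limitations

* All attenuation data, tissue compositions and insert chemistries are
  nominal synthetic stand-ins; absolute SPR accuracies here do not
  transfer to any physical scanner.
* Rank-2 noise cannot reproduce cross-method noise orderings that stem
  from proprietary calibrations or reconstruction internals (above).
* No projection-space effects, beam hardening, spatially correlated
  noise textures, or partial-volume mixing.
* The range model is a WEPL proxy; absolute ranges and distal falloff
  shapes are out of scope, as is any dosimetric claim.
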