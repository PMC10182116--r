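---
title: "Quantifying breast density with PDFF: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying breast density with PDFF: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastpdff)
```

## The problem

Breast density — the proportion of fibroglandular (glandular and stromal)
tissue in the breast — is one of the strongest independent risk factors
for breast cancer, yet it is routinely graded by eye from mammograms into
the four ACR BI-RADS categories (A, almost entirely fatty, through D,
extremely dense), a reading with known inter-observer variability.
Chemical-shift-encoded water-fat MRI offers a quantitative alternative:
the proton density fat fraction (PDFF), the ratio of triglyceride proton
density to total (triglyceride + water) proton density per voxel, is a
confounder-corrected measure of tissue fat concentration.  A fatty breast
has high whole-breast PDFF; a dense breast has low PDFF.  This package
implements the full analysis chain — signal model, water-fat separation,
semi-automated breast and fibroglandular segmentation, per-breast
summaries, and the cohort statistics relating PDFF to ACR grades —
together with a digital phantom simulator that provides exact ground
truth, so every stage is testable without any patient data.

## Signal model

A spoiled gradient-echo acquisition samples the complex signal at echo
times $t_n$ (here six echoes, $TE_1 = 1.43$ ms, $\Delta TE = 1.1$ ms at
3 T).  Water and fat contribute

$$ s_n = \left( W + F c_n \right)
   e^{i(\phi_0 + 2\pi\psi t_n)} e^{-t_n R_2^*}, \qquad
   c_n = \sum_p a_p e^{i 2\pi f_p t_n}, $$

with $W, F \ge 0$ the water/fat magnitudes sharing a common initial phase
$\phi_0$, $\psi$ the B0 off-resonance (field map, Hz), a single $R_2^* =
1/T_2^*$ decay for both species, and $c_n$ the multi-peak fat phasor.
Triglyceride is not a single resonance: the packaged default spectrum has
7 peaks (shifts $-3.80$ to $-0.50$ ppm from water, amplitudes summing to
one).  Vendor-calibrated spectra differ slightly between platforms, so the
spectrum is a configuration input (`fat7.yaml` in `inst/extdata`), not a
constant.  PDFF is reported as $100 \cdot F / (W + F)$ from the fitted
magnitudes, clipped to $[0, 100]$; $T_2^*$ as $1/R_2^*$ in ms, with
$R_2^* < 10^{-6}$/ms reported as missing rather than an infinite time.

Echo times are stored in milliseconds (matching protocol notation) and
converted to seconds only inside phase terms; $R_2^*$ is in 1/ms and
$\psi$ in Hz, the conventional units of each quantity.

## Water-fat separation

For fixed $(\psi, R_2^*)$ the model is linear in the complex amplitudes,
so the fit uses variable projection (VARPRO): amplitudes are solved
analytically per iterate and the residual is minimised over the two
nonlinear parameters only.  The well-known difficulty is the water-fat
swap: the residual in $\psi$ has a second minimum roughly one fat-water
shift ($\approx 434$ Hz at 3 T) away where the roles of water and fat are
exchanged.  The pipeline addresses it in two stages:

1. **Field-map initialisation** (`fieldmap_init()`): the residual is
   evaluated on a $\psi$ grid (10 Hz spacing over $\pm 1/(2\Delta TE)$,
   minimised over a small $R_2^*$ probe grid), the local minima of each
   voxel's profile are retained as candidates, and candidate selection is
   iterated a few times against a magnitude-weighted neighbourhood mean —
   a smoothing relaxation that propagates the unambiguous high-SNR voxels
   into ambiguous ones.  The selection score mixes the normalised residual
   with the distance to the neighbourhood mean (weight 0.5); the
   neighbourhood is a $5^3$ box.  A design deviation worth noting: the
   spatial reference is a weighted *mean* rather than a median — the mean
   is separable and therefore cheap on whole volumes, and on smooth
   simulated field maps the two are indistinguishable.
2. **Local refinement** (`fit_voxel()`, `fit_volume()`): alternating
   Brent line searches in $\psi$ (within $\pm 1.5$ grid steps of the
   initialisation) and $R_2^* \in [0, 0.5]$/ms, stopping when the
   residual decrease falls below $10^{-8}$ relative (or 100 iterations,
   flagged as non-convergent).  When no initialisation is supplied,
   `fit_voxel()` refines the two best grid minima and keeps the lower —
   which is also how the documented swap is reproduced on demand by
   seeding the aliased branch.

Background voxels are excluded before fitting: k-means (k = 3) on the
first-echo magnitude, threshold twice the mean of the darkest cluster.
When the darkest cluster is not clearly darker than the brightest (no air
in the field of view) every non-zero voxel is kept.  Excluded and
degenerate voxels carry QC flag 2, non-convergent fits flag 1; all
summaries use flag-0 voxels only.  `qc_report()` emulates a dataset-level
screen: a dataset fails when more than 20% (configurable) of its
foreground is flagged — the signature of a failed phase correction is
exactly such a volume-wide breakdown.

### Bipolar phase errors

Bipolar readouts alternate gradient polarity between echoes and pick up a
phase error of opposite sign on odd/even echoes, modelled here as
$\sigma_n (a + b x)$ with $\sigma_n$ the per-echo polarity and $x$ the
centred readout (RL) coordinate in voxels.  `correct_bipolar_phase()`
estimates $(a, b)$ by minimising the summed VARPRO residual of a
400-voxel high-magnitude subsample (spread along the readout axis) over
candidate corrections, with Nelder-Mead plus a fine-simplex restart.  Two
details matter: the per-voxel residual refines the *three* best field-map
candidates and keeps the lowest, so voxels near the swap ambiguity cannot
flip branches as $(a, b)$ vary and roughen the cost; and estimates below
$10^{-4}$ rad across the field of view are treated as "no parity error",
which makes the correction idempotent and a no-op on monopolar data.

## Segmentation workflow

The semi-automated workflow mirrors how such pipelines are run in
practice.  Its input besides the fitted maps is a sparse manual
delineation of the pectoralis-parenchyma interface drawn on every second
axial slice.

* `cluster_tissues()`: k-means (k = 3, 10 restarts, seeded; features
  min-max scaled per channel) on `(fat_mag, water_mag)` splits the field
  of view into background, water-dominant and fat-dominant voxels.
  Clusters are relabelled from their centroids (background = lowest total
  intensity, fat = higher fat centroid of the rest), making the labels
  invariant to the k-means seed on separated data.
* `densify_border()`: annotations are copied to un-drawn slices from the
  nearest drawn slice (the simplest scheme that honours every-second-slice
  coverage), then box-dilated (default radius 2) into a surface guaranteed
  to close jitter-induced gaps.  Both the thin sheet and the dilated
  surface are returned.
* `breast_centroids()`: border voxels are projected along AP, split at the
  RL midpoint of the delineation extent, averaged per side, and displaced
  anteriorly (default 10 voxels) so the seed lands inside breast tissue.
* `isolate_breasts()`: the dilated border is removed from the foreground,
  26-connected components are labelled, and each breast is the component
  containing its centroid.  The voxels removed by the dilation — but not
  the sheet itself — are then reassigned by simultaneous equal-speed front
  growth from both breasts and the thorax.  This reclaiming step is the
  package's resolution of a genuine design tension: subtracting the full
  dilated surface from the breasts costs 2-3 posterior voxel layers
  (several percent of breast volume, visibly biasing both Dice overlap and
  mean PDFF), while the separating job of the dilation is done once the
  components are labelled.  The final masks stay disjoint from the
  delineated sheet, from each other and from the thorax.
* `segment_fibroglandular()`: fibroglandular tissue carries very low fat
  signal (empirically 0-10% PDFF), so the FGT mask is the water-dominant
  breast voxels with PDFF strictly below a 20% cutoff.  The comparison is
  strict; with FGT at 0-10% and adipose near 90% the boundary voxel at
  exactly 20% is immaterial, and the water-dominance constraint is the
  operational reading of the "sharp delineation between fat and
  fibroglandular tissue".  Raising the cutoff can only grow the mask.
* `summarize_breast()`: arithmetic means of PDFF over the whole breast and
  of PDFF and $T_2^*$ over the FGT, restricted to QC-flag-0 voxels; FGT
  means are missing when the mask is empty.

Side selection for cohort analyses (left/right) is a user input, as
exclusion criteria that pick one breast per subject are clinical, not
algorithmic.

## The phantom simulator

`make_phantom()` builds a parametric two-breast digital phantom on a
64 x 64 x 32 grid (FH x AP x RL, 1.7 mm isotropic by default): two
half-ellipsoid breasts (adipose shell, concentric fibroglandular core
scaled by bisection to hit the target FGT volume fraction within 2
percentage points) attached to a pectoralis slab, air elsewhere.  Tissue
defaults: adipose PDFF 90%, $T_2^*$ 30 ms; FGT PDFF 6%, $T_2^*$ 22 ms;
muscle PDFF 5%, $T_2^*$ 25 ms, proton density 0.9.  The field map is a
smooth second-order polynomial scaled to 60 Hz maximum; noise is i.i.d.
circular complex Gaussian calibrated so that SNR = first-echo adipose
magnitude / per-channel noise SD (default 50, a realistic mid-range value
for an accelerated 3-T acquisition); an optional bipolar parity phase is
injected through the same polarity convention the correction assumes.
Everything derives from a single integer seed.

`make_cohort()` samples an ACR-graded population: FGT volume fractions
per category from non-overlapping ranges (A 0.02-0.08, B 0.10-0.25,
C 0.30-0.50, D 0.55-0.75 — design values chosen so the four grades are
distinct by construction), adipose PDFF from a truncated Normal(90, 2) on
[80, 98]%, FGT PDFF from Uniform(3, 10)% consistent with the 0-10% FGT
fat signal, and FGT $T_2^*$ drifting mildly upward with density category
(20 to 25 ms).  The last is deliberately documented as a *simulation
choice* echoing an observed trend direction, not a physical claim.  Ages
increase with the adipose fraction; two mammography and two MRI readers
are simulated from the true category with adjacent-category error
probabilities of 0.2 and 0.15.

What the phantom does **not** emulate: coil sensitivities, motion,
partial-volume mixing at tissue boundaries (compartments are voxel-sharp),
ductal microstructure, silicone, $T_1$ bias, or anatomical shape
variability.  Passing tests on the phantom therefore demonstrate the
correctness of the algorithms under the stated model, not clinical
performance on patient data.

## Cohort statistics

`spearman_rho()` computes the tie-corrected Spearman correlation (ACR
letters coded A=1..D=4) with the t approximation for the two-sided p.
`kruskal_wallis_holm()` computes the tie-corrected Kruskal-Wallis H; the
post-hoc procedure — unspecified in common usage of "Kruskal-Wallis
followed by Holm" — is all pairwise two-sided Wilcoxon rank-sum tests with
Holm's step-down adjustment.  For small samples (pooled n at or below 10
globally, 12 per pair) p-values come from exhaustive permutation
enumeration rather than the chi-squared/normal approximations; with
separated pairs such as {1,2}/{3,4}/{5,6} the exact p (6/90) differs from
the approximation by far more than any reasonable tolerance, which is why
the exact path exists.  `cohens_kappa()` is unweighted kappa with the
standard asymptotic CI; `icc_paired()` is ICC(2,1) — two-way random
effects, single measure, absolute agreement — the conventional choice for
left/right reliability, and configurable in principle via the mean-squares
decomposition it documents.  `auxiliary_tests()` adds the chi-squared test
of independence on the mammography-vs-MRI cross-tabulation (no continuity
correction, so canonical hand-computed tables reproduce exactly) and a
paired t-test on left/right means with an explicit zero-variance guard.
Missing values are dropped pairwise with a message.  The significance
threshold throughout is a two-tailed 0.05.

## Numerical choices

* VARPRO refinement: alternating Brent line searches; convergence at
  relative residual decrease $< 10^{-8}$ with an absolute floor of
  $10^{-14} \times$ signal energy so exact fits terminate; search windows
  contract after the first alternation (the $\psi$/$R_2^*$ coupling is
  weak).  Whole-volume fits use Brent tolerances of $10^{-4}$ Hz /
  $10^{-7}$ ms$^{-1}$; single-voxel fits use $10^{-8}$ / $10^{-11}$.
* Grid-stage $R_2^*$ probes: {0.02, 0.08}/ms — two values suffice to rank
  $\psi$ basins; the refinement re-estimates $R_2^*$ continuously.
* Connected components and front growth run in compiled code with
  26-connectivity (oblique boundaries must not split components); ties in
  the equal-speed growth resolve by deterministic queue order.
* k-means degeneracy (constant volumes, fewer than three distinct
  intensities) raises an error rather than returning arbitrary labels.
* All RNG flows through explicit seeds via `withr::with_seed()`; no
  global RNG state is disturbed, and two runs with equal seeds are
  bit-identical.

## Validation scale

The packaged validation (tests and `scripts/acceptance.R`) runs entirely
on simulated data at sizes chosen to exercise every code path at desk
scale: the 99-point noiseless recovery grid; 100 noise replicates of a
$16^3$ two-compartment phantom at SNR 50; a $24^3$-scale bipolar
injection/recovery study; the default 64 x 64 x 32 phantom for
segmentation fidelity; and a 60-subject simulated cohort (15 per ACR
category) for the end-to-end category separation.  Cohort-scale clinical
quantities (a specific Spearman rho against mammographic readings, kappa
between human readers, population medians) depend on a real patient
population and are not reproducible from simulation; the package instead
validates their qualitative counterparts — negative ordinal correlation,
strictly ordered category medians, all pairwise comparisons rejecting —
which the cohort generator guarantees by construction.

## Known limitations

* The single-$T_2^*$ model is the stated acquisition model; tissues where
  water and fat decay very differently will bias PDFF slightly.
* Magnitude-based PDFF discards the fitted common phase; at very low SNR
  the magnitude operation itself biases amplitudes (visible in the
  SNR-10 arm of the noise study).
* The parity-phase model is constant + linear along the readout; higher
  order eddy-current terms are not modelled (nor simulated).
* The field-map relaxation assumes spatial smoothness; discontinuous
  susceptibility boundaries (metal, air pockets inside tissue) can still
  swap locally.
* Segmentation assumes the border delineation separates breast from
  thorax once densified; grossly misplaced annotations fail loudly (the
  "border does not separate" error) rather than silently.
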