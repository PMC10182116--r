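# breastpdff

Quantitative breast density from chemical-shift-encoded water-fat MRI, in
R.  The package is aimed at quantitative-MRI researchers and biostatistics
teams who want a fully scripted, testable path from multi-echo
gradient-echo data to per-breast density summaries and cohort-level
statistics — plus a digital phantom simulator with exact ground truth, so
the whole pipeline can be validated without patient data.

## What it computes

The proton density fat fraction (PDFF) is the fraction of MR-visible
protons in a voxel that belong to triglyceride:

```
PDFF = 100 * F / (W + F)   [percent]
```

where `W` and `F` are the water and fat magnitudes of the multi-echo
signal model

```
s_n = (W + F * c_n) * exp(i (phi0 + 2 pi psi t_n)) * exp(-t_n R2*),
c_n = sum_p a_p exp(i 2 pi f_p t_n)
```

with a pre-calibrated multi-peak fat spectrum (7 peaks by default), a
single T2* decay shared by water and fat, and the B0 off-resonance `psi`
(the field map).  Fitting is by variable projection: `W, F` are solved
linearly at each `(psi, R2*)` iterate, the field map is initialised by a
grid search with spatial-consistency relaxation (the water-fat-swap
safeguard), and bipolar readout phase errors can be estimated and removed
first.  A dense breast has low whole-breast PDFF; an almost entirely
fatty one is near 90%.

Downstream, the semi-automated segmentation reproduces the standard
workflow: k-means tissue clustering of the field of view, densification of
a manual pectoralis-border delineation drawn on every second slice,
centroid-seeded isolation of the left and right breast, and fibroglandular
tissue (FGT) segmentation as the water-dominant breast voxels with PDFF
below a 20% fat-concentration cutoff.  Cohort statistics cover Spearman
correlation against ordinal ACR density grades, Kruskal-Wallis with
Holm-adjusted pairwise rank-sum tests (exact permutation p-values at small
n), Cohen's kappa, ICC(2,1) and paired t / chi-squared auxiliary tests.

## Worked example

Simulate a phantom acquisition, fit it, segment it, and compare against
the built-in ground truth:

```r
library(breastpdff)

res <- process_subject(phantom_spec(seed = 7))   # 64 x 64 x 32, SNR 50
res$summary
#>   subject_id  side mean_pdff_breast mean_pdff_fgt mean_t2star_fgt n_breast_vox n_fgt_vox
#> 1      seed7  left         77.70483      6.032530        22.14914        10458      1530
#> 2      seed7 right         77.71882      6.037714        22.18718        10498      1535

res$phantom$truth$summaries[, c("side", "mean_pdff_breast", "mean_pdff_fgt")]
#>    side mean_pdff_breast mean_pdff_fgt
#> 1  left         77.39463             6
#> 2 right         77.39463             6

dice_coefficient(res$seg$left_breast, res$phantom$truth$breast_left)
#> [1] 0.9773832

qc_report(res$maps)$pass
#> [1] TRUE
```

The recovered whole-breast mean PDFF (77.7%) sits within a third of a
percentage point of the mask-weighted ground truth (77.4%), the breast
mask overlaps the true breast at Dice 0.98, and the recovered FGT mean
PDFF and T2* (6.03%, 22.1 ms) match the simulated tissue values (6%,
22 ms).  `run_cohort()` scales the same pipeline over an ACR-graded
simulated cohort and returns the table that `cohort_report()` analyses.

A thin command-line wrapper for the same steps ships in
`inst/cli/breastpdff.R` (`simulate`, `fit`, `segment`, `stats`
subcommands).

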