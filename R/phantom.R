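# Digital two-breast phantom: parametric half-ellipsoid breasts (adipose
# shell with a fibroglandular core) anterior to a pectoralis slab, plus air.
# Geometry is parametric so ground-truth masks and summaries are exact.
#
# Label codes used in the ground truth: 0 air, 1 adipose, 2 fibroglandular,
# 3 pectoralis.

#' Default tissue parameters for the phantom
#'
#' PDFF (percent), T2* (ms) and relative proton density per compartment.
#' Adipose tissue is almost pure fat (PDFF near 90%), fibroglandular
#' tissue carries very low fat signal, and the pectoralis muscle behaves
#' like lean tissue.
#'
#' @return named list of per-compartment parameter lists.
#' @export
default_tissue_params <- function() {
  list(
    adipose     = list(pdff_percent = 90, t2star_ms = 30, proton_density = 1.0),
    fgt         = list(pdff_percent = 6,  t2star_ms = 22, proton_density = 1.0),
    pectoralis  = list(pdff_percent = 5,  t2star_ms = 25, proton_density = 0.9)
  )
}

#' Specification of a digital two-breast phantom
#'
#' @param grid_shape volume dimensions `(FH, AP, RL)`.
#' @param voxel_size_mm isotropic voxel size.
#' @param fgt_volume_fraction target fibroglandular volume fraction of each
#'   breast, in `[0, 1)`; realised within +/- 2 percentage points.
#' @param tissue_params per-compartment parameters, see
#'   [default_tissue_params()].
#' @param fieldmap_max_Hz maximum absolute off-resonance of the smooth
#'   second-order polynomial field map (Hz).
#' @param snr signal-to-noise ratio (first-echo adipose magnitude over the
#'   per-channel noise standard deviation); `Inf` for noiseless.
#' @param parity_phase bipolar parity phase error
#'   `c(constant_rad, linear_rad_per_voxel)` applied with the per-echo
#'   readout polarity (linear term along the centred RL coordinate).
#' @param seed integer seed governing all randomness of the phantom.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32), voxel_size_mm = 1.7,
                         fgt_volume_fraction = 0.15,
                         tissue_params = default_tissue_params(),
                         fieldmap_max_Hz = 60, snr = 50,
                         parity_phase = c(0, 0), seed = 1) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  stopifnot(fgt_volume_fraction >= 0, fgt_volume_fraction < 1)
  for (nm in c("adipose", "fgt", "pectoralis")) {
    p <- tissue_params[[nm]]
    if (is.null(p)) stop("tissue_params is missing compartment '", nm, "'")
    stopifnot(p$pdff_percent >= 0, p$pdff_percent <= 100,
              p$t2star_ms > 0, p$proton_density > 0)
  }
  stopifnot(fieldmap_max_Hz >= 0, snr > 0, length(parity_phase) == 2L)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 fgt_volume_fraction = fgt_volume_fraction,
                 tissue_params = tissue_params,
                 fieldmap_max_Hz = fieldmap_max_Hz, snr = snr,
                 parity_phase = as.numeric(parity_phase),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Compartment labels for the parametric geometry.
phantom_labels <- function(d) {
  ap0 <- floor(0.70 * d[2])          # last breast layer; slab starts at ap0+1
  fh <- slice.index(array(0L, d), 1)
  ap <- slice.index(array(0L, d), 2)
  rl <- slice.index(array(0L, d), 3)
  fh_c <- (d[1] + 1) / 2
  a <- 0.31 * d[1]; b <- 0.21 * d[3]; cc <- 0.60 * d[2]
  rl_l <- 0.27 * (d[3] + 1); rl_r <- 0.73 * (d[3] + 1)
  ell <- function(rc, s = 1) {
    ((fh - fh_c) / (s * a))^2 + ((ap - ap0) / (s * cc))^2 +
      ((rl - rc) / (s * b))^2 <= 1 & ap <= ap0
  }
  lab <- array(0L, d)
  lab[ap > ap0] <- 3L
  breast <- ell(rl_l) | ell(rl_r)
  lab[breast] <- 1L
  list(labels = lab, ell = ell, rl_l = rl_l, rl_r = rl_r, ap0 = ap0, rl = rl)
}

# Scale factor for the concentric fibroglandular core achieving the target
# volume fraction (monotone in s; bisection on voxel counts).
fgt_scale <- function(geom, target) {
  breast_n <- sum(geom$labels == 1L)
  frac <- function(s) {
    sum((geom$ell(geom$rl_l, s) | geom$ell(geom$rl_r, s)) & geom$labels == 1L) /
      breast_n
  }
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' Simulate a multi-echo phantom acquisition with ground truth
#'
#' Builds the compartment geometry, assigns per-voxel true PDFF, r2*,
#' proton density and a smooth second-order polynomial field map, then
#' evaluates the forward water-fat signal model at every voxel and echo.
#' Optionally injects a bipolar parity phase error and adds i.i.d. complex
#' circular Gaussian noise calibrated to the requested SNR.  Everything is
#' deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param acq an [acq_params()].
#' @param spectrum a [fat_spectrum()].
#' @return list of class `phantom` with elements `series`
#'   (an [echo_series()]) and `truth` (labels, true `pdff`, `r2star`,
#'   `fieldmap`, per-side breast/FGT masks, the pectoralis `interface`
#'   mask, realised FGT fractions and a per-side summary table).
#' @export
make_phantom <- function(spec, acq = default_acq(),
                         spectrum = default_fat_spectrum()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(acq, "acq_params"))
  d <- spec$grid_shape
  geom <- phantom_labels(d)
  lab <- geom$labels
  if (spec$fgt_volume_fraction > 0) {
    s <- fgt_scale(geom, spec$fgt_volume_fraction)
    core <- (geom$ell(geom$rl_l, s) | geom$ell(geom$rl_r, s)) & lab == 1L
    lab[core] <- 2L
  }

  tp <- spec$tissue_params
  pdff <- array(NA_real_, d); r2 <- array(0, d); pd <- array(0, d)
  assign_tissue <- function(code, p) {
    sel <- lab == code
    pdff[sel] <<- p$pdff_percent
    r2[sel] <<- 1 / p$t2star_ms
    pd[sel] <<- p$proton_density
  }
  assign_tissue(1L, tp$adipose)
  assign_tissue(2L, tp$fgt)
  assign_tissue(3L, tp$pectoralis)

  # smooth 2nd-order polynomial field map over normalised coordinates
  nrm <- function(i, n) 2 * (i - 1) / (n - 1) - 1
  u <- nrm(slice.index(array(0, d), 1), d[1])
  v <- nrm(slice.index(array(0, d), 2), d[2])
  w <- nrm(slice.index(array(0, d), 3), d[3])
  poly <- u + 0.5 * v + 0.8 * u^2 - 0.6 * w^2 + 0.4 * u * v
  fieldmap <- if (spec$fieldmap_max_Hz > 0) {
    spec$fieldmap_max_Hz * poly / max(abs(poly))
  } else array(0, d)

  W <- ifelse(is.na(pdff), 0, pd * (1 - pdff / 100))
  F_ <- ifelse(is.na(pdff), 0, pd * pdff / 100)
  cn <- fat_phasor(spectrum, acq)
  t_s <- echo_times_s(acq); t_ms <- acq$echo_times_ms
  nE <- n_echoes(acq)
  sig <- array(0i, dim = c(d, nE))
  for (n in seq_len(nE)) {
    sig[, , , n] <- (W + F_ * cn[n]) *
      exp(1i * 2 * pi * fieldmap * t_s[n]) * exp(-r2 * t_ms[n])
  }

  if (any(spec$parity_phase != 0)) {
    x <- geom$rl - (d[3] + 1) / 2
    phi <- spec$parity_phase[1] + spec$parity_phase[2] * x
    for (n in seq_len(nE)) {
      sig[, , , n] <- sig[, , , n] * exp(1i * acq$readout_polarity[n] * phi)
    }
  }

  adipose <- lab == 1L
  if (is.finite(spec$snr)) {
    sigma <- mean(Mod(sig[, , , 1])[adipose]) / spec$snr
    noise <- withr::with_seed(spec$seed, {
      complex(real = rnorm(length(sig), sd = sigma),
              imaginary = rnorm(length(sig), sd = sigma))
    })
    sig <- sig + array(noise, dim = dim(sig))
  }

  mid <- d[3] / 2
  left_side <- geom$rl <= mid
  breast <- lab == 1L | lab == 2L
  pect <- lab == 3L
  interface <- breast & shift_array(pect, -1L, 2L)
  fgt_all <- lab == 2L
  masks <- list(breast_left = breast & left_side,
                breast_right = breast & !left_side,
                fgt_left = fgt_all & left_side,
                fgt_right = fgt_all & !left_side)
  t2star <- ifelse(r2 > 0, 1 / r2, NA_real_)
  summarise_side <- function(side) {
    bm <- masks[[paste0("breast_", side)]]
    fm <- masks[[paste0("fgt_", side)]]
    data.frame(side = side,
               mean_pdff_breast = mean(pdff[bm]),
               mean_pdff_fgt = if (any(fm)) mean(pdff[fm]) else NA_real_,
               mean_t2star_fgt = if (any(fm)) mean(t2star[fm]) else NA_real_,
               n_breast_vox = sum(bm), n_fgt_vox = sum(fm),
               fgt_fraction = sum(fm) / sum(bm),
               stringsAsFactors = FALSE)
  }
  truth <- list(labels = lab, pdff = pdff, r2star = r2,
                fieldmap = fieldmap, interface = interface,
                breast_left = masks$breast_left, breast_right = masks$breast_right,
                fgt_left = masks$fgt_left, fgt_right = masks$fgt_right,
                summaries = rbind(summarise_side("left"), summarise_side("right")))
  structure(list(series = echo_series(sig, acq, spec$voxel_size_mm),
                 truth = truth, spec = spec),
            class = "phantom")
}

#' Flat two-compartment test phantom
#'
#' A cube split into two tissue slabs along the RL axis (no air), intended
#' for fitting-accuracy studies where segmentation is not involved.
#'
#' @param n edge length in voxels.
#' @param pdff_percent PDFF of the two compartments (percent).
#' @param t2star_ms T2* of the two compartments (ms).
#' @param fieldmap_Hz scalar, or 3D array, of true off-resonance.
#' @param snr SNR as in [phantom_spec()]; `Inf` for noiseless.
#' @param seed noise seed.
#' @param acq,spectrum acquisition and spectrum.
#' @return list with `series` and `truth` (`pdff`, `r2star`, `fieldmap`,
#'   `labels` 1/2).
#' @export
make_two_compartment <- function(n = 16, pdff_percent = c(90, 5),
                                 t2star_ms = c(30, 25), fieldmap_Hz = 0,
                                 snr = Inf, seed = 1, acq = default_acq(),
                                 spectrum = default_fat_spectrum()) {
  d <- c(n, n, n)
  rl <- slice.index(array(0L, d), 3)
  lab <- ifelse(rl <= n / 2, 1L, 2L)
  pdff <- array(pdff_percent[lab], d)
  r2 <- array(1 / t2star_ms[lab], d)
  fieldmap <- if (length(fieldmap_Hz) == 1L) array(fieldmap_Hz, d)
              else array(fieldmap_Hz, d)
  W <- 1 - pdff / 100; F_ <- pdff / 100
  cn <- fat_phasor(spectrum, acq)
  t_s <- echo_times_s(acq); t_ms <- acq$echo_times_ms
  nE <- n_echoes(acq)
  sig <- array(0i, dim = c(d, nE))
  for (k in seq_len(nE)) {
    sig[, , , k] <- (W + F_ * cn[k]) *
      exp(1i * 2 * pi * fieldmap * t_s[k]) * exp(-r2 * t_ms[k])
  }
  if (is.finite(snr)) {
    sigma <- mean(Mod(sig[, , , 1])) / snr
    noise <- withr::with_seed(seed, {
      complex(real = rnorm(length(sig), sd = sigma),
              imaginary = rnorm(length(sig), sd = sigma))
    })
    sig <- sig + array(noise, dim = dim(sig))
  }
  list(series = echo_series(sig, acq, 1.7),
       truth = list(pdff = pdff, r2star = r2, fieldmap = fieldmap, labels = lab))
}

#' Simulate a manual border delineation
#'
#' Extracts the pectoralis-parenchyma interface from the ground truth on
#' every `every_k_slices`-th axial slice and perturbs each annotated voxel
#' by bounded random jitter along the AP axis, emulating an operator
#' drawing the border on a subset of slices.
#'
#' @param truth the `truth` element of a [make_phantom()] result.
#' @param every_k_slices draw on every k-th slice (default 2).
#' @param jitter_voxels maximum AP displacement per voxel (default 1).
#' @param seed jitter seed.
#' @return a [border_delineation()].
#' @export
make_delineation <- function(truth, every_k_slices = 2, jitter_voxels = 1,
                             seed = 1) {
  interface <- truth$interface
  if (is.null(interface) || !any(interface)) {
    stop("ground truth has no pectoralis interface")
  }
  d <- dim(interface)
  if (every_k_slices > d[1]) stop("every_k_slices exceeds the slice count")
  slices <- which(apply(interface, 1, any))
  drawn <- slices[seq(1, length(slices), by = every_k_slices)]
  mask <- array(FALSE, d)
  vox <- mask_coords(interface)
  vox <- vox[vox[, 1] %in% drawn, , drop = FALSE]
  jit <- if (jitter_voxels > 0) {
    withr::with_seed(seed,
      sample(seq(-jitter_voxels, jitter_voxels), nrow(vox), replace = TRUE))
  } else rep(0L, nrow(vox))
  ap <- pmin(pmax(vox[, 2] + jit, 1L), d[2])
  mask[cbind(vox[, 1], ap, vox[, 3])] <- TRUE
  border_delineation(mask, drawn)
}

#' Simulate an ACR-graded phantom cohort
#'
#' Samples one phantom specification per subject with fibroglandular
#' volume fractions drawn from non-overlapping per-category ranges
#' (defaults: A 0.02-0.08, B 0.10-0.25, C 0.30-0.50, D 0.55-0.75 — design
#' values chosen to emulate the four ACR density grades), adipose PDFF
#' from a truncated Normal(90, 2) on \[80, 98\]%, fibroglandular PDFF from
#' Uniform(3, 10)% (fibroglandular tissue carries 0-10% fat signal),
#' fibroglandular T2* increasing mildly with density category (20 to 25
#' ms), and age increasing with the adipose fraction.  Visual ACR readings
#' by two mammography and two MRI readers are simulated from the true
#' category with an adjacent-category error probability.
#'
#' @param n_per_category subjects per ACR category (>= 1).
#' @param density_ranges named list `A`..`D` of `c(lo, hi)` fibroglandular
#'   volume-fraction ranges; must be disjoint and increasing.
#' @param grid_shape,snr passed to each [phantom_spec()].
#' @param reader_error adjacent-category mis-grading probability for
#'   `c(mammo, mri)` readers.
#' @param seed master seed; per-subject phantom seeds are derived from it.
#' @return list with `specs` (list of [phantom_spec()]) and `truth`
#'   (data.frame with true category, sampled tissue parameters, expected
#'   mask-weighted summaries and simulated reader categories).
#' @export
make_cohort <- function(n_per_category = 15,
                        density_ranges = list(A = c(0.02, 0.08),
                                              B = c(0.10, 0.25),
                                              C = c(0.30, 0.50),
                                              D = c(0.55, 0.75)),
                        grid_shape = c(64, 64, 32), snr = 50,
                        reader_error = c(mammo = 0.2, mri = 0.15),
                        seed = 1) {
  stopifnot(n_per_category >= 1)
  cats <- c("A", "B", "C", "D")
  stopifnot(setequal(names(density_ranges), cats))
  rg <- do.call(rbind, density_ranges[cats])
  if (any(rg[, 1] >= rg[, 2]) || any(diff(as.vector(t(rg))) <= 0)) {
    stop("density ranges must be increasing and non-overlapping A -> D")
  }
  fgt_t2s_base <- c(A = 20, B = 21.7, C = 23.3, D = 25)

  n_tot <- 4L * n_per_category
  cat_i <- rep(cats, each = n_per_category)
  draws <- withr::with_seed(as.integer(seed), {
    fgt_frac <- runif(n_tot, rg[cat_i, 1], rg[cat_i, 2])
    ad_pdff <- vapply(seq_len(n_tot), function(i) {
      repeat {
        x <- rnorm(1, 90, 2)
        if (x >= 80 && x <= 98) return(x)
      }
    }, numeric(1))
    fgt_pdff <- runif(n_tot, 3, 10)
    fgt_t2s <- fgt_t2s_base[cat_i] + runif(n_tot, -0.8, 0.8)
    ad_t2s <- 30 + runif(n_tot, -2, 2)
    age <- round(pmin(81, pmax(29, 30 + 28 * (1 - fgt_frac) + rnorm(n_tot, 0, 4))))
    read_cat <- function(true, p_err) {
      vapply(true, function(tc) {
        k <- match(tc, cats)
        if (runif(1) < p_err) {
          opts <- intersect(c(k - 1, k + 1), 1:4)
          k <- if (length(opts) == 1) opts else sample(opts, 1)
        }
        cats[k]
      }, character(1))
    }
    list(fgt_frac = fgt_frac, ad_pdff = ad_pdff, fgt_pdff = fgt_pdff,
         fgt_t2s = fgt_t2s, ad_t2s = ad_t2s, age = age,
         mam1 = read_cat(cat_i, reader_error[[1]]),
         mam2 = read_cat(cat_i, reader_error[[1]]),
         mri1 = read_cat(cat_i, reader_error[[2]]),
         mri2 = read_cat(cat_i, reader_error[[2]]))
  })

  base_seed <- as.integer(seed) %% 100000L
  specs <- lapply(seq_len(n_tot), function(i) {
    tp <- default_tissue_params()
    tp$adipose$pdff_percent <- draws$ad_pdff[i]
    tp$adipose$t2star_ms <- draws$ad_t2s[i]
    tp$fgt$pdff_percent <- draws$fgt_pdff[i]
    tp$fgt$t2star_ms <- draws$fgt_t2s[i]
    phantom_spec(grid_shape = grid_shape,
                 fgt_volume_fraction = draws$fgt_frac[i],
                 tissue_params = tp, snr = snr,
                 seed = base_seed * 1000L + i)
  })
  truth <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_tot)),
    acr_true = cat_i,
    fgt_volume_fraction = draws$fgt_frac,
    adipose_pdff = draws$ad_pdff,
    fgt_pdff = draws$fgt_pdff,
    fgt_t2star_ms = unname(draws$fgt_t2s),
    age_years = draws$age,
    mean_pdff_breast_expected =
      (1 - draws$fgt_frac) * draws$ad_pdff + draws$fgt_frac * draws$fgt_pdff,
    mean_pdff_fgt_expected = draws$fgt_pdff,
    acr_mammo_reader1 = draws$mam1,
    acr_mammo_reader2 = draws$mam2,
    acr_mri_reader1 = draws$mri1,
    acr_mri_reader2 = draws$mri2,
    stringsAsFactors = FALSE
  )
  list(specs = specs, truth = truth)
}
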