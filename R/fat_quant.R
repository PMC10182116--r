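#' Configuration for volume water-fat fitting
#'
#' @param correct_bipolar apply [correct_bipolar_phase()] before fitting.
#'   Off by default: the correction is an acquisition-specific
#'   preprocessing step that callers enable when parity phase errors are
#'   expected.
#' @param psi_step_Hz field-map grid spacing (Hz).
#' @param r2_grid_per_ms r2* values probed during the grid stage (1/ms).
#' @param r2_max_per_ms upper bound for r2* in the refinement (1/ms).
#' @param psi_refine_halfwidth_Hz half-width of the local psi search around
#'   the field-map initialisation; defaults to 1.5 grid steps.
#' @param tol relative residual-decrease convergence tolerance.
#' @param max_iter maximum alternating iterations per voxel.
#' @param background_factor the background threshold is this multiple of
#'   the mean first-echo magnitude of the lowest k-means intensity cluster.
#' @param fieldmap_smooth_iters,fieldmap_smooth_radius,n_fieldmap_candidates
#'   spatial-consistency settings passed to [fieldmap_init()].
#' @param seed seed for the k-means background clustering.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(correct_bipolar = FALSE,
                       psi_step_Hz = 10,
                       r2_grid_per_ms = c(0.02, 0.08),
                       r2_max_per_ms = 0.5,
                       psi_refine_halfwidth_Hz = NULL,
                       tol = 1e-8,
                       max_iter = 100,
                       background_factor = 2,
                       fieldmap_smooth_iters = 4,
                       fieldmap_smooth_radius = 2,
                       n_fieldmap_candidates = 4,
                       seed = 1) {
  if (is.null(psi_refine_halfwidth_Hz)) psi_refine_halfwidth_Hz <- 1.5 * psi_step_Hz
  structure(as.list(environment()), class = "fit_config")
}

# Top-K local minima of per-voxel psi residual profiles (n_psi x V).
# Returns V x K matrices of candidate frequencies and residuals (Inf when a
# voxel has fewer than K local minima).
top_local_minima <- function(prof, psi_grid, K) {
  P <- nrow(prof); V <- ncol(prof)
  up <- prof[c(1, seq_len(P - 1)), , drop = FALSE]; up[1, ] <- Inf
  dn <- prof[c(seq_len(P - 1) + 1, P), , drop = FALSE]; dn[P, ] <- Inf
  masked <- prof
  masked[!(prof <= up & prof <= dn)] <- Inf
  tP <- t(masked)
  cand_psi <- matrix(psi_grid[1], V, K)
  cand_res <- matrix(Inf, V, K)
  for (k in seq_len(K)) {
    j <- max.col(-tP, ties.method = "first")
    cand_psi[, k] <- psi_grid[j]
    cand_res[, k] <- tP[cbind(seq_len(V), j)]
    tP[cbind(seq_len(V), j)] <- Inf
  }
  list(psi = cand_psi, res = cand_res)
}

# Foreground detection: k-means (k = 3) on the first-echo magnitude; the
# threshold is `factor` times the mean magnitude of the lowest cluster.
background_mask <- function(mag, factor = 2, seed = 1) {
  v <- as.vector(mag)
  if (length(unique(v)) < 3L) {
    return(array(v > 0, dim = dim(mag)))
  }
  km <- withr::with_seed(seed, kmeans(v, centers = 3, nstart = 5, iter.max = 100,
                                    algorithm = "MacQueen"))
  lo <- which.min(km$centers)
  # when the lowest cluster is not clearly darker than the brightest one the
  # volume has no air background; keep every non-zero voxel
  if (min(km$centers) > 0.3 * max(km$centers)) {
    return(array(v > 0, dim = dim(mag)))
  }
  thr <- factor * mean(v[km$cluster == lo])
  array(v > thr, dim = dim(mag))
}

#' Proton density fat fraction from water/fat magnitudes
#'
#' `PDFF = 100 * fat / (water + fat)` percent.  Voxels where both inputs
#' are zero are undefined and returned as `NA` (callers flag them).
#'
#' @param water_mag,fat_mag non-negative magnitudes (scalars or arrays of
#'   identical shape).
#' @return PDFF in percent, in `[0, 100]`; `NA` where both inputs vanish.
#' @examples
#' compute_pdff(20, 80)  # 80
#' @export
compute_pdff <- function(water_mag, fat_mag) {
  if (any(water_mag < 0, na.rm = TRUE) || any(fat_mag < 0, na.rm = TRUE)) {
    stop("magnitudes must be non-negative")
  }
  tot <- water_mag + fat_mag
  out <- ifelse(tot > 0, 100 * fat_mag / tot, NA_real_)
  if (!is.null(dim(water_mag))) out <- array(out, dim = dim(water_mag))
  out
}

#' Field-map initialisation by grid search with spatial consistency
#'
#' Evaluates the variable-projection residual on a grid of candidate
#' off-resonance frequencies (minimised over a small r2* grid), extracts
#' the local minima of each voxel's residual profile, and resolves the
#' water-fat ambiguity by iteratively re-selecting, for every voxel, the
#' candidate that balances its residual against closeness to the
#' magnitude-weighted neighbourhood mean.  The first pass seeds every voxel
#' with its global residual minimum, which is reliable in high-SNR voxels
#' and then propagates spatially, yielding a smooth field-map estimate.
#'
#' @param series an [echo_series()].
#' @param spectrum a [fat_spectrum()].
#' @param psi_grid candidate frequencies (Hz); must span at least
#'   +/- 1/(2 dTE).  Default: 10 Hz spacing over that range.
#' @param mask logical foreground mask; defaults to all non-zero voxels.
#' @param r2_grid_per_ms r2* values probed (1/ms).
#' @param n_candidates number of residual local minima retained per voxel.
#' @param smooth_iters,smooth_radius,smooth_weight spatial-consistency
#'   iterations, neighbourhood half-width (voxels) and penalty weight.
#' @return 3D array of field-map estimates (Hz, grid-valued; 0 outside the
#'   mask), with attributes `grid_step` and `mask`.
#' @export
fieldmap_init <- function(series, spectrum, psi_grid = NULL, mask = NULL,
                          r2_grid_per_ms = c(0.02, 0.08),
                          n_candidates = 4, smooth_iters = 4,
                          smooth_radius = 2, smooth_weight = 0.5) {
  stopifnot(inherits(series, "echo_series"), inherits(spectrum, "fat_spectrum"))
  acq <- series$acq
  if (n_echoes(acq) < 3L) stop("field-map estimation needs at least 3 echoes")
  d <- dim(series$data)[1:3]
  dte_s <- min(diff(echo_times_s(acq)))
  half <- 1 / (2 * dte_s)
  if (is.null(psi_grid)) {
    step <- 10
    half_c <- ceiling(half / step) * step
    psi_grid <- seq(-half_c, half_c, by = step)
  }
  psi_grid <- sort(as.numeric(psi_grid))
  if (max(psi_grid) < half * 0.999 || min(psi_grid) > -half * 0.999) {
    stop("psi_grid must span at least +/- 1/(2 dTE) = +/- ",
         format(half, digits = 5), " Hz")
  }
  mag <- sqrt(apply(abs(series$data)^2, 1:3, sum))
  if (is.null(mask)) mask <- mag > 0
  if (!any(mask)) stop("no signal: field map cannot be estimated")

  S <- signal_matrix(series, mask)
  cn <- fat_phasor(spectrum, acq)
  g <- varpro_grid_cpp(S, echo_times_s(acq), acq$echo_times_ms, cn,
                       psi_grid, r2_grid_per_ms, profile = TRUE)
  prof <- g$profile                      # n_psi x V
  P <- nrow(prof); V <- ncol(prof)
  energy <- pmax(as.numeric(g$energy), .Machine$double.xmin)

  K <- max(1L, n_candidates)
  cand <- top_local_minima(prof, psi_grid, K)
  cand_psi <- cand$psi
  cand_res <- cand$res

  psi_hat <- cand_psi[, 1]
  w <- sqrt(energy)
  span <- max(psi_grid) - min(psi_grid)
  midx <- which(mask)
  for (it in seq_len(smooth_iters)) {
    psi_full <- array(0, dim = d); psi_full[midx] <- psi_hat
    w_full <- array(0, dim = d); w_full[midx] <- w
    ref <- box_mean_weighted(psi_full, w_full, smooth_radius)[midx]
    score <- cand_res / energy +
      smooth_weight * abs(cand_psi - ref) / span
    pick <- max.col(-score, ties.method = "first")
    psi_hat <- cand_psi[cbind(seq_len(V), pick)]
  }

  out <- array(0, dim = d)
  out[midx] <- psi_hat
  attr(out, "grid_step") <- if (P > 1) min(diff(psi_grid)) else NA_real_
  attr(out, "mask") <- mask
  out
}

#' Fit the water-fat model in a single voxel
#'
#' Variable-projection nonlinear least squares over (psi, r2*) with the
#' complex water/fat amplitudes solved linearly at each iterate.  When
#' `psi_init` is missing, a full-range grid search is run first and the two
#' best separated residual minima are refined, keeping the lower one (this
#' resolves the water-fat ambiguity in isolated voxels).  Initialising on
#' the aliased branch instead reproduces the documented water-fat swap.
#'
#' @param signal complex vector, one value per echo.
#' @param acq an [acq_params()].
#' @param spectrum a [fat_spectrum()].
#' @param psi_init optional field-map initialisation (Hz).
#' @param r2_init initial r2* (1/ms).
#' @param config a [fit_config()].
#' @return a list with the estimated `water_amp`, `fat_amp`,
#'   `common_phase_rad`, `fieldmap_Hz`, `r2star_per_ms`, `pdff_percent`,
#'   the fit `resid`, and logical `converged` / `flagged`.
#' @export
fit_voxel <- function(signal, acq, spectrum, psi_init = NULL, r2_init = 0.05,
                      config = fit_config()) {
  stopifnot(inherits(acq, "acq_params"), inherits(spectrum, "fat_spectrum"))
  signal <- as.complex(signal)
  if (length(signal) != n_echoes(acq)) stop("signal length must equal echo count")
  if (n_echoes(acq) < 3L) stop("fitting needs at least 3 echoes")
  if (any(!is.finite(Re(signal))) || any(!is.finite(Im(signal)))) {
    stop("signal must be finite")
  }
  if (all(Mod(signal) == 0)) {
    return(list(water_amp = 0, fat_amp = 0, common_phase_rad = 0,
                fieldmap_Hz = 0, r2star_per_ms = 0, pdff_percent = NA_real_,
                resid = 0, converged = FALSE, flagged = TRUE))
  }
  S <- matrix(signal, ncol = 1)
  t_s <- echo_times_s(acq); t_ms <- acq$echo_times_ms
  cn <- fat_phasor(spectrum, acq)
  hw <- config$psi_refine_halfwidth_Hz

  refine_from <- function(psi0) {
    varpro_refine_cpp(S, t_s, t_ms, cn, psi0, r2_init,
                      hw, config$r2_max_per_ms, config$tol, config$max_iter,
                      psi_tol = 1e-8, r2_tol = 1e-11)
  }

  if (is.null(psi_init)) {
    dte_s <- min(diff(t_s))
    half <- ceiling(1 / (2 * dte_s) / config$psi_step_Hz) * config$psi_step_Hz
    psi_grid <- seq(-half, half, by = config$psi_step_Hz)
    g <- varpro_grid_cpp(S, t_s, t_ms, cn, psi_grid, config$r2_grid_per_ms,
                         profile = TRUE)
    prof <- g$profile[, 1]
    P <- length(prof)
    up <- c(Inf, prof[-P]); dn <- c(prof[-1], Inf)
    is_min <- prof <= up & prof <= dn
    ord <- order(ifelse(is_min, prof, Inf))
    starts <- psi_grid[ord[seq_len(min(2L, sum(is_min)))]]
    fits <- lapply(starts, refine_from)
    best <- fits[[which.min(vapply(fits, function(f) f$resid[1], numeric(1)))]]
  } else {
    best <- refine_from(psi_init)
  }

  W <- best$water[1]; F_ <- best$fat[1]
  wamp <- Mod(W); famp <- Mod(F_)
  phase <- if (wamp + famp > 0) Arg(W + F_) else 0
  list(water_amp = wamp, fat_amp = famp, common_phase_rad = phase,
       fieldmap_Hz = best$psi_Hz[1], r2star_per_ms = best$r2star_per_ms[1],
       pdff_percent = compute_pdff(wamp, famp),
       resid = best$resid[1], converged = best$converged[1] == 1L,
       flagged = FALSE)
}

#' Fit PDFF / T2* maps over a whole volume
#'
#' Pipeline: optional bipolar phase-error correction, background masking
#' (k-means on the first-echo magnitude), field-map initialisation
#' ([fieldmap_init()]), per-voxel variable-projection refinement, then
#' PDFF computation.  Background voxels are excluded and flagged with QC
#' code 2; non-convergent voxels carry code 1.
#'
#' @param series an [echo_series()].
#' @param spectrum a [fat_spectrum()].
#' @param config a [fit_config()].
#' @return an object of class `quant_maps`: 3D arrays `pdff_percent`
#'   (percent, `NA` where flagged 2), `r2star_per_ms`, `t2star_ms` (`NA`
#'   where r2* < 1e-6/ms), `fieldmap_Hz`, `water_mag`, `fat_mag`,
#'   `qc_flags` (0 ok / 1 non-convergent / 2 excluded) and the logical
#'   `foreground` mask.
#' @export
fit_volume <- function(series, spectrum, config = fit_config()) {
  stopifnot(inherits(series, "echo_series"), inherits(spectrum, "fat_spectrum"))
  if (n_echoes(series$acq) < 3L) stop("fitting needs at least 3 echoes")
  if (isTRUE(config$correct_bipolar)) {
    series <- correct_bipolar_phase(series)
  }
  acq <- series$acq
  d <- dim(series$data)[1:3]
  mag1 <- abs(series$data[, , , 1, drop = TRUE])
  dim(mag1) <- d
  fg <- background_mask(mag1, config$background_factor, config$seed)

  empty <- function() {
    na <- array(NA_real_, dim = d); z <- array(0, dim = d)
    structure(list(pdff_percent = na, r2star_per_ms = z, t2star_ms = na,
                   fieldmap_Hz = z, water_mag = z, fat_mag = z,
                   qc_flags = array(2L, dim = d),
                   foreground = array(FALSE, dim = d),
                   acq = acq, voxel_size_mm = series$voxel_size_mm),
              class = "quant_maps")
  }
  if (!any(fg)) return(empty())

  psi0_map <- fieldmap_init(series, spectrum, mask = fg,
                            r2_grid_per_ms = config$r2_grid_per_ms,
                            n_candidates = config$n_fieldmap_candidates,
                            smooth_iters = config$fieldmap_smooth_iters,
                            smooth_radius = config$fieldmap_smooth_radius)
  S <- signal_matrix(series, fg)
  cn <- fat_phasor(spectrum, acq)
  idx <- which(fg)
  fit <- varpro_refine_cpp(S, echo_times_s(acq), acq$echo_times_ms, cn,
                           psi0_map[idx], rep(0.05, length(idx)),
                           config$psi_refine_halfwidth_Hz,
                           config$r2_max_per_ms, config$tol, config$max_iter,
                           psi_tol = 1e-4, r2_tol = 1e-7)

  wmag <- Mod(fit$water); fmag <- Mod(fit$fat)
  pdff_v <- compute_pdff(wmag, fmag)
  pdff_v <- pmin(pmax(pdff_v, 0), 100)
  qc_v <- ifelse(fit$converged == 1L, 0L, 1L)
  qc_v[wmag + fmag <= 0] <- 2L
  pdff_v[qc_v == 2L] <- NA_real_

  na <- array(NA_real_, dim = d); z <- array(0, dim = d)
  maps <- list(pdff_percent = na, r2star_per_ms = z, t2star_ms = na,
               fieldmap_Hz = z, water_mag = z, fat_mag = z,
               qc_flags = array(2L, dim = d), foreground = fg,
               acq = acq, voxel_size_mm = series$voxel_size_mm)
  maps$pdff_percent[idx] <- pdff_v
  maps$r2star_per_ms[idx] <- fit$r2star_per_ms
  maps$t2star_ms[idx] <- ifelse(fit$r2star_per_ms >= 1e-6,
                                1 / fit$r2star_per_ms, NA_real_)
  maps$fieldmap_Hz[idx] <- fit$psi_Hz
  maps$water_mag[idx] <- wmag
  maps$fat_mag[idx] <- fmag
  maps$qc_flags[idx] <- qc_v
  structure(maps, class = "quant_maps")
}

#' @export
print.quant_maps <- function(x, ...) {
  d <- dim(x$pdff_percent)
  fg <- sum(x$foreground)
  cat(sprintf("quant_maps: %d x %d x %d voxels, %d foreground (%.1f%%)\n",
              d[1], d[2], d[3], fg, 100 * fg / prod(d)))
  if (fg > 0) {
    ok <- x$qc_flags == 0L & x$foreground
    cat(sprintf("  PDFF over qc=0 voxels: median %.1f%% (n = %d)\n",
                median(x$pdff_percent[ok]), sum(ok)))
  }
  invisible(x)
}

#' Dataset-level quality-control report
#'
#' Screens a fitted dataset the way failing phase correction shows up in
#' practice: as a large fraction of flagged or out-of-range voxels within
#' the foreground.  The dataset fails when the flagged fraction exceeds
#' `threshold`.
#'
#' @param maps a `quant_maps` object from [fit_volume()].
#' @param threshold maximum tolerated flagged fraction of the foreground
#'   (default 0.2).
#' @return a list with `fraction_flagged`, `fraction_out_of_range`,
#'   `n_foreground` and logical `pass`.
#' @export
qc_report <- function(maps, threshold = 0.2) {
  stopifnot(inherits(maps, "quant_maps"))
  fg <- maps$foreground
  n_fg <- sum(fg)
  if (n_fg == 0) {
    return(list(fraction_flagged = 1, fraction_out_of_range = 1,
                n_foreground = 0L, pass = FALSE))
  }
  qc <- maps$qc_flags[fg]
  frac_fl <- mean(qc != 0L)
  frac_oor <- mean(qc == 2L)
  list(fraction_flagged = frac_fl, fraction_out_of_range = frac_oor,
       n_foreground = n_fg, pass = frac_fl <= threshold)
}
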