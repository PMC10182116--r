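#' Run the full quantification + segmentation pipeline on one phantom
#'
#' Simulates the acquisition ([make_phantom()]), fits PDFF / T2* maps
#' ([fit_volume()]), simulates the sparse manual border delineation
#' ([make_delineation()]), and runs the segmentation workflow
#' ([cluster_tissues()], [densify_border()], [breast_centroids()],
#' [isolate_breasts()], [segment_fibroglandular()], [summarize_breast()]),
#' asserting the containment/disjointness invariants on every run.
#'
#' @param spec a [phantom_spec()].
#' @param acq,spectrum acquisition and fat spectrum.
#' @param config a [fit_config()].
#' @param every_k_slices,jitter_voxels delineation simulation settings.
#' @param cutoff_percent fibroglandular fat-concentration cutoff.
#' @param dilation_radius border dilation radius (voxels).
#' @param anterior_offset centroid anterior displacement (voxels).
#' @return list with the `phantom`, fitted `maps`, `tissue_labels`,
#'   `border`, `centroids`, segmentation masks (`seg`, `fgt_left`,
#'   `fgt_right`) and the two-row per-breast `summary` table.
#' @export
process_subject <- function(spec, acq = default_acq(),
                            spectrum = default_fat_spectrum(),
                            config = fit_config(),
                            every_k_slices = 2, jitter_voxels = 1,
                            cutoff_percent = 20, dilation_radius = 2,
                            anterior_offset = 10) {
  ph <- make_phantom(spec, acq, spectrum)
  maps <- fit_volume(ph$series, spectrum, config)
  delin <- make_delineation(ph$truth, every_k_slices, jitter_voxels,
                            seed = spec$seed + 500L)
  border <- densify_border(delin, dilation_radius)
  cents <- breast_centroids(delin, anterior_offset)
  labels <- cluster_tissues(maps$fat_mag, maps$water_mag, seed = spec$seed)
  iso <- isolate_breasts(labels, border, cents)
  fgt_l <- suppressWarnings(
    segment_fibroglandular(iso$left_breast, labels, maps$pdff_percent,
                           cutoff_percent))
  fgt_r <- suppressWarnings(
    segment_fibroglandular(iso$right_breast, labels, maps$pdff_percent,
                           cutoff_percent))
  check_segmentation_invariants(iso, fgt_l, fgt_r, labels)
  sid <- sprintf("seed%d", spec$seed)
  summary <- rbind(
    summarize_breast(iso$left_breast, fgt_l, maps$pdff_percent,
                     maps$t2star_ms, maps$qc_flags, sid, "left"),
    summarize_breast(iso$right_breast, fgt_r, maps$pdff_percent,
                     maps$t2star_ms, maps$qc_flags, sid, "right"))
  list(phantom = ph, maps = maps, tissue_labels = labels, border = border,
       centroids = cents, seg = iso, fgt_left = fgt_l, fgt_right = fgt_r,
       summary = summary)
}

# Containment / disjointness invariants of the segmentation set.
check_segmentation_invariants <- function(iso, fgt_l, fgt_r, labels) {
  fg <- labels != TISSUE_BACKGROUND
  stopifnot(
    all(!fgt_l | iso$left_breast),
    all(!fgt_r | iso$right_breast),
    all(!iso$left_breast | fg),
    all(!iso$right_breast | fg),
    !any(iso$left_breast & iso$right_breast),
    !any((iso$left_breast | iso$right_breast) & iso$border$sheet)
  )
  invisible(TRUE)
}

#' Run the pipeline over a simulated cohort
#'
#' Processes every phantom of a [make_cohort()] result and assembles the
#' cohort table: simulated reader categories and sampled truth joined with
#' the recovered per-subject summaries (`mean_pdff_breast`,
#' `mean_pdff_fgt`, `mean_t2star_fgt` for the analysis side, plus
#' left/right columns for reliability analyses).
#'
#' @param cohort result of [make_cohort()].
#' @param side analysis side per subject, `"left"` or `"right"`.
#' @param verbose print one line per subject.
#' @inheritParams process_subject
#' @return cohort `data.frame`, one row per subject.
#' @export
run_cohort <- function(cohort, acq = default_acq(),
                       spectrum = default_fat_spectrum(),
                       config = fit_config(), side = "left",
                       every_k_slices = 2, jitter_voxels = 1,
                       cutoff_percent = 20, verbose = FALSE) {
  stopifnot(side %in% c("left", "right"))
  rows <- vector("list", length(cohort$specs))
  for (i in seq_along(cohort$specs)) {
    res <- process_subject(cohort$specs[[i]], acq, spectrum, config,
                           every_k_slices, jitter_voxels, cutoff_percent)
    s <- res$summary
    tr <- res$phantom$truth$summaries
    pick <- function(df, sd_, col) df[df$side == sd_, col]
    rows[[i]] <- data.frame(
      mean_pdff_breast = pick(s, side, "mean_pdff_breast"),
      mean_pdff_fgt = pick(s, side, "mean_pdff_fgt"),
      mean_t2star_fgt = pick(s, side, "mean_t2star_fgt"),
      mean_pdff_breast_left = pick(s, "left", "mean_pdff_breast"),
      mean_pdff_breast_right = pick(s, "right", "mean_pdff_breast"),
      n_breast_vox = pick(s, side, "n_breast_vox"),
      n_fgt_vox = pick(s, side, "n_fgt_vox"),
      true_mean_pdff_breast = pick(tr, side, "mean_pdff_breast"),
      true_mean_pdff_fgt = pick(tr, side, "mean_pdff_fgt"),
      true_mean_t2star_fgt = pick(tr, side, "mean_t2star_fgt")
    )
    if (verbose) {
      message(sprintf("subject %d/%d: breast PDFF %.1f%% (true %.1f%%)",
                      i, length(cohort$specs),
                      rows[[i]]$mean_pdff_breast, rows[[i]]$true_mean_pdff_breast))
    }
  }
  cbind(cohort$truth, side = side, do.call(rbind, rows))
}
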