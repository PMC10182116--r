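# Semi-automated breast segmentation workflow:
#   k-means tissue clustering -> densified manual border -> per-side
#   centroids -> connected-component breast isolation -> fibroglandular
#   segmentation by water-dominance and a fat-concentration cutoff.
#
# Tissue label codes: 0 = background, 1 = water_dominant, 2 = fat_dominant.

TISSUE_BACKGROUND <- 0L
TISSUE_WATER <- 1L
TISSUE_FAT <- 2L

#' Manual border delineation
#'
#' A sparse manual delineation of the pectoralis-parenchyma interface,
#' drawn on a subset of axial (constant-FH) slices.
#'
#' @param mask 3D logical volume of annotated voxels.
#' @param drawn_slices FH slice indices carrying annotations; defaults to
#'   the slices where `mask` is non-empty.
#' @return an object of class `border_delineation`.
#' @export
border_delineation <- function(mask, drawn_slices = NULL) {
  stopifnot(length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim = dim(mask))
  with_ann <- which(apply(mask, 1, any))
  if (is.null(drawn_slices)) drawn_slices <- with_ann
  drawn_slices <- sort(unique(as.integer(drawn_slices)))
  if (!all(with_ann %in% drawn_slices)) {
    stop("annotations found outside drawn_slices")
  }
  structure(list(mask = mask, drawn_slices = drawn_slices),
            class = "border_delineation")
}

#' k-means tissue clustering of the field of view
#'
#' Clusters voxels into background, water-dominant and fat-dominant tissue
#' with k = 3 k-means on the per-voxel feature `(fat_mag, water_mag)`
#' (min-max scaled per channel, 10 restarts, seeded).  Clusters are
#' relabelled deterministically from their centroids in original intensity
#' units: background is the lowest total-intensity centroid, fat the
#' higher-fat centroid of the remaining two, water the remainder — so the
#' output is invariant to the k-means random seed on well-separated data.
#'
#' @param fat_mag,water_mag non-negative 3D magnitude volumes of equal shape.
#' @param seed RNG seed for the k-means restarts.
#' @return integer 3D array with codes 0 (background), 1 (water_dominant),
#'   2 (fat_dominant).
#' @export
cluster_tissues <- function(fat_mag, water_mag, seed = 1) {
  stopifnot(identical(dim(fat_mag), dim(water_mag)))
  if (any(fat_mag < 0) || any(water_mag < 0)) stop("magnitudes must be non-negative")
  f <- as.vector(fat_mag); w <- as.vector(water_mag)
  feat <- cbind(f, w)
  rng <- apply(feat, 2, range)
  spanf <- rng[2, ] - rng[1, ]
  if (all(spanf == 0)) stop("degenerate clustering: constant-intensity volume")
  sc <- sweep(feat, 2, rng[1, ], "-")
  sc <- sweep(sc, 2, ifelse(spanf > 0, spanf, 1), "/")
  if (nrow(unique(sc)) < 3L) stop("degenerate clustering: fewer than 3 distinct intensities")
  km <- withr::with_seed(seed,
    kmeans(sc, centers = 3, nstart = 10, iter.max = 100,
           algorithm = "MacQueen"))
  cf <- tapply(f, km$cluster, mean)
  cw <- tapply(w, km$cluster, mean)
  bg <- which.min(cf + cw)
  rest <- setdiff(1:3, bg)
  fat_cl <- rest[which.max(cf[rest])]
  wat_cl <- setdiff(rest, fat_cl)
  codes <- integer(3)
  codes[bg] <- TISSUE_BACKGROUND
  codes[fat_cl] <- TISSUE_FAT
  codes[wat_cl] <- TISSUE_WATER
  array(codes[km$cluster], dim = dim(fat_mag))
}

#' Densify a sparse border delineation
#'
#' Propagates annotations from the drawn slices to the intervening
#' un-drawn slices by nearest-slice copy (inside the drawn span), then
#' applies a morphological box dilation so that the resulting surface
#' closes any gaps and separates breast from thorax.  Both the thin
#' propagated sheet and the dilated cutting surface are returned: the
#' dilated surface is used to cut the foreground, while the sheet is the
#' border proper that final masks must stay disjoint from.
#'
#' @param delin a [border_delineation()].
#' @param dilation_radius_voxels box dilation radius (default 2).
#' @return a list of class `border_mask` with logical volumes `sheet`
#'   (densified, undilated) and `dilated`.
#' @export
densify_border <- function(delin, dilation_radius_voxels = 2) {
  stopifnot(inherits(delin, "border_delineation"))
  if (!any(delin$mask)) stop("empty delineation")
  d <- dim(delin$mask)
  sheet <- array(FALSE, dim = d)
  drawn <- delin$drawn_slices
  lo <- min(drawn); hi <- max(drawn)
  for (s in lo:hi) {
    nearest <- drawn[which.min(abs(drawn - s))]
    sheet[s, , ] <- delin$mask[nearest, , ]
  }
  dil <- dilate_box(sheet, dilation_radius_voxels)
  structure(list(sheet = sheet, dilated = dil,
                 dilation_radius = dilation_radius_voxels),
            class = "border_mask")
}

# Accept either a border_mask or a plain logical volume as border input.
as_border_mask <- function(border) {
  if (inherits(border, "border_mask")) return(border)
  stopifnot(length(dim(border)) == 3L)
  b <- array(as.logical(border), dim = dim(border))
  structure(list(sheet = b, dilated = b, dilation_radius = 0L),
            class = "border_mask")
}

#' Left/right breast centroids from the border delineation
#'
#' Projects the delineated border voxels along the AP axis, splits them at
#' the RL midpoint of the delineation extent, and takes the per-side mean
#' of the projected (FH, RL) coordinates.  The AP coordinate is the
#' per-side mean border AP displaced anteriorly (towards lower AP index)
#' by `anterior_offset_voxels` so the centroid lands inside breast tissue.
#'
#' @param delin a [border_delineation()].
#' @param anterior_offset_voxels anterior displacement (voxels).
#' @return list with numeric `left` and `right` voxel coordinates
#'   `(FH, AP, RL)`; "left" is the lower-RL-index side.
#' @export
breast_centroids <- function(delin, anterior_offset_voxels = 10) {
  stopifnot(inherits(delin, "border_delineation"))
  vox <- mask_coords(delin$mask)     # columns: FH, AP, RL
  if (nrow(vox) == 0) stop("empty delineation")
  mid <- (min(vox[, 3]) + max(vox[, 3])) / 2
  left <- vox[vox[, 3] <= mid, , drop = FALSE]
  right <- vox[vox[, 3] > mid, , drop = FALSE]
  if (nrow(left) == 0) stop("delineation has no voxels on the left side")
  if (nrow(right) == 0) stop("delineation has no voxels on the right side")
  cen <- function(v) {
    c(FH = mean(v[, 1]),
      AP = max(1, mean(v[, 2]) - anterior_offset_voxels),
      RL = mean(v[, 3]))
  }
  list(left = cen(left), right = cen(right))
}

#' Isolate the left and right breast from the thorax
#'
#' Removes the dilated border surface from the foreground, labels the
#' remaining voxels by 26-connectivity, and takes the component containing
#' each per-side centroid as that breast.  Foreground voxels removed by the
#' dilation (but not on the thin border sheet itself) are then reassigned
#' to the nearest region by simultaneous equal-speed front growth, so the
#' dilation radius does not bias breast volumes; the border sheet stays
#' outside every mask.
#'
#' @param tissue_labels integer array from [cluster_tissues()].
#' @param border a `border_mask` from [densify_border()] (or a plain
#'   logical volume, used both as sheet and cutting surface).
#' @param centroids list with `left`/`right` coordinates, as returned by
#'   [breast_centroids()].
#' @return list with logical masks `left_breast`, `right_breast`, the
#'   `thorax` remainder and the `border` used.
#' @export
isolate_breasts <- function(tissue_labels, border, centroids) {
  border <- as_border_mask(border)
  d <- dim(tissue_labels)
  stopifnot(identical(d, dim(border$sheet)))
  fg <- tissue_labels != TISSUE_BACKGROUND
  cut <- fg & !border$dilated
  dims <- as.integer(d)

  seed_of <- function(cen, side) {
    li <- linear_index(cen, d)
    if (!fg[li]) stop(side, " centroid lies in background")
    if (border$dilated[li]) stop(side, " centroid lies on the border mask")
    li
  }
  sl <- seed_of(centroids$left, "left")
  sr <- seed_of(centroids$right, "right")

  left <- array(flood_component_cpp(as.vector(cut), dims, sl), dim = d)
  if (left[sr]) stop("border does not separate: both centroids fall in one component")
  right <- array(flood_component_cpp(as.vector(cut), dims, sr), dim = d)

  # reassign the dilation band (minus the sheet) by equal-speed growth
  lab <- array(0L, dim = d)
  lab[left] <- 1L; lab[right] <- 2L
  lab[cut & !left & !right] <- 3L
  allowed <- fg & border$dilated & !border$sheet
  lab <- array(multilabel_grow_cpp(as.vector(lab), as.vector(allowed), dims),
               dim = d)
  out <- list(left_breast = lab == 1L, right_breast = lab == 2L,
              thorax = lab == 3L, border = border)
  stopifnot(!any(out$left_breast & out$right_breast),
            !any((out$left_breast | out$right_breast) & border$sheet))
  out
}

#' Fibroglandular tissue segmentation
#'
#' Fibroglandular tissue (FGT) empirically carries very low fat signal, so
#' it is segmented as the water-dominant breast voxels whose PDFF lies
#' strictly below a fat-concentration cutoff (default 20%).
#'
#' @param breast_mask logical breast mask.
#' @param tissue_labels integer array from [cluster_tissues()].
#' @param pdff_map PDFF volume in percent (`NA` allowed; excluded).
#' @param cutoff_percent cutoff in (0, 100), strict comparison.
#' @return logical FGT mask (a warning is emitted when empty).
#' @export
segment_fibroglandular <- function(breast_mask, tissue_labels, pdff_map,
                                   cutoff_percent = 20) {
  stopifnot(identical(dim(breast_mask), dim(tissue_labels)),
            identical(dim(breast_mask), dim(pdff_map)))
  if (!is.numeric(cutoff_percent) || length(cutoff_percent) != 1L ||
      !is.finite(cutoff_percent) || cutoff_percent <= 0 || cutoff_percent >= 100) {
    stop("cutoff_percent must lie strictly inside (0, 100)")
  }
  fgt <- breast_mask & tissue_labels == TISSUE_WATER &
    !is.na(pdff_map) & pdff_map < cutoff_percent
  if (!any(fgt)) warning("fibroglandular mask is empty")
  fgt
}

#' Per-breast summary statistics
#'
#' Arithmetic mean PDFF over the whole breast and mean PDFF / T2* over the
#' fibroglandular tissue, restricted to voxels with QC flag 0.  FGT means
#' are reported as `NA` when the FGT mask is empty.
#'
#' @param breast_mask,fgt_mask logical masks (FGT must be inside breast).
#' @param pdff_map,t2star_map quantitative volumes (percent / ms).
#' @param qc_flags integer QC volume (0 = usable).
#' @param subject_id,side identifiers copied into the output row.
#' @return one-row `data.frame` with columns `subject_id`, `side`,
#'   `mean_pdff_breast`, `mean_pdff_fgt`, `mean_t2star_fgt`,
#'   `n_breast_vox`, `n_fgt_vox`.
#' @export
summarize_breast <- function(breast_mask, fgt_mask, pdff_map, t2star_map,
                             qc_flags, subject_id = NA_character_,
                             side = NA_character_) {
  stopifnot(identical(dim(breast_mask), dim(pdff_map)))
  if (!any(breast_mask)) stop("empty breast mask")
  if (any(fgt_mask & !breast_mask)) stop("FGT mask extends outside the breast mask")
  ok <- qc_flags == 0L
  bsel <- breast_mask & ok
  fsel <- fgt_mask & ok
  mean_or_na <- function(x, sel) {
    v <- x[sel]; v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  data.frame(
    subject_id = subject_id,
    side = side,
    mean_pdff_breast = mean_or_na(pdff_map, bsel),
    mean_pdff_fgt = if (any(fsel)) mean_or_na(pdff_map, fsel) else NA_real_,
    mean_t2star_fgt = if (any(fsel)) mean_or_na(t2star_map, fsel) else NA_real_,
    n_breast_vox = sum(breast_mask),
    n_fgt_vox = sum(fgt_mask),
    stringsAsFactors = FALSE
  )
}
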