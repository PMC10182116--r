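# Internal array helpers shared by the segmentation and field-map code.
# Volumes are indexed (FH, AP, RL); axial slices are constant-FH planes.

# Shift a 3D array by `by` voxels along `axis`, padding with `fill`.
shift_array <- function(x, by, axis, fill = if (is.logical(x)) FALSE else 0) {
  if (by == 0L) return(x)
  d <- dim(x)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0L) 1:(n - by) else (1 - by):n
  dst <- if (by > 0L) (1 + by):n else 1:(n + by)
  idx_src <- list(1:d[1], 1:d[2], 1:d[3])
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Separable box ("max") dilation of a logical volume.
dilate_box <- function(mask, radius) {
  stopifnot(length(dim(mask)) == 3L, radius >= 0L)
  if (radius == 0L) return(mask)
  out <- mask
  for (axis in 1:3) {
    acc <- out
    for (s in seq_len(radius)) {
      acc <- acc | shift_array(out, s, axis) | shift_array(out, -s, axis)
    }
    out <- acc
  }
  out
}

# Separable box sum (moving window of half-width `radius` along every axis).
box_sum <- function(x, radius) {
  out <- x
  for (axis in 1:3) {
    acc <- out
    for (s in seq_len(radius)) {
      acc <- acc + shift_array(out, s, axis) + shift_array(out, -s, axis)
    }
    out <- acc
  }
  out
}

# Weighted local mean over a (2r+1)^3 box; voxels with zero local weight
# keep `default`.
box_mean_weighted <- function(x, w, radius, default = 0) {
  num <- box_sum(x * w, radius)
  den <- box_sum(w, radius)
  out <- ifelse(den > 0, num / den, default)
  array(out, dim = dim(x))
}

# arrayInd/linear-index helpers -------------------------------------------

linear_index <- function(coord, dims) {
  coord <- round(coord)
  stopifnot(all(coord >= 1), all(coord <= dims))
  as.integer(coord[1] + dims[1] * ((coord[2] - 1) + dims[2] * (coord[3] - 1)))
}

# Directed/symmetric Hausdorff distance between two voxel point sets given
# as n x 3 coordinate matrices (in voxel units).  Used by tests and QC.
hausdorff_voxels <- function(a, b) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  d2 <- function(p, q) {
    # max over p of min distance to q
    mx <- 0
    for (i in seq_len(nrow(p))) {
      dd <- sqrt(min(colSums((t(q) - p[i, ])^2)))
      if (dd > mx) mx <- dd
    }
    mx
  }
  max(d2(a, b), d2(b, a))
}

mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# Dice overlap between two logical masks.
#' Dice coefficient between two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`; returns `NA` when both masks are empty.
#'
#' @param a,b logical arrays of identical dimension.
#' @return numeric in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
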