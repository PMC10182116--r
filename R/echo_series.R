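#' Multi-echo complex image series
#'
#' Container for a 4D complex gradient-echo volume, indexed
#' `(FH, AP, RL, echo)`, together with its acquisition parameters and
#' isotropic voxel size.
#'
#' @param data 4D complex (or real, promoted to complex) array; the fourth
#'   dimension must match the number of echoes in `acq`.
#' @param acq an [acq_params()].
#' @param voxel_size_mm isotropic voxel spacing in mm.
#' @return an object of class `echo_series`.
#' @export
echo_series <- function(data, acq, voxel_size_mm = 1.7) {
  stopifnot(inherits(acq, "acq_params"))
  if (length(dim(data)) != 4L) stop("data must be a 4D array (FH, AP, RL, echo)")
  if (dim(data)[4] != n_echoes(acq)) {
    stop("echo dimension (", dim(data)[4], ") does not match acquisition (",
         n_echoes(acq), " echoes)")
  }
  if (!is.complex(data)) data <- data + 0i
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data)))) {
    stop("echo series contains non-finite values")
  }
  stopifnot(is.finite(voxel_size_mm), voxel_size_mm > 0)
  structure(list(data = data, acq = acq, voxel_size_mm = voxel_size_mm),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("echo_series: %d x %d x %d voxels, %d echoes, %.2g mm isotropic\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm))
  invisible(x)
}

# nE x V complex signal matrix for the voxels selected by `mask` (logical 3D).
signal_matrix <- function(series, mask) {
  d <- dim(series$data)
  m <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  t(m[as.vector(mask), , drop = FALSE])
}
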