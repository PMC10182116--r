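# NIfTI / TSV input-output.  Complex echo data is stored as a real/imag
# pair of 4D NIfTI volumes (the NIfTI complex type is not portable across
# toolchains); quantitative maps are written as float32 volumes.

#' Write / read a multi-echo series as NIfTI
#'
#' `write_echo_series()` writes `<prefix>_real.nii.gz` and
#' `<prefix>_imag.nii.gz` plus `<prefix>_acq.yaml` with the acquisition
#' metadata; `read_echo_series()` reads them back.
#'
#' @param series an [echo_series()].
#' @param prefix output path prefix.
#' @return the prefix (write) or an `echo_series` (read), invisibly/visibly.
#' @export
write_echo_series <- function(series, prefix) {
  stopifnot(inherits(series, "echo_series"))
  vs <- series$voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(Re(series$data), pixdim = rep(vs, 3)),
                     paste0(prefix, "_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(series$data), pixdim = rep(vs, 3)),
                     paste0(prefix, "_imag.nii.gz"))
  yaml::write_yaml(list(field_strength_T = series$acq$field_strength_T,
                        echo_times_ms = series$acq$echo_times_ms,
                        readout_polarity = series$acq$readout_polarity,
                        voxel_size_mm = vs),
                   paste0(prefix, "_acq.yaml"))
  invisible(prefix)
}

#' @rdname write_echo_series
#' @export
read_echo_series <- function(prefix) {
  re <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_real.nii.gz"))),
              dim = dim(RNifti::readNifti(paste0(prefix, "_real.nii.gz"))))
  im <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_imag.nii.gz"))),
              dim = dim(re))
  meta <- yaml::read_yaml(paste0(prefix, "_acq.yaml"))
  acq <- acq_params(echo_times_ms = as.numeric(meta$echo_times_ms),
                    field_strength_T = as.numeric(meta$field_strength_T),
                    readout_polarity = as.numeric(meta$readout_polarity))
  echo_series(complex(real = re, imaginary = im) |> array(dim = dim(re)),
              acq, as.numeric(meta$voxel_size_mm %||% 1.7))
}

#' Write quantitative maps as float32 NIfTI volumes
#'
#' Writes `pdff`, `t2star`, `r2star`, `fieldmap`, `water`, `fat` and `qc`
#' volumes as `<dir>/<name>.nii.gz`.
#'
#' @param maps a `quant_maps` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_quant_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "quant_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- maps$voxel_size_mm
  wr <- function(x, name, datatype = "float") {
    img <- RNifti::asNifti(x, pixdim = rep(vs, 3), datatype = datatype)
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")),
                       datatype = datatype)
  }
  wr(maps$pdff_percent, "pdff")
  wr(maps$t2star_ms, "t2star")
  wr(maps$r2star_per_ms, "r2star")
  wr(maps$fieldmap_Hz, "fieldmap")
  wr(maps$water_mag, "water")
  wr(maps$fat_mag, "fat")
  wr(maps$qc_flags + 0L, "qc", datatype = "int16")
  invisible(dir)
}

#' Write / read a binary mask as NIfTI
#'
#' @param mask logical 3D array.
#' @param path output `.nii(.gz)` path.
#' @param voxel_size_mm voxel spacing.
#' @return `path` / logical array.
#' @export
write_mask <- function(mask, path, voxel_size_mm = 1.7) {
  img <- RNifti::asNifti(mask + 0L, pixdim = rep(voxel_size_mm, 3),
                         datatype = "uint8")
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0, dim = dim(img))
}

#' Write / read a cohort table as TSV
#'
#' @param table cohort data.frame.
#' @param path TSV path.
#' @return `path` / data.frame.
#' @export
write_cohort_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
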