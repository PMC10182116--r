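#' Single-voxel tissue parameters
#'
#' Parameters of the water-fat signal model in one voxel: non-negative
#' water and fat magnitudes, a common initial phase shared by both species,
#' the B0 off-resonance (field-map) frequency psi in Hz, and the common
#' transverse decay rate r2* in 1/ms (a single T2* for water and fat).
#'
#' @param water_amp water signal magnitude (arbitrary units, >= 0).
#' @param fat_amp fat signal magnitude (>= 0).
#' @param common_phase_rad shared initial phase (rad).
#' @param fieldmap_Hz off-resonance frequency psi (Hz).
#' @param r2star_per_ms transverse decay rate 1/T2* (1/ms, >= 0).
#' @return an object of class `voxel_params`.
#' @export
voxel_params <- function(water_amp, fat_amp, common_phase_rad = 0,
                         fieldmap_Hz = 0, r2star_per_ms = 0) {
  vals <- c(water_amp, fat_amp, common_phase_rad, fieldmap_Hz, r2star_per_ms)
  if (any(!is.finite(vals))) stop("voxel parameters must be finite")
  if (water_amp < 0 || fat_amp < 0) stop("amplitudes must be non-negative")
  if (r2star_per_ms < 0) stop("r2star_per_ms must be non-negative")
  structure(list(water_amp = water_amp, fat_amp = fat_amp,
                 common_phase_rad = common_phase_rad,
                 fieldmap_Hz = fieldmap_Hz,
                 r2star_per_ms = r2star_per_ms),
            class = "voxel_params")
}

#' Complex fat phasor at given echoes
#'
#' The fat signal at echo time `t_n` is modulated by the spectrum-weighted
#' phasor `c_n = sum_p a_p exp(i 2 pi f_p t_n)` with peak frequencies
#' `f_p = shift_ppm_p * gamma * B0` in Hz.  Because the amplitudes sum to
#' one, `|c_n| <= 1` with equality for a single peak.
#'
#' @param spectrum a [fat_spectrum()].
#' @param acq an [acq_params()].
#' @param echo_index integer echo index (or vector); defaults to all echoes.
#' @return complex vector of phasors, one per requested echo.
#' @examples
#' fat_phasor(default_fat_spectrum(), default_acq(), 1)
#' @export
fat_phasor <- function(spectrum, acq, echo_index = seq_len(n_echoes(acq))) {
  stopifnot(inherits(spectrum, "fat_spectrum"), inherits(acq, "acq_params"))
  if (any(echo_index < 1L) || any(echo_index > n_echoes(acq))) {
    stop("echo_index out of range")
  }
  f_Hz <- spectrum$shift_ppm * acq$gyromagnetic_ratio_MHz_per_T *
    acq$field_strength_T  # MHz/T * T * ppm -> Hz
  t_s <- echo_times_s(acq)[echo_index]
  # outer product: echoes x peaks
  ph <- outer(t_s, f_Hz, function(t, f) 2 * pi * f * t)
  drop(exp(1i * ph) %*% spectrum$amplitude)
}

#' Forward multi-echo water-fat signal
#'
#' Evaluates the signal model
#' `s_n = (W + F c_n) exp(i (phi0 + 2 pi psi t_n)) exp(-t_n r2*)`
#' at every echo of the acquisition, with `c_n` the multi-peak fat phasor.
#' Times enter the off-resonance phase in seconds and the decay in
#' milliseconds (r2* is in 1/ms).
#'
#' @param voxel a [voxel_params()].
#' @param acq an [acq_params()].
#' @param spectrum a [fat_spectrum()].
#' @return complex vector with one value per echo.
#' @examples
#' v <- voxel_params(water_amp = 100, fat_amp = 0)
#' forward_signal(v, default_acq(), default_fat_spectrum())
#' @export
forward_signal <- function(voxel, acq, spectrum) {
  stopifnot(inherits(voxel, "voxel_params"), inherits(acq, "acq_params"),
            inherits(spectrum, "fat_spectrum"))
  cn <- fat_phasor(spectrum, acq)
  t_s <- echo_times_s(acq)
  t_ms <- acq$echo_times_ms
  (voxel$water_amp + voxel$fat_amp * cn) *
    exp(1i * (voxel$common_phase_rad + 2 * pi * voxel$fieldmap_Hz * t_s)) *
    exp(-t_ms * voxel$r2star_per_ms)
}
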