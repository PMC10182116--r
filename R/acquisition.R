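#' Multi-echo acquisition parameters
#'
#' Describes the gradient-echo echo train: field strength, echo times and
#' the per-echo readout polarity (alternating +1/-1 for bipolar readouts,
#' all +1 for monopolar).  Echo times are stored in milliseconds and
#' converted to seconds inside phase computations; the gyromagnetic ratio
#' is fixed at 42.577 MHz/T.
#'
#' @param echo_times_ms strictly increasing vector of echo times (ms).
#' @param field_strength_T main magnetic field in tesla.
#' @param readout_polarity per-echo sign vector (+1/-1); defaults to the
#'   alternating bipolar pattern.
#' @param gyromagnetic_ratio_MHz_per_T proton gyromagnetic ratio.
#' @return an object of class `acq_params`.
#' @examples
#' default_acq()            # 6 echoes, TE1 = 1.43 ms, dTE = 1.1 ms, 3 T
#' @export
acq_params <- function(echo_times_ms, field_strength_T = 3,
                       readout_polarity = NULL,
                       gyromagnetic_ratio_MHz_per_T = 42.577) {
  echo_times_ms <- as.numeric(echo_times_ms)
  n <- length(echo_times_ms)
  if (n < 1L || any(!is.finite(echo_times_ms))) {
    stop("echo_times_ms must be a non-empty finite vector")
  }
  if (n > 1L && any(diff(echo_times_ms) <= 0)) {
    stop("echo times must be strictly increasing")
  }
  if (is.null(readout_polarity)) {
    readout_polarity <- rep_len(c(1, -1), n)
  }
  readout_polarity <- as.numeric(readout_polarity)
  if (length(readout_polarity) != n || !all(readout_polarity %in% c(-1, 1))) {
    stop("readout_polarity must be a +1/-1 vector with one entry per echo")
  }
  stopifnot(is.finite(field_strength_T), field_strength_T > 0)
  structure(list(
    field_strength_T = field_strength_T,
    echo_times_ms = echo_times_ms,
    readout_polarity = readout_polarity,
    gyromagnetic_ratio_MHz_per_T = gyromagnetic_ratio_MHz_per_T
  ), class = "acq_params")
}

#' Default six-echo bipolar echo train
#'
#' TE1 = 1.43 ms, echo spacing 1.1 ms, 6 echoes, 3 T, bipolar readout.
#'
#' @param n_echoes number of echoes.
#' @param te1_ms first echo time (ms).
#' @param dte_ms echo spacing (ms).
#' @param field_strength_T field strength (T).
#' @param bipolar if `TRUE`, alternating readout polarity.
#' @return an `acq_params` object.
#' @export
default_acq <- function(n_echoes = 6, te1_ms = 1.43, dte_ms = 1.1,
                        field_strength_T = 3, bipolar = TRUE) {
  acq_params(
    echo_times_ms = te1_ms + dte_ms * (seq_len(n_echoes) - 1),
    field_strength_T = field_strength_T,
    readout_polarity = if (bipolar) rep_len(c(1, -1), n_echoes)
                       else rep(1, n_echoes)
  )
}

#' Read acquisition parameters from a YAML config
#'
#' Expected keys: `field_strength_T`, `echo_times_ms`, optional
#' `readout_polarity`.
#'
#' @param path file path.
#' @return an `acq_params` object.
#' @export
read_acq_params <- function(path) {
  raw <- yaml::read_yaml(path)
  acq_params(
    echo_times_ms = as.numeric(raw$echo_times_ms),
    field_strength_T = as.numeric(raw$field_strength_T %||% 3),
    readout_polarity = if (!is.null(raw$readout_polarity))
      as.numeric(raw$readout_polarity) else NULL
  )
}

n_echoes <- function(acq) length(acq$echo_times_ms)

echo_times_s <- function(acq) acq$echo_times_ms / 1000

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("acq_params: %d echoes at %.3g T, TE = %s ms, polarity %s\n",
              n_echoes(x), x$field_strength_T,
              paste(format(x$echo_times_ms), collapse = ", "),
              paste(ifelse(x$readout_polarity > 0, "+", "-"), collapse = "")))
  invisible(x)
}
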