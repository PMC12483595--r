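#' Acquisition settings of a logger recording
#'
#' Describes how a multichannel voltage recording was digitised. The slow
#' data loggers this package targets are configured by a per-channel
#' *conversion time*; the sampling rate is its reciprocal (a 60 ms
#' conversion time gives approximately 16.667 Hz).
#'
#' @param conversion_time Duration of one analog-to-digital conversion per
#'   channel, in seconds. Default 0.060 s.
#' @param start_time Epoch offset of the first sample, in seconds. All
#'   in-package times are seconds since this origin.
#'
#' @return A list of class `myco_acquisition` with elements
#'   `conversion_time`, `sampling_rate` (derived as `1/conversion_time`)
#'   and `start_time`.
#' @examples
#' acq <- acquisition(0.060)
#' acq$sampling_rate # ~16.667 Hz
#' @export
acquisition <- function(conversion_time = 0.060, start_time = 0) {
  if (!is.numeric(conversion_time) || length(conversion_time) != 1 ||
      !is.finite(conversion_time) || conversion_time <= 0) {
    abort("`conversion_time` must be a single positive number of seconds.")
  }
  structure(
    list(
      conversion_time = as.numeric(conversion_time),
      sampling_rate = 1 / as.numeric(conversion_time),
      start_time = as.numeric(start_time)
    ),
    class = "myco_acquisition"
  )
}

#' @export
print.myco_acquisition <- function(x, ...) {
  cat(sprintf(
    "<acquisition> conversion time %.4g s, sampling rate %.6g Hz, start %.6g s\n",
    x$conversion_time, x$sampling_rate, x$start_time
  ))
  invisible(x)
}

validate_acquisition <- function(acq) {
  if (!inherits(acq, "myco_acquisition")) {
    abort("`acq` must be created by `acquisition()`.")
  }
  rel <- abs(acq$sampling_rate * acq$conversion_time - 1)
  if (rel > 1e-9) {
    abort(sprintf(
      "acquisition inconsistent: sampling_rate * conversion_time differs from 1 by %.3g",
      rel
    ))
  }
  invisible(acq)
}

# Recognised treatment labels for channel metadata.
treatment_levels <- function() {
  c(
    "none", "cycloheximide", "voriconazole", "calcimycin",
    "sodium_azide", "water_control", "dmso_control"
  )
}
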