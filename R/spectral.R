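#' Four-term Blackman-Harris window
#'
#' The minimum-sidelobe four-term Blackman-Harris taper (-92 dB sidelobes),
#' in the periodic convention used for spectral estimation: for even `n`
#' the peak value is exactly 1 at index `n/2` (0-based) and the window is
#' symmetric about it.
#'
#' @param n Window length in samples (>= 8).
#' @return Numeric vector of length `n`.
#' @examples
#' w <- blackman_harris(1024)
#' which.max(w) # 513, i.e. 0-based index 512
#' @export
blackman_harris <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 8) {
    abort("`n` must be a single integer >= 8.")
  }
  n <- as.integer(n)
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- 0:(n - 1)
  a[1] - a[2] * cos(2 * pi * k / n) + a[3] * cos(4 * pi * k / n) -
    a[4] * cos(6 * pi * k / n)
}

#' STFT framing parameters
#'
#' @param window_length Samples per analysis frame (default 1024).
#' @param overlap_fraction Fractional overlap between consecutive frames
#'   (default 0.80, i.e. a hop of ~20% of the window).
#' @param window_kind Only `"blackman_harris_4term"` is provided.
#' @return A list of class `myco_stft_params` with the derived `hop`.
#' @export
stft_params <- function(window_length = 1024, overlap_fraction = 0.80,
                        window_kind = "blackman_harris_4term") {
  if (!identical(window_kind, "blackman_harris_4term")) {
    abort(sprintf("unsupported window_kind: %s", window_kind))
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must be in [0, 1).")
  }
  hop <- round(window_length * (1 - overlap_fraction))
  if (hop < 1) abort("overlap too large: derived hop is < 1 sample")
  structure(
    list(window_length = as.integer(window_length),
         overlap_fraction = overlap_fraction,
         hop = as.integer(hop),
         window_kind = window_kind),
    class = "myco_stft_params"
  )
}

stft_n_frames <- function(n, params) {
  if (n < params$window_length) return(0L)
  as.integer((n - params$window_length) %/% params$hop + 1L)
}

# Frame a vector into a window_length x n_frames matrix (columns = frames).
stft_frames <- function(x, params) {
  nf <- stft_n_frames(length(x), params)
  wl <- params$window_length
  idx <- outer(seq_len(wl), (seq_len(nf) - 1L) * params$hop, `+`)
  matrix(x[idx], nrow = wl, ncol = nf)
}

#' Short-time Fourier transform spectrogram
#'
#' Runs a tapered window along the signal and takes the squared FFT
#' amplitude in each frame, giving time-resolved frequency content: the
#' spectrogram in which mycelial colonization shows up as components above
#' 1.5 Hz appearing on top of the sub-1 Hz background.
#'
#' @param x Numeric vector (a cleaned voltage trace, volts) or a
#'   single-channel `myco_recordings` tibble.
#' @param fs Sampling rate in Hz (taken from the set when `x` is one).
#' @param params [stft_params()].
#' @return An object of class `myco_spectrogram`: list with `times`
#'   (frame-centre seconds), `freqs` (Hz, 0..fs/2), `power` (frames x bins
#'   matrix of squared STFT amplitude, V^2), `params`, `source_rate`.
#' @export
stft_spectrogram <- function(x, fs = NULL, params = stft_params()) {
  if (inherits(x, "myco_recordings")) {
    if (nrow(x) != 1) abort("pass a single-channel set (or a numeric vector)")
    fs <- sampling_rate(x)
    x <- x$samples[[1]]
  }
  if (is.null(fs)) abort("`fs` must be given for a numeric vector")
  if (anyNA(x)) abort("input contains missing samples; run drop_missing() first")
  wl <- params$window_length
  if (length(x) < wl) {
    abort(sprintf("fewer samples than one window (%d < %d)", length(x), wl))
  }
  frames <- stft_frames(x, params)
  w <- blackman_harris(wl)
  spec <- stats::mvfft(frames * w)
  nbin <- wl %/% 2 + 1L
  pow <- t(Mod(spec[seq_len(nbin), , drop = FALSE])^2)
  structure(
    list(
      times = ((seq_len(ncol(frames)) - 1L) * params$hop + wl / 2) / fs,
      freqs = (seq_len(nbin) - 1L) * fs / wl,
      power = pow,
      params = params,
      source_rate = fs
    ),
    class = "myco_spectrogram"
  )
}

#' @export
print.myco_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d frames x %d bins, 0-%.4g Hz, %.4g s span (%d-sample %s window, %.0f%% overlap)\n",
    nrow(x$power), ncol(x$power), max(x$freqs),
    max(x$times) + x$params$window_length / 2 / x$source_rate,
    x$params$window_length, x$params$window_kind,
    100 * x$params$overlap_fraction
  ))
  invisible(x)
}

#' Tidy a spectrogram into long form
#'
#' @param x A `myco_spectrogram`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `freq`, `power`.
#' @method tidy myco_spectrogram
#' @export
tidy.myco_spectrogram <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$times)),
    power = as.vector(x$power)
  )
}

#' Write a spectrogram as a portable text matrix
#'
#' Tab-separated: '#'-prefixed header lines carry the axes and windowing
#' parameters, then one row per frame.
#'
#' @param sg A `myco_spectrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(sg, path) {
  header <- c(
    "# mycovolt-spectrogram v1",
    sprintf("# source_rate: %.9g", sg$source_rate),
    sprintf("# window_length: %d", sg$params$window_length),
    sprintf("# overlap_fraction: %.6g", sg$params$overlap_fraction),
    sprintf("# times: %s", paste(sprintf("%.9g", sg$times), collapse = " ")),
    sprintf("# freqs: %s", paste(sprintf("%.9g", sg$freqs), collapse = " "))
  )
  body <- apply(sg$power, 1, function(r) {
    paste(sprintf("%.9g", r), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- Welch-averaged power spectral density --------------------------------

#' Welch power spectral density estimate
#'
#' Averaged tapered periodogram using the same Blackman-Harris framing as
#' the spectrogram, normalized as a one-sided density so that the PSD
#' integrated over all frequencies equals the signal's mean square (the
#' variance identity that fixes the estimator's convention).
#'
#' @param x Numeric vector, no missing values.
#' @param fs Sampling rate in Hz.
#' @param params [stft_params()].
#' @return A tibble with columns `freq` (bin centres, Hz) and `psd`
#'   (V^2/Hz), plus attribute `bin_width` (Hz).
#' @export
welch_psd <- function(x, fs, params = stft_params()) {
  if (anyNA(x)) abort("input contains missing samples")
  wl <- params$window_length
  if (length(x) < wl) {
    abort(sprintf("fewer samples than one window (%d < %d)", length(x), wl))
  }
  frames <- stft_frames(x, params)
  w <- blackman_harris(wl)
  spec <- stats::mvfft(frames * w)
  nbin <- wl %/% 2 + 1L
  p2 <- rowMeans(Mod(spec[seq_len(nbin), , drop = FALSE])^2)
  scale <- 1 / (fs * sum(w^2))
  psd <- p2 * scale
  interior <- seq_len(nbin) > 1 & (wl %% 2 != 0 | seq_len(nbin) < nbin)
  psd[interior] <- 2 * psd[interior]
  out <- tibble::tibble(freq = (seq_len(nbin) - 1L) * fs / wl, psd = psd)
  attr(out, "bin_width") <- fs / wl
  out
}

#' Integrate a PSD over a frequency band
#'
#' A bin contributes if its centre frequency lies in `[low, high)`
#' (half-open at both the lower and the upper edge), which makes band
#' powers exactly additive over adjacent bands sharing an edge.
#'
#' @param psd A tibble from [welch_psd()].
#' @param low,high Band edges in Hz, `low < high`.
#' @return Average power in the band, V^2.
#' @export
band_power <- function(psd, low, high) {
  if (!(low >= 0 && high > low)) abort("need 0 <= low < high")
  dfreq <- attr(psd, "bin_width")
  sel <- psd$freq >= low & psd$freq < high
  sum(psd$psd[sel]) * dfreq
}

#' Band-integrated average power of a recording segment
#'
#' For each channel, estimates the one-sided PSD of the samples in
#' `[start, end)` and integrates it over the requested band, giving the
#' single cumulative power value used to compare conditions. When
#' `resample = TRUE` (the analysis default) the segment is first low-pass
#' filtered and resampled via [lowpass_resample()], so the band must lie
#' within the resampled Nyquist range.
#'
#' @param set A cleaned `myco_recordings` tibble.
#' @param start,end Segment bounds in seconds (half-open).
#' @param band Numeric `c(low, high)` in Hz.
#' @param band_label Optional label stored with the result.
#' @param resample Apply the anti-alias low-pass + resample first?
#' @param cutoff,target_rate,transition_fraction Passed to
#'   [lowpass_resample()] when `resample = TRUE`.
#' @param params [stft_params()] for the PSD estimate.
#' @return A tibble with one row per channel: `channel_id`, `start`, `end`,
#'   `band_low`, `band_high`, `band_label`, `n_samples`, `power` (V^2).
#' @export
segment_average_power <- function(set, start, end, band = c(0, 4),
                                  band_label = NULL,
                                  resample = TRUE,
                                  cutoff = 4.0, target_rate = 8.0,
                                  transition_fraction = 0.05,
                                  params = stft_params()) {
  validate_recording_set(set)
  assert_clean(set, "segment_average_power()")
  if (length(band) != 2 || band[2] <= band[1]) {
    abort("`band` must be c(low, high) with low < high")
  }
  seg <- crop_recordings(set, start, end)
  if (resample) seg <- lowpass_resample(seg, cutoff, target_rate, transition_fraction)
  fs <- sampling_rate(seg)
  if (band[1] >= fs / 2) {
    abort(sprintf("band [%g, %g) lies above the Nyquist frequency %.4g Hz",
                  band[1], band[2], fs / 2))
  }
  if (is.null(band_label)) band_label <- sprintf("%g-%g Hz", band[1], band[2])
  powers <- vapply(seg$samples, function(x) {
    band_power(welch_psd(x, fs, params), band[1], band[2])
  }, numeric(1))
  tibble::tibble(
    channel_id = seg$channel_id,
    start = start, end = end,
    band_low = band[1], band_high = band[2], band_label = band_label,
    n_samples = vapply(seg$samples, length, integer(1)),
    power = powers
  )
}
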