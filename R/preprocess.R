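#' Remove missing samples from a recording set
#'
#' Slow loggers drop occasional conversions and pause entirely while the
#' plate is opened for stimulus addition, leaving `NA` runs in every
#' channel. Cleaning excises those samples and concatenates the remainder,
#' keeping all channels aligned on one compressed time base: a sample index
#' is removed from every channel if it is missing in any channel.
#'
#' Each removed run is logged (1-based start index and length, in the
#' original indexing) in the `gap_log` attribute, and every channel's
#' `induction_time` is remapped onto the cleaned time base so that
#' downstream segmentation stays anchored to the induction event.
#'
#' @param set A `myco_recordings` tibble.
#' @return The cleaned `myco_recordings` tibble, with attribute `gap_log`
#'   (a tibble with columns `start`, `length`) and no `NA` samples.
#' @examples
#' rs <- recording_set(list(c(1, NA, NA, 2, 3) * 1e-6))
#' cleaned <- drop_missing(rs)
#' attr(cleaned, "gap_log")
#' @export
drop_missing <- function(set) {
  validate_recording_set(set)
  if (nrow(set) == 0) {
    attr(set, "gap_log") <- tibble::tibble(start = integer(), length = integer())
    return(set)
  }
  n <- length(set$samples[[1]])
  missing_any <- Reduce(`|`, lapply(set$samples, is.na))
  keep <- !missing_any
  if (!any(keep)) abort("empty after cleaning: every sample index is missing")

  runs <- rle(missing_any)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  gap_log <- tibble::tibble(
    start = starts[runs$values],
    length = runs$lengths[runs$values]
  )

  fs <- sampling_rate(set)
  removed_before <- cumsum(missing_any)
  out <- set
  out$samples <- lapply(set$samples, function(x) x[keep])
  out$n_samples <- rep(sum(keep), nrow(set))
  # remap induction to the cleaned time base
  it <- set$induction_time
  idx <- pmin(pmax(floor(it * fs) + 1, 1), n)
  new_it <- ifelse(is.na(it), NA_real_,
                   (idx - 1 - removed_before[idx]) / fs)
  out$induction_time <- pmin(new_it, sum(keep) / fs)
  attr(out, "gap_log") <- gap_log
  validate_recording_set(out)
}

gap_log_of <- function(set) {
  gl <- attr(set, "gap_log")
  if (is.null(gl)) tibble::tibble(start = integer(), length = integer()) else gl
}

assert_clean <- function(set, what) {
  if (any(vapply(set$samples, anyNA, logical(1)))) {
    abort(sprintf("%s requires a cleaned recording set; run drop_missing() first.", what))
  }
  invisible(set)
}

#' Crop a recording set to a time interval
#'
#' Extracts the samples whose times fall in `[start, end)` seconds (relative
#' to the set's time origin) from every channel. The returned set is
#' re-based so its first sample is at time 0; the absolute offset is folded
#' into the acquisition `start_time` and each channel's `induction_time` is
#' shifted accordingly.
#'
#' @param set A `myco_recordings` tibble.
#' @param start,end Interval bounds in seconds, half-open `[start, end)`.
#' @return A `myco_recordings` tibble covering the interval.
#' @export
crop_recordings <- function(set, start, end) {
  validate_recording_set(set)
  if (end <= start) abort("`end` must exceed `start`.")
  span <- recording_span(set)
  if (start < 0 || start >= span) {
    abort(sprintf("interval [%.6g, %.6g) outside recording span [0, %.6g]",
                  start, end, span))
  }
  fs <- sampling_rate(set)
  n <- length(set$samples[[1]])
  i1 <- floor(start * fs) + 1
  i2 <- min(n, floor(end * fs))
  out <- set
  out$samples <- lapply(set$samples, function(x) x[i1:i2])
  out$n_samples <- rep(i2 - i1 + 1L, nrow(set))
  out$induction_time <- set$induction_time - start
  out$induction_time[!is.na(out$induction_time) &
                       (out$induction_time < 0 |
                          out$induction_time > (i2 - i1 + 1) / fs)] <- NA_real_
  a <- acq(set)
  attr(out, "acq") <- acquisition(a$conversion_time, a$start_time + start)
  out
}

# ---- anti-alias filtering and resampling ----------------------------------

# Best rational approximation p/q to `ratio` with q bounded, via Stern-
# Brocot style continued fractions.
rational_approx <- function(ratio, max_q = 1000, tol = 1e-9) {
  stopifnot(ratio > 0)
  best <- c(p = round(ratio), q = 1)
  cf <- ratio
  h <- c(1, floor(cf)); k <- c(0, 1)
  x <- cf
  repeat {
    if (abs(h[2] / k[2] - ratio) <= tol * ratio || k[2] > max_q) break
    frac <- x - floor(x)
    if (frac < 1e-12) break
    x <- 1 / frac
    a <- floor(x)
    h <- c(h[2], a * h[2] + h[1])
    k <- c(k[2], a * k[2] + k[1])
  }
  if (k[2] <= max_q) best <- c(p = h[2], q = k[2])
  best
}

# Smallest 5-smooth number (2^a 3^b 5^c) >= x, so FFT lengths stay fast.
next_smooth5 <- function(x) {
  best <- Inf
  p5 <- 1
  while (p5 < 2 * x) {
    p3 <- 1
    while (p5 * p3 < 2 * x) {
      rest <- x / (p5 * p3)
      n <- p5 * p3 * 2^max(0, ceiling(log2(rest)))
      if (n >= x && n < best) best <- n
      p3 <- p3 * 3
    }
    p5 <- p5 * 5
  }
  best
}

# Triangle-wave index reflection onto 1..n (period 2n-2).
reflect_idx <- function(idx, n) {
  k <- (idx - 1) %% (2 * (n - 1))
  k <- ifelse(k >= (n - 1), 2 * (n - 1) - k, k)
  k + 1
}

# Zero-phase FIR low-pass + rational resampling in one spectral pass.
# The FIR is a linear-phase low-pass (signal::fir1, Hamming taper) whose
# realized cutoff sits at the middle of the transition band
# [cutoff*(1 - transition_fraction), cutoff]; applying its zero-centred
# (rotated) impulse response in the frequency domain gives an exactly
# zero-phase filter. The spectrum is then truncated and inverse-transformed
# at the rationally resampled length.
design_lowpass <- function(fs, cutoff, transition_fraction) {
  f_lo <- cutoff * (1 - transition_fraction)
  width <- cutoff - f_lo
  n_taps <- ceiling(3.3 * fs / width)           # Hamming transition heuristic
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  taps <- signal::fir1(n_taps - 1, (f_lo + cutoff) / 2 / (fs / 2), type = "low")
  list(taps = as.numeric(taps), n_taps = n_taps,
       realized_cutoff = (f_lo + cutoff) / 2, passband_edge = f_lo,
       stopband_edge = cutoff)
}

filter_resample_vec <- function(x, fs, des, p, q) {
  n <- length(x)
  if (n < des$n_taps + 2 * q) {
    abort(sprintf(
      "segment too short to filter: %d samples but the anti-alias filter needs %d",
      n, des$n_taps + 2 * q
    ))
  }
  # odd-reflect padding so edges see continuous data; the left pad is a
  # multiple of q so the padded span maps to an integer number of output
  # samples, and the padded length is q times a 5-smooth number so both
  # FFTs stay O(n log n)
  pad <- q * ceiling(des$n_taps / q)
  np <- q * next_smooth5(ceiling((n + 2 * pad) / q))
  pad_r <- np - n - pad
  left <- 2 * x[1] - x[reflect_idx(seq(pad + 1, 2), n)]
  right <- 2 * x[n] - x[reflect_idx(seq(n - 1, by = -1, length.out = pad_r), n)]
  xp <- c(left, x, right)
  m <- np %/% q * p

  # zero-phase frequency response of the linear-phase taps
  d <- (des$n_taps - 1) / 2
  h <- numeric(np)
  h[1:(d + 1)] <- des$taps[(d + 1):des$n_taps]
  h[(np - d + 1):np] <- des$taps[1:d]
  H <- Re(fft(h))

  X <- fft(xp) * H
  # truncate to the resampled Nyquist
  Y <- complex(m)
  kmax <- min(np, m) %/% 2
  Y[1] <- X[1]
  if (kmax >= 2) {
    Y[2:kmax] <- X[2:kmax]
    Y[m:(m - kmax + 2)] <- X[np:(np - kmax + 2)]
  }
  if (m %% 2 == 0 && kmax >= 1) {
    # shared Nyquist bin: keep it real
    Y[kmax + 1] <- Re(X[kmax + 1])
  }
  y <- Re(fft(Y, inverse = TRUE)) / np
  off <- pad %/% q * p
  m_keep <- floor(n * p / q)
  y[(off + 1):(off + m_keep)]
}

#' Anti-alias filter and resample a recording set
#'
#' Implements the standard preparation for band-power analysis of slow
#' electrophysiological traces: a zero-phase low-pass limiting the spectrum
#' to `cutoff` (default 4 Hz) followed by resampling to `target_rate`
#' (default 8 Hz). Because 4 Hz is exactly the Nyquist frequency of the
#' 8 Hz target, the realized filter places its half-amplitude point at
#' `cutoff * (1 - transition_fraction/2)` with the transition band ending at
#' `cutoff`; the passband is flat within 0.1 dB below
#' `cutoff * (1 - transition_fraction)` and the stop band is attenuated by
#' more than 50 dB.
#'
#' Resampling uses the closest rational factor p/q to
#' `target_rate / sampling_rate(set)` (12/25 for the 60 ms logger
#' configuration) applied by spectral truncation, which is exactly
#' band-limited and adds no group delay. The realized output rate
#' `sampling_rate * p/q` and the relative rate error are recorded in the
#' `resample_info` attribute.
#'
#' @param set A cleaned `myco_recordings` tibble (see [drop_missing()]).
#' @param cutoff Low-pass band edge in Hz.
#' @param target_rate Output sampling rate in Hz; must not exceed the input
#'   rate, and `cutoff <= target_rate / 2`.
#' @param transition_fraction Fraction of `cutoff` used as the filter
#'   transition band.
#' @return A `myco_recordings` tibble at the new rate, with attribute
#'   `resample_info` describing the realized filter and rational factors.
#' @export
lowpass_resample <- function(set, cutoff = 4.0, target_rate = 8.0,
                             transition_fraction = 0.05) {
  validate_recording_set(set)
  assert_clean(set, "lowpass_resample()")
  fs <- sampling_rate(set)
  if (!(cutoff > 0 && cutoff <= target_rate / 2)) {
    abort("`cutoff` must satisfy 0 < cutoff <= target_rate / 2.")
  }
  if (target_rate > fs) {
    abort(sprintf("target_rate (%.6g Hz) exceeds the source rate (%.6g Hz)",
                  target_rate, fs))
  }
  des <- design_lowpass(fs, cutoff, transition_fraction)
  pq <- rational_approx(target_rate / fs)
  p <- unname(pq["p"]); q <- unname(pq["q"])
  rate_realized <- fs * p / q
  rate_err <- abs(rate_realized / target_rate - 1)

  out <- set
  out$samples <- lapply(set$samples, filter_resample_vec,
                        fs = fs, des = des, p = p, q = q)
  out$n_samples <- vapply(out$samples, length, integer(1))
  attr(out, "acq") <- acquisition(1 / rate_realized, acq(set)$start_time)
  attr(out, "resample_info") <- list(
    p = p, q = q, source_rate = fs, target_rate = target_rate,
    realized_rate = rate_realized, relative_rate_error = rate_err,
    n_taps = des$n_taps, realized_cutoff = des$realized_cutoff,
    passband_edge = des$passband_edge, stopband_edge = des$stopband_edge
  )
  if (rate_err > 1e-6) {
    warn(sprintf(
      "realized resample rate %.9g Hz differs from target %.9g Hz by %.3g (relative)",
      rate_realized, target_rate, rate_err
    ))
  }
  out
}
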