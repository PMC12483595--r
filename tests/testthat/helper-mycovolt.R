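# Shared fixtures, all generated in code.

# A recording set holding one pure tone (volts) at the default logger rate.
tone_recording <- function(freq, amplitude = 1, duration = 3600,
                           conversion_time = 0.060, phase = 0) {
  a <- acquisition(conversion_time)
  n <- round(duration * a$sampling_rate)
  t <- (seq_len(n) - 1) / a$sampling_rate
  suppressWarnings(recording_set(list(amplitude * sin(2 * pi * freq * t + phase)),
                                 channel_id = "tone", acq = a))
}

# Small, fast scenario used by most simulator tests: 15-minute "days",
# otherwise the default study design scaled down in channel count.
fast_scenario <- function(...) {
  args <- list(day_seconds = 900, duration_days = 7.3,
               n_inoculated = 3, n_control = 2, pause_gap = 60)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

# Brute-force STFT frame enumerator: slide a window of length wl by hop and
# count the positions that fit entirely inside n samples.
count_frames_brute <- function(n, wl, hop) {
  count <- 0L
  pos <- 1L
  while (pos + wl - 1L <= n) {
    count <- count + 1L
    pos <- pos + hop
  }
  count
}
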