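test_that("channels are deterministic in (seed, role, index) and differ across seeds", {
  cfg <- fast_scenario(master_seed = 5)
  a1 <- simulate_channel(cfg, "inoculated", 1)
  a2 <- simulate_channel(cfg, "inoculated", 1)
  expect_identical(a1$samples, a2$samples)

  b <- simulate_channel(cfg, "inoculated", 2)
  expect_false(identical(a1$samples, b$samples))
  ctrl <- simulate_channel(cfg, "control", 1)
  expect_false(identical(a1$samples, ctrl$samples))

  other <- simulate_channel(fast_scenario(master_seed = 6), "inoculated", 1)
  expect_false(identical(a1$samples, other$samples))

  # generation order does not matter: generating channel 2 first leaves
  # channel 1 unchanged
  b_first <- simulate_channel(cfg, "inoculated", 2)
  a_after <- simulate_channel(cfg, "inoculated", 1)
  expect_identical(a_after$samples, a1$samples)
  expect_identical(b_first$samples, b$samples)
})

test_that("simulated files are byte-identical for identical configs and seeds", {
  cfg <- fast_scenario(n_inoculated = 2, n_control = 1, master_seed = 3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_recording_set(simulate_experiment(cfg), f1)
  write_recording_set(simulate_experiment(cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("experiments carry the full replicate structure and metadata", {
  cfg <- fast_scenario(n_inoculated = 3, n_control = 2)
  set <- simulate_experiment(cfg)
  expect_equal(nrow(set), 5)
  expect_equal(sum(set$inoculated), 3)
  expect_true(all(set$induction_time == cfg$induction_days * cfg$day_seconds))
  expect_equal(sampling_rate(set), cfg$acq$sampling_rate)
  expect_true(all(vapply(set$samples, anyNA, logical(1))))  # induction pause

  defaults <- scenario_config()
  expect_equal(defaults$n_inoculated + defaults$n_control, 32)
  expect_equal(defaults$acq$conversion_time, 0.060)
  expect_equal(defaults$colonization_onset_days, 4)
  expect_equal(defaults$induction_days, 7)

  nullset <- simulate_experiment(fast_scenario(n_inoculated = 0, n_control = 2))
  expect_equal(nrow(nullset), 2)
  expect_false(any(nullset$inoculated))
})

test_that("invalid scenarios are rejected with the list of violations", {
  expect_error(scenario_config(colonization_onset_days = 8),
               "onset must precede induction")
  expect_error(scenario_config(duration_days = 5),
               "induction must precede")
  expect_error(scenario_config(tone_freq = 12),
               "Nyquist")
  expect_error(scenario_config(n_inoculated = -1, background_pole = 2),
               "counts must be >= 0.*modulus < 1")
})

test_that("only colonized channels carry signature-band power after onset", {
  cfg <- fast_scenario(master_seed = 21)
  day <- cfg$day_seconds
  post <- c((cfg$colonization_onset_days + cfg$ramp_days) * day,
            cfg$induction_days * day)

  sig_power <- function(ch) {
    cl <- drop_missing(ch)
    segment_average_power(cl, post[1], post[2], band = c(1.5, 8),
                          resample = FALSE)$power
  }
  ino <- sig_power(simulate_channel(cfg, "inoculated", 1))
  ctl <- sig_power(simulate_channel(cfg, "control", 1))
  expect_lt(ctl, 0.05 * ino)

  off <- sig_power(simulate_channel(fast_scenario(master_seed = 21, colonize = FALSE),
                                    "inoculated", 1))
  expect_lt(off, 0.05 * ino)
})

test_that("pre-onset spectra stay below the noise floor while post-onset peaks at 2 Hz", {
  cfg <- fast_scenario(master_seed = 31)
  day <- cfg$day_seconds
  ch <- drop_missing(simulate_channel(cfg, "inoculated", 1))

  pre <- segment_average_power(ch, 0, cfg$colonization_onset_days * day,
                               band = c(1.5, 8), resample = FALSE)$power
  post_sig <- segment_average_power(
    ch, (cfg$colonization_onset_days + cfg$ramp_days) * day,
    cfg$induction_days * day, band = c(1.5, 8), resample = FALSE)$power
  # pre-onset signature-band content is instrument noise: bounded by the
  # white floor plus the small background tail, and far below the signature
  expect_lt(pre, 2 * cfg$noise_floor^2)
  expect_lt(pre, 0.05 * post_sig)

  post <- crop_recordings(ch, (cfg$colonization_onset_days + cfg$ramp_days) * day,
                          cfg$induction_days * day)
  sg <- stft_spectrogram(post)
  avg <- colMeans(sg$power)
  bin_width <- sg$freqs[2] - sg$freqs[1]
  above <- sg$freqs > 1.5
  expect_lt(abs(sg$freqs[above][which.max(avg[above])] - cfg$tone_freq), bin_width)
})

test_that("treatment responses shape post-induction signature power", {
  day <- 900
  band <- c(1.5, 8)
  power_in <- function(ch, from, to) {
    segment_average_power(drop_missing(ch), from, to, band = band,
                          resample = FALSE)$power
  }

  kill <- fast_scenario(master_seed = 41, duration_days = 9,
                        response = treatment_response("full_suppression"))
  ch <- simulate_channel(kill, "inoculated", 1)
  pre <- power_in(ch, (kill$colonization_onset_days + kill$ramp_days) * day,
                  kill$induction_days * day)
  post <- power_in(ch, kill$induction_days * day + 60, 9 * day)
  expect_lt(post, 0.10 * pre)

  rec <- fast_scenario(master_seed = 41, duration_days = 9,
                       response = treatment_response("suppress_recover"))
  chr <- simulate_channel(rec, "inoculated", 1)
  resp <- rec$response
  recovered_from <- (rec$induction_days + resp$recovery_delay_days +
                       resp$recovery_ramp_days) * day
  during <- power_in(chr, rec$induction_days * day + 60,
                     (rec$induction_days + resp$recovery_delay_days) * day)
  after <- power_in(chr, recovered_from, 9 * day)
  pre_r <- power_in(chr, (rec$colonization_onset_days + rec$ramp_days) * day,
                    rec$induction_days * day)
  expect_lt(during, 0.10 * pre_r)
  expect_gte(after, 0.50 * pre_r)

  dent <- fast_scenario(master_seed = 41, duration_days = 9,
                        response = treatment_response("transient_dent"))
  chd <- simulate_channel(dent, "inoculated", 1)
  during_dent <- power_in(chd, dent$induction_days * day + 60,
                          (dent$induction_days + dent$response$dent_duration_days) * day)
  after_dent <- power_in(chd, (dent$induction_days + dent$response$dent_duration_days) * day,
                         9 * day)
  expect_lt(during_dent, 0.5 * after_dent)
})
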