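#' Response of the mycelial signature to a chemical stimulus
#'
#' Describes how the colonization-signature components (the >1.5 Hz
#' activity) change after induction. Durations are given in days so the
#' whole scenario scales coherently with `day_seconds` (see
#' [scenario_config()]).
#'
#' @param mode One of `"none"` (carrier control), `"full_suppression"`
#'   (signature killed from induction on), `"transient_dent"` (amplitude
#'   dips to `dent_factor` for `dent_duration_days`, then restores), or
#'   `"suppress_recover"` (suppressed for `recovery_delay_days`, about
#'   18 h by default, then ramps back to full amplitude).
#' @param suppression_factor Fraction of signature amplitude removed while
#'   suppressed, in `[0, 1]` (1 = complete suppression).
#' @param recovery_delay_days Delay before recovery begins (default 0.75
#'   day = 18 h).
#' @param recovery_ramp_days Length of the linear recovery ramp.
#' @param dent_factor Amplitude multiplier during a transient dent.
#' @param dent_duration_days Length of the dent (default 0.5 day).
#' @return A list of class `myco_response`.
#' @export
treatment_response <- function(mode = c("none", "full_suppression",
                                        "transient_dent", "suppress_recover"),
                               suppression_factor = 1,
                               recovery_delay_days = 0.75,
                               recovery_ramp_days = 1 / 12,
                               dent_factor = 0.5,
                               dent_duration_days = 0.5) {
  mode <- match.arg(mode)
  if (suppression_factor < 0 || suppression_factor > 1) {
    abort("`suppression_factor` must lie in [0, 1]")
  }
  if (recovery_delay_days < 0 || recovery_ramp_days < 0 || dent_duration_days < 0) {
    abort("delays and durations must be >= 0")
  }
  structure(
    list(mode = mode, suppression_factor = suppression_factor,
         recovery_delay_days = recovery_delay_days,
         recovery_ramp_days = recovery_ramp_days,
         dent_factor = dent_factor, dent_duration_days = dent_duration_days),
    class = "myco_response"
  )
}

# Multiplier applied to signature amplitude at absolute times t (seconds),
# for induction at `induction` seconds, with day length `day` seconds.
response_modulation <- function(t, response, induction, day) {
  m <- rep(1, length(t))
  post <- t >= induction
  if (!any(post) || response$mode == "none") return(m)
  residual <- 1 - response$suppression_factor
  if (response$mode == "full_suppression") {
    m[post] <- residual
  } else if (response$mode == "transient_dent") {
    dent <- post & t < induction + response$dent_duration_days * day
    m[dent] <- response$dent_factor
  } else if (response$mode == "suppress_recover") {
    delay <- response$recovery_delay_days * day
    ramp <- max(response$recovery_ramp_days * day, .Machine$double.eps)
    dt <- t[post] - induction
    m[post] <- ifelse(dt < delay, residual,
                      pmin(1, residual + (1 - residual) * (dt - delay) / ramp))
  }
  m
}

#' Parametric description of a synthetic mycelium-recording experiment
#'
#' Generates the default study design: `n_inoculated` electrode pairs
#' carrying a fungus plus `n_control` blank pairs, recorded for
#' `duration_days` with a chemical stimulus at `induction_days`. Every
#' channel carries a sub-1 Hz background (an AR(1) drift with its pole
#' near 1) plus a white noise floor; inoculated channels additionally gain
#' the colonization signature -- a 2 Hz tone plus weak 1.5-8 Hz band noise
#' -- ramping in at `colonization_onset_days` and modulated after
#' induction by the treatment `response`. A run of `pause_gap` missing
#' samples at the induction time emulates the logger pausing while the
#' stimulus is added.
#'
#' Amplitudes are calibrated so that 0-4 Hz segment powers land at the
#' magnitudes typical of these recordings (about `2e-8` V^2 for controls
#' and `3e-7` V^2 for colonized pairs pre-induction). `day_seconds`
#' compresses the scenario clock for fast tests without touching any
#' frequency: 21600 gives 6-hour "days".
#'
#' @param n_inoculated,n_control Channel counts (defaults 24 and 8).
#' @param day_seconds Seconds per scenario day (86400 for real time).
#' @param duration_days,colonization_onset_days,induction_days,ramp_days
#'   Scenario timeline, in days; must satisfy
#'   `colonization_onset < induction < duration`.
#' @param acq [acquisition()]; default the 60 ms logger configuration.
#' @param background_rms RMS of the AR(1) background drift, volts.
#' @param background_pole AR(1) pole; closer to 1 concentrates power at
#'   lower frequency.
#' @param tone_freq,tone_amplitude Signature tone (Hz; peak volts).
#' @param band_noise_band,band_noise_rms Signature band noise (Hz pair;
#'   RMS volts).
#' @param noise_floor White measurement-noise RMS, volts.
#' @param amplitude_jitter Lognormal sdlog of per-channel amplitude
#'   variation (biological replicate variability).
#' @param response A [treatment_response()] applied to inoculated channels.
#' @param treatment_inoculated,treatment_control Treatment labels recorded
#'   in the metadata (single value or one per channel).
#' @param colonize Set `FALSE` to disable the signature entirely (null
#'   experiment: inoculated channels become statistically identical to
#'   controls).
#' @param pause_gap Missing samples inserted at induction (default 600).
#' @param master_seed Integer seed; every channel derives its own
#'   independent stream from `(master_seed, role, index)`.
#' @param experiment_id Label for the generated set.
#' @return A list of class `myco_scenario`.
#' @export
scenario_config <- function(n_inoculated = 24, n_control = 8,
                            day_seconds = 86400,
                            duration_days = 10,
                            colonization_onset_days = 4,
                            induction_days = 7,
                            ramp_days = 0.5,
                            acq = acquisition(0.060),
                            background_rms = 1.42e-4,
                            background_pole = 0.98,
                            tone_freq = 2.0,
                            tone_amplitude = 8.04e-4,
                            band_noise_band = c(1.5, 8),
                            band_noise_rms = 3e-5,
                            noise_floor = 3e-5,
                            amplitude_jitter = 0.15,
                            response = treatment_response("none"),
                            treatment_inoculated = "none",
                            treatment_control = "water_control",
                            colonize = TRUE,
                            pause_gap = 600,
                            master_seed = 1,
                            experiment_id = "synthetic") {
  cfg <- structure(
    list(
      n_inoculated = as.integer(n_inoculated), n_control = as.integer(n_control),
      day_seconds = day_seconds, duration_days = duration_days,
      colonization_onset_days = colonization_onset_days,
      induction_days = induction_days, ramp_days = ramp_days,
      acq = acq,
      background_rms = background_rms, background_pole = background_pole,
      tone_freq = tone_freq, tone_amplitude = tone_amplitude,
      band_noise_band = band_noise_band, band_noise_rms = band_noise_rms,
      noise_floor = noise_floor, amplitude_jitter = amplitude_jitter,
      response = response,
      treatment_inoculated = treatment_inoculated,
      treatment_control = treatment_control,
      colonize = isTRUE(colonize),
      pause_gap = as.integer(pause_gap),
      master_seed = as.integer(master_seed),
      experiment_id = experiment_id
    ),
    class = "myco_scenario"
  )
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_inoculated >= 0 && cfg$n_control >= 0, "channel counts must be >= 0")
  chk(cfg$day_seconds > 0, "day_seconds must be > 0")
  chk(cfg$colonization_onset_days < cfg$induction_days,
      "colonization onset must precede induction")
  chk(cfg$induction_days < cfg$duration_days,
      "induction must precede the end of the recording")
  chk(cfg$background_rms >= 0 && cfg$tone_amplitude >= 0 &&
        cfg$band_noise_rms >= 0 && cfg$noise_floor >= 0,
      "amplitudes must be >= 0")
  chk(abs(cfg$background_pole) < 1, "background_pole must have modulus < 1")
  chk(cfg$tone_freq > 0 && cfg$tone_freq < cfg$acq$sampling_rate / 2,
      "tone frequency must lie below the acquisition Nyquist frequency")
  chk(length(cfg$band_noise_band) == 2 &&
        cfg$band_noise_band[1] < cfg$band_noise_band[2],
      "band_noise_band must be c(low, high) with low < high")
  chk(cfg$pause_gap >= 0, "pause_gap must be >= 0")
  chk(inherits(cfg$response, "myco_response"), "response must be a treatment_response()")
  validate_acquisition(cfg$acq)
  if (length(problems)) {
    abort(paste0("invalid scenario configuration:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  cfg
}

# Deterministic per-channel seed from (master_seed, role, index), independent
# of generation order. Kept below 2^31.
channel_seed <- function(master_seed, role, index) {
  role_code <- if (identical(role, "inoculated")) 1L else 2L
  as.integer((as.double(master_seed) * 48271 + role_code * 1299709 +
                index * 7919) %% 2147483629)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stationary AR(1) drift with pole a, unit RMS, length n.
ar1_drift <- function(n, a) {
  innov <- rnorm(n) * sqrt(1 - a^2)
  as.numeric(stats::filter(innov, a, method = "recursive", init = rnorm(1)))
}

#' Simulate one synthetic channel
#'
#' Deterministic given `(master_seed, role, index)`; see
#' [scenario_config()] for the signal model.
#'
#' @param cfg A [scenario_config()].
#' @param role `"inoculated"` or `"control"`.
#' @param index Channel index within its role (1-based).
#' @return A single-channel `myco_recordings` tibble.
#' @export
simulate_channel <- function(cfg, role = c("inoculated", "control"), index = 1) {
  validate_scenario(cfg)
  role <- match.arg(role)
  day <- cfg$day_seconds
  fs <- cfg$acq$sampling_rate
  n <- round(cfg$duration_days * day * fs)
  induction <- cfg$induction_days * day

  x <- with_local_seed(channel_seed(cfg$master_seed, role, index), {
    jit <- exp(rnorm(3, 0, cfg$amplitude_jitter))
    bg <- ar1_drift(n, cfg$background_pole) * cfg$background_rms * jit[1]
    noise <- rnorm(n) * cfg$noise_floor
    sig <- 0
    if (role == "inoculated" && cfg$colonize) {
      t <- (seq_len(n) - 1) / fs
      onset <- cfg$colonization_onset_days * day
      ramp <- max(cfg$ramp_days * day, .Machine$double.eps)
      env <- pmin(pmax((t - onset) / ramp, 0), 1) *
        response_modulation(t, cfg$response, induction, day)
      phase <- runif(1, 0, 2 * pi)
      tone <- cfg$tone_amplitude * jit[2] * sin(2 * pi * cfg$tone_freq * t + phase)
      bf <- signal::butter(2, cfg$band_noise_band / (fs / 2), type = "pass")
      bn <- as.numeric(signal::filter(bf, rnorm(n)))
      bn <- bn / max(sd(bn), .Machine$double.eps) * cfg$band_noise_rms * jit[3]
      sig <- (tone + bn) * env
    }
    bg + noise + sig
  })

  if (cfg$pause_gap > 0) {
    i0 <- floor(induction * fs) + 1
    x[seq(i0, min(n, i0 + cfg$pause_gap - 1))] <- NA_real_
  }

  treatment <- if (role == "inoculated") {
    if (length(cfg$treatment_inoculated) >= index) cfg$treatment_inoculated[[index]]
    else cfg$treatment_inoculated[[1]]
  } else {
    if (length(cfg$treatment_control) >= index) cfg$treatment_control[[index]]
    else cfg$treatment_control[[1]]
  }
  recording_set(
    list(x),
    channel_id = sprintf("%s_%02d", if (role == "inoculated") "fungi" else "blank", index),
    inoculated = role == "inoculated",
    treatment = treatment,
    induction_time = induction,
    acq = cfg$acq,
    experiment_id = cfg$experiment_id
  )
}

#' Simulate a full multichannel experiment
#'
#' Generates `n_inoculated + n_control` channels with independent
#' per-channel random streams derived from the master seed, shared
#' acquisition settings and metadata populated.
#'
#' @param cfg A [scenario_config()].
#' @return A `myco_recordings` tibble with one row per channel.
#' @examples
#' cfg <- scenario_config(n_inoculated = 2, n_control = 1, day_seconds = 360,
#'                        pause_gap = 10)
#' simulate_experiment(cfg)
#' @export
simulate_experiment <- function(cfg) {
  validate_scenario(cfg)
  parts <- c(
    lapply(seq_len(cfg$n_inoculated), function(i) simulate_channel(cfg, "inoculated", i)),
    lapply(seq_len(cfg$n_control), function(i) simulate_channel(cfg, "control", i))
  )
  if (!length(parts)) {
    return(recording_set(list(), channel_id = character(), acq = cfg$acq,
                         experiment_id = cfg$experiment_id))
  }
  meta <- dplyr::bind_rows(lapply(parts, function(p) tibble::as_tibble(unclass(p))))
  new_recording_set(meta, acq = cfg$acq, experiment_id = cfg$experiment_id)
}
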