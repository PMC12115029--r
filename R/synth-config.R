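#' Default segment plan for a synthetic recording session
#'
#' The emulated protocol is a baseline rest period followed by four
#' stress-inducing tasks, each followed by a two-minute relaxation interval.
#' Task durations are chosen so the whole session lasts exactly 884 s, which
#' at a 3 s window / 1 s step segmentation yields 882 analysis windows per
#' subject. Each task carries a ground-truth stress state that modulates blink
#' statistics, plus a self-reported Likert rating (0--4) consistent with that
#' state; rest phases have no rating.
#'
#' @return A tibble with columns `phase`, `duration_s`, `state`
#'   (`"rest"`, `"stress1"` or `"stress2"`) and `rating` (integer or `NA`).
#' @export
#' @examples
#' default_segment_plan()
default_segment_plan <- function() {
  tibble::tibble(
    phase      = c("rest0", "task1", "rest1", "task2", "rest2",
                   "task3", "rest3", "task4"),
    duration_s = c(120, 101, 120, 101, 120, 101, 120, 101),
    state      = c("rest", "stress1", "rest", "stress1", "rest",
                   "stress2", "rest", "stress2"),
    rating     = c(NA, 2L, NA, 3L, NA, 4L, NA, 4L)
  )
}

#' Configuration for the synthetic EOG + accelerometer generator
#'
#' Bundles every tunable of the session generator: cohort size, sampling rate,
#' the segment plan, resting-state blink statistics and their per-stress-state
#' multipliers, between-subject variability, saccade/drift/noise/artifact
#' parameters and the master seed. All rates are per minute, amplitudes in
#' microvolts (EOG) or g (acceleration), durations in seconds.
#'
#' Stress modulation follows the fatigue-literature direction: under load the
#' blink rate rises, blink duration lengthens and blink amplitude shrinks.
#' Defaults multiply the resting rate by 1.4/1.8, duration by 1.2/1.4 and
#' amplitude by 0.85/0.7 for stress levels 1/2.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param sampling_rate Sampling rate in Hz. Must exceed 15 Hz so the 7.5 Hz
#'   EOG band is below Nyquist.
#' @param segment_plan Tibble as returned by [default_segment_plan()].
#' @param blink_rate Resting blink rate, blinks/min.
#' @param blink_duration_s Mean resting blink duration, s.
#' @param blink_amplitude_uv Mean resting blink amplitude, microvolts.
#' @param stress_mod Named list of per-state multipliers; each element is a
#'   numeric vector `c(rate =, duration =, amplitude =)`.
#' @param subject_sdlog Log-normal between-subject variability (sdlog) applied
#'   to rate, duration and amplitude.
#' @param blink_shape Gamma shape for per-blink duration/amplitude jitter
#'   (larger = tighter around the mean).
#' @param saccade_rate Saccade events/min (applied uniformly over the session).
#' @param saccade_amplitude_uv Mean saccade step amplitude, microvolts.
#' @param drift_amplitude_uv Amplitude of the sinusoidal baseline drift.
#' @param drift_period_s Period of the baseline drift, s.
#' @param noise_sd_uv White measurement noise on the EOG channels, microvolts.
#' @param acc_noise_sd_g White noise on each acceleration axis, g.
#' @param artifact_rate Motion-artifact events/min.
#' @param artifact_eog_uv EOG spike amplitude of a motion artifact.
#' @param artifact_acc_g Acceleration burst amplitude of a motion artifact.
#' @param seed Integer master seed; identical configs give bit-identical
#'   cohorts.
#' @return An object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 2, seed = 42)
#' cfg$n_subjects
synth_config <- function(n_subjects = 12,
                         sampling_rate = 50,
                         segment_plan = default_segment_plan(),
                         blink_rate = 16,
                         blink_duration_s = 0.25,
                         blink_amplitude_uv = 130,
                         stress_mod = list(
                           stress1 = c(rate = 1.4, duration = 1.2, amplitude = 0.85),
                           stress2 = c(rate = 1.8, duration = 1.4, amplitude = 0.70)
                         ),
                         subject_sdlog = c(rate = 0.12, duration = 0.08,
                                           amplitude = 0.15),
                         blink_shape = 25,
                         saccade_rate = 12,
                         saccade_amplitude_uv = 25,
                         drift_amplitude_uv = 40,
                         drift_period_s = 60,
                         noise_sd_uv = 5,
                         acc_noise_sd_g = 0.02,
                         artifact_rate = 1,
                         artifact_eog_uv = 400,
                         artifact_acc_g = 1,
                         seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, sampling_rate = sampling_rate,
    segment_plan = segment_plan, blink_rate = blink_rate,
    blink_duration_s = blink_duration_s,
    blink_amplitude_uv = blink_amplitude_uv, stress_mod = stress_mod,
    subject_sdlog = subject_sdlog, blink_shape = blink_shape,
    saccade_rate = saccade_rate, saccade_amplitude_uv = saccade_amplitude_uv,
    drift_amplitude_uv = drift_amplitude_uv, drift_period_s = drift_period_s,
    noise_sd_uv = noise_sd_uv, acc_noise_sd_g = acc_noise_sd_g,
    artifact_rate = artifact_rate, artifact_eog_uv = artifact_eog_uv,
    artifact_acc_g = artifact_acc_g, seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1) {
    abort("`n_subjects` must be >= 1.", class = "eogstress_parameter_error")
  }
  if (cfg$sampling_rate <= 2 * 7.5) {
    abort("`sampling_rate` must exceed 15 Hz (twice the 7.5 Hz EOG band edge).",
          class = "eogstress_parameter_error")
  }
  plan <- cfg$segment_plan
  req <- c("phase", "duration_s", "state", "rating")
  if (!all(req %in% names(plan))) {
    abort("`segment_plan` must have columns phase, duration_s, state, rating.",
          class = "eogstress_parameter_error")
  }
  if (any(plan$duration_s <= 0)) {
    abort("segment durations must be positive.",
          class = "eogstress_parameter_error")
  }
  if (anyDuplicated(plan$phase)) {
    abort("segment phase names must be unique.",
          class = "eogstress_parameter_error")
  }
  bad_state <- setdiff(unique(plan$state), c("rest", names(cfg$stress_mod)))
  if (length(bad_state)) {
    abort(paste0("unknown segment state(s): ", paste(bad_state, collapse = ", ")),
          class = "eogstress_parameter_error")
  }
  nonneg <- c("blink_rate", "blink_duration_s", "blink_amplitude_uv",
              "saccade_rate", "saccade_amplitude_uv", "drift_amplitude_uv",
              "noise_sd_uv", "acc_noise_sd_g", "artifact_rate",
              "artifact_eog_uv", "artifact_acc_g")
  for (nm in nonneg) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0 ||
        !is.finite(cfg[[nm]])) {
      abort(paste0("`", nm, "` must be a single non-negative finite number."),
            class = "eogstress_parameter_error")
    }
  }
  if (cfg$drift_period_s <= 0) {
    abort("`drift_period_s` must be positive.",
          class = "eogstress_parameter_error")
  }
  invisible(cfg)
}

# Blink parameters (rate /min, duration s, amplitude uV) for one state,
# after applying stress multipliers and per-subject factors.
state_blink_params <- function(cfg, state, subject_factors = c(rate = 1,
                                                               duration = 1,
                                                               amplitude = 1)) {
  mult <- if (identical(state, "rest")) {
    c(rate = 1, duration = 1, amplitude = 1)
  } else {
    cfg$stress_mod[[state]]
  }
  list(
    rate = cfg$blink_rate * mult[["rate"]] * subject_factors[["rate"]],
    duration = cfg$blink_duration_s * mult[["duration"]] *
      subject_factors[["duration"]],
    amplitude = cfg$blink_amplitude_uv * mult[["amplitude"]] *
      subject_factors[["amplitude"]],
    shape = cfg$blink_shape
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  subjects:     ", x$n_subjects, "\n")
  cat("  sampling rate:", x$sampling_rate, "Hz\n")
  cat("  session:      ", sum(x$segment_plan$duration_s), "s in",
      nrow(x$segment_plan), "segments\n")
  cat("  rest blinks:  ", x$blink_rate, "/min,", x$blink_duration_s, "s,",
      x$blink_amplitude_uv, "uV\n")
  cat("  seed:         ", x$seed, "\n")
  invisible(x)
}
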