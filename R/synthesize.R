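#' Sample a train of blink events from a renewal process
#'
#' Inter-blink intervals follow a Gamma(shape = 2) renewal process with a
#' physiological refractory gap: consecutive apices are separated by the mean
#' of the two adjacent blink durations plus a Gamma-distributed open-eye gap
#' whose mean is chosen so the marginal inter-blink interval mean is exactly
#' `60 / rate` seconds. This rules out overlapping blinks by construction
#' while keeping the configured rate unbiased. Per-blink durations and
#' amplitudes are Gamma-jittered around their state means.
#'
#' Uses the current RNG state; seed upstream (e.g. [withr::with_seed()]) for
#' reproducibility.
#'
#' @param state_params List with elements `rate` (blinks/min), `duration`
#'   (mean blink duration, s), `amplitude` (mean amplitude, microvolts) and
#'   optionally `shape` (jitter Gamma shape, default 25).
#' @param duration_s Length of the interval to fill, s.
#' @return Tibble with columns `apex_time_s`, `duration_s`, `amplitude_uv`,
#'   apex times strictly increasing; zero rows when `rate` is 0.
#' @export
#' @examples
#' withr::with_seed(1, sample_blink_train(
#'   list(rate = 16, duration = 0.25, amplitude = 130), duration_s = 60))
sample_blink_train <- function(state_params, duration_s) {
  rate <- state_params$rate
  mean_dur <- state_params$duration
  mean_amp <- state_params$amplitude
  shape <- state_params$shape %||% 25
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "eogstress_parameter_error")
  }
  if (rate < 0 || mean_dur < 0 || mean_amp < 0) {
    abort("blink rate, duration and amplitude must be non-negative.",
          class = "eogstress_parameter_error")
  }
  empty <- tibble::tibble(apex_time_s = double(), duration_s = double(),
                          amplitude_uv = double())
  if (rate == 0) return(empty)

  mean_iv <- 60 / rate
  gap_mean <- mean_iv - mean_dur
  if (gap_mean <= 0) {
    abort("blink rate too high for the configured blink duration.",
          class = "eogstress_parameter_error")
  }
  n_max <- ceiling(duration_s / mean_iv + 6 * sqrt(duration_s / mean_iv) + 20)
  durs <- rgamma(n_max, shape = shape, scale = mean_dur / shape)
  amps <- rgamma(n_max, shape = shape, scale = mean_amp / shape)
  gaps <- rgamma(n_max, shape = 2, scale = gap_mean / 2)
  # apex_1 = gap_1 + dur_1/2; apex_{i+1} = apex_i + (dur_i + dur_{i+1})/2 + gap_{i+1}
  refr <- (durs + dplyr::lag(durs, default = 0)) / 2
  refr[1] <- durs[1] / 2
  apices <- cumsum(gaps + refr)
  keep <- apices + durs / 2 <= duration_s
  if (!any(keep)) return(empty)
  idx <- which(keep)
  tibble::tibble(apex_time_s = apices[idx], duration_s = durs[idx],
                 amplitude_uv = amps[idx])
}

# Unit-amplitude raised-cosine (Hann) pulse of `duration_s` seconds sampled at
# `fs`; peak exactly 1, endpoints exactly 0.
hann_pulse <- function(duration_s, fs) {
  n <- max(3L, 2L * round(duration_s * fs / 2) + 1L)
  0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
}

# Add `pulse * scale` centred on sample `centre` of `x`, clipping at the edges.
add_pulse <- function(x, pulse, centre, scale) {
  half <- (length(pulse) - 1L) %/% 2L
  i0 <- centre - half
  i1 <- centre + half
  p0 <- max(1L, i0)
  p1 <- min(length(x), i1)
  if (p0 > p1) return(x)
  x[p0:p1] <- x[p0:p1] + scale * pulse[(p0 - i0 + 1L):(p1 - i0 + 1L)]
  x
}

#' Render one synthetic recording session
#'
#' Builds the multichannel recording for one subject: the vertical EOG channel
#' is the sum of blink pulses (raised-cosine waveforms at their sampled
#' amplitude and duration), the vertical projection of a saccade step process,
#' a sinusoidal baseline drift, white measurement noise and motion-artifact
#' spikes; the horizontal channel carries the horizontal saccade projection
#' plus noise. The three acceleration axes are a 1 g gravity baseline on z
#' plus noise, with a horizontal-plane burst at every artifact time, so every
#' EOG artifact spike has a coincident acceleration burst.
#'
#' @param config A [synth_config()].
#' @param subject_index Positive integer; selects the subject-specific RNG
#'   stream and variability factors.
#' @return An object of class `eog_session`: a list with `signals` (tibble
#'   `time_s, eog_v, eog_h, acc_x, acc_y, acc_z`), `segments`,
#'   `ratings`, `truth` (ground-truth blink table, artifact times and
#'   per-sample state labels), `sampling_rate` and `subject_id`.
#' @export
#' @examples
#' s <- render_session(synth_config(n_subjects = 1, seed = 7))
#' s
render_session <- function(config, subject_index = 1L) {
  validate_synth_config(config)
  fs <- config$sampling_rate
  plan <- config$segment_plan
  total_s <- sum(plan$duration_s)
  n <- round(total_s * fs)
  seg_start <- cumsum(c(0, plan$duration_s[-nrow(plan)]))
  seg_end <- seg_start + plan$duration_s

  withr::with_seed(derive_seed(config$seed, subject_index), {
    sf <- c(
      rate = exp(rnorm(1, 0, config$subject_sdlog[["rate"]])),
      duration = exp(rnorm(1, 0, config$subject_sdlog[["duration"]])),
      amplitude = exp(rnorm(1, 0, config$subject_sdlog[["amplitude"]]))
    )

    blinks <- purrr::pmap(
      list(plan$state, plan$duration_s, seg_start, plan$phase),
      function(state, dur, start, phase) {
        tr <- sample_blink_train(state_blink_params(config, state, sf), dur)
        tr$apex_time_s <- tr$apex_time_s + start
        tr$phase <- rep(phase, nrow(tr))
        tr$state <- rep(state, nrow(tr))
        tr
      }
    )
    blinks <- dplyr::bind_rows(blinks)

    t <- (seq_len(n) - 1) / fs
    eog_v <- numeric(n)
    if (nrow(blinks)) {
      for (i in seq_len(nrow(blinks))) {
        eog_v <- add_pulse(eog_v, hann_pulse(blinks$duration_s[i], fs),
                           round(blinks$apex_time_s[i] * fs) + 1L,
                           blinks$amplitude_uv[i])
      }
    }

    # saccade step process: each event steps both channels by a random 2-D
    # gaze displacement that persists until the next event
    n_sac <- rpois(1, config$saccade_rate / 60 * total_s)
    step_v <- numeric(n)
    step_h <- numeric(n)
    if (n_sac > 0 && config$saccade_amplitude_uv > 0) {
      sac_t <- sort(runif(n_sac, 0, total_s))
      sac_a <- config$saccade_amplitude_uv * runif(n_sac, 0.5, 1.5)
      theta <- runif(n_sac, 0, 2 * pi)
      iv <- numeric(n)
      ih <- numeric(n)
      idx <- pmin(n, round(sac_t * fs) + 1L)
      for (k in seq_len(n_sac)) {
        iv[idx[k]] <- iv[idx[k]] + sac_a[k] * sin(theta[k])
        ih[idx[k]] <- ih[idx[k]] + sac_a[k] * cos(theta[k])
      }
      step_v <- cumsum(iv)
      step_h <- cumsum(ih)
    }

    drift <- config$drift_amplitude_uv *
      sin(2 * pi * t / config$drift_period_s + runif(1, 0, 2 * pi))

    n_art <- rpois(1, config$artifact_rate / 60 * total_s)
    art_t <- if (n_art > 0) sort(runif(n_art, 2, total_s - 2)) else numeric(0)
    art_pulse_eog <- hann_pulse(0.15, fs)
    acc_x <- rnorm(n, 0, config$acc_noise_sd_g)
    acc_y <- rnorm(n, 0, config$acc_noise_sd_g)
    acc_z <- 1 + rnorm(n, 0, config$acc_noise_sd_g)
    burst_len <- max(3L, 2L * round(0.15 * fs) + 1L)
    burst <- exp(-0.5 * (seq(-3, 3, length.out = burst_len))^2)
    for (ta in art_t) {
      ci <- round(ta * fs) + 1L
      eog_v <- add_pulse(eog_v, art_pulse_eog, ci, config$artifact_eog_uv)
      phi <- runif(1, 0, 2 * pi)
      acc_x <- add_pulse(acc_x, burst, ci, config$artifact_acc_g * cos(phi))
      acc_y <- add_pulse(acc_y, burst, ci, config$artifact_acc_g * sin(phi))
    }

    eog_v <- eog_v + step_v + drift + rnorm(n, 0, config$noise_sd_uv)
    eog_h <- step_h + rnorm(n, 0, config$noise_sd_uv)

    seg_of_sample <- findInterval(t, seg_start)
    session <- structure(list(
      signals = tibble::tibble(
        time_s = t, eog_v = eog_v, eog_h = eog_h,
        acc_x = acc_x, acc_y = acc_y, acc_z = acc_z
      ),
      segments = tibble::tibble(
        phase = plan$phase, state = plan$state, rating = plan$rating,
        start_s = seg_start, end_s = seg_end
      ),
      ratings = plan[!is.na(plan$rating), c("phase", "rating")],
      truth = list(
        blinks = blinks,
        artifact_times_s = art_t,
        state_per_sample = plan$state[seg_of_sample]
      ),
      sampling_rate = fs,
      subject_id = sprintf("S%02d", subject_index)
    ), class = "eog_session")
    session
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' One session per subject, each with its own reproducible RNG stream derived
#' from the master seed, and log-normal between-subject variability applied to
#' the blink rate, duration and amplitude.
#'
#' @param config A [synth_config()].
#' @return A named list of [render_session()] results; names are the unique
#'   subject ids `S01`, `S02`, ...
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_subjects = 2, seed = 3))
#' names(cohort)
generate_cohort <- function(config) {
  validate_synth_config(config)
  sessions <- purrr::map(seq_len(config$n_subjects),
                         ~ render_session(config, .x))
  names(sessions) <- purrr::map_chr(sessions, "subject_id")
  sessions
}

#' @export
print.eog_session <- function(x, ...) {
  dur <- nrow(x$signals) / x$sampling_rate
  cat("<eog_session> subject", x$subject_id, "-", dur, "s at",
      x$sampling_rate, "Hz\n")
  cat("  segments:", nrow(x$segments), " true blinks:",
      nrow(x$truth$blinks), " artifacts:", length(x$truth$artifact_times_s),
      "\n")
  invisible(x)
}

#' Plot the channels of a session
#'
#' @param object An `eog_session`.
#' @param t_lim Optional numeric length-2 time range (s) to display.
#' @param ... Unused.
#' @return A ggplot object faceted by channel.
#' @method autoplot eog_session
#' @export
autoplot.eog_session <- function(object, t_lim = NULL, ...) {
  df <- tidyr::pivot_longer(object$signals, -"time_s",
                            names_to = "channel", values_to = "value")
  if (!is.null(t_lim)) {
    df <- dplyr::filter(df, .data$time_s >= t_lim[1], .data$time_s <= t_lim[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste("Session", object$subject_id))
}
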