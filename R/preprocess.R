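#' Filter specification for EOG and acceleration channels
#'
#' The EOG channel is band-passed with a 6th-order Butterworth (0.25--7.5 Hz),
#' realized as second-order sections of the order-3 analog prototype and
#' applied forward-backward (zero phase) so blink apices are not delayed.
#' Acceleration axes are low-passed with an order-8 windowed-sinc (Hamming)
#' FIR at 10 Hz, also applied zero-phase.
#'
#' @param sampling_rate Sampling rate, Hz.
#' @param eog_order Overall Butterworth band-pass order (even).
#' @param eog_low,eog_high Band edges, Hz.
#' @param accel_order FIR order (number of taps minus one).
#' @param accel_cutoff FIR cutoff, Hz.
#' @return A `filter_spec` object.
#' @export
#' @examples
#' filter_spec(50)
filter_spec <- function(sampling_rate = 50, eog_order = 6,
                        eog_low = 0.25, eog_high = 7.5,
                        accel_order = 8, accel_cutoff = 10) {
  nyq <- sampling_rate / 2
  if (!(eog_low > 0 && eog_low < eog_high && eog_high < nyq)) {
    abort("need 0 < low_cut < high_cut < sampling_rate/2.",
          class = "eogstress_parameter_error")
  }
  if (!(accel_cutoff > 0 && accel_cutoff < nyq)) {
    abort("accel cutoff must lie below Nyquist.",
          class = "eogstress_parameter_error")
  }
  if (eog_order < 2 || eog_order %% 2 != 0 || accel_order < 1) {
    abort("filter orders must be positive (band-pass order even).",
          class = "eogstress_parameter_error")
  }
  structure(list(sampling_rate = sampling_rate, eog_order = eog_order,
                 eog_low = eog_low, eog_high = eog_high,
                 accel_order = accel_order, accel_cutoff = accel_cutoff),
            class = "filter_spec")
}

check_signal <- function(x, min_len, what = "signal") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(paste0(what, " must be finite numeric."),
          class = "eogstress_input_error")
  }
  if (length(x) <= min_len) {
    abort(paste0(what, " too short for the filter (need > ", min_len,
                 " samples)."), class = "eogstress_length_error")
  }
  invisible(x)
}

# Zero-phase filtering with reflection padding to suppress edge transients.
filtfilt_padded <- function(filt, x, pad) {
  pad <- min(pad, length(x) - 1L)
  xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]),
          x,
          2 * x[length(x)] - rev(x[length(x) - seq_len(pad)]))
  yp <- signal::filtfilt(filt, xp)
  yp[pad + seq_along(x)]
}

#' Band-pass filter a vertical or horizontal EOG trace
#'
#' @param x Numeric EOG samples (microvolts).
#' @param spec A [filter_spec()].
#' @return Filtered trace of the same length; DC and drift below 0.25 Hz and
#'   noise above 7.5 Hz are attenuated.
#' @export
#' @examples
#' fs <- filter_spec(50)
#' y <- bandpass_eog(sin(2 * pi * 2 * seq(0, 10, by = 0.02)) * 100, fs)
bandpass_eog <- function(x, spec) {
  check_signal(x, 3L * spec$eog_order, "EOG signal")
  w <- c(spec$eog_low, spec$eog_high) / (spec$sampling_rate / 2)
  bf <- signal::butter(spec$eog_order / 2, w, type = "pass")
  pad <- min(length(x) - 1L,
             ceiling(3 / spec$eog_low * spec$sampling_rate))
  # remove the mean first: DC is outside the passband anyway, and doing it
  # exactly avoids a slowly-decaying numerical residual of the offset
  filtfilt_padded(bf, x - mean(x), pad)
}

#' Low-pass filter one acceleration axis
#'
#' @param x Numeric acceleration samples (g).
#' @param spec A [filter_spec()].
#' @return Filtered trace of the same length; DC (gravity) is preserved.
#' @export
lowpass_accel <- function(x, spec) {
  check_signal(x, 3L * spec$accel_order, "acceleration signal")
  h <- signal::fir1(spec$accel_order,
                    spec$accel_cutoff / (spec$sampling_rate / 2),
                    type = "low")
  h <- h / sum(h)  # exact unit gain at DC (gravity must pass unscaled)
  pad <- min(length(x) - 1L, 10L * spec$accel_order)
  filtfilt_padded(signal::Ma(h), x, pad)
}

#' Euclidean magnitude of the 3-axis acceleration
#'
#' @param acc_x,acc_y,acc_z Equal-length numeric vectors (g).
#' @return Non-negative vector `sqrt(x^2 + y^2 + z^2)`.
#' @export
#' @examples
#' accel_magnitude(0.6, 0.8, 0)
accel_magnitude <- function(acc_x, acc_y, acc_z) {
  if (length(acc_x) != length(acc_y) || length(acc_y) != length(acc_z)) {
    abort("acceleration axes must have equal length.",
          class = "eogstress_input_error")
  }
  sqrt(acc_x^2 + acc_y^2 + acc_z^2)
}

#' Motion-artifact mask from the acceleration magnitude
#'
#' A sample is flagged as a motion artifact when the (low-pass-filtered)
#' acceleration magnitude strictly exceeds the session threshold
#' mean + 3 * sd of the magnitude. The strict inequality makes a constant
#' magnitude (sd = 0) yield an empty mask.
#'
#' @param magnitude Non-empty numeric vector (g).
#' @return An `artifact_mask` object: list with logical `flag`,
#'   `threshold_value`, `mean_mag`, `sd_mag` and `masked_fraction`.
#' @export
#' @examples
#' m <- compute_artifact_mask(c(rep(1, 999), 5))
#' m$masked_fraction
compute_artifact_mask <- function(magnitude) {
  if (!is.numeric(magnitude) || length(magnitude) == 0 || anyNA(magnitude)) {
    abort("`magnitude` must be non-empty finite numeric.",
          class = "eogstress_input_error")
  }
  mu <- mean(magnitude)
  s <- sd(magnitude)
  if (length(magnitude) == 1) s <- 0
  thr <- mu + 3 * s
  flag <- magnitude > thr
  structure(list(flag = flag, threshold_value = thr, mean_mag = mu,
                 sd_mag = s, masked_fraction = mean(flag)),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> threshold %.4f g (mean %.4f + 3 x sd %.4f); %.2f%% masked\n",
              x$threshold_value, x$mean_mag, x$sd_mag,
              100 * x$masked_fraction))
  invisible(x)
}

#' Eliminate EOG peaks coincident with excessive acceleration
#'
#' Samples within `guard_s` of any masked sample are replaced by linear
#' interpolation between the nearest unmasked samples on either side, which
#' removes the artifact peak while preserving the uniform time base that the
#' fixed-length feature windows require. Runs touching the signal edge are
#' extended with the nearest unmasked value.
#'
#' @param eog Numeric EOG samples.
#' @param mask An [compute_artifact_mask()] result (or a logical vector).
#' @param sampling_rate Hz.
#' @param guard_s Half-width of the guard region around each masked sample, s.
#' @return Cleaned trace of the same length.
#' @export
remove_artifact_peaks <- function(eog, mask, sampling_rate, guard_s = 0.5) {
  flag <- if (inherits(mask, "artifact_mask")) mask$flag else as.logical(mask)
  if (length(flag) != length(eog)) {
    abort("mask length must equal signal length.",
          class = "eogstress_input_error")
  }
  if (guard_s < 0) {
    abort("`guard_s` must be >= 0.", class = "eogstress_parameter_error")
  }
  if (!any(flag)) return(eog)
  guard_n <- round(guard_s * sampling_rate)
  bad <- guard_dilate(flag, guard_n)
  if (all(bad)) {
    abort("signal is fully masked; nothing left to interpolate from.",
          class = "eogstress_degenerate_input_error")
  }
  idx <- seq_along(eog)
  interp <- approx(idx[!bad], eog[!bad], xout = idx[bad], rule = 2)$y
  out <- eog
  out[bad] <- interp
  out
}

# Dilate a logical run mask by n samples on each side.
guard_dilate <- function(flag, n) {
  if (n <= 0) return(flag)
  w <- which(flag)
  hits <- unique(pmin(pmax(rep(w, each = 2 * n + 1) + (-n):n, 1L),
                      length(flag)))
  out <- logical(length(flag))
  out[hits] <- TRUE
  out
}

#' Preprocess a whole session
#'
#' Applies the full cleaning chain: band-pass both EOG channels, low-pass the
#' three acceleration axes, compute the acceleration magnitude and its
#' mean + 3 sd artifact mask, and interpolate EOG samples inside the guarded
#' artifact regions.
#'
#' @param session An `eog_session`.
#' @param spec A [filter_spec()]; defaults to the session's sampling rate.
#' @param guard_s Guard half-width around masked samples, s.
#' @return The session with cleaned `signals`, plus `artifact_mask` and a
#'   `preprocess_log` entry recording the threshold and masked fraction.
#' @export
preprocess_session <- function(session, spec = NULL, guard_s = 0.5) {
  spec <- spec %||% filter_spec(session$sampling_rate)
  sig <- session$signals
  acc_f <- purrr::map(sig[c("acc_x", "acc_y", "acc_z")],
                      lowpass_accel, spec = spec)
  mag <- accel_magnitude(acc_f$acc_x, acc_f$acc_y, acc_f$acc_z)
  mask <- compute_artifact_mask(mag)
  out <- session
  out$signals <- dplyr::mutate(
    sig,
    eog_v = remove_artifact_peaks(bandpass_eog(sig$eog_v, spec), mask,
                                  session$sampling_rate, guard_s),
    eog_h = remove_artifact_peaks(bandpass_eog(sig$eog_h, spec), mask,
                                  session$sampling_rate, guard_s),
    acc_x = acc_f$acc_x, acc_y = acc_f$acc_y, acc_z = acc_f$acc_z
  )
  out$artifact_mask <- mask
  out$preprocess_log <- tibble::tibble(
    subject_id = session$subject_id,
    threshold_g = mask$threshold_value,
    masked_fraction = mask$masked_fraction,
    guard_s = guard_s
  )
  out
}
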