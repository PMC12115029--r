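#' Canonical blink template
#'
#' A unit-amplitude raised-cosine (Hann) pulse: smooth, unimodal, zero at both
#' endpoints, which matches the morphology of a vertical-EOG blink deflection.
#' Candidate events are scored by the RMSE of their least-squares fit to this
#' template.
#'
#' @param duration_s Template duration, s.
#' @param sampling_rate Hz.
#' @return A `blink_template`: list with `duration_s`, `shape` (numeric
#'   vector, peak exactly 1) and `n_samples`.
#' @export
#' @examples
#' tpl <- blink_template(0.3, 50)
#' tpl$n_samples
blink_template <- function(duration_s = 0.3, sampling_rate = 50) {
  if (duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "eogstress_parameter_error")
  }
  shape <- hann_pulse(duration_s, sampling_rate)
  structure(list(duration_s = duration_s, shape = shape,
                 n_samples = length(shape)),
            class = "blink_template")
}

# Prominence of each local maximum: height above the higher of the two lowest
# points separating it from higher terrain on either side.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p - 1L)]
    right <- x[seq.int(p + 1L, length(x))]
    higher_l <- which(left > x[p])
    base_l <- if (length(higher_l)) {
      min(left[seq.int(max(higher_l), length(left))])
    } else min(left)
    higher_r <- which(right > x[p])
    base_r <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r))])
    } else min(right)
    x[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Find candidate blink apices
#'
#' Local maxima of the filtered vertical EOG whose topographic prominence is
#' at least `min_prominence`, thinned so surviving apices are pairwise
#' separated by at least `min_separation_s` (higher peaks win). The default
#' prominence floor is 3 times a robust (MAD-based) estimate of the noise sd.
#'
#' @param eog_v Filtered vertical EOG samples.
#' @param sampling_rate Hz.
#' @param min_prominence Microvolts; `NULL` for the robust default.
#' @param min_separation_s Minimum apex separation, s.
#' @return Integer vector of apex sample indices (possibly empty), increasing.
#' @export
detect_candidates <- function(eog_v, sampling_rate, min_prominence = NULL,
                              min_separation_s = 0.2) {
  if (length(eog_v) < 3) return(integer(0))
  min_prominence <- min_prominence %||% (3 * mad(eog_v))
  if (min_prominence <= 0) {
    abort("`min_prominence` must be positive.",
          class = "eogstress_parameter_error")
  }
  dx <- diff(eog_v)
  peaks <- which(dx[-length(dx)] > 0 & dx[-1] <= 0) + 1L
  if (!length(peaks)) return(integer(0))
  prom <- peak_prominence(eog_v, peaks)
  peaks <- peaks[prom >= min_prominence]
  if (!length(peaks)) return(integer(0))
  # enforce separation, keeping the taller of any close pair
  ord <- peaks[order(eog_v[peaks], decreasing = TRUE)]
  min_gap <- round(min_separation_s * sampling_rate)
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Score one candidate apex against the blink template
#'
#' The template is centred on the apex and scaled by least squares onto the
#' signal excerpt; the event amplitude is that scale, and `rmse_norm` is the
#' fit RMSE divided by the amplitude, making the score invariant to signal
#' scaling. The event duration is the template duration rescaled to the
#' excerpt's measured half-amplitude width.
#'
#' @param eog_v Filtered vertical EOG samples.
#' @param apex Apex sample index.
#' @param template A [blink_template()].
#' @param sampling_rate Hz.
#' @return A one-row tibble (`apex_time_s`, `onset_s`, `offset_s`,
#'   `amplitude_uv`, `duration_s`, `rmse_norm`), or `NULL` when the apex is
#'   too close to the signal edge or the fitted amplitude is not positive.
#' @export
score_candidate <- function(eog_v, apex, template, sampling_rate) {
  half <- (template$n_samples - 1L) %/% 2L
  if (apex - half < 1L || apex + half > length(eog_v)) return(NULL)
  excerpt <- eog_v[(apex - half):(apex + half)]
  tpl <- template$shape
  amp <- sum(excerpt * tpl) / sum(tpl^2)
  if (!is.finite(amp) || amp <= 0) return(NULL)
  rmse <- sqrt(mean((excerpt - amp * tpl)^2))
  # half-amplitude width of the excerpt around its centre
  above <- excerpt >= amp / 2
  centre <- half + 1L
  lo <- centre
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- centre
  while (hi < length(above) && above[hi + 1L]) hi <- hi + 1L
  half_width_s <- (hi - lo) / sampling_rate
  # a Hann pulse of duration D has half-amplitude width D/2
  dur <- max(2 * half_width_s, 2 / sampling_rate)
  apex_s <- (apex - 1) / sampling_rate
  tibble::tibble(
    apex_time_s = apex_s,
    onset_s = apex_s - dur / 2,
    offset_s = apex_s + dur / 2,
    amplitude_uv = amp,
    duration_s = dur,
    rmse_norm = rmse / amp
  )
}

#' Adaptive acceptance of scored blink candidates
#'
#' An event is accepted when its normalized template-fit error is no larger
#' than the Tukey upper fence of the session's `rmse_norm` distribution
#' (q75 + 1.5 IQR), capped by an absolute ceiling. The fence adapts to the
#' session's noise level; the cap rejects grossly non-blink morphologies even
#' when the whole candidate set is poor.
#'
#' @param events Tibble of scored events (needs an `rmse_norm` column).
#' @param absolute_cap Upper bound on the acceptance threshold.
#' @return The events with a logical `accepted` column added; row order kept.
#' @export
adaptive_accept <- function(events, absolute_cap = 0.5) {
  if (nrow(events) == 0) {
    events$accepted <- logical(0)
    return(events)
  }
  q <- quantile(events$rmse_norm, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  thr <- min(absolute_cap, fence)
  dplyr::mutate(events, accepted = .data$rmse_norm <= thr)
}

#' Detect blinks in a preprocessed session
#'
#' Full detector: candidate apices by prominence, template scoring of each
#' candidate, then adaptive acceptance. Candidates too close to the signal
#' edge for a full template excerpt are dropped.
#'
#' @param session A preprocessed `eog_session` (or any list with `signals`
#'   containing `eog_v` and a `sampling_rate`).
#' @param template A [blink_template()]; default 0.3 s at the session rate.
#' @param min_prominence Passed to [detect_candidates()].
#' @param min_separation_s Passed to [detect_candidates()].
#' @param absolute_cap Passed to [adaptive_accept()].
#' @return Tibble of blink events with `subject_id` and `accepted` columns.
#' @export
#' @examples
#' s <- preprocess_session(render_session(synth_config(n_subjects = 1)))
#' head(detect_blinks(s))
detect_blinks <- function(session, template = NULL, min_prominence = NULL,
                          min_separation_s = 0.2, absolute_cap = 0.5) {
  fs <- session$sampling_rate
  template <- template %||% blink_template(0.3, fs)
  v <- session$signals$eog_v
  apices <- detect_candidates(v, fs, min_prominence, min_separation_s)
  scored <- purrr::map(apices, ~ score_candidate(v, .x, template, fs))
  scored <- dplyr::bind_rows(scored)
  if (nrow(scored) == 0) {
    scored <- tibble::tibble(apex_time_s = double(), onset_s = double(),
                             offset_s = double(), amplitude_uv = double(),
                             duration_s = double(), rmse_norm = double())
  }
  out <- adaptive_accept(scored, absolute_cap)
  out$subject_id <- rep(session$subject_id %||% NA_character_, nrow(out))
  out
}

#' Match detected blink apices to ground truth
#'
#' Greedy one-to-one matching by increasing time difference, with a matching
#' tolerance; used to score a detector against the generator's ground truth.
#'
#' @param detected_s,truth_s Numeric apex times, s.
#' @param tol_s Maximum time difference for a match.
#' @return List with counts `tp`, `fp`, `fn` and `precision`, `recall`, `f1`.
#' @export
match_blinks <- function(detected_s, truth_s, tol_s = 0.1) {
  if (length(detected_s) == 0 || length(truth_s) == 0) {
    tp <- 0L
  } else {
    pairs <- expand.grid(d = seq_along(detected_s), t = seq_along(truth_s))
    pairs$dt <- abs(detected_s[pairs$d] - truth_s[pairs$t])
    pairs <- pairs[pairs$dt <= tol_s, ]
    pairs <- pairs[order(pairs$dt), ]
    used_d <- logical(length(detected_s))
    used_t <- logical(length(truth_s))
    tp <- 0L
    for (i in seq_len(nrow(pairs))) {
      d <- pairs$d[i]; t <- pairs$t[i]
      if (!used_d[d] && !used_t[t]) {
        used_d[d] <- TRUE; used_t[t] <- TRUE; tp <- tp + 1L
      }
    }
  }
  fp <- length(detected_s) - tp
  fn <- length(truth_s) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}
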