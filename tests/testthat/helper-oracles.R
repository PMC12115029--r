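# Shared fixtures and independent brute-force oracles for the test suite.

# A short session plan so unit tests stay fast: 140 s, two tasks.
tiny_config <- function(seed = 1L, n_subjects = 1L, ...) {
  synth_config(
    n_subjects = n_subjects,
    segment_plan = tibble::tibble(
      phase = c("rest0", "task1", "rest1", "task2"),
      duration_s = c(40, 40, 20, 40),
      state = c("rest", "stress1", "rest", "stress2"),
      rating = c(NA, 2L, NA, 4L)
    ),
    seed = seed,
    ...
  )
}

# A config with every signal source switched off except what the caller adds.
silent_config <- function(seed = 1L, blink_rate = 0, ...) {
  tiny_config(seed = seed, blink_rate = blink_rate,
              saccade_rate = 0, drift_amplitude_uv = 0,
              noise_sd_uv = 0, artifact_rate = 0, acc_noise_sd_g = 0, ...)
}

# Naive first-principles recomputation of the nine window features, written
# with explicit loops so it shares nothing with the implementation.
oracle_window_features <- function(eog_v, eog_h, blinks, window_start_s,
                                   window_s, sampling_rate) {
  n <- length(eog_v)
  total <- numeric(n)
  for (i in seq_len(n)) total[i] <- eog_v[i] + eog_h[i]
  naive_mean <- function(x) sum(x) / length(x)
  naive_pvar <- function(x) {
    m <- naive_mean(x)
    s <- 0
    for (xi in x) s <- s + (xi - m)^2
    s / length(x)
  }
  nb <- nrow(blinks)
  p2p <- 0
  if (nb > 0) {
    tot_p2p <- 0
    for (i in seq_len(nb)) {
      i0 <- max(1, round((blinks$onset_s[i] - window_start_s) * sampling_rate) + 1)
      i1 <- min(n, round((blinks$offset_s[i] - window_start_s) * sampling_rate) + 1)
      seg <- eog_v[i0:i1]
      tot_p2p <- tot_p2p + (max(seg) - min(seg))
    }
    p2p <- tot_p2p / nb
  }
  mv <- naive_mean(eog_v)
  mt <- naive_mean(total)
  cov_vt <- 0
  for (i in seq_len(n)) cov_vt <- cov_vt + (eog_v[i] - mv) * (total[i] - mt)
  c(
    blink_freq = nb / window_s,
    mean_p2p_v = p2p,
    var_v = naive_pvar(eog_v),
    cov_v = cov_vt / n,
    sd_peaks = if (nb >= 2) sqrt(naive_pvar(blinks$amplitude_uv)) else 0,
    rms_signal = sqrt(naive_mean(total^2)),
    max_v = max(eog_v),
    mean_total = mt,
    sd_total = sqrt(naive_pvar(total))
  )
}

# Independent per-class confusion-matrix metrics, computed cell by cell.
oracle_metrics <- function(cm) {
  classes <- rownames(cm)
  out <- list()
  total <- sum(cm)
  correct <- 0
  for (cl in classes) correct <- correct + cm[cl, cl]
  for (cl in classes) {
    tp <- cm[cl, cl]
    fp <- sum(cm[setdiff(classes, cl), cl])
    fn <- sum(cm[cl, setdiff(classes, cl)])
    tn <- total - tp - fp - fn
    out[[cl]] <- c(
      precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
      specificity = if (tn + fp > 0) tn / (tn + fp) else 0
    )
  }
  list(accuracy = correct / total, per_class = out)
}

# Simple amplitude-threshold reference blink detector, independent of the
# template-matching path: runs above 4 robust sd, apex at each run's maximum.
reference_blink_detector <- function(eog_v, sampling_rate) {
  thr <- 4 * mad(eog_v)
  above <- eog_v > thr
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  apices <- numeric(0)
  for (i in which(r$values)) {
    seg <- starts[i]:ends[i]
    apices <- c(apices, seg[which.max(eog_v[seg])])
  }
  # merge apices closer than 0.2 s, keeping the larger
  apices <- sort(apices)
  keep <- rep(TRUE, length(apices))
  for (i in seq_along(apices)[-1]) {
    if (apices[i] - apices[i - 1] < 0.2 * sampling_rate) {
      drop <- if (eog_v[apices[i]] >= eog_v[apices[i - 1]]) i - 1 else i
      keep[drop] <- FALSE
    }
  }
  (apices[keep] - 1) / sampling_rate
}

# Random feature table with labels independent of (or dependent on) features;
# used for protocol and null-simulation tests.
random_feature_table <- function(n, seed, signal = 0) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 9), n, 9,
                dimnames = list(NULL, eogstress:::feature_names()))
    eta <- signal * (x[, "blink_freq"] + x[, "mean_p2p_v"])
    lab <- ifelse(runif(n) < plogis(eta), "stress", "no_stress")
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("S%02d", rep_len(1:4, n)),
        start_s = seq_len(n),
        phase = rep_len(c("rest0", "task1"), n),
        label2 = lab,
        label3 = lab
      ),
      tibble::as_tibble(x)
    )
  })
}
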