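#' Sliding-window start times
#'
#' Windows of `window_s` seconds advanced by `step_s`; a start is kept while
#' the whole window fits inside the session, so the count is
#' `floor((duration - window) / step) + 1`. An 884 s session at 3 s / 1 s
#' yields 882 windows.
#'
#' @param session_duration_s Session length, s.
#' @param window_s Window length, s.
#' @param step_s Step between consecutive window starts, s.
#' @return Numeric vector of start times (s); empty with a warning when the
#'   session is shorter than one window.
#' @export
#' @examples
#' length(segment_windows(884))
segment_windows <- function(session_duration_s, window_s = 3, step_s = 1) {
  if (window_s <= 0 || step_s <= 0) {
    abort("`window_s` and `step_s` must be positive.",
          class = "eogstress_parameter_error")
  }
  if (session_duration_s < window_s) {
    warn("session shorter than one window; no windows produced.")
    return(numeric(0))
  }
  n <- floor((session_duration_s - window_s) / step_s) + 1
  seq(0, by = step_s, length.out = n)
}

feature_names <- function() {
  c("blink_freq", "mean_p2p_v", "var_v", "cov_v", "sd_peaks",
    "rms_signal", "max_v", "mean_total", "sd_total")
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Compute the nine per-window features
#'
#' Features of one 3 s excerpt of the cleaned signals: blink frequency
#' (accepted apices per second), mean peak-to-peak vertical amplitude over
#' the in-window blinks, population variance of the vertical component,
#' population covariance between the vertical and the total signal, sd of the
#' in-window blink amplitudes, RMS of the total signal, vertical maximum, and
#' mean and sd of the total signal. The total EOG signal is the element-wise
#' sum of the vertical and horizontal components. Blink-dependent features
#' are 0 in blink-free windows so the matrix stays dense.
#'
#' @param eog_v,eog_h Window excerpts of the cleaned channels (equal length).
#' @param blinks Tibble of accepted blinks whose apex falls in the window
#'   (columns `apex_time_s`, `onset_s`, `offset_s`, `amplitude_uv`).
#' @param window_start_s Window start time, s.
#' @param window_s Window length, s.
#' @param sampling_rate Hz.
#' @return A named numeric vector of the nine features.
#' @export
compute_window_features <- function(eog_v, eog_h, blinks, window_start_s,
                                    window_s = 3, sampling_rate = 50) {
  if (anyNA(eog_v) || anyNA(eog_h)) {
    abort("window contains NaN samples.", class = "eogstress_input_error")
  }
  if (length(eog_v) != length(eog_h)) {
    abort("vertical and horizontal excerpts must have equal length.",
          class = "eogstress_input_error")
  }
  total <- eog_v + eog_h
  n_blinks <- nrow(blinks)
  p2p <- 0
  if (n_blinks > 0) {
    p2p <- mean(vapply(seq_len(n_blinks), function(i) {
      i0 <- max(1L, round((blinks$onset_s[i] - window_start_s) *
                            sampling_rate) + 1L)
      i1 <- min(length(eog_v), round((blinks$offset_s[i] - window_start_s) *
                                       sampling_rate) + 1L)
      seg <- eog_v[i0:i1]
      max(seg) - min(seg)
    }, numeric(1)))
  }
  sd_peaks <- if (n_blinks >= 2) sqrt(pop_var(blinks$amplitude_uv)) else 0
  c(
    blink_freq = n_blinks / window_s,
    mean_p2p_v = p2p,
    var_v = pop_var(eog_v),
    cov_v = mean((eog_v - mean(eog_v)) * (total - mean(total))),
    sd_peaks = sd_peaks,
    rms_signal = sqrt(mean(total^2)),
    max_v = max(eog_v),
    mean_total = mean(total),
    sd_total = sqrt(pop_var(total))
  )
}

#' Map a window's phase and Likert rating to stress labels
#'
#' Rest phases are `no_stress` in both schemes. Task phases are labelled from
#' the subject's self-reported 0--4 Likert rating: the two-class label is
#' `stress` when the rating is at least 2; the three-class label is
#' `no_stress` for ratings 0--1, `stress1` for 2--3 and `stress2` for 4.
#'
#' @param state Segment state, `"rest"` or a task state.
#' @param rating Likert rating 0--4 (ignored for rest).
#' @return Named list with `label2` and `label3` character scalars.
#' @export
#' @examples
#' assign_labels("task", 4)
assign_labels <- function(state, rating) {
  if (identical(state, "rest")) {
    return(list(label2 = "no_stress", label3 = "no_stress"))
  }
  if (is.na(rating)) {
    abort("task segment is missing its Likert rating.",
          class = "eogstress_labeling_error")
  }
  if (rating < 0 || rating > 4) {
    abort("Likert rating must lie in 0..4.",
          class = "eogstress_labeling_error")
  }
  list(
    label2 = if (rating >= 2) "stress" else "no_stress",
    label3 = if (rating <= 1) "no_stress" else if (rating <= 3) "stress1"
             else "stress2"
  )
}

#' Extract the per-window feature table for one session
#'
#' Segments the session into sliding windows, computes the nine features per
#' window from the cleaned channels and the accepted blinks (assigned to a
#' window when the apex time lies in `[start, start + window)`), and labels
#' each window from its segment's phase and rating. Windows that cross a
#' segment boundary are dropped: a window spanning rest and task has no
#' single true label.
#'
#' @param session A preprocessed `eog_session`.
#' @param blinks Blink table from [detect_blinks()]; only accepted rows are
#'   used.
#' @param window_s,step_s Windowing parameters, s.
#' @return Tibble with one row per labelled window: `subject_id`, `start_s`,
#'   `phase`, `label2`, `label3` and the nine feature columns.
#' @export
extract_features <- function(session, blinks, window_s = 3, step_s = 1) {
  fs <- session$sampling_rate
  sig <- session$signals
  duration <- nrow(sig) / fs
  starts <- segment_windows(duration, window_s, step_s)
  if (!length(starts)) return(tibble::tibble())
  acc <- blinks[blinks$accepted, , drop = FALSE]
  segs <- session$segments
  win_n <- round(window_s * fs)

  rows <- purrr::map(starts, function(s0) {
    seg_i <- which(segs$start_s <= s0 & s0 + window_s <= segs$end_s)
    if (length(seg_i) != 1) return(NULL)  # boundary-crossing window
    i0 <- round(s0 * fs) + 1L
    idx <- i0:(i0 + win_n - 1L)
    inb <- acc[acc$apex_time_s >= s0 & acc$apex_time_s < s0 + window_s, ,
               drop = FALSE]
    fts <- compute_window_features(sig$eog_v[idx], sig$eog_h[idx], inb,
                                   s0, window_s, fs)
    lab <- assign_labels(segs$state[seg_i], segs$rating[seg_i])
    tibble::tibble(
      subject_id = session$subject_id, start_s = s0,
      phase = segs$phase[seg_i], label2 = lab$label2, label3 = lab$label3,
      !!!as.list(fts)
    )
  })
  dplyr::bind_rows(rows)
}

#' Extract features for a whole cohort
#'
#' Runs preprocessing, blink detection and [extract_features()] on every
#' session and binds the results.
#'
#' @param cohort List of sessions from [generate_cohort()].
#' @param spec Optional [filter_spec()].
#' @param ... Passed to [extract_features()].
#' @return Combined feature tibble across subjects.
#' @export
cohort_features <- function(cohort, spec = NULL, ...) {
  dplyr::bind_rows(purrr::map(cohort, function(s) {
    p <- preprocess_session(s, spec)
    extract_features(p, detect_blinks(p), ...)
  }))
}

#' Lasso feature selection
#'
#' Fits an L1-penalized (multinomial) logistic regression on the standardized
#' training features and keeps the features with a non-zero coefficient at
#' the chosen penalty. When `lambda` is `NULL` it is picked by internal
#' 10-fold cross-validation on misclassification error (`lambda.1se`, the
#' sparsest model within one standard error of the minimum CV error).
#' Constant feature columns cannot be
#' standardized and are excluded up front.
#'
#' @param features Tibble or matrix of training-fold feature columns.
#' @param labels Class labels (character or factor), length `nrow(features)`.
#' @param lambda Penalty; `NULL` for CV choice.
#' @param seed Seed for the CV fold assignment.
#' @return Named logical vector (the selection mask) with attributes
#'   `lambda` (penalty used) and `dropped_constant` (names of any constant
#'   columns excluded).
#' @export
lasso_select <- function(features, labels, lambda = NULL, seed = 1L) {
  x <- as.matrix(features[feature_cols(features)])
  labels <- as.factor(as.character(labels))
  if (!is.null(lambda) && lambda < 0) {
    abort("`lambda` must be >= 0.", class = "eogstress_parameter_error")
  }
  sds <- apply(x, 2, sd)
  constant <- sds == 0
  if (any(constant)) {
    inform(paste("dropping constant feature(s):",
                 paste(colnames(x)[constant], collapse = ", ")))
  }
  mask <- setNames(rep(FALSE, ncol(x)), colnames(x))
  xs <- scale(x[, !constant, drop = FALSE])
  fam <- if (nlevels(labels) > 2) "multinomial" else "binomial"
  if (is.null(lambda)) {
    cv <- withr::with_seed(seed, glmnet::cv.glmnet(
      xs, labels, family = fam, alpha = 1, standardize = FALSE,
      nfolds = 10, type.measure = "class"))
    lambda <- cv$lambda.1se
    fit <- cv$glmnet.fit
  } else if (lambda == 0) {
    # unpenalized limit: every (non-constant) feature is retained
    mask[colnames(xs)] <- TRUE
    attr(mask, "lambda") <- 0
    attr(mask, "dropped_constant") <- colnames(x)[constant]
    return(mask)
  } else {
    fit <- glmnet::glmnet(xs, labels, family = fam, alpha = 1,
                          standardize = FALSE)
  }
  cf <- coef(fit, s = lambda)
  nz <- if (is.list(cf)) {
    Reduce(`|`, lapply(cf, function(m) as.matrix(m)[-1, 1] != 0))
  } else {
    as.matrix(cf)[-1, 1] != 0
  }
  mask[names(nz)[nz]] <- TRUE
  attr(mask, "lambda") <- lambda
  attr(mask, "dropped_constant") <- colnames(x)[constant]
  mask
}

# Names of the feature columns present in a feature table.
feature_cols <- function(features) {
  intersect(feature_names(), colnames(features))
}
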