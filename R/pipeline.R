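session_header <- c("time_s", "eog_v", "eog_h", "acc_x", "acc_y", "acc_z")

#' Write a session to CSV (+ JSON sidecar)
#'
#' The CSV holds the six signal columns at full double precision (so a
#' write-read cycle reproduces the samples exactly); the sidecar
#' `<path>.json` holds the segment annotations, Likert ratings, sampling rate,
#' subject id and (when present) the ground truth.
#'
#' @param session An `eog_session`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  df <- session$signals[session_header]
  readr::write_csv(df, path)
  sidecar <- list(
    subject_id = session$subject_id,
    sampling_rate = session$sampling_rate,
    segments = session$segments,
    ratings = session$ratings,
    truth = if (!is.null(session$truth)) list(
      blinks = session$truth$blinks,
      artifact_times_s = session$truth$artifact_times_s
    )
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a session written by [write_session_csv()]
#'
#' Validates the exact six-column header, time monotonicity and (when a
#' sampling rate is known from the sidecar) the sample spacing.
#'
#' @param path CSV path; the JSON sidecar `<path>.json` is read when present.
#' @return An `eog_session`.
#' @export
read_session_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, session_header)) {
    missing_cols <- setdiff(session_header, hdr)
    abort(paste0("line 1: bad session header",
                 if (length(missing_cols)) paste0(" (missing: ",
                   paste(missing_cols, collapse = ", "), ")")),
          class = "eogstress_format_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double()))
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    abort(paste0("line ", which(dt <= 0)[1] + 2,
                 ": time column is not strictly increasing."),
          class = "eogstress_format_error")
  }
  sidecar_path <- paste0(path, ".json")
  session <- list(signals = tibble::as_tibble(df))
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    fs <- sc$sampling_rate
    if (!is.null(fs) && max(abs(dt - 1 / fs)) > 1e-6) {
      abort(paste0("line ", which.max(abs(dt - 1 / fs)) + 2,
                   ": sample spacing does not match the declared ",
                   fs, " Hz rate."),
            class = "eogstress_format_error")
    }
    session$sampling_rate <- fs
    session$subject_id <- sc$subject_id
    session$segments <- tibble::as_tibble(sc$segments)
    session$ratings <- tibble::as_tibble(sc$ratings)
    if (!is.null(sc$truth)) {
      session$truth <- list(
        blinks = tibble::as_tibble(sc$truth$blinks),
        artifact_times_s = as.numeric(sc$truth$artifact_times_s %||%
                                        numeric(0))
      )
    }
  } else {
    session$sampling_rate <- round(1 / median(dt))
  }
  structure(session, class = "eog_session")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> preprocess -> detect blinks -> extract features ->
#' (Lasso inside each training fold) -> train -> evaluate for every requested
#' classifier and protocol, optionally writing all intermediate artifacts and
#' a manifest with a content hash per file. Rerunning with the same config
#' reproduces identical reports.
#'
#' @param config A [synth_config()]; its seed drives every stage.
#' @param classifiers Character vector of classifier names.
#' @param class_schemes Character vector, subset of `c("two", "three")`.
#' @param protocols Subset of `c("kfold", "loso")`.
#' @param out_dir Optional directory for artifacts (sessions, blink tables,
#'   feature table, reports, manifest).
#' @param lasso Apply per-fold Lasso selection?
#' @return List with `features`, `blinks`, `preprocess_log`, `reports`
#'   (nested by scheme/protocol/classifier), `summary` (tibble of mean
#'   metrics) and `manifest`.
#' @export
run_pipeline <- function(config = synth_config(),
                         classifiers = c("rf", "lr", "svm", "dt", "knn"),
                         class_schemes = c("two", "three"),
                         protocols = "kfold",
                         out_dir = NULL, lasso = TRUE) {
  cohort <- generate_cohort(config)
  spec <- filter_spec(config$sampling_rate)
  processed <- purrr::map(cohort, preprocess_session, spec = spec)
  blinks <- purrr::map(processed, detect_blinks)
  features <- dplyr::bind_rows(purrr::map2(
    processed, blinks, ~ extract_features(.x, .y)))
  preprocess_log <- dplyr::bind_rows(purrr::map(processed, "preprocess_log"))

  reports <- list()
  summary_rows <- list()
  for (scheme in class_schemes) {
    for (protocol in protocols) {
      for (clf in classifiers) {
        ms <- model_spec(clf, scheme, seed = derive_seed(config$seed, 1))
        rep_obj <- if (identical(protocol, "loso")) {
          evaluate_loso(features, ms, lasso = lasso)
        } else {
          evaluate_kfold(features, ms, lasso = lasso,
                         seed = derive_seed(config$seed, 2))
        }
        reports[[scheme]][[protocol]][[clf]] <- rep_obj
        summary_rows[[length(summary_rows) + 1]] <- glance(rep_obj)
      }
    }
  }
  result <- list(
    features = features,
    blinks = dplyr::bind_rows(blinks),
    preprocess_log = preprocess_log,
    reports = reports,
    summary = dplyr::bind_rows(summary_rows)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in cohort) {
      write_session_csv(s, file.path(out_dir,
                                     paste0("session_", s$subject_id, ".csv")))
    }
    readr::write_csv(result$blinks, file.path(out_dir, "blinks.csv"))
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(result$summary, file.path(out_dir, "summary.csv"))
    jsonlite::write_json(
      purrr::map(reports, function(by_proto) purrr::map(by_proto,
        function(by_clf) purrr::map(by_clf, glance))),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    result$manifest <- manifest
  }
  result
}
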