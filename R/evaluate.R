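#' Confusion matrix from truth/prediction vectors
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class ordering; defaults to the sorted union.
#' @return A `confusion_matrix`: square integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.",
          class = "eogstress_input_error")
  }
  if (length(truth) == 0) {
    abort("cannot build a confusion matrix from zero predictions.",
          class = "eogstress_input_error")
  }
  classes <- classes %||% sort(unique(c(as.character(truth),
                                        as.character(predicted))))
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy plus one-vs-rest precision, recall, F1 and specificity
#' per class, and their macro averages:
#' accuracy = sum(TP_i) / total, Pr_i = TP_i/(TP_i+FP_i),
#' Re_i = TP_i/(TP_i+FN_i), F1_i = 2 TP_i/(2 TP_i+FP_i+FN_i),
#' Spe_i = TN_i/(TN_i+FP_i). A zero-denominator cell yields 0 and sets the
#' `zero_denominator` flag for that class.
#'
#' @param cm A [confusion_matrix()] (any square matrix with class dimnames).
#' @return List with `accuracy`, `per_class` (tibble of class, tp, fp, tn,
#'   fn, precision, recall, f1, specificity, zero_denominator) and `macro`
#'   (one-row tibble of macro-averaged precision, recall, f1, specificity).
#' @export
#' @examples
#' cm <- confusion_matrix(rep(c("n", "s"), c(50, 50)),
#'                        rep(c("n", "s", "n", "s"), c(45, 5, 5, 45)))
#' metrics_from_confusion(cm)$accuracy
metrics_from_confusion <- function(cm) {
  if (is.null(dim(cm)) || nrow(cm) == 0 || nrow(cm) != ncol(cm)) {
    abort("`cm` must be a non-empty square matrix.",
          class = "eogstress_input_error")
  }
  total <- sum(cm)
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  per_class <- tibble::tibble(
    class = classes,
    tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    specificity = safe_div(tn, tn + fp),
    zero_denominator = (tp + fp == 0) | (tp + fn == 0) | (tn + fp == 0)
  )
  list(
    accuracy = sum(tp) / total,
    per_class = per_class,
    macro = tibble::tibble(
      precision = mean(per_class$precision),
      recall = mean(per_class$recall),
      f1 = mean(per_class$f1),
      specificity = mean(per_class$specificity)
    )
  )
}

# Stratified assignment of rows to k folds. Within each class, shuffled rows
# are dealt evenly; each class's remainder goes to the currently least-filled
# folds, so total fold sizes also differ by at most one.
stratified_folds <- function(labels, k, seed) {
  if (any(table(labels) < k)) {
    abort(paste0("every class needs at least ", k,
                 " windows for stratified ", k, "-fold CV."),
          class = "eogstress_stratification_error")
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    fill <- integer(k)
    for (cl in unique(labels)) {
      ix <- sample(which(labels == cl))
      n_c <- length(ix)
      cnt <- rep(n_c %/% k, k)
      extra <- n_c %% k
      if (extra > 0) {
        take <- order(fill, seq_len(k))[seq_len(extra)]
        cnt[take] <- cnt[take] + 1L
      }
      folds[ix] <- rep.int(seq_len(k), cnt)
      fill <- fill + cnt
    }
  })
  folds
}

evaluate_folds <- function(features, fold_id, spec, lasso, lambda,
                           grid = NULL) {
  lab_col <- label_column(spec$class_scheme)
  classes <- sort(unique(features[[lab_col]]))
  fold_rows <- list()
  predictions <- vector("list", length(unique(fold_id)))
  fold_levels <- sort(unique(fold_id))
  for (i in seq_along(fold_levels)) {
    f <- fold_levels[i]
    test <- features[fold_id == f, , drop = FALSE]
    train <- features[fold_id != f, , drop = FALSE]
    hp <- NULL
    if (!is.null(grid)) {
      gs <- grid_search(spec$classifier, grid, train,
                        class_scheme = spec$class_scheme,
                        seed = derive_seed(spec$seed, i), lasso = FALSE)
      hp <- gs$best
    }
    fold_spec <- model_spec(spec$classifier, spec$class_scheme,
                            hyperparameters = hp %||% spec$hyperparameters,
                            seed = spec$seed)
    fit <- fit_stress_model(train, fold_spec, lasso = lasso, lambda = lambda)
    pred <- predict(fit, test)
    cm <- confusion_matrix(test[[lab_col]], pred, classes)
    met <- metrics_from_confusion(cm)
    fold_rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n_test = nrow(test), accuracy = met$accuracy),
      met$macro
    )
    predictions[[i]] <- dplyr::mutate(
      test[c("subject_id", "start_s", "phase", lab_col)],
      fold = f, predicted = pred
    )
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  predictions <- dplyr::bind_rows(predictions)
  pooled_cm <- confusion_matrix(predictions[[lab_col]],
                                predictions$predicted, classes)
  structure(list(
    spec = spec,
    classes = classes,
    fold_metrics = fold_metrics,
    summary = dplyr::summarise(fold_metrics, dplyr::across(
      c("accuracy", "precision", "recall", "f1", "specificity"), mean)),
    pooled_confusion = pooled_cm,
    pooled_per_class = metrics_from_confusion(pooled_cm)$per_class,
    predictions = predictions
  ), class = "evaluation_report")
}

#' Stratified 10-fold cross-validation
#'
#' Windows are partitioned into `k` stratified folds; each window is tested
#' exactly once. Per fold the classifier is fitted on the remaining windows
#' (standardization and Lasso refitted on training rows only; when a `grid`
#' is given, hyperparameters are re-tuned per fold on a stratified 10%
#' inner-validation split of the training rows). The report averages the
#' per-fold metrics.
#'
#' @param features Cohort feature tibble.
#' @param spec A [model_spec()].
#' @param k Number of folds.
#' @param lasso,lambda Passed to [fit_stress_model()].
#' @param grid Optional hyperparameter grid for per-fold [grid_search()].
#' @param seed Seed for the fold assignment.
#' @return An `evaluation_report`.
#' @export
evaluate_kfold <- function(features, spec, k = 10, lasso = TRUE,
                           lambda = NULL, grid = NULL, seed = 1L) {
  lab_col <- label_column(spec$class_scheme)
  fold_id <- stratified_folds(features[[lab_col]], k, seed)
  rep <- evaluate_folds(features, fold_id, spec, lasso, lambda, grid)
  rep$protocol <- "kfold"
  rep$k <- k
  rep
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: every window of the held-out subject is tested on a
#' model trained on the other subjects' windows, measuring subject-level
#' generalization. An audit asserts that the training and test subject-id
#' sets are disjoint in every fold.
#'
#' @inheritParams evaluate_kfold
#' @return An `evaluation_report` with one fold per subject.
#' @export
evaluate_loso <- function(features, spec, lasso = TRUE, lambda = NULL,
                          grid = NULL) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2) {
    abort("leave-one-subject-out needs at least 2 subjects.",
          class = "eogstress_protocol_error")
  }
  fold_id <- match(features$subject_id, subjects)
  # audit: identical feature rows filed under different subject ids would
  # leak a held-out subject's windows into training via the back door
  key <- apply(as.matrix(features[feature_cols(features)]), 1,
               paste, collapse = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup) &&
      any(tapply(features$subject_id[dup], key[dup],
                 function(s) length(unique(s))) > 1)) {
    abort("identical feature rows appear under different subject ids.",
          class = "eogstress_leakage_error")
  }
  # audit: held-out subject never appears in its training partition
  for (f in seq_along(subjects)) {
    overlap <- intersect(unique(features$subject_id[fold_id == f]),
                         unique(features$subject_id[fold_id != f]))
    if (length(overlap)) {
      abort(paste("subject leakage detected for:",
                  paste(overlap, collapse = ", ")),
            class = "eogstress_leakage_error")
    }
  }
  rep <- evaluate_folds(features, fold_id, spec, lasso, lambda, grid)
  rep$protocol <- "loso"
  rep$fold_metrics$subject_id <- subjects[rep$fold_metrics$fold]
  rep
}

#' Per-task accuracy of an evaluation report
#'
#' For each task phase, the accuracy over that task's test windows together
#' with all rest-phase test windows — how well the model separates one task
#' from rest. Tasks absent from the test predictions are reported as `NA`.
#'
#' @param report An `evaluation_report`.
#' @param rest_prefix Prefix identifying rest phases in the `phase` column.
#' @return Tibble with `task`, `n_windows` and `accuracy`.
#' @export
per_task_accuracy <- function(report, rest_prefix = "rest") {
  preds <- report$predictions
  lab_col <- label_column(report$spec$class_scheme)
  is_rest <- startsWith(preds$phase, rest_prefix)
  tasks <- sort(unique(preds$phase[!is_rest]))
  purrr::map_dfr(tasks, function(task) {
    sel <- preds$phase == task | is_rest
    n <- sum(preds$phase == task)
    tibble::tibble(
      task = task, n_windows = n,
      accuracy = if (n == 0) NA_real_ else {
        mean(preds$predicted[sel] == preds[[lab_col]][sel])
      }
    )
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", toupper(x$spec$classifier),
      paste0(x$spec$class_scheme, "-class"), x$protocol %||% "", "\n")
  s <- x$summary
  cat(sprintf("  mean over %d folds: acc %.3f | pr %.3f | re %.3f | f1 %.3f | spe %.3f\n",
              nrow(x$fold_metrics), s$accuracy, s$precision, s$recall,
              s$f1, s$specificity))
  invisible(x)
}

#' Fold-level metrics of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$fold_metrics

#' One-row summary of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row tibble: classifier, scheme, protocol, folds and the mean
#'   metrics.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(classifier = x$spec$classifier,
                   class_scheme = x$spec$class_scheme,
                   protocol = x$protocol %||% NA_character_,
                   n_folds = nrow(x$fold_metrics)),
    x$summary
  )
}

#' Heatmap of the pooled confusion matrix
#'
#' @param object An `evaluation_report`.
#' @param normalize Show row-normalized proportions instead of counts?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, normalize = FALSE, ...) {
  cm <- object$pooled_confusion
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("true", "predicted", "n")
  if (normalize) {
    df <- df |>
      dplyr::group_by(.data$true) |>
      dplyr::mutate(n = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (normalize) sprintf("%.2f", .data$n) else .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = paste(toupper(object$spec$classifier),
                                object$protocol %||% ""),
                  fill = if (normalize) "prop" else "count")
}
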