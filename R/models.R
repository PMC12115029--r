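#' Default hyperparameters for the five reference classifiers
#'
#' The shipped defaults are the grid-search optima for each class scheme:
#' random forest depth 12 with 8 trees (two-class) or depth 14 with 6 trees
#' (three-class), ridge-penalized logistic regression with C = 0.05 / 0.03,
#' linear SVM with C = 0.1 / 0.5 (one-vs-one multi-class), decision tree of
#' depth 15 / 20, and distance-weighted k-nearest neighbours with k = 7 / 9
#' (Euclidean, i.e. Minkowski p = 2).
#'
#' @param classifier One of `"rf"`, `"lr"`, `"svm"`, `"dt"`, `"knn"`.
#' @param class_scheme `"two"` or `"three"`.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(classifier, class_scheme = "two") {
  two <- list(
    rf  = list(max_depth = 12, n_estimators = 8, criterion = "gini"),
    lr  = list(C = 0.05, max_iter = 75, solver = "newton-cg"),
    svm = list(C = 0.1, max_iter = 80, kernel = "linear",
               decision_function_shape = "ovo"),
    dt  = list(max_depth = 15, criterion = "gini"),
    knn = list(n_neighbors = 7, metric = "minkowski", p = 2,
               weights = "distance")
  )
  three <- list(
    rf  = list(max_depth = 14, n_estimators = 6, criterion = "gini"),
    lr  = list(C = 0.03, max_iter = 65, solver = "newton-cg"),
    svm = list(C = 0.5, max_iter = 70, kernel = "linear",
               decision_function_shape = "ovo"),
    dt  = list(max_depth = 20, criterion = "gini"),
    knn = list(n_neighbors = 9, metric = "minkowski", p = 2,
               weights = "distance")
  )
  tab <- if (identical(class_scheme, "three")) three else two
  tab[[classifier]]
}

#' Specify a classifier
#'
#' @param classifier One of `"rf"`, `"lr"`, `"svm"`, `"dt"`, `"knn"`.
#' @param class_scheme `"two"` (stress / no stress) or `"three"` (no stress /
#'   stress level 1 / stress level 2); picks the label column and the default
#'   hyperparameters.
#' @param hyperparameters Named list overriding individual defaults.
#' @param seed Seed for any stochastic fitting (random forest).
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("rf", "two")
model_spec <- function(classifier = c("rf", "lr", "svm", "dt", "knn"),
                       class_scheme = c("two", "three"),
                       hyperparameters = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  class_scheme <- match.arg(class_scheme)
  hp <- modifyList(default_hyperparameters(classifier, class_scheme),
                   hyperparameters %||% list())
  structure(list(classifier = classifier, class_scheme = class_scheme,
                 hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", toupper(x$classifier), "-", x$class_scheme, "classes\n")
  hp <- x$hyperparameters
  cat(" ", paste(names(hp), unlist(hp), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

label_column <- function(class_scheme) {
  if (identical(class_scheme, "three")) "label3" else "label2"
}

#' Fit a stress classifier on a training feature table
#'
#' Standardization parameters and (optionally) the Lasso selection mask are
#' fitted on the training rows only, so nothing about the test fold leaks
#' into the model. Prediction then uses exactly the selected, standardized
#' features.
#'
#' @param features Training-fold feature tibble (from [extract_features()] /
#'   [cohort_features()]), containing the label column for the spec's scheme.
#' @param spec A [model_spec()].
#' @param lasso Apply [lasso_select()] on the training rows first?
#' @param lambda Optional fixed Lasso penalty (otherwise CV-chosen).
#' @return A fitted `stress_model`.
#' @export
fit_stress_model <- function(features, spec, lasso = TRUE, lambda = NULL) {
  lab_col <- label_column(spec$class_scheme)
  if (!lab_col %in% names(features)) {
    abort(paste0("feature table lacks the `", lab_col, "` column."),
          class = "eogstress_schema_error")
  }
  y <- factor(features[[lab_col]])
  if (nlevels(droplevels(y)) < 2) {
    abort("training labels contain a single class.",
          class = "eogstress_training_error")
  }
  y <- droplevels(y)
  x <- as.matrix(features[feature_cols(features)])
  centers <- colMeans(x)
  scales <- apply(x, 2, sd)
  usable <- scales > 0
  mask <- setNames(usable, colnames(x))
  if (lasso) {
    lm_mask <- lasso_select(features, y, lambda = lambda, seed = spec$seed)
    mask <- mask & lm_mask
    if (!any(mask)) mask <- setNames(usable, colnames(x))  # guard: keep all
  }
  xs <- sweep(sweep(x[, mask, drop = FALSE], 2, centers[mask]), 2,
              scales[mask], "/")
  hp <- spec$hyperparameters
  fit <- switch(
    spec$classifier,
    rf = ranger::ranger(
      x = xs, y = y, num.trees = hp$n_estimators, max.depth = hp$max_depth,
      splitrule = "gini", seed = spec$seed, num.threads = 1
    ),
    lr = glmnet::glmnet(
      pad_two_cols(xs), y,
      family = if (nlevels(y) > 2) "multinomial" else "binomial",
      alpha = 0, lambda = 1 / (hp$C * nrow(xs)), standardize = FALSE
    ),
    svm = e1071::svm(x = xs, y = y, kernel = "linear", cost = hp$C,
                     scale = FALSE),
    dt = {
      df <- data.frame(xs, .y = y, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     maxdepth = min(30, hp$max_depth), cp = 0,
                     minsplit = 2, minbucket = 1, xval = 0))
    },
    knn = list(x = xs, y = y, k = hp$n_neighbors, p = hp$p %||% 2)
  )
  structure(list(spec = spec, fit = fit, centers = centers, scales = scales,
                 mask = mask, classes = levels(y), label_column = lab_col),
            class = "stress_model")
}

# glmnet requires >= 2 predictor columns; pad with an all-zero column when
# feature selection leaves a single feature (the pad coefficient is 0).
pad_two_cols <- function(xs) {
  if (ncol(xs) >= 2) return(xs)
  cbind(xs, .pad = rep(0, nrow(xs)))
}

# Distance-weighted k-nearest-neighbour vote. Exact feature matches get
# infinite weight (the tied training labels then decide); remaining ties
# break towards the first class in the model's class ordering.
predict_wknn <- function(fit, xs, classes) {
  ntr <- nrow(fit$x)
  k <- min(fit$k, ntr)
  tr_sq <- rowSums(fit$x^2)
  out <- character(nrow(xs))
  chunk <- max(1L, floor(5e6 / ntr))
  for (s in seq(1L, nrow(xs), by = chunk)) {
    idx <- s:min(nrow(xs), s + chunk - 1L)
    d2 <- outer(rep(1, length(idx)), tr_sq) - 2 * xs[idx, , drop = FALSE] %*%
      t(fit$x) + rowSums(xs[idx, , drop = FALSE]^2)
    d2[d2 < 0] <- 0
    for (r in seq_along(idx)) {
      nn <- order(d2[r, ])[seq_len(k)]
      d <- sqrt(d2[r, nn])
      w <- if (any(d == 0)) as.numeric(d == 0) else 1 / d
      votes <- vapply(classes, function(cl) sum(w[fit$y[nn] == cl]),
                      numeric(1))
      out[idx[r]] <- classes[which.max(votes)]
    }
  }
  out
}

#' Predict stress labels for new windows
#'
#' @param object A fitted `stress_model`.
#' @param newdata Feature tibble containing all nine feature columns; the
#'   model applies its own standardization and feature mask.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row.
#' @export
predict.stress_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(names(object$mask), colnames(newdata))
  if (length(missing_cols)) {
    abort(paste("missing feature column(s):",
                paste(missing_cols, collapse = ", ")),
          class = "eogstress_schema_error")
  }
  x <- as.matrix(newdata[names(object$mask)])
  m <- object$mask
  xs <- sweep(sweep(x[, m, drop = FALSE], 2, object$centers[m]), 2,
              object$scales[m], "/")
  pred <- switch(
    object$spec$classifier,
    rf = as.character(predict(object$fit, data = xs, num.threads = 1,
                              seed = object$spec$seed)$predictions),
    lr = {
      p <- predict(object$fit, newx = pad_two_cols(xs), type = "class")
      as.character(p[, 1])
    },
    svm = as.character(predict(object$fit, newdata = xs)),
    dt = as.character(predict(object$fit,
                              newdata = data.frame(xs, check.names = FALSE),
                              type = "class")),
    knn = predict_wknn(object$fit, xs, object$classes)
  )
  pred
}

#' @export
print.stress_model <- function(x, ...) {
  cat("<stress_model>", toupper(x$spec$classifier), "-",
      x$spec$class_scheme, "classes;",
      sum(x$mask), "of", length(x$mask), "features\n")
  invisible(x)
}

#' Grid search over hyperparameters with an inner validation split
#'
#' Holds out a stratified 10% of the training rows as a validation set, fits
#' one model per grid row on the remainder and returns the row with the
#' highest validation accuracy; ties break towards the earliest grid row.
#'
#' @param classifier Classifier name, as in [model_spec()].
#' @param grid Tibble / data frame; each row is one hyperparameter setting.
#' @param features Training feature table.
#' @param class_scheme `"two"` or `"three"`.
#' @param val_fraction Fraction of training rows held out for validation.
#' @param seed Seed for the validation split.
#' @param lasso Passed to [fit_stress_model()].
#' @return List with `best` (named list), `accuracy` and `results` (one row
#'   per grid point with its validation accuracy).
#' @export
grid_search <- function(classifier, grid, features, class_scheme = "two",
                        val_fraction = 0.1, seed = 1L, lasso = FALSE) {
  if (is.null(grid) || nrow(grid) == 0) {
    abort("hyperparameter grid is empty.", class = "eogstress_parameter_error")
  }
  lab_col <- label_column(class_scheme)
  y <- features[[lab_col]]
  val_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      sample(ix, max(1L, round(length(ix) * val_fraction)))
    }), use.names = FALSE)
  })
  train <- features[-val_idx, , drop = FALSE]
  val <- features[val_idx, , drop = FALSE]
  accs <- vapply(seq_len(nrow(grid)), function(i) {
    hp <- as.list(grid[i, , drop = FALSE])
    spec <- model_spec(classifier, class_scheme, hyperparameters = hp,
                       seed = seed)
    fit <- fit_stress_model(train, spec, lasso = lasso)
    mean(predict(fit, val) == val[[lab_col]])
  }, numeric(1))
  best_i <- which.max(accs)  # which.max returns the first maximum
  list(best = as.list(grid[best_i, , drop = FALSE]),
       accuracy = accs[best_i],
       results = dplyr::mutate(tibble::as_tibble(grid),
                               val_accuracy = accs))
}

#' Per-feature summary of a fitted stress model
#'
#' @param x A `stress_model`.
#' @param ... Unused.
#' @return Tibble with one row per feature: selection flag and the
#'   standardization parameters fitted on the training rows.
#' @method tidy stress_model
#' @export
tidy.stress_model <- function(x, ...) {
  tibble::tibble(
    feature = names(x$mask),
    selected = unname(x$mask),
    center = unname(x$centers),
    scale = unname(x$scales)
  )
}

#' One-row summary of a fitted stress model
#'
#' @param x A `stress_model`.
#' @param ... Unused.
#' @return One-row tibble: classifier, scheme, retained feature count,
#'   class count.
#' @method glance stress_model
#' @export
glance.stress_model <- function(x, ...) {
  tibble::tibble(
    classifier = x$spec$classifier,
    class_scheme = x$spec$class_scheme,
    n_features = sum(x$mask),
    n_classes = length(x$classes)
  )
}
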