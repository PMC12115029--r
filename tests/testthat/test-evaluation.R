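test_that("metrics reproduce closed-form values on a hand-built matrix", {
  # binary: stress is the positive class; TP=40 FP=10 TN=45 FN=5
  cm <- matrix(c(45L, 10L, 5L, 40L), 2, 2, byrow = TRUE,
               dimnames = list(true = c("no_stress", "stress"),
                               predicted = c("no_stress", "stress")))
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 0.85, tolerance = 1e-12)
  stress <- m$per_class[m$per_class$class == "stress", ]
  expect_equal(stress$precision, 40 / 50, tolerance = 1e-12)
  expect_equal(stress$recall, 40 / 45, tolerance = 1e-12)
  expect_equal(stress$f1, 80 / (80 + 10 + 5), tolerance = 1e-12)
  expect_equal(stress$specificity, 45 / 55, tolerance = 1e-12)
})

test_that("a perfect diagonal matrix scores 1 on every metric", {
  cm <- diag(c(10L, 20L, 30L))
  dimnames(cm) <- list(true = letters[1:3], predicted = letters[1:3])
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro$precision, 1)
  expect_equal(m$macro$recall, 1)
  expect_equal(m$macro$f1, 1)
  expect_equal(m$macro$specificity, 1)
})

test_that("macro metrics equal a brute-force per-class recomputation", {
  for (seed in 1:10) {
    cm <- withr::with_seed(seed, matrix(rpois(9, 20), 3, 3))
    dimnames(cm) <- list(true = c("x", "y", "z"), predicted = c("x", "y", "z"))
    m <- metrics_from_confusion(cm)
    want <- oracle_metrics(cm)
    expect_equal(m$accuracy, want$accuracy, tolerance = 1e-12)
    for (cl in c("x", "y", "z")) {
      row <- m$per_class[m$per_class$class == cl, ]
      expect_equal(row$precision, want$per_class[[cl]][["precision"]],
                   tolerance = 1e-12)
      expect_equal(row$recall, want$per_class[[cl]][["recall"]],
                   tolerance = 1e-12)
      expect_equal(row$f1, want$per_class[[cl]][["f1"]], tolerance = 1e-12)
      expect_equal(row$specificity, want$per_class[[cl]][["specificity"]],
                   tolerance = 1e-12)
    }
    expect_equal(unlist(m$macro),
                 colMeans(do.call(rbind, want$per_class))[names(unlist(m$macro))],
                 tolerance = 1e-12)
  }
})

test_that("macro metrics are invariant under class relabeling", {
  cm <- withr::with_seed(4, matrix(rpois(9, 15), 3, 3))
  dimnames(cm) <- list(true = c("a", "b", "c"), predicted = c("a", "b", "c"))
  perm <- c(3, 1, 2)
  cm_p <- cm[perm, perm]
  expect_equal(metrics_from_confusion(cm)$macro,
               metrics_from_confusion(cm_p)$macro, tolerance = 1e-12)
  expect_equal(metrics_from_confusion(cm)$accuracy,
               metrics_from_confusion(cm_p)$accuracy, tolerance = 1e-12)
})

test_that("accuracy from the matrix equals direct prediction counting", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      truth <- sample(c("a", "b", "c"), 200, replace = TRUE)
      pred <- sample(c("a", "b", "c"), 200, replace = TRUE)
    })
    cm <- confusion_matrix(truth, pred)
    expect_equal(metrics_from_confusion(cm)$accuracy, mean(truth == pred))
  }
  expect_error(confusion_matrix(character(0), character(0)),
               class = "eogstress_input_error")
  expect_error(confusion_matrix(c("a", "b"), "a"),
               class = "eogstress_input_error")
})

test_that("k-fold partition tests every window exactly once", {
  tab <- random_feature_table(100, seed = 41, signal = 1)
  rep10 <- evaluate_kfold(tab, model_spec("dt", "two"), lasso = FALSE,
                          seed = 3)
  expect_equal(nrow(rep10$fold_metrics), 10)
  expect_equal(sort(rep10$fold_metrics$n_test), rep(10, 10))
  key <- paste(rep10$predictions$subject_id, rep10$predictions$start_s)
  expect_equal(sort(key), sort(paste(tab$subject_id, tab$start_s)))
  expect_equal(anyDuplicated(key), 0)

  small <- random_feature_table(12, seed = 42, signal = 0)
  expect_error(evaluate_kfold(small, model_spec("dt", "two"), lasso = FALSE),
               class = "eogstress_stratification_error")
})

test_that("LOSO holds out whole subjects with disjoint id sets", {
  tab <- random_feature_table(120, seed = 43, signal = 2)
  rep_l <- evaluate_loso(tab, model_spec("dt", "two"), lasso = FALSE)
  expect_equal(nrow(rep_l$fold_metrics), length(unique(tab$subject_id)))
  for (f in rep_l$fold_metrics$fold) {
    test_subj <- unique(rep_l$predictions$subject_id[
      rep_l$predictions$fold == f])
    expect_length(test_subj, 1)
  }

  two <- tab[tab$subject_id %in% c("S01", "S02"), ]
  rep2 <- evaluate_loso(two, model_spec("dt", "two"), lasso = FALSE)
  expect_equal(nrow(rep2$fold_metrics), 2)

  one <- tab[tab$subject_id == "S01", ]
  expect_error(evaluate_loso(one, model_spec("dt", "two")),
               class = "eogstress_protocol_error")
})

test_that("duplicating a subject's windows under a new id is rejected", {
  tab <- random_feature_table(80, seed = 44, signal = 2)
  dup <- tab[tab$subject_id == "S01", ]
  dup$subject_id <- "S99"
  leaky <- dplyr::bind_rows(tab, dup)
  expect_error(evaluate_loso(leaky, model_spec("dt", "two"), lasso = FALSE),
               class = "eogstress_leakage_error")
})

test_that("per-task accuracy reflects task separability and composition", {
  # all predictions correct: every task scores 1
  preds <- tibble::tibble(
    subject_id = "S01", start_s = 1:40,
    phase = rep(c("rest0", "task1", "task2", "rest1"), each = 10),
    label2 = rep(c("no_stress", "stress", "stress", "no_stress"), each = 10),
    fold = 1L, predicted = label2
  )
  rep_fake <- structure(list(predictions = preds,
                             spec = model_spec("rf", "two")),
                        class = "evaluation_report")
  pt <- per_task_accuracy(rep_fake)
  expect_equal(pt$accuracy, c(1, 1))

  # one task perfectly misclassified: accuracy = rest-correct scaled by mix
  preds2 <- preds
  wrong <- preds2$phase == "task2"
  preds2$predicted[wrong] <- "no_stress"
  rep_fake2 <- structure(list(predictions = preds2,
                              spec = model_spec("rf", "two")),
                         class = "evaluation_report")
  pt2 <- per_task_accuracy(rep_fake2)
  # task2 row: 10 wrong task windows + 20 correct rest windows
  expect_equal(pt2$accuracy[pt2$task == "task2"], 20 / 30)
  expect_equal(pt2$accuracy[pt2$task == "task1"], 1)
})

test_that("report accessors expose fold metrics and summaries", {
  tab <- random_feature_table(100, seed = 45, signal = 2)
  rep10 <- evaluate_kfold(tab, model_spec("lr", "two"), lasso = FALSE)
  expect_equal(nrow(tidy(rep10)), 10)
  gl <- glance(rep10)
  expect_equal(gl$protocol, "kfold")
  expect_true(all(unlist(rep10$summary) >= 0 & unlist(rep10$summary) <= 1))
  expect_s3_class(autoplot(rep10), "ggplot")
})
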