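test_that("window segmentation follows the floor formula", {
  expect_length(segment_windows(884), 882)
  expect_equal(segment_windows(3), 0)
  expect_equal(segment_windows(10), 0:7)
  expect_warning(w <- segment_windows(2), "shorter")
  expect_length(w, 0)
  # property: count formula for assorted geometries
  for (dur in c(9, 30, 121, 884)) {
    for (step in c(0.5, 1, 2)) {
      starts <- segment_windows(dur, 3, step)
      expect_length(starts, floor((dur - 3) / step) + 1)
      expect_true(all(starts + 3 <= dur + 1e-9))
    }
  }
})

test_that("window features match closed forms on toy inputs", {
  none <- tibble::tibble(apex_time_s = double(), onset_s = double(),
                         offset_s = double(), amplitude_uv = double())
  f0 <- compute_window_features(rep(0, 150), rep(0, 150), none, 0)
  expect_equal(unname(f0), rep(0, 9))

  f <- compute_window_features(c(1, 2, 3), c(0, 0, 0), none, 0,
                               window_s = 3, sampling_rate = 1)
  expect_equal(unname(f["var_v"]), 2 / 3)       # population convention
  expect_equal(unname(f["cov_v"]), 2 / 3)       # total == vertical here
  expect_equal(unname(f["max_v"]), 3)
  expect_equal(unname(f["mean_total"]), 2)

  expect_error(compute_window_features(c(1, NA), c(1, 2), none, 0),
               class = "eogstress_input_error")
})

test_that("window features equal a brute-force recomputation", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      v <- rnorm(150, 0, 20)
      h <- rnorm(150, 0, 10)
      nb <- sample(0:3, 1)
      apices <- sort(runif(nb, 0.4, 2.6))
      blinks <- tibble::tibble(
        apex_time_s = apices,
        onset_s = apices - 0.15,
        offset_s = apices + 0.15,
        amplitude_uv = runif(nb, 50, 200)
      )
    })
    got <- compute_window_features(v, h, blinks, 0, 3, 50)
    want <- oracle_window_features(v, h, blinks, 0, 3, 50)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("labels follow the Likert mapping", {
  expect_equal(assign_labels("rest", NA),
               list(label2 = "no_stress", label3 = "no_stress"))
  expect_equal(assign_labels("task", 4),
               list(label2 = "stress", label3 = "stress2"))
  expect_equal(assign_labels("task", 0),
               list(label2 = "no_stress", label3 = "no_stress"))
  expect_equal(assign_labels("task", 1)$label3, "no_stress")
  expect_equal(assign_labels("task", 2)$label3, "stress1")
  expect_equal(assign_labels("task", 3)$label3, "stress1")
  expect_error(assign_labels("task", NA),
               class = "eogstress_labeling_error")
  expect_error(assign_labels("task", 7),
               class = "eogstress_labeling_error")
})

test_that("extract_features drops boundary windows and conserves blinks", {
  s <- render_session(tiny_config(seed = 12))
  p <- preprocess_session(s)
  b <- detect_blinks(p)
  f <- extract_features(p, b)
  # every window sits inside exactly one segment
  segs <- s$segments
  for (i in seq_len(nrow(f))) {
    seg <- segs[segs$phase == f$phase[i], ]
    expect_true(seg$start_s <= f$start_s[i] &&
                  f$start_s[i] + 3 <= seg$end_s)
  }
  # window count: per segment, starts on the integer grid fitting inside
  expected_n <- sum(vapply(seq_len(nrow(segs)), function(i) {
    starts <- segment_windows(140)
    sum(starts >= segs$start_s[i] & starts + 3 <= segs$end_s[i])
  }, numeric(1)))
  expect_equal(nrow(f), expected_n)

  # blink conservation by direct enumeration: each accepted apex appears in
  # exactly the retained windows whose span contains it
  acc <- b[b$accepted, ]
  expected_blinks <- sum(vapply(acc$apex_time_s, function(a) {
    sum(f$start_s <= a & a < f$start_s + 3)
  }, numeric(1)))
  expect_equal(sum(f$blink_freq * 3), expected_blinks)
})

test_that("lasso limits: huge penalty empties, zero penalty keeps all", {
  tab <- random_feature_table(300, seed = 21, signal = 2)
  x <- tab[eogstress:::feature_names()]
  none <- lasso_select(x, tab$label2, lambda = 5)
  expect_false(any(none))
  all_in <- lasso_select(x, tab$label2, lambda = 0)
  expect_true(all(all_in))
  expect_error(lasso_select(x, tab$label2, lambda = -1),
               class = "eogstress_parameter_error")
})

test_that("constant feature columns are dropped before standardization", {
  tab <- random_feature_table(200, seed = 22, signal = 2)
  tab$sd_total <- 0
  expect_message(
    mask <- lasso_select(tab[eogstress:::feature_names()], tab$label2,
                         lambda = 0.05),
    "constant")
  expect_false(mask[["sd_total"]])
  expect_equal(attr(mask, "dropped_constant"), "sd_total")
})

test_that("CV-chosen penalty recovers the informative support", {
  fn <- eogstress:::feature_names()
  informative <- c("blink_freq", "mean_p2p_v")
  hits <- 0
  for (rep_i in 1:10) {
    tab <- random_feature_table(500, seed = 3000 + rep_i, signal = 2)
    mask <- lasso_select(tab[fn], tab$label2, seed = rep_i)
    if (!any(mask[setdiff(fn, informative)])) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
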