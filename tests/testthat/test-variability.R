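test_that("segment_windows cuts non-overlapping windows and drops the remainder", {
  X <- matrix(seq_len(23 * 2), 23, 2)
  w <- segment_windows(X, 10)
  expect_length(w, 2L)
  expect_identical(w[[1]], X[1:10, ])
  expect_identical(w[[2]], X[11:20, ])
  expect_error(segment_windows(X, 2), "at least 3")
  expect_error(segment_windows(X, 15), "insufficient windows")
})

test_that("window_fc computes Pearson blocks and flags flat channels", {
  set.seed(101)
  W <- matrix(rnorm(30), 10, 3)
  expect_equal(window_fc(W), stats::cor(W), tolerance = 1e-12)
  expect_equal(window_fc(W, rows = 1:2, cols = 3),
               stats::cor(W[, 1:2, drop = FALSE], W[, 3, drop = FALSE]),
               tolerance = 1e-12)
  W[, 2] <- 1
  expect_error(window_fc(W), "zero-variance")
})

test_that("variability values stay in [0, 2] and respect the fisher flag", {
  set.seed(111)
  X <- matrix(rnorm(80 * 4), 80, 4)
  v <- within_network_variability(X, 1:4, lengths = c(10, 20))
  expect_gte(v, 0); expect_lte(v, 2)
  vf <- within_network_variability(X, 1:4, lengths = c(10, 20), fisher = TRUE)
  expect_false(identical(v, vf))
  vb <- between_network_variability(X, 1:2, 3:4, lengths = c(10, 20))
  expect_gte(vb, 0); expect_lte(vb, 2)
  expect_error(within_network_variability(X, 1, lengths = 10), "at least 2")
  expect_error(between_network_variability(X[, 1:2], 1, 2, lengths = 10),
               "at least 2 entries")
})

test_that("variability_profile matches the single-pair functions and counts features", {
  set.seed(121)
  map <- default_network_map(channels_per_network = 3,
                             networks = c("A", "B", "C"))
  X <- matrix(rnorm(90 * 9), 90, 9,
              dimnames = list(NULL, map$channels))
  ts <- parcellated_ts(X, "s1")
  vp <- variability_profile(ts, map, lengths = c(15, 20))
  expect_length(vp$within, 3L)
  expect_identical(nrow(vp$between_pairs), 3L)
  expect_equal(unname(vp$within["B"]),
               within_network_variability(X, 4:6, lengths = c(15, 20)),
               tolerance = 1e-12)
  expect_equal(unname(vp$between["A", "C"]),
               between_network_variability(X, 1:3, 7:9, lengths = c(15, 20)),
               tolerance = 1e-12)
  expect_equal(vp$between["A", "C"], vp$between["C", "A"])
  expect_true(all(is.na(diag(vp$between))))
  expect_identical(vp$subject_id, "s1")
})

test_that("variability_profile validates channels and map coverage", {
  map <- default_network_map(channels_per_network = 2,
                             networks = c("A", "B"))
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, map$channels))
  colnames(X)[4] <- "unknown"
  expect_error(variability_profile(parcellated_ts(X, "s"), map, lengths = 15),
               "absent")
  Xf <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, map$channels))
  Xf[, 2] <- 3
  expect_error(variability_profile(parcellated_ts(Xf, "s"), map, lengths = 15),
               "zero-variance")
})

test_that("cohort_variability returns one labelled row per subject", {
  co <- tiny_cohort(n_subjects = 2, seed = 14)
  vt <- cohort_variability(co$timeseries, co$network_map, lengths = c(20, 30))
  expect_identical(nrow(vt), 2L)
  expect_identical(vt$subject_id, c("sub0001", "sub0002"))
  expect_identical(ncol(vt), 1L + 17L + 136L)
  expect_true(all(vt[, -1] >= 0 & vt[, -1] <= 2))
  expect_true("between_VisCent__VisPeri" %in% names(vt))
})
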