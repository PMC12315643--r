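test_that("sample_transition_matrix is row-stochastic with the requested stickiness", {
  m <- sample_transition_matrix(4, 0.9)
  expect_equal(rowSums(m), rep(1, 4), tolerance = 1e-12)
  expect_equal(diag(m), rep(0.9, 4), tolerance = 1e-12)
  expect_identical(sample_transition_matrix(1, 0.5), matrix(1, 1, 1))
  expect_error(sample_transition_matrix(3, 1), "stickiness")
})

test_that("simulate_state_path respects the chain", {
  p <- simulate_state_path(sample_transition_matrix(3, 0.8), rep(1 / 3, 3),
                           100, seed = 1)
  expect_length(p, 100L)
  expect_true(all(p %in% 1:3))
  # identity transitions never leave the initial state
  p2 <- simulate_state_path(diag(2), c(0, 1), 50, seed = 2)
  expect_identical(unique(p2), 2L)
})

test_that("state emission parameters have the planted separation and SPD covariances", {
  map <- default_network_map()
  set.seed(42)
  em <- statedyn:::state_emission_params(5, map, separation = 3)
  d <- as.matrix(stats::dist(em$means))
  expect_equal(d[upper.tri(d)], rep(3, 10), tolerance = 1e-8)
  for (ck in em$covs) expect_silent(chol(ck))
  expect_equal(vapply(em$covs, function(c) max(abs(diag(c) - 1)), numeric(1)),
               rep(0, 5), tolerance = 1e-12)
})

test_that("simulate_cohort is reproducible and carries full ground truth", {
  co1 <- tiny_cohort(n_subjects = 3, seed = 9)
  co2 <- tiny_cohort(n_subjects = 3, seed = 9)
  co3 <- tiny_cohort(n_subjects = 3, seed = 10)
  expect_identical(co1$timeseries[[1]]$data, co2$timeseries[[1]]$data)
  expect_false(identical(co1$timeseries[[1]]$data, co3$timeseries[[1]]$data))
  gt <- co1$ground_truth
  expect_named(gt, c("subject_id", "theta", "delta", "paths", "trans", "fo",
                     "max_fo", "sr", "emission_means", "emission_covs",
                     "drift_phase", "drift_coupling_freq", "b_sr", "b_var",
                     "noise_sd"), ignore.order = TRUE)
  expect_equal(rowSums(gt$fo), rep(1, 3), tolerance = 1e-12)
  expect_true(all(gt$theta >= 0.80 & gt$theta <= 0.98))
})

test_that("score couples to true switching rate when only b_SR is planted", {
  co <- simulate_cohort(cohort_config(n_subjects = 200, b_sr = 0.3,
                                      b_var = 0, noise_sd = 0), seed = 77)
  expect_gt(stats::cor(co$phenotypes$score, co$ground_truth$sr,
                       method = "spearman"), 0.9)
})

test_that("drifting subjects have strictly higher windowed-FC variability than stationary ones", {
  map <- default_network_map()
  set.seed(515)
  em <- statedyn:::state_emission_params(8, map, 3)
  tg <- cohort_config()$drift_targets
  N <- length(map$channels)
  psi <- rep(NA_real_, N)
  for (i in seq_along(tg)) {
    idx <- which(map$network_of[map$channels] == tg[i])
    psi[idx] <- 2 * pi * (i - 1) / length(tg) +
      2 * pi * (seq_along(idx) - 1) / length(idx)
  }
  targ <- which(!is.na(psi))
  cfreq <- rep(NA_real_, N)
  cfreq[targ] <- 2 * pi * (2 + 5 * (seq_along(targ) - 1) /
                             (length(targ) - 1)) / 242
  trans <- sample_transition_matrix(8, 0.9)
  da <- which(map$network_of[map$channels] == "DefaultA")
  v0 <- v5 <- numeric(50)
  for (s in 1:50) {
    p <- simulate_state_path(trans, rep(1 / 8, 8), 242)
    args <- list(p, em$means, em$covs, drift_phase = psi,
                 coupling_freq = cfreq, factors = em$factors)
    y0 <- do.call(simulate_subject_bold, c(args, delta = 0, seed = 9000 + s))
    y5 <- do.call(simulate_subject_bold, c(args, delta = 0.5, seed = 9000 + s))
    v0[s] <- within_network_variability(y0$data, da)
    v5[s] <- within_network_variability(y5$data, da)
  }
  expect_lt(mean(v0), mean(v5))
  expect_true(all(v0 >= 0 & v0 <= 2, v5 >= 0 & v5 <= 2))
})

test_that("simulate_subject_bold validates inputs", {
  map <- default_network_map(channels_per_network = 2,
                             networks = c("A", "B"))
  set.seed(3)
  em <- statedyn:::state_emission_params(2, map, 2)
  p <- rep(1:2, each = 10)
  expect_error(simulate_subject_bold(p, em$means, em$covs, delta = 1,
                                     factors = em$factors),
               "delta")
  expect_error(simulate_subject_bold(p, em$means, em$covs, delta = 0.3),
               "drift_phase")
  y <- simulate_subject_bold(p, em$means, em$covs, seed = 4)
  expect_s3_class(y, "parcellated_ts")
  expect_identical(dim(y$data), c(20L, 4L))
})

test_that("cohort_config validates its arguments", {
  expect_error(cohort_config(delta_max = 1), "delta_max")
  expect_error(cohort_config(stickiness_range = c(0.9, 0.5)))
  expect_error(cohort_config(drift_targets = "NotANetwork"), "subset")
})
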