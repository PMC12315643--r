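test_that("hmm_model validates its components", {
  means <- matrix(0, 2, 2)
  covs <- list(diag(2), diag(2))
  expect_error(hmm_model(c(0.6, 0.5), diag(2), means, covs), "init")
  expect_error(hmm_model(c(0.5, 0.5), matrix(1, 2, 2), means, covs),
               "row-stochastic")
  bad <- covs; bad[[2]] <- matrix(c(1, 2, 2, 1), 2)   # not PD
  expect_error(hmm_model(c(0.5, 0.5), diag(2), means, bad),
               "positive definite")
})

test_that("log_emission matches the textbook Gaussian log-density", {
  set.seed(21)
  N <- 3
  means <- rbind(rnorm(N), rnorm(N, 2))
  covs <- lapply(1:2, function(k) {
    A <- matrix(rnorm(N * N), N); crossprod(A) + diag(N)
  })
  X <- matrix(rnorm(5 * N), 5, N)
  ld <- statedyn:::log_emission(X, means, covs)
  for (t in 1:5) for (k in 1:2)
    expect_equal(ld[t, k], oracle_dmvnorm_log(X[t, ], means[k, ], covs[[k]]),
                 tolerance = 1e-10)
})

test_that("network_average computes per-network channel means", {
  map <- network_map(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  X <- matrix(1:20, 5, 4, dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  ts <- parcellated_ts(X, "s")
  av <- network_average(ts, map)
  expect_identical(av$channel_labels, c("A", "B"))
  expect_equal(av$data[, "A"], rowMeans(X[, 1:2]))
  expect_equal(av$data[, "B"], rowMeans(X[, 3:4]))
  ts2 <- parcellated_ts(X, "s", channel_labels = c("a1", "a2", "b1", "zz"))
  expect_error(network_average(ts2, map), "zz")
})

test_that("standardize_and_concatenate z-scores per subject and records boundaries", {
  set.seed(31)
  ts1 <- parcellated_ts(matrix(rnorm(20, 5, 3), 10, 2), "s1",
                        channel_labels = c("a", "b"))
  ts2 <- parcellated_ts(matrix(rnorm(16, -2, 0.5), 8, 2), "s2",
                        channel_labels = c("a", "b"))
  cc <- standardize_and_concatenate(list(ts1, ts2))
  expect_identical(cc$starts, c(1L, 11L))
  expect_identical(dim(cc$X), c(18L, 2L))
  expect_equal(unname(colMeans(cc$X[1:10, ])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(cc$X[11:18, ], 2, stats::sd)), c(1, 1),
               tolerance = 1e-12)
  flat <- parcellated_ts(cbind(rep(1, 10), rnorm(10)), "s3",
                         channel_labels = c("a", "b"))
  expect_error(standardize_and_concatenate(list(flat)),
               "zero-variance channel 'a' in subject s3")
  ts3 <- parcellated_ts(matrix(rnorm(20), 10, 2), "s4",
                        channel_labels = c("x", "y"))
  expect_error(standardize_and_concatenate(list(ts1, ts3)), "mismatched")
})

test_that("forward_backward posteriors are proper and decoding is consistent", {
  set.seed(41)
  model <- hmm_model(c(0.5, 0.5), sample_transition_matrix(2, 0.8),
                     rbind(c(-2, -2), c(2, 2)), list(diag(2), diag(2)))
  X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  fb <- forward_backward(model, X)
  expect_equal(rowSums(fb$gamma), rep(1, 40), tolerance = 1e-12)
  d <- decode_states(model, X, subject_id = "s")
  expect_s3_class(d, "state_decoding")
  expect_identical(d$viterbi_path, viterbi(model, X))
  expect_equal(d$loglik, fb$loglik)
  # well-separated data decodes to the generating block structure
  expect_identical(d$viterbi_path, rep(1:2, each = 20L))
})

test_that("fit_hmm is seed-reproducible and reports restarts", {
  set.seed(51)
  X <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100, 4), 50, 2))
  m1 <- fit_hmm(X, K = 2, n_restarts = 3, seed = 8)
  m2 <- fit_hmm(X, K = 2, n_restarts = 3, seed = 8)
  expect_identical(m1$loglik, m2$loglik)
  expect_identical(m1$means, m2$means)
  expect_length(m1$restart_logliks, 3L)
  expect_identical(m1$loglik, max(m1$restart_logliks))
})

test_that("dynamics_metrics handles posterior FO and input validation", {
  expect_error(dynamics_metrics(c(1L, 3L), K = 2), "1..K")
  set.seed(61)
  model <- hmm_model(c(0.5, 0.5), sample_transition_matrix(2, 0.8),
                     rbind(c(-2, -2), c(2, 2)), list(diag(2), diag(2)))
  X <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  d <- decode_states(model, X)
  m <- dynamics_metrics(d, posterior_fo = TRUE)
  expect_equal(m$fo, colMeans(d$gamma), tolerance = 1e-12)
  expect_error(dynamics_metrics(c(1L, 2L, 1L), posterior_fo = TRUE),
               "state_decoding")
})

test_that("decoded dynamics metrics track ground truth on a planted cohort", {
  co <- simulate_cohort(cohort_config(n_subjects = 100, mean_separation = 4),
                        seed = 55)
  netts <- lapply(co$timeseries, network_average, map = co$network_map)
  cc <- standardize_and_concatenate(netts)
  fit <- suppressWarnings(fit_hmm(cc, K = 8, n_restarts = 2, seed = 3,
                                  max_iter = 40, tol = 1e-5))
  met <- cohort_dynamics(fit, cc)
  expect_gt(stats::cor(met$sr, co$ground_truth$sr), 0.8)
  expect_gt(stats::cor(met$max_fo, co$ground_truth$max_fo), 0.8)
})

test_that("scan_states reports stable assignments for well-separated data", {
  set.seed(71)
  ts_list <- lapply(1:4, function(s) {
    p <- simulate_state_path(sample_transition_matrix(2, 0.9), c(0.5, 0.5), 120)
    parcellated_ts(matrix(rnorm(120 * 3), 120, 3) + 4 * cbind(p, p, p), s,
                   channel_labels = c("a", "b", "c"))
  })
  sc <- scan_states(ts_list, K_range = 2, n_runs = 2, seed = 5, max_iter = 30)
  expect_identical(nrow(sc$runs), 2L)
  expect_gt(sc$similarity$mean_ari[1], 0.9)
})
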