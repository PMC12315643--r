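test_that("state_mean_profile subtracts the weighted grand mean", {
  means <- rbind(c(1, 2), c(3, 6), c(5, 10))
  covs <- replicate(3, diag(2), simplify = FALSE)
  model <- hmm_model(rep(1 / 3, 3), sample_transition_matrix(3, 0.8),
                     means, covs, channel_labels = c("a", "b"))
  expect_equal(state_mean_profile(model, 1), c(a = 1 - 3, b = 2 - 6))
  w <- c(1, 0, 0)   # grand mean = state 1 itself
  expect_equal(state_mean_profile(model, 1, weights = w), c(a = 0, b = 0))
  expect_equal(state_mean_profile(model, 3, weights = c(0.5, 0.5, 0)),
               c(a = 5 - 2, b = 10 - 4))
  expect_error(state_mean_profile(model, 4), "out of range")
  expect_error(state_mean_profile(model, 1, weights = c(1, 1)), "weights")
})

test_that("top_positive_fc keeps the ceiling(fraction * positive) strongest edges", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 0.9
  C[1, 3] <- C[3, 1] <- 0.5
  C[2, 3] <- C[3, 2] <- -0.4
  C[3, 4] <- C[4, 3] <- 0.2
  C <- C + diag(4) * 0.5   # keep PD
  model <- hmm_model(1, matrix(1, 1, 1), matrix(0, 1, 4), list(C),
                     channel_labels = letters[1:4])
  # 3 positive edges; fraction 0.5 keeps ceiling(1.5) = 2, strongest first
  top <- top_positive_fc(model, 1, fraction = 0.5)
  expect_identical(nrow(top), 2L)
  expect_identical(top$channel_i, c("a", "a"))
  expect_identical(top$channel_j, c("b", "c"))
  expect_true(all(diff(top$weight) <= 0))
  # fraction 1 keeps all positive edges and none of the negative ones
  expect_identical(nrow(top_positive_fc(model, 1, fraction = 1)), 3L)
  expect_error(top_positive_fc(model, 1, fraction = 0), "fraction")
})

test_that("top_positive_fc warns and returns no rows without positive edges", {
  C <- diag(2); C[1, 2] <- C[2, 1] <- -0.3
  model <- hmm_model(1, matrix(1, 1, 1), matrix(0, 1, 2), list(C))
  expect_warning(top <- top_positive_fc(model, 1), "no positive")
  expect_identical(nrow(top), 0L)
})

test_that("retained edges concentrate in a planted high-correlation block", {
  N <- 20
  C <- diag(N) * 0.2 + matrix(0.05, N, N)
  block <- 1:5
  C[block, block] <- 0.9
  diag(C) <- 1
  model <- hmm_model(1, matrix(1, 1, 1), matrix(0, 1, N), list(C))
  top <- top_positive_fc(model, 1, fraction = 0.05)
  in_block <- top$i %in% block & top$j %in% block
  expect_gte(mean(in_block), 0.8)
})

test_that("recovered state profiles match the planted mean sign pattern", {
  cfg <- cohort_config(n_subjects = 8, n_states = 2, mean_separation = 6,
                       b_sr = 0, b_var = 0, delta_max = 0)
  co <- simulate_cohort(cfg, seed = 31)
  netts <- lapply(co$timeseries, network_average, map = co$network_map)
  cc <- standardize_and_concatenate(netts)
  fit <- fit_hmm(cc, K = 2, n_restarts = 3, seed = 4)
  # planted network-level relative means
  map <- co$network_map
  planted <- t(vapply(1:2, function(k) {
    vapply(map$network_names, function(m)
      mean(co$ground_truth$emission_means[k, map$network_of[map$channels] == m]),
      numeric(1))
  }, numeric(17)))
  planted_rel <- sweep(planted, 2L, colMeans(planted))
  fitted_rel <- rbind(state_mean_profile(fit, 1), state_mean_profile(fit, 2))
  # match fitted to planted states by profile correlation
  ord <- if (stats::cor(fitted_rel[1, ], planted_rel[1, ]) >=
               stats::cor(fitted_rel[2, ], planted_rel[1, ])) 1:2 else 2:1
  agree <- mean(sign(fitted_rel[ord[1], ]) == sign(planted_rel[1, ])) / 2 +
    mean(sign(fitted_rel[ord[2], ]) == sign(planted_rel[2, ])) / 2
  expect_gte(agree, 0.9)
})

test_that("state_profile bundles activation, FC and top edges", {
  set.seed(91)
  A <- matrix(rnorm(9), 3)
  model <- hmm_model(c(0.5, 0.5), sample_transition_matrix(2, 0.8),
                     matrix(rnorm(6), 2, 3),
                     list(crossprod(A) + diag(3), diag(3)))
  pr <- state_profile(model, 1, fraction = 1)
  expect_s3_class(pr, "state_profile")
  expect_equal(pr$fc, stats::cov2cor(model$covs[[1]]))
  expect_identical(pr$state, 1)
})
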