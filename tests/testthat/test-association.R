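test_that("partial_correlation equals residualize-then-correlate with lm", {
  set.seed(131)
  n <- 40
  Z <- cbind(z1 = rnorm(n), z2 = runif(n))
  x <- 0.5 * Z[, 1] + rnorm(n)
  y <- -0.3 * Z[, 1] + 0.4 * x + rnorm(n)
  got <- partial_correlation(x, y, Z)
  want <- oracle_partial_cor(x, y, Z)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_identical(got$df, as.integer(n - 2 - 2))
})

test_that("partial_correlation validates inputs", {
  expect_error(partial_correlation(1:5, 1:4), "equal length")
  expect_error(partial_correlation(rnorm(10), rnorm(10),
                                   cbind(1:10, 2 * (1:10))),
               "rank-deficient")
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4))),
               "observations")
  expect_error(partial_correlation(rep(1, 10), rnorm(10)),
               "zero residual variance")
})

test_that("bh_fdr implements BH step-up and validates p-values", {
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-14)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
  # order-preserving under permutation
  set.seed(141)
  p <- runif(9)
  perm <- sample(9)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]), tolerance = 1e-14)
})

test_that("association battery applies per-family FDR and raw p for MaxFO/SR", {
  co <- simulate_cohort(cohort_config(n_subjects = 40), seed = 17)
  set.seed(171)
  feats <- data.frame(subject_id = co$phenotypes$subject_id,
                      fo_state1 = rnorm(40), fo_state2 = rnorm(40),
                      max_fo = rnorm(40), sr = rnorm(40),
                      within_DefaultA = rnorm(40),
                      within_DefaultB = rnorm(40),
                      between_DefaultA__DefaultB = rnorm(40),
                      stringsAsFactors = FALSE)
  res <- run_association_battery(feats, co$phenotypes)
  expect_s3_class(res, "association_table")
  expect_identical(res$family[res$feature == "max_fo"], "hmm_global")
  expect_identical(res$family[res$feature == "fo_state2"], "state_fo")
  expect_identical(res$family[res$feature == "within_DefaultB"], "within_net")
  expect_identical(res$family[res$feature == "between_DefaultA__DefaultB"],
                   "between_net")
  # global metrics keep raw p
  glob <- res$family == "hmm_global"
  expect_identical(res$p_fdr[glob], res$p[glob])
  # families adjusted independently
  fam <- res$family == "state_fo"
  expect_equal(res$p_fdr[fam], oracle_bh(res$p[fam]), tolerance = 1e-12)
  expect_identical(res$significant, res$p_fdr <= 0.05)
  # each r/p matches a direct partial correlation
  covm <- as.matrix(co$phenotypes[, c("sex", "age", "mean_fd")])
  pc <- partial_correlation(feats$sr, co$phenotypes$score, covm)
  expect_equal(res$r[res$feature == "sr"], pc$r, tolerance = 1e-12)
  expect_equal(res$p[res$feature == "sr"], pc$p, tolerance = 1e-12)
})

test_that("association battery rejects subject mismatches", {
  co <- tiny_cohort(n_subjects = 3, seed = 18)
  feats <- data.frame(subject_id = c("sub0001", "sub0002", "nope"),
                      sr = c(0.1, 0.2, 0.3), stringsAsFactors = FALSE)
  expect_error(run_association_battery(feats, co$phenotypes),
               "nope|sub0003")
})

test_that("network_contribution aggregates significant pairs to both endpoints", {
  res <- data.frame(
    feature = c("between_A__B", "between_A__C", "between_B__C", "within_A"),
    family = c("between_net", "between_net", "between_net", "within_net"),
    r = c(0.5, 0.3, -0.2, 0.9),
    p = c(0.001, 0.002, 0.001, 0.5),
    p_fdr = c(0.003, 0.006, 0.003, 0.5),
    significant = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  out <- network_contribution(res)
  expect_identical(out$network[out$rank == 1], "A")
  expect_equal(out$cumulative_r[out$network == "A"], 0.8)
  expect_equal(out$cumulative_r[out$network == "B"], 0.5)
  expect_equal(out$cumulative_r[out$network == "C"], 0.3)
  expect_identical(out$n_pairs[out$network == "A"], 2L)
  # explicit network list includes empty networks
  out2 <- network_contribution(res, networks = c("A", "B", "C", "D"))
  expect_identical(out2$cumulative_r[out2$network == "D"], 0)
  bad <- res; bad$feature[1] <- "between_AB"
  expect_error(network_contribution(bad), "unparseable")
})
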