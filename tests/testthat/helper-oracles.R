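# Independent oracle implementations used by the test suite. Everything here
# is deliberately written the slow, obvious way (explicit loops, textbook
# formulas) so it cannot share bugs with the package's vectorized/C++ code.

# Multivariate normal log-density, textbook form.
oracle_dmvnorm_log <- function(x, mu, sigma) {
  N <- length(mu)
  d <- x - mu
  -0.5 * (N * log(2 * pi) + determinant(sigma, logarithm = TRUE)$modulus[1] +
            as.numeric(t(d) %*% solve(sigma) %*% d))
}

# All K^T state paths as rows.
oracle_all_paths <- function(K, Tn) {
  as.matrix(do.call(expand.grid, rep(list(seq_len(K)), Tn)))
}

# Brute-force HMM: total log-likelihood by enumeration over every path, and
# the maximum-probability path (first in row order on exact ties).
oracle_hmm_enumerate <- function(model, X) {
  Tn <- nrow(X)
  K <- model$K
  paths <- oracle_all_paths(K, Tn)
  logp <- apply(paths, 1L, function(p) {
    lp <- log(model$init[p[1]]) +
      oracle_dmvnorm_log(X[1, ], model$means[p[1], ], model$covs[[p[1]]])
    if (Tn > 1) for (t in 2:Tn) {
      lp <- lp + log(model$trans[p[t - 1], p[t]]) +
        oracle_dmvnorm_log(X[t, ], model$means[p[t], ], model$covs[[p[t]]])
    }
    lp
  })
  m <- max(logp)
  list(loglik = m + log(sum(exp(logp - m))),
       viterbi = as.integer(paths[which.max(logp), ]))
}

# Explicit double-loop temporal variability: split into floor(T/l) windows,
# Pearson FC per window, extract entries, 1 - mean pairwise correlation of
# the pattern vectors, averaged over window lengths.
oracle_variability <- function(X, entry_rows, entry_cols,
                               lengths = seq(20, 40, by = 2)) {
  vls <- numeric(0)
  for (l in lengths) {
    n <- floor(nrow(X) / l)
    pats <- vector("list", n)
    for (w in seq_len(n)) {
      W <- X[((w - 1) * l + 1):(w * l), , drop = FALSE]
      F <- stats::cor(W)
      pats[[w]] <- mapply(function(i, j) F[i, j], entry_rows, entry_cols)
    }
    acc <- 0
    np <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      acc <- acc + stats::cor(pats[[i]], pats[[j]])
      np <- np + 1
    }
    vls <- c(vls, 1 - acc / np)
  }
  mean(vls)
}

# Entry index pairs (rows/cols of the FC matrix) for a within-network block.
oracle_within_entries <- function(channels) {
  rows <- integer(0); cols <- integer(0)
  for (a in seq_along(channels)) for (b in seq_along(channels)) {
    if (a < b) { rows <- c(rows, channels[a]); cols <- c(cols, channels[b]) }
  }
  list(rows = rows, cols = cols)
}

# Entry index pairs for a full cross-block, in the package's
# (row-of-upper-triangle) enumeration order.
oracle_between_entries <- function(channels_a, channels_b, n_channels) {
  rows <- integer(0); cols <- integer(0)
  for (j in 2:n_channels) for (i in seq_len(j - 1)) {
    ina <- i %in% channels_a; inb <- i %in% channels_b
    jna <- j %in% channels_a; jnb <- j %in% channels_b
    if ((ina && jnb) || (inb && jna)) { rows <- c(rows, i); cols <- c(cols, j) }
  }
  list(rows = rows, cols = cols)
}

# All permutations of 1..n (n small), for Hungarian-style state matching.
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_permutations(n - 1)) {
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# Best label mapping decoded -> true by accuracy over all permutations.
oracle_match_states <- function(decoded, true_path, K) {
  best_acc <- -1
  best_perm <- NULL
  for (p in oracle_permutations(K)) {
    p <- unlist(p)
    acc <- mean(p[decoded] == true_path)
    if (acc > best_acc) { best_acc <- acc; best_perm <- p }
  }
  list(accuracy = best_acc, perm = best_perm)
}

# Benjamini-Hochberg step-up by the definition: find the largest k with
# p_(k) <= k/m * alpha-free adjusted form p_adj(i) = min over j >= rank(i)
# of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, m * ps[j] / j)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Residualize-then-correlate partial correlation using lm(), with the
# t-based two-sided p-value.
oracle_partial_cor <- function(x, y, Z) {
  rx <- stats::residuals(stats::lm(x ~ ., data = as.data.frame(Z)))
  ry <- stats::residuals(stats::lm(y ~ ., data = as.data.frame(Z)))
  r <- stats::cor(rx, ry)
  df <- length(x) - 2 - ncol(Z)
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df)
}

# Small deterministic test cohort helper (keeps per-test runtime low).
tiny_cohort <- function(n_subjects = 6, seed = 404, ...) {
  simulate_cohort(cohort_config(n_subjects = n_subjects, ...), seed = seed)
}
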