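# K-state Gaussian-observation HMM: maximum-likelihood EM (Baum-Welch) with
# restarts, log-space/scaled forward-backward, Viterbi decoding, and the
# occupancy/switching metrics computed from decoded paths.

#' Construct/validate a Gaussian HMM model object
#'
#' @param init length-K initial state distribution (sums to 1).
#' @param trans K x K row-stochastic transition matrix.
#' @param means K x N matrix of state means.
#' @param covs list of K symmetric positive-definite N x N covariances.
#' @param channel_labels optional channel names.
#' @return object of class `hmm_model`.
#' @export
hmm_model <- function(init, trans, means, covs, channel_labels = NULL) {
  means <- as.matrix(means)
  trans <- as.matrix(trans)
  K <- nrow(means)
  if (length(init) != K || abs(sum(init) - 1) > 1e-10 || any(init < 0))
    stop("init must be a length-K probability vector (sum 1 within 1e-10)")
  if (nrow(trans) != K || ncol(trans) != K ||
      any(abs(rowSums(trans) - 1) > 1e-10) || any(trans < 0))
    stop("trans must be K x K row-stochastic (rows sum to 1 within 1e-10)")
  if (length(covs) != K) stop("need one covariance per state")
  covs <- lapply(seq_len(K), function(k) {
    ck <- as.matrix(covs[[k]])
    if (!isTRUE(all.equal(ck, t(ck), tolerance = 1e-8)))
      stop("covariance ", k, " is not symmetric")
    if (min(eigen(ck, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("covariance ", k, " is not positive definite")
    (ck + t(ck)) / 2
  })
  structure(list(K = K, init = as.numeric(init), trans = trans, means = means,
                 covs = covs, channel_labels = channel_labels),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("hmm_model: %d states over %d channels\n", x$K, ncol(x$means)))
  if (!is.null(x$loglik)) cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

as_series_matrix <- function(series) {
  if (inherits(series, "parcellated_ts")) series$data else as.matrix(series)
}

# T x K matrix of Gaussian log-densities, one column per state.
log_emission <- function(X, means, covs) {
  K <- nrow(means)
  N <- ncol(means)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    R <- tryCatch(chol(covs[[k]]), error = function(e) NULL)
    if (is.null(R))
      stop("singular covariance for state ", k,
           "; consider regularization (add eps * I)")
    Z <- sweep(X, 2L, means[k, ], `-`)
    V <- backsolve(R, t(Z), transpose = TRUE)
    out[, k] <- -0.5 * (N * log(2 * pi) + 2 * sum(log(diag(R))) +
                          colSums(V * V))
  }
  out
}

#' Average channels into per-network signals
#'
#' Computes the mean signal over each network's member channels, mirroring
#' network-level time-series extraction from a parcellation.
#'
#' @param ts [parcellated_ts()] object.
#' @param map [network_map()]; must cover every channel of `ts`.
#' @return [parcellated_ts()] with one channel per network, in map order.
#' @export
network_average <- function(ts, map) {
  stopifnot(inherits(ts, "parcellated_ts"), inherits(map, "network_map"))
  unmapped <- setdiff(ts$channel_labels, map$channels)
  if (length(unmapped) > 0L)
    stop("channels not in network map: ", paste(unmapped, collapse = ", "))
  nets <- map$network_of[ts$channel_labels]
  X <- vapply(map$network_names,
              function(m) rowMeans(ts$data[, nets == m, drop = FALSE]),
              numeric(nrow(ts$data)))
  parcellated_ts(X, ts$subject_id, channel_labels = map$network_names,
                 tr_seconds = ts$tr_seconds)
}

#' Standardize per subject and concatenate a cohort
#'
#' Each subject's each channel is z-scored (mean 0, SD 1 within subject)
#' before row-wise concatenation; subject boundaries are recorded so
#' inference never carries probability mass across subjects.
#'
#' @param ts_list list of [parcellated_ts()] sharing channel count/order.
#' @return object of class `concat_ts`: `X` (sum(T) x N matrix), `starts`
#'   (1-based segment start indices), `subject_ids`, `channel_labels`.
#' @export
standardize_and_concatenate <- function(ts_list) {
  stopifnot(length(ts_list) >= 1L)
  labels <- ts_list[[1L]]$channel_labels
  mats <- vector("list", length(ts_list))
  for (s in seq_along(ts_list)) {
    ts <- ts_list[[s]]
    if (!identical(ts$channel_labels, labels))
      stop("subject ", ts$subject_id, " has mismatched channel labels")
    sds <- apply(ts$data, 2L, stats::sd)
    zero <- which(sds == 0)
    if (length(zero) > 0L)
      stop(sprintf("zero-variance channel '%s' in subject %s",
                   labels[zero[1L]], ts$subject_id))
    mats[[s]] <- scale(ts$data)
  }
  lens <- vapply(mats, nrow, integer(1L))
  structure(list(X = do.call(rbind, mats),
                 starts = cumsum(c(1L, lens[-length(lens)])),
                 subject_ids = vapply(ts_list, function(t) t$subject_id,
                                      character(1L)),
                 channel_labels = labels),
            class = "concat_ts")
}

as_concat <- function(x) {
  if (inherits(x, "concat_ts")) return(x)
  if (inherits(x, "parcellated_ts")) return(standardize_and_concatenate(list(x)))
  if (is.list(x) && all(vapply(x, inherits, logical(1L), "parcellated_ts")))
    return(standardize_and_concatenate(x))
  if (is.matrix(x))
    return(structure(list(X = x, starts = 1L, subject_ids = "series1",
                          channel_labels = colnames(x)),
                     class = "concat_ts"))
  stop("expected a matrix, parcellated_ts, list of parcellated_ts, or concat_ts")
}

#' Forward-backward state inference for one series
#'
#' Computes per-timepoint posterior state probabilities and the data
#' log-likelihood under the model using the scaled forward-backward
#' recursions (no underflow at any series length).
#'
#' @param model [hmm_model()].
#' @param series T x N matrix or [parcellated_ts()] (used as-is; standardize
#'   beforehand if the model was fitted on standardized data).
#' @return list with `gamma` (T x K posterior, rows sum to 1) and `loglik`.
#' @export
forward_backward <- function(model, series) {
  X <- as_series_matrix(series)
  ld <- log_emission(X, model$means, model$covs)
  r <- .fb_cpp(ld, model$init, model$trans, 0L)
  list(gamma = r$gamma, loglik = r$loglik)
}

#' Viterbi decoding for one series
#'
#' Returns a maximum-probability state path; ties are broken toward the
#' lowest state index.
#'
#' @inheritParams forward_backward
#' @return integer vector of length T with values in 1..K.
#' @export
viterbi <- function(model, series) {
  X <- as_series_matrix(series)
  ld <- log_emission(X, model$means, model$covs)
  logsafe <- function(p) log(pmax(p, 1e-300))
  .viterbi_cpp(ld, logsafe(model$init), logsafe(model$trans), 0L)
}

#' Decode states for one subject
#'
#' @inheritParams forward_backward
#' @param subject_id identifier attached to the decoding.
#' @return object of class `state_decoding`: `subject_id`, `gamma`,
#'   `viterbi_path`, `loglik`.
#' @export
decode_states <- function(model, series, subject_id = "series1") {
  if (inherits(series, "parcellated_ts") && missing(subject_id))
    subject_id <- series$subject_id
  fb <- forward_backward(model, series)
  structure(list(subject_id = subject_id, gamma = fb$gamma,
                 viterbi_path = viterbi(model, series), loglik = fb$loglik),
            class = "state_decoding")
}

# One EM run from a given restart seed; returns model + trace.
em_run <- function(X, starts, K, seed, tol, max_iter) {
  N <- ncol(X)
  nobs <- nrow(X)
  events <- character(0L)
  with_seed(seed, {
    # initializer only; a non-converged k-means is still a usable seed
    km <- if (K == 1L) list(centers = matrix(colMeans(X), 1L))
      else suppressWarnings(stats::kmeans(X, centers = K, iter.max = 50L,
                                          nstart = 1L))
    means <- matrix(km$centers, K, N)
    pooled <- stats::cov(X)
    pooled <- pooled + diag(1e-8 * mean(diag(pooled)), N)
    covs <- replicate(K, pooled, simplify = FALSE)
    init <- rep(1 / K, K)
    trans <- sample_transition_matrix(K, if (K == 1L) NA else 0.9)
    trace <- numeric(0L)
    ll_prev <- -Inf
    inc <- Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      ld <- log_emission(X, means, covs)
      e <- .fb_cpp(ld, init, trans, as.integer(starts - 1L))
      ll <- e$loglik
      trace <- c(trace, ll)
      inc <- (ll - ll_prev) / nobs
      if (is.finite(ll_prev) && inc < tol) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      gamma <- e$gamma
      w <- colSums(gamma)
      init <- e$init_post / sum(e$init_post)
      if (K > 1L) {
        trans <- e$xi / pmax(rowSums(e$xi), .Machine$double.xmin)
        trans <- trans / rowSums(trans)
      }
      for (k in seq_len(K)) {
        if (w[k] < N + 2) {   # state collapse: re-seat on a random datapoint
          means[k, ] <- X[sample.int(nobs, 1L), ]
          covs[[k]] <- pooled
          events <- c(events, sprintf("iter %d: state %d collapsed (weight %.3g), re-seeded",
                                      iter, k, w[k]))
          next
        }
        mu <- colSums(gamma[, k] * X) / w[k]
        Xc <- sweep(X, 2L, mu, `-`)
        ck <- crossprod(Xc * gamma[, k], Xc) / w[k]
        ck <- (ck + t(ck)) / 2
        ev <- eigen(ck, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > 1e10) {
          eps <- 1e-6 * mean(diag(ck))
          ck <- ck + diag(eps, N)
          events <- c(events, sprintf("iter %d: state %d covariance regularized (+%.3g I)",
                                      iter, k, eps))
        }
        means[k, ] <- mu
        covs[[k]] <- ck
      }
    }
    if (!converged)
      warning(sprintf("EM did not converge in %d iterations (last increment %.3g); returning best-so-far",
                      max_iter, inc),
              call. = FALSE)
    model <- hmm_model(init, trans, means, covs)
    model$loglik <- trace[length(trace)]
    model$loglik_trace <- trace
    model$n_iter <- length(trace)
    model$converged <- converged
    model$events <- events
    model
  })
}

#' Fit a Gaussian HMM by EM with restarts
#'
#' Baum-Welch maximum-likelihood estimation. Each restart is initialized by
#' k-means on timepoints (means), the pooled covariance for every state,
#' uniform initial probabilities and a 0.9-diagonal transition matrix;
#' restart r uses `seed + r`. The restart with the highest final
#' log-likelihood is returned (selection by objective, as in free-energy
#' based run selection). The E-step restarts the chain at every subject
#' boundary.
#'
#' @param x matrix, [parcellated_ts()], list of [parcellated_ts()] (which is
#'   standardized and concatenated), or a `concat_ts`.
#' @param K number of states.
#' @param n_restarts number of EM restarts (default 10).
#' @param seed base RNG seed.
#' @param tol convergence threshold on the per-timepoint log-likelihood
#'   increment (default 1e-6).
#' @param max_iter maximum EM iterations per restart.
#' @return `hmm_model` with fields `loglik`, `loglik_trace` (monotone
#'   non-decreasing), `restart_logliks`, `n_iter`, `events`,
#'   `channel_labels`.
#' @export
fit_hmm <- function(x, K, n_restarts = 10, seed = 1, tol = 1e-6,
                    max_iter = 100) {
  stopifnot(K >= 1, n_restarts >= 1)
  cc <- as_concat(x)
  best <- NULL
  finals <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    m <- em_run(cc$X, cc$starts, K, seed + r, tol, max_iter)
    finals[r] <- m$loglik
    if (is.null(best) || m$loglik > best$loglik) best <- m
  }
  best$restart_logliks <- finals
  best$channel_labels <- cc$channel_labels
  best
}

#' Scan model orders for run-to-run stability
#'
#' Fits `n_runs` independent models per state count and summarizes
#' run-to-run state-assignment similarity as the mean pairwise adjusted
#' Rand index between concatenated Viterbi paths — supporting a
#' stability-based choice of K.
#'
#' @param x data accepted by [fit_hmm()].
#' @param K_range state counts to scan (default 8:12).
#' @param n_runs independent runs per K (default 10).
#' @param seed base seed; run j of order K uses a distinct child seed.
#' @param ... passed to [fit_hmm()] (e.g. `tol`, `max_iter`).
#' @return list with `runs` (data.frame K, run, loglik, n_iter) and
#'   `similarity` (data.frame K, mean_ari; NA when n_runs < 2).
#' @export
scan_states <- function(x, K_range = 8:12, n_runs = 10, seed = 1, ...) {
  stopifnot(length(K_range) >= 1L, n_runs >= 1L)
  cc <- as_concat(x)
  runs <- list()
  sims <- list()
  for (K in K_range) {
    paths <- vector("list", n_runs)
    for (j in seq_len(n_runs)) {
      m <- fit_hmm(cc, K, n_restarts = 1L, seed = seed + 997L * j + 131L * K,
                   ...)
      paths[[j]] <- viterbi(m, cc$X)
      runs[[length(runs) + 1L]] <- data.frame(K = K, run = j,
                                              loglik = m$loglik,
                                              n_iter = m$n_iter)
    }
    mean_ari <- NA_real_
    if (n_runs >= 2L) {
      prs <- utils::combn(n_runs, 2L)
      mean_ari <- mean(apply(prs, 2L, function(p)
        mclust::adjustedRandIndex(paths[[p[1L]]], paths[[p[2L]]])))
    }
    sims[[length(sims) + 1L]] <- data.frame(K = K, mean_ari = mean_ari)
  }
  list(runs = do.call(rbind, runs), similarity = do.call(rbind, sims))
}

#' Occupancy and switching metrics from a decoded path
#'
#' Fractional occupancy FO_k is the fraction of timepoints assigned to
#' state k; MaxFO is the largest FO; the switching rate SR is the number of
#' state switches divided by the number of timepoints.
#'
#' @param decoding a `state_decoding`, or an integer state path.
#' @param K number of states (inferred from a decoding's gamma).
#' @param posterior_fo if TRUE, FO is computed from posterior probabilities
#'   (column means of gamma) instead of the hard path; SR always counts hard
#'   switches.
#' @return object of class `dynamics_metrics`: `subject_id`, `fo` (sums to
#'   1), `max_fo`, `sr`.
#' @export
dynamics_metrics <- function(decoding, K = NULL, posterior_fo = FALSE) {
  if (inherits(decoding, "state_decoding")) {
    path <- decoding$viterbi_path
    if (is.null(K)) K <- ncol(decoding$gamma)
    subject_id <- decoding$subject_id
    gamma <- decoding$gamma
  } else {
    path <- as.integer(decoding)
    if (is.null(K)) K <- max(path)
    subject_id <- NA_character_
    gamma <- NULL
    if (posterior_fo) stop("posterior_fo requires a state_decoding")
  }
  if (any(path < 1L | path > K)) stop("path values must lie in 1..K")
  Tn <- length(path)
  fo <- if (posterior_fo) colMeans(gamma) else tabulate(path, K) / Tn
  structure(list(subject_id = subject_id, fo = fo, max_fo = max(fo),
                 sr = sum(diff(path) != 0) / Tn),
            class = "dynamics_metrics")
}

#' Per-subject dynamics metrics for a fitted cohort
#'
#' Decodes every subject of a standardized, concatenated cohort under one
#' model and returns the FO/MaxFO/SR feature table used by the association
#' battery.
#'
#' @param model fitted [hmm_model()].
#' @param x data accepted by [fit_hmm()] (standardization is applied the
#'   same way as during fitting).
#' @param posterior_fo see [dynamics_metrics()].
#' @return data.frame with columns `subject_id`, `fo_state1..K`, `max_fo`,
#'   `sr`.
#' @export
cohort_dynamics <- function(model, x, posterior_fo = FALSE) {
  cc <- as_concat(x)
  S <- length(cc$starts)
  ends <- c(cc$starts[-1L] - 1L, nrow(cc$X))
  rows <- vector("list", S)
  for (s in seq_len(S)) {
    seg <- cc$X[cc$starts[s]:ends[s], , drop = FALSE]
    d <- decode_states(model, seg, subject_id = cc$subject_ids[s])
    m <- dynamics_metrics(d, posterior_fo = posterior_fo)
    row <- as.data.frame(as.list(stats::setNames(
      m$fo, paste0("fo_state", seq_along(m$fo)))))
    row$max_fo <- m$max_fo
    row$sr <- m$sr
    row <- cbind(data.frame(subject_id = cc$subject_ids[s],
                            stringsAsFactors = FALSE), row)
    rows[[s]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
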