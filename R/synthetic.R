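# Synthetic resting-state cohorts with known ground truth: Markov state
# switching, state-specific Gaussian emissions over network-structured
# channels, a slow connectivity drift that plants higher windowed-FC
# variability, and a depression-like score coupled to the dynamics.

#' Names of the 17 canonical large-scale networks
#'
#' Network labels following the 17-network cortical parcellation commonly
#' used for resting-state analyses (visual, somatomotor, attention, limbic,
#' control, default-mode and temporoparietal subsystems).
#' @return character vector of length 17.
#' @export
schaefer17_names <- function() {
  c("VisCent", "VisPeri", "SomMotA", "SomMotB", "DorsAttnA", "DorsAttnB",
    "SalVentAttnA", "SalVentAttnB", "LimbicA", "LimbicB", "ContA", "ContB",
    "ContC", "DefaultA", "DefaultB", "DefaultC", "TempPar")
}

#' Default channel-to-network map for synthetic cohorts
#'
#' @param channels_per_network number of simulated channels (ROIs) per
#'   network; at least 3 so that within-network FC patterns have enough
#'   entries for pattern correlations.
#' @param networks character vector of network names.
#' @return [network_map()] object.
#' @export
default_network_map <- function(channels_per_network = 4,
                                networks = schaefer17_names()) {
  stopifnot(channels_per_network >= 1)
  ch <- unlist(lapply(networks, function(m)
    paste0(m, "_", seq_len(channels_per_network))))
  network_map(ch, rep(networks, each = channels_per_network))
}

#' Sample a sticky row-stochastic transition matrix
#'
#' Diagonal entries equal `stickiness`; the remaining mass is spread
#' uniformly over the off-diagonal entries of each row.
#'
#' @param K number of states (>= 1).
#' @param stickiness self-transition probability, in (0,1).
#' @return K x K row-stochastic matrix.
#' @export
sample_transition_matrix <- function(K, stickiness) {
  stopifnot(K >= 1)
  if (K == 1L) return(matrix(1, 1, 1))
  if (stickiness <= 0 || stickiness >= 1)
    stop("stickiness must be in (0,1)")
  off <- (1 - stickiness) / (K - 1)
  m <- matrix(off, K, K)
  diag(m) <- stickiness
  m
}

#' Simulate a Markov state path
#'
#' The state at time t depends only on the state at time t-1 through the
#' transition matrix; the first state is drawn from `init`.
#'
#' @param trans K x K row-stochastic transition matrix.
#' @param init initial state distribution (sums to 1).
#' @param n_timepoints path length T.
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @return integer vector of length T with values in 1..K.
#' @export
simulate_state_path <- function(trans, init, n_timepoints, seed = NULL) {
  trans <- as.matrix(trans)
  K <- nrow(trans)
  if (ncol(trans) != K) stop("transition matrix must be square")
  if (any(abs(rowSums(trans) - 1) > 1e-8) || any(trans < 0))
    stop("transition matrix must be row-stochastic")
  if (length(init) != K || abs(sum(init) - 1) > 1e-8 || any(init < 0))
    stop("init must be a length-K probability vector")
  stopifnot(n_timepoints >= 1)
  with_seed(seed, {
    path <- integer(n_timepoints)
    path[1L] <- sample.int(K, 1L, prob = init)
    if (n_timepoints > 1L)
      for (t in 2:n_timepoints)
        path[t] <- sample.int(K, 1L, prob = trans[path[t - 1L], ])
    path
  })
}

#' Simulate one subject's BOLD series from a state path
#'
#' With `delta = 0`, row t is drawn from a multivariate Gaussian with the
#' mean and covariance of the active state. With `delta > 0`, emissions are
#' drawn from the equivalent latent factor model (see `factors`) under two
#' slow sinusoidal connectivity drifts of amplitude `delta`:
#' \itemize{
#'   \item within-network: the factor loadings of each drift channel are
#'     multiplied by `1 + delta * sin(2*pi*(t-1)/period + drift_phase[c])`,
#'     so every off-diagonal covariance entry touching a drift channel is
#'     modulated with a pattern that changes shape over time (per-channel
#'     phases);
#'   \item between-network: each drift-target channel loads on one shared
#'     latent factor with signed sinusoidal weight
#'     `a_i(t) = delta * sin(coupling_freq[i] * (t-1) + drift_phase[i])`, so
#'     any pair of target channels gains an FC component proportional to
#'     `a_i(t) a_j(t)`. Because the channels use distinct frequencies, the
#'     product averages to about zero over the run (no stable added
#'     structure, which would raise rather than lower window-pattern
#'     correlations) while its window means oscillate at the difference
#'     frequency, changing the cross-block FC pattern from window to window.
#'     Channel variance gains a mild `a_i(t)^2` ripple, which the FC
#'     normalization absorbs.
#' }
#' The instantaneous covariance remains positive definite by construction,
#' and larger `delta` plants larger temporal variability of windowed FC.
#' Phases must differ across channels/networks: a homogeneous modulation is
#' invisible to pattern correlations, which are affine-invariant.
#'
#' @param path integer state path (values 1..K).
#' @param means K x N matrix of state means.
#' @param covs list of K symmetric positive-definite N x N covariances.
#' @param delta drift amplitude, in [0, 1); 0 disables the drift.
#' @param drift_phase length-N vector of phases in radians, NA for channels
#'   the drift does not load on. Required when delta > 0.
#' @param coupling_freq length-N vector of angular frequencies (radians per
#'   timepoint) of the shared-factor loadings, NA for channels outside the
#'   between-network drift. Frequencies should be distinct across coupled
#'   channels and slow relative to the window lengths of interest.
#' @param period sinusoid period in timepoints (default 96).
#' @param factors latent factor parameterization of the state covariances,
#'   as built by the cohort generator (fields `gamma`: global-factor
#'   loadings; `net_loading`: network-factor loadings; `idio`: idiosyncratic
#'   SDs; `net_idx`: network index per channel; `signs`: K x N per-state
#'   sign flips). Required when delta > 0; must be consistent with `covs`
#'   (i.e. `covs[[k]] = (d_k d_k') * (gamma gamma' + blockdiag(net_loading
#'   net_loading') + diag(idio^2))`).
#' @param channel_labels optional channel names.
#' @param subject_id subject identifier.
#' @param seed optional RNG seed.
#' @return [parcellated_ts()] object.
#' @export
simulate_subject_bold <- function(path, means, covs, delta = 0,
                                  drift_phase = NULL, coupling_freq = NULL,
                                  period = 96, factors = NULL,
                                  channel_labels = NULL,
                                  subject_id = "sim", seed = NULL) {
  path <- as.integer(path)
  means <- as.matrix(means)
  K <- nrow(means)
  N <- ncol(means)
  if (length(covs) != K) stop("need one covariance per state")
  if (any(path < 1L | path > K)) stop("path values must be in 1..K")
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)")
  chols <- lapply(seq_len(K), function(k) {
    ck <- as.matrix(covs[[k]])
    if (!isTRUE(all.equal(ck, t(ck), tolerance = 1e-8)))
      stop("covariance for state ", k, " is not symmetric")
    r <- tryCatch(chol(ck), error = function(e) NULL)
    if (is.null(r)) stop("covariance for state ", k,
                         " is not positive definite")
    r
  })
  Tn <- length(path)
  with_seed(seed, {
    if (delta == 0) {
      Z <- matrix(stats::rnorm(Tn * N), Tn, N)
      X <- matrix(0, Tn, N)
      for (k in unique(path)) {
        rows <- which(path == k)
        X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[k]] +
          matrix(means[k, ], length(rows), N, byrow = TRUE)
      }
    } else {
      if (is.null(drift_phase) || is.null(factors))
        stop("drift_phase and factors are required when delta > 0")
      if (length(drift_phase) != N)
        stop("drift_phase must have one entry per channel")
      psi <- drift_phase
      theta <- 2 * pi * (seq_len(Tn) - 1) / period
      Mmod <- matrix(1, Tn, N)
      active <- which(!is.na(psi))
      if (length(active) > 0L)
        Mmod[, active] <- 1 + delta * sin(outer(theta, psi[active], `+`))
      G <- stats::rnorm(Tn)
      Fm <- matrix(stats::rnorm(Tn * max(factors$net_idx)), Tn)
      E <- matrix(stats::rnorm(Tn * N), Tn, N)
      Fpart <- sweep(Fm[, factors$net_idx, drop = FALSE], 2L,
                     factors$net_loading, `*`)
      coupled <- if (is.null(coupling_freq)) integer(0)
        else which(!is.na(coupling_freq))
      if (any(is.na(psi[coupled])))
        stop("coupled channels must have a drift_phase")
      if (length(coupled) > 0L) {
        zeta <- stats::rnorm(Tn)
        tt <- seq_len(Tn) - 1
        A <- delta * sin(tt %o% coupling_freq[coupled] +
                           rep(psi[coupled], each = Tn))
        Fpart[, coupled] <- Fpart[, coupled] + A * zeta
      }
      Y <- Mmod * (outer(G, factors$gamma) + Fpart) +
        sweep(E, 2L, factors$idio, `*`)
      X <- means[path, , drop = FALSE] +
        factors$signs[path, , drop = FALSE] * Y
    }
    parcellated_ts(X, subject_id, channel_labels = channel_labels)
  })
}

# Base network-block correlation template, factor-structured so window-FC
# patterns are heterogeneous and stable at baseline: within-block
# correlations lambda_c * lambda_d (lambda spread over [0.55, 0.95] within
# each block), cross-block gamma_c * gamma_d with gamma = cross_scale *
# lambda (weaker between- than within-network FC). cross_scale must be
# large enough that the stable cross-block pattern is detectable against
# window sampling noise, otherwise between-network variability sits at its
# noise ceiling (V ~ 1) for every subject and planted drift has no
# headroom. The construction C = gamma gamma' +
# blockdiag(lambda lambda' - gamma gamma') + diag(1 - lambda^2) is a sum of
# PSD terms plus a positive diagonal, hence positive definite.
base_correlation_template <- function(map, within_loading = c(0.55, 0.95),
                                      cross_scale = 0.85) {
  net <- map$network_of[map$channels]
  N <- length(map$channels)
  lambda <- numeric(N)
  for (m in map$network_names) {
    idx <- which(net == m)
    lambda[idx] <- seq(within_loading[1L], within_loading[2L],
                       length.out = length(idx))
  }
  gamma <- cross_scale * lambda
  C <- gamma %o% gamma
  same <- outer(net, net, `==`)
  C[same] <- (lambda %o% lambda)[same]
  diag(C) <- 1
  C
}

# State-specific emission parameters: orthonormal network-level mean
# patterns scaled to a given pairwise channel-space separation, and
# covariances derived from the factor-structured base template by
# sign-flipping the channels of randomly selected blocks (a congruence
# D C D, hence exactly SPD). Channels listed in flip_exclude never flip:
# state-dependent sign scrambling of a cross-block destroys its stable
# window-FC pattern, so the drift-target networks are kept flip-free to
# preserve the variability headroom the drift needs. The factor
# decomposition (global loading gamma, network-factor loading,
# idiosyncratic SD, per-state signs) is returned alongside so the drift can
# modulate loadings at sampling time.
state_emission_params <- function(K, map, separation, flip_prob = 0.3,
                                  within_loading = c(0.55, 0.95),
                                  cross_scale = 0.85, flip_exclude = NULL) {
  M <- length(map$network_names)
  N <- length(map$channels)
  cpn <- N / M
  if (K > M) stop("state count exceeds network count; cannot build orthogonal mean patterns")
  Q <- qr.Q(qr(matrix(stats::rnorm(M * K), M, K)))
  scale_a <- separation / sqrt(2 * cpn)
  net_idx <- match(map$network_of[map$channels], map$network_names)
  means <- t(vapply(seq_len(K),
                    function(k) scale_a * Q[net_idx, k], numeric(N)))
  C0 <- base_correlation_template(map, within_loading, cross_scale)
  net <- map$network_of[map$channels]
  lambda <- numeric(N)
  for (m in map$network_names) {
    idx <- which(net == m)
    lambda[idx] <- seq(within_loading[1L], within_loading[2L],
                       length.out = length(idx))
  }
  gamma <- cross_scale * lambda
  signs <- matrix(1, K, N)
  for (k in seq_len(K)) {
    flip_nets <- map$network_names[stats::runif(M) < flip_prob]
    signs[k, net %in% flip_nets] <- -1
  }
  if (length(flip_exclude) > 0L) signs[, flip_exclude] <- 1
  covs <- lapply(seq_len(K), function(k) (signs[k, ] %o% signs[k, ]) * C0)
  list(means = means, covs = covs,
       factors = list(gamma = gamma,
                      net_loading = sqrt(lambda^2 - gamma^2),
                      idio = sqrt(1 - lambda^2),
                      net_idx = net_idx, signs = signs))
}

#' Default configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions the pipeline is designed for:
#' T = 242 volumes at TR = 2 s, 17 networks, an 8-state switching process
#' with subject stickiness in (0.80, 0.98) (dwell times of tens of
#' volumes), motion below 0.2 mm, age ~ N(19.42, 1.38), and a score coupled
#' positively to switching rate and connectivity variability.
#'
#' @param n_subjects cohort size.
#' @param n_timepoints volumes per subject.
#' @param n_states number of latent states K.
#' @param channels_per_network simulated channels (ROIs) per network.
#' @param networks network names.
#' @param stickiness_range range for the per-subject self-transition
#'   probability theta_s.
#' @param mean_separation pairwise Euclidean distance between state means in
#'   channel-SD units.
#' @param b_sr,b_var score couplings on (negative) stickiness and drift
#'   amplitude; positive values plant score ~ +SR, -MaxFO, +variability.
#' @param noise_sd SD of the Gaussian noise added to the score.
#' @param delta_max per-subject drift amplitude is U(0, delta_max).
#' @param drift_period sinusoid period in volumes; slower than the longest
#'   variability window so windows sample different drift phases.
#' @param drift_targets networks whose FC the drift modulates.
#' @param sex_p probability of sex = 1.
#' @param age_mean,age_sd age distribution (years).
#' @param fd_max mean framewise displacement is U(0, fd_max) mm.
#' @param tr_seconds repetition time metadata.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 100, n_timepoints = 242, n_states = 8,
                          channels_per_network = 4,
                          networks = schaefer17_names(),
                          stickiness_range = c(0.80, 0.98),
                          mean_separation = 3,
                          b_sr = 0.3, b_var = 0.3, noise_sd = 1,
                          delta_max = 0.5, drift_period = 96,
                          drift_targets = c("DefaultA", "DefaultB",
                                            "SalVentAttnA", "ContC",
                                            "SomMotB"),
                          sex_p = 204 / 696, age_mean = 19.42, age_sd = 1.38,
                          fd_max = 0.2, tr_seconds = 2) {
  stopifnot(n_subjects >= 2, n_timepoints >= 2, n_states >= 1,
            stickiness_range[1L] > 0, stickiness_range[2L] < 1,
            stickiness_range[1L] <= stickiness_range[2L],
            delta_max >= 0, delta_max < 1, noise_sd >= 0)
  if (!all(drift_targets %in% networks))
    stop("drift_targets must be a subset of the network names")
  structure(list(n_subjects = n_subjects, n_timepoints = n_timepoints,
                 n_states = n_states,
                 channels_per_network = channels_per_network,
                 networks = networks, stickiness_range = stickiness_range,
                 mean_separation = mean_separation, b_sr = b_sr,
                 b_var = b_var, noise_sd = noise_sd, delta_max = delta_max,
                 drift_period = drift_period, drift_targets = drift_targets,
                 sex_p = sex_p, age_mean = age_mean, age_sd = age_sd,
                 fd_max = fd_max, tr_seconds = tr_seconds),
            class = "cohort_config")
}

#' Simulate a synthetic cohort with ground truth
#'
#' For each subject s: stickiness theta_s ~ U(stickiness range) governs a
#' sticky transition matrix; a Markov path drives state-specific Gaussian
#' emissions; a drift amplitude delta_s ~ U(0, delta_max) modulates FC in
#' the drift-target networks. The depression-like score is
#' `standardize(-b_sr * z(theta_s) + b_var * z(delta_s))` plus small
#' loadings (0.1) on sex, age and mean FD and Gaussian noise — so by
#' construction the score is positively associated with true switching rate
#' and planted variability, and negatively with MaxFO.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; identical seed + config gives an identical cohort.
#' @return object of class `synthetic_cohort`: list with `timeseries` (list
#'   of [parcellated_ts()]), `phenotypes` (`phenotype_table`),
#'   `ground_truth`, `network_map`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  map <- default_network_map(cfg$channels_per_network, cfg$networks)
  N <- length(map$channels)
  K <- cfg$n_states
  S <- cfg$n_subjects
  Tn <- cfg$n_timepoints
  with_seed(seed, {
    # per-channel drift phases: spread across and within target networks so
    # the modulation is heterogeneous (visible to pattern correlations)
    psi <- rep(NA_real_, N)
    tg <- cfg$drift_targets
    for (i in seq_along(tg)) {
      idx <- which(map$network_of[map$channels] == tg[i])
      psi[idx] <- 2 * pi * (i - 1) / length(tg) +
        2 * pi * (seq_along(idx) - 1) / length(idx)
    }
    # distinct slow frequencies (2 to 7 cycles per run) for the shared-factor
    # loadings of the target channels, so injected pairwise structure has
    # near-zero time average but oscillating window means
    targ <- which(!is.na(psi))
    cfreq <- rep(NA_real_, N)
    if (length(targ) > 0L)
      cfreq[targ] <- 2 * pi *
        (2 + 5 * (seq_along(targ) - 1) / max(1L, length(targ) - 1L)) / Tn
    em <- state_emission_params(K, map, cfg$mean_separation,
                                flip_exclude = targ)
    theta <- stats::runif(S, cfg$stickiness_range[1L], cfg$stickiness_range[2L])
    delta <- stats::runif(S, 0, cfg$delta_max)
    sex <- stats::rbinom(S, 1, cfg$sex_p)
    age <- stats::rnorm(S, cfg$age_mean, cfg$age_sd)
    mean_fd <- stats::runif(S, 0, cfg$fd_max)
    zs <- function(v) if (stats::sd(v) > 0) as.numeric(scale(v)) else rep(0, length(v))
    base <- -cfg$b_sr * zs(theta) + cfg$b_var * zs(delta)
    base <- zs(base)
    score <- base + 0.1 * (sex - mean(sex)) + 0.1 * zs(age) +
      0.1 * zs(mean_fd) + cfg$noise_sd * stats::rnorm(S)
    ids <- sprintf("sub%04d", seq_len(S))
    init <- rep(1 / K, K)
    ts_list <- vector("list", S)
    paths <- vector("list", S)
    trans_list <- vector("list", S)
    fo <- matrix(0, S, K)
    sr <- numeric(S)
    for (s in seq_len(S)) {
      trans_list[[s]] <- sample_transition_matrix(K, theta[s])
      p <- simulate_state_path(trans_list[[s]], init, Tn)
      paths[[s]] <- p
      fo[s, ] <- tabulate(p, K) / Tn
      sr[s] <- sum(diff(p) != 0) / Tn
      ts_list[[s]] <- simulate_subject_bold(
        p, em$means, em$covs, delta = delta[s], drift_phase = psi,
        coupling_freq = cfreq, period = cfg$drift_period,
        factors = em$factors, channel_labels = map$channels,
        subject_id = ids[s])
    }
    phenotypes <- as_phenotype_table(
      data.frame(subject_id = ids, score = score, sex = sex, age = age,
                 mean_fd = mean_fd, stringsAsFactors = FALSE),
      filter_fd = FALSE)
    ground_truth <- list(
      subject_id = ids, theta = theta, delta = delta,
      paths = paths, trans = trans_list,
      fo = fo, max_fo = apply(fo, 1L, max), sr = sr,
      emission_means = em$means, emission_covs = em$covs,
      drift_phase = psi, drift_coupling_freq = cfreq,
      b_sr = cfg$b_sr, b_var = cfg$b_var,
      noise_sd = cfg$noise_sd)
    structure(list(timeseries = ts_list, phenotypes = phenotypes,
                   ground_truth = ground_truth, network_map = map,
                   config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d timepoints x %d channels, %d states\n",
              length(x$timeseries), x$config$n_timepoints,
              length(x$network_map$channels), x$config$n_states))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Layout: `timeseries/<subject_id>.tsv`, `phenotypes.tsv`,
#' `network_map.yaml`, `ground_truth.json`, `config.json`.
#'
#' @param cohort `synthetic_cohort` object.
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$timeseries)
    write_timeseries(ts, file.path(dir, "timeseries",
                                   paste0(ts$subject_id, ".tsv")))
  ph <- as.data.frame(cohort$phenotypes)
  utils::write.table(ph, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network_map(cohort$network_map, file.path(dir, "network_map.yaml"))
  gt <- cohort$ground_truth
  gt$trans <- lapply(gt$trans, function(m) unclass(m))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory.
#' @param filter_fd apply the motion filter when reading phenotypes.
#' @return list with `timeseries`, `phenotypes`, `network_map`.
#' @export
read_cohort <- function(dir, filter_fd = FALSE) {
  files <- list.files(file.path(dir, "timeseries"), pattern = "\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no time-series files in ", dir)
  ts_list <- lapply(files, function(f)
    read_timeseries(f, sub("\\.tsv$", "", basename(f))))
  phenotypes <- read_phenotypes(file.path(dir, "phenotypes.tsv"),
                                filter_fd = filter_fd)
  map <- read_network_map(file.path(dir, "network_map.yaml"))
  list(timeseries = ts_list, phenotypes = phenotypes, network_map = map)
}
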