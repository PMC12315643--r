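# Temporal variability of windowed functional connectivity: one minus the
# mean pairwise Pearson correlation between the vectorized FC patterns of
# non-overlapping time windows, averaged over a range of window lengths.

#' Split a series into non-overlapping windows
#'
#' Windows are anchored at the start of the series; the trailing
#' `T mod l` timepoints are discarded.
#'
#' @param series T x k numeric matrix (or [parcellated_ts()]).
#' @param l window length in timepoints (>= 3).
#' @return list of `floor(T/l)` matrices of shape l x k (at least 2).
#' @export
segment_windows <- function(series, l) {
  X <- as_series_matrix(series)
  if (l < 3) stop("window length must be at least 3")
  n <- floor(nrow(X) / l)
  if (n < 2) stop(sprintf("insufficient windows: T=%d gives %d window(s) of length %d",
                          nrow(X), n, l))
  lapply(seq_len(n), function(i) X[((i - 1L) * l + 1L):(i * l), , drop = FALSE])
}

#' Pearson FC of one window between two channel subsets
#'
#' @param window l x k matrix.
#' @param rows,cols channel indices or names (default: all channels).
#' @return |rows| x |cols| matrix of Pearson correlations over the window.
#' @export
window_fc <- function(window, rows = NULL, cols = NULL) {
  W <- as.matrix(window)
  rows <- rows %||% seq_len(ncol(W))
  cols <- cols %||% seq_len(ncol(W))
  involved <- unique(c(rows, cols))
  sds <- apply(W[, involved, drop = FALSE], 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- involved[which(sds == 0)[1L]]
    stop("zero-variance channel ", bad, " within window")
  }
  stats::cor(W[, rows, drop = FALSE], W[, cols, drop = FALSE])
}

# Fisher z-transform clipped away from |r| = 1.
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

# Variability of a sequence of vectorized window-FC patterns (rows of E):
# 1 - mean Pearson correlation over distinct window pairs.
pattern_variability <- function(E, fisher = FALSE) {
  if (fisher) E <- fisher_z(E)
  v <- .pattern_variability_cpp(E, list(seq_len(ncol(E))))
  if (is.na(v))
    stop("window-pair correlation undefined (constant FC pattern in a window)")
  v
}

# Window-FC pattern rows for a single l: one row per window.
fc_pattern_rows <- function(X, l, extract) {
  wins <- segment_windows(X, l)
  t(vapply(seq_along(wins), function(i) {
    W <- wins[[i]]
    sds <- apply(W, 2L, stats::sd)
    if (any(sds == 0))
      stop(sprintf("zero-variance channel %d within window %d (length %d)",
                   which(sds == 0)[1L], i, l))
    extract(stats::cor(W))
  }, extract(diag(ncol(X)))))
}

#' Within-network temporal variability
#'
#' For each window length l: the series is cut into non-overlapping windows,
#' the within-network FC (strict upper triangle of the k x k Pearson matrix
#' over the network's channels) is vectorized per window, and
#' `V_l = 1 - mean` over distinct window pairs of the Pearson correlation
#' between the two FC vectors. The returned value is the mean of V_l over
#' the window lengths (default 20, 22, ..., 40).
#'
#' @param series T x N matrix or [parcellated_ts()].
#' @param channels indices or names of the network's channels (>= 2).
#' @param lengths window lengths (each must satisfy T >= 2l).
#' @param fisher apply a Fisher z-transform to FC values before pattern
#'   correlation (off by default).
#' @return a value in [0, 2].
#' @export
within_network_variability <- function(series, channels,
                                       lengths = seq(20, 40, by = 2),
                                       fisher = FALSE) {
  X <- as_series_matrix(series)
  if (is.character(channels)) channels <- match(channels, colnames(X))
  if (length(channels) < 2L) stop("network must have at least 2 channels")
  Xs <- X[, channels, drop = FALSE]
  k <- ncol(Xs)
  ut <- which(upper.tri(diag(k)))
  vl <- vapply(lengths, function(l) {
    E <- fc_pattern_rows(Xs, l, function(F) F[ut])
    pattern_variability(E, fisher)
  }, numeric(1L))
  mean(vl)
}

#' Between-network temporal variability
#'
#' Same construction as [within_network_variability()], using the full
#' vectorized cross-block (|a| x |b| Pearson correlations between the two
#' networks' channels) as the per-window FC pattern.
#'
#' @inheritParams within_network_variability
#' @param channels_a,channels_b channel indices or names of the two
#'   networks; the cross-block must have at least 2 entries.
#' @return a value in [0, 2].
#' @export
between_network_variability <- function(series, channels_a, channels_b,
                                        lengths = seq(20, 40, by = 2),
                                        fisher = FALSE) {
  X <- as_series_matrix(series)
  if (is.character(channels_a)) channels_a <- match(channels_a, colnames(X))
  if (is.character(channels_b)) channels_b <- match(channels_b, colnames(X))
  if (length(channels_a) < 1L || length(channels_b) < 1L)
    stop("both networks need at least one channel")
  if (length(channels_a) * length(channels_b) < 2L)
    stop("cross-block must have at least 2 entries")
  na <- length(channels_a)
  cols <- c(channels_a, channels_b)
  vl <- vapply(lengths, function(l) {
    E <- fc_pattern_rows(X[, cols, drop = FALSE], l, function(F)
      as.numeric(F[seq_len(na), na + seq_along(channels_b), drop = FALSE]))
    pattern_variability(E, fisher)
  }, numeric(1L))
  mean(vl)
}

#' Within- and between-network variability profile of one subject
#'
#' Computes all M within-network values and all M(M-1)/2 between-network
#' values (M = 17 networks gives 136 pairs) efficiently by vectorizing each
#' window's full FC matrix once per window length.
#'
#' @param series T x N matrix or [parcellated_ts()].
#' @param map [network_map()] covering the series' channels.
#' @inheritParams within_network_variability
#' @return object of class `variability_profile`: `subject_id`, `within`
#'   (named length-M vector), `between` (M x M symmetric matrix, NA
#'   diagonal), `between_pairs` (data.frame network_a, network_b, value).
#' @export
variability_profile <- function(series, map, lengths = seq(20, 40, by = 2),
                                fisher = FALSE) {
  X <- as_series_matrix(series)
  subject_id <- if (inherits(series, "parcellated_ts")) series$subject_id
    else NA_character_
  labels <- colnames(X) %||% map$channels
  if (!all(labels %in% map$channels))
    stop("series has channels absent from the network map")
  net <- unname(map$network_of[labels])
  M <- length(map$network_names)
  N <- ncol(X)
  up <- upper_pairs(N)
  net_i <- net[up$i]
  net_j <- net[up$j]
  # per-feature entry index sets into the vectorized upper triangle
  idx <- list()
  feat <- character(0L)
  for (m in map$network_names) {
    sel <- which(net_i == m & net_j == m)
    if (length(sel) < 1L)
      stop("network ", m, " has fewer than 2 channels")
    idx[[length(idx) + 1L]] <- sel
    feat <- c(feat, paste0("within_", m))
  }
  pair_a <- character(0L)
  pair_b <- character(0L)
  for (a in seq_len(M - 1L)) for (b in (a + 1L):M) {
    na_ <- map$network_names[a]
    nb_ <- map$network_names[b]
    sel <- which((net_i == na_ & net_j == nb_) | (net_i == nb_ & net_j == na_))
    if (length(sel) < 2L) stop("cross-block ", na_, "/", nb_, " has fewer than 2 entries")
    idx[[length(idx) + 1L]] <- sel
    feat <- c(feat, paste0("between_", na_, "__", nb_))
    pair_a <- c(pair_a, na_)
    pair_b <- c(pair_b, nb_)
  }
  acc <- numeric(length(idx))
  for (l in lengths) {
    if (l < 3) stop("window length must be at least 3")
    if (floor(nrow(X) / l) < 2L)
      stop(sprintf("insufficient windows: T=%d gives %d window(s) of length %d",
                   nrow(X), floor(nrow(X) / l), l))
    E <- .window_fc_rows_cpp(X, as.integer(l))
    if (fisher) E <- fisher_z(E)
    v <- .pattern_variability_cpp(E, idx)
    if (anyNA(v))
      stop("window-pair correlation undefined (constant FC pattern) for feature ",
           feat[which(is.na(v))[1L]], " at window length ", l)
    acc <- acc + v
  }
  vals <- acc / length(lengths)
  within <- stats::setNames(vals[seq_len(M)], map$network_names)
  bet <- matrix(NA_real_, M, M,
                dimnames = list(map$network_names, map$network_names))
  bv <- vals[-seq_len(M)]
  for (p in seq_along(bv)) {
    bet[pair_a[p], pair_b[p]] <- bv[p]
    bet[pair_b[p], pair_a[p]] <- bv[p]
  }
  structure(list(subject_id = subject_id, within = within, between = bet,
                 between_pairs = data.frame(network_a = pair_a,
                                            network_b = pair_b,
                                            value = bv,
                                            stringsAsFactors = FALSE)),
            class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, ...) {
  cat(sprintf("variability_profile: subject %s, %d within + %d between values\n",
              x$subject_id, length(x$within), nrow(x$between_pairs)))
  invisible(x)
}

#' Cohort variability feature table
#'
#' @param ts_list list of [parcellated_ts()].
#' @param map [network_map()].
#' @inheritParams within_network_variability
#' @return data.frame: `subject_id`, `within_<net>` columns, then
#'   `between_<netA>__<netB>` columns.
#' @export
cohort_variability <- function(ts_list, map, lengths = seq(20, 40, by = 2),
                               fisher = FALSE) {
  rows <- lapply(ts_list, function(ts) {
    vp <- variability_profile(ts, map, lengths, fisher)
    vals <- c(stats::setNames(as.numeric(vp$within),
                              paste0("within_", names(vp$within))),
              stats::setNames(vp$between_pairs$value,
                              paste0("between_", vp$between_pairs$network_a,
                                     "__", vp$between_pairs$network_b)))
    cbind(data.frame(subject_id = ts$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
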