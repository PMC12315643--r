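# State characterization: mean-activation profiles relative to the grand
# mean, and the strongest positive FC edges of each state.

#' Mean-activation profile of a state
#'
#' Returns the state mean minus the weighted grand mean across states, i.e.
#' the relative loading of each channel with respect to the overall mean
#' activation. Weights default to equal; pass cohort fractional occupancies
#' for an occupancy-weighted reference.
#'
#' @param model [hmm_model()].
#' @param k state index.
#' @param weights length-K non-negative weights for the grand mean
#'   (normalized internally); default equal.
#' @return numeric length-N vector (named if the model carries labels).
#' @export
state_mean_profile <- function(model, k, weights = NULL) {
  stopifnot(inherits(model, "hmm_model"))
  if (k < 1 || k > model$K) stop("state index out of range")
  if (is.null(weights)) weights <- rep(1, model$K)
  if (length(weights) != model$K || any(weights < 0) || sum(weights) == 0)
    stop("weights must be K non-negative values")
  w <- weights / sum(weights)
  grand <- colSums(w * model$means)
  out <- model$means[k, ] - grand
  if (!is.null(model$channel_labels)) names(out) <- model$channel_labels
  out
}

#' Strongest positive FC edges of a state
#'
#' Converts the state covariance to a correlation matrix and retains, among
#' the strictly positive off-diagonal upper-triangle entries, the
#' `ceiling(fraction * count)` largest (default: top 5% of positive FC).
#' Ties are broken deterministically by (i, j) lexicographic order.
#'
#' @param model [hmm_model()].
#' @param k state index.
#' @param fraction fraction of the positive edges to retain, in (0, 1].
#' @return data.frame with columns `i`, `j`, `channel_i`, `channel_j`,
#'   `weight`, sorted by decreasing weight. Zero rows (with a warning) when
#'   no positive edges exist.
#' @export
top_positive_fc <- function(model, k, fraction = 0.05) {
  stopifnot(inherits(model, "hmm_model"))
  if (k < 1 || k > model$K) stop("state index out of range")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  fc <- stats::cov2cor(model$covs[[k]])
  up <- upper_pairs(ncol(fc))
  w <- fc[up$linear]
  pos <- which(w > 0)
  labels <- model$channel_labels %||% paste0("ch", seq_len(ncol(fc)))
  if (length(pos) == 0L) {
    warning("state ", k, " has no positive off-diagonal FC entries")
    return(data.frame(i = integer(0), j = integer(0),
                      channel_i = character(0), channel_j = character(0),
                      weight = numeric(0)))
  }
  n_keep <- ceiling(fraction * length(pos))
  ord <- pos[order(-w[pos], up$i[pos], up$j[pos])][seq_len(n_keep)]
  data.frame(i = up$i[ord], j = up$j[ord],
             channel_i = labels[up$i[ord]], channel_j = labels[up$j[ord]],
             weight = w[ord], stringsAsFactors = FALSE)
}

#' Full profile of one state
#'
#' @inheritParams top_positive_fc
#' @param weights passed to [state_mean_profile()].
#' @return object of class `state_profile`: `state`, `mean_activation`,
#'   `fc` (correlation matrix), `top_edges`.
#' @export
state_profile <- function(model, k, fraction = 0.05, weights = NULL) {
  structure(list(state = k,
                 mean_activation = state_mean_profile(model, k, weights),
                 fc = stats::cov2cor(model$covs[[k]]),
                 top_edges = top_positive_fc(model, k, fraction)),
            class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  cat(sprintf("state_profile: state %d, %d channels, %d retained edges\n",
              x$state, length(x$mean_activation), nrow(x$top_edges)))
  invisible(x)
}
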