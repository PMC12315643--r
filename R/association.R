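# Covariate-adjusted association testing of dynamics features against the
# phenotype score, with BH-FDR control per feature family and
# network-contribution aggregation of significant between-network effects.

#' Partial correlation with covariate adjustment
#'
#' Residualizes `x` and `y` on an intercept plus the covariates by ordinary
#' least squares and returns the Pearson correlation of the residuals. The
#' two-sided p-value comes from `t = r * sqrt(df / (1 - r^2))` with
#' `df = n - 2 - c` (c covariates).
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix/data.frame with one row per observation,
#'   or NULL for a plain Pearson correlation.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  c_ <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < c_ + 4L) stop("need at least c + 4 observations")
  if (c_ > 0L) {
    Z <- cbind(1, as.matrix(covariates))
    if (qr(Z)$rank < ncol(Z)) stop("covariate matrix is rank-deficient")
    rx <- stats::lsfit(Z, x, intercept = FALSE)$residuals
    ry <- stats::lsfit(Z, y, intercept = FALSE)$residuals
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero residual variance; partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2L - c_
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r = r, p = p, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement (via
#' `stats::p.adjust(method = "BH")`); order-preserving under permutation of
#' the input.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

feature_family <- function(feature) {
  ifelse(grepl("^fo_state", feature), "state_fo",
    ifelse(feature %in% c("max_fo", "sr"), "hmm_global",
      ifelse(grepl("^within_", feature), "within_net",
        ifelse(grepl("^between_", feature), "between_net", "other"))))
}

#' Association battery: every dynamics feature against the score
#'
#' Computes the partial correlation (controlling for sex, age and mean
#' framewise displacement) of each feature column with the phenotype score.
#' BH-FDR is applied separately within each feature family (state FO,
#' within-network, between-network, other); `max_fo` and `sr` are reported
#' at their raw p-values (`p_fdr` set equal to `p`), matching how those two
#' global metrics are conventionally reported.
#'
#' @param features data.frame with a `subject_id` column and numeric feature
#'   columns (e.g. from [cohort_dynamics()] and [cohort_variability()],
#'   merged by subject).
#' @param phenotypes `phenotype_table` with matching subjects.
#' @param alpha significance level (default 0.05).
#' @param covariates phenotype columns to adjust for.
#' @return data.frame of class `association_table`: `feature`, `family`,
#'   `r`, `p`, `p_fdr`, `significant`.
#' @export
run_association_battery <- function(features, phenotypes, alpha = 0.05,
                                    covariates = c("sex", "age", "mean_fd")) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  mismatch <- c(setdiff(features$subject_id, phenotypes$subject_id),
                setdiff(phenotypes$subject_id, features$subject_id))
  if (length(mismatch) > 0L)
    stop("subject mismatch between features and phenotypes: ",
         paste(unique(mismatch), collapse = ", "))
  ph <- phenotypes[match(features$subject_id, phenotypes$subject_id), ,
                   drop = FALSE]
  covmat <- as.matrix(ph[, covariates, drop = FALSE])
  feat_cols <- setdiff(names(features), "subject_id")
  res <- lapply(feat_cols, function(f) {
    pc <- partial_correlation(features[[f]], ph$score, covmat)
    data.frame(feature = f, family = feature_family(f), r = pc$r, p = pc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- out$p
  for (fam in setdiff(unique(out$family), "hmm_global")) {
    sel <- out$family == fam
    out$p_fdr[sel] <- bh_fdr(out$p[sel])
  }
  out$significant <- out$p_fdr <= alpha
  class(out) <- c("association_table", "data.frame")
  out
}

#' Aggregate significant between-network effects per network
#'
#' Each significant between-network pair's correlation coefficient is added
#' to both endpoint networks; networks are ranked by their cumulative r.
#'
#' @param results association table (needs the `between_net` family with
#'   feature names of the form `between_<netA>__<netB>`).
#' @param networks network names to tabulate; defaults to all networks
#'   appearing in the pair labels. Pass `map$network_names` to include
#'   networks with no significant pairs (cumulative r 0).
#' @return data.frame: `network`, `cumulative_r`, `n_pairs`, `rank`
#'   (1 = largest cumulative r), sorted by rank.
#' @export
network_contribution <- function(results, networks = NULL) {
  stopifnot(is.data.frame(results))
  bet <- results[results$family == "between_net", , drop = FALSE]
  labs <- sub("^between_", "", bet$feature)
  parts <- strsplit(labs, "__", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("unparseable between-network pair label: ",
         labs[which(lengths(parts) != 2L)[1L]])
  a <- vapply(parts, `[`, character(1L), 1L)
  b <- vapply(parts, `[`, character(1L), 2L)
  if (is.null(networks)) networks <- sort(unique(c(a, b)))
  cum <- stats::setNames(numeric(length(networks)), networks)
  npair <- stats::setNames(integer(length(networks)), networks)
  sig <- which(bet$significant)
  for (s in sig) {
    for (net in c(a[s], b[s])) {
      if (!net %in% networks) stop("network not in contribution table: ", net)
      cum[net] <- cum[net] + bet$r[s]
      npair[net] <- npair[net] + 1L
    }
  }
  out <- data.frame(network = networks, cumulative_r = unname(cum),
                    n_pairs = unname(npair), stringsAsFactors = FALSE)
  out$rank <- rank(-out$cumulative_r, ties.method = "min")
  out[order(out$rank, out$network), , drop = FALSE]
}
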