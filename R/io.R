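# Readers/writers and typed containers for every table the pipeline touches.

sep_char <- function(delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  if (delim == "tab") "\t" else ","
}

#' Construct a parcellated BOLD time-series object
#'
#' Container for one subject's T x N matrix of parcel/network signals with
#' time running down the rows. Signals are in arbitrary BOLD units; the
#' repetition time is carried as optional metadata only.
#'
#' @param data numeric T x N matrix, no missing values, T >= 2, N >= 2.
#' @param subject_id subject identifier (string).
#' @param channel_labels character vector of N unique channel names; taken
#'   from `colnames(data)` when omitted.
#' @param tr_seconds repetition time in seconds (optional metadata).
#' @return An object of class `parcellated_ts` with fields `subject_id`,
#'   `data`, `channel_labels`, `tr_seconds`.
#' @export
parcellated_ts <- function(data, subject_id, channel_labels = colnames(data),
                           tr_seconds = NA_real_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (nrow(data) < 2L) stop("time series must have at least 2 timepoints (rows)")
  if (ncol(data) < 2L) stop("time series must have at least 2 channels (columns)")
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("missing/non-finite value at row %d, column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(data))
    stop("channel_labels length does not match column count")
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique")
  if (!is.na(tr_seconds) && tr_seconds <= 0) stop("tr_seconds must be positive")
  dimnames(data) <- list(NULL, channel_labels)
  structure(list(subject_id = as.character(subject_id), data = data,
                 channel_labels = channel_labels, tr_seconds = tr_seconds),
            class = "parcellated_ts")
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("parcellated_ts: subject %s, %d timepoints x %d channels\n",
              x$subject_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Read one subject's parcellated time series
#'
#' Reads a delimited numeric table (header row = channel labels, rows =
#' timepoints in acquisition order) and validates it.
#'
#' @param path file path.
#' @param subject_id subject identifier attached to the object.
#' @param delim "tab" (default) or "comma".
#' @param tr_seconds optional repetition time metadata.
#' @return A [parcellated_ts()] object.
#' @export
read_timeseries <- function(path, subject_id, delim = c("tab", "comma"),
                            tr_seconds = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = sep_char(delim),
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) < 2L) stop("time series must have at least 2 timepoints (rows)")
  m <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    nonnum <- which(is.na(v) & !(trimws(df[[j]]) %in% c("NA", "NaN", "")))
    if (length(nonnum) > 0L)
      stop(sprintf("non-numeric entry at row %d, column %d ('%s')",
                   nonnum[1L], j, df[nonnum[1L], j]))
    m[, j] <- v
  }
  colnames(m) <- colnames(df)
  parcellated_ts(m, subject_id, tr_seconds = tr_seconds)
}

#' Write a parcellated time series to a delimited file
#'
#' Values are written with 15 significant digits so that write-then-read
#' round-trips losslessly for practical purposes.
#'
#' @param ts a [parcellated_ts()] object.
#' @param path output file path.
#' @param delim "tab" or "comma".
#' @export
write_timeseries <- function(ts, path, delim = c("tab", "comma")) {
  stopifnot(inherits(ts, "parcellated_ts"))
  ch <- matrix(sprintf("%.15g", ts$data), nrow(ts$data), ncol(ts$data))
  colnames(ch) <- ts$channel_labels
  utils::write.table(ch, path, sep = sep_char(delim), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Requires columns `subject_id`, `score`, `sex` (0/1), `age` (years) and
#' `mean_fd` (mm). By default rows with mean framewise displacement above
#' 0.2 mm are dropped (the conventional resting-state motion exclusion);
#' the number dropped is reported and stored in attribute `n_dropped`.
#'
#' @param path file path.
#' @param delim "tab" or "comma".
#' @param fd_threshold motion exclusion threshold in mm (default 0.2).
#' @param filter_fd apply the motion filter (default TRUE). Set FALSE to
#'   keep all rows.
#' @return data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path, delim = c("tab", "comma"),
                            fd_threshold = 0.2, filter_fd = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = sep_char(delim),
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_phenotype_table(df, fd_threshold = fd_threshold, filter_fd = filter_fd)
}

#' Validate a data.frame as a phenotype table
#'
#' @param df data.frame with the required phenotype columns.
#' @inheritParams read_phenotypes
#' @return data.frame of class `phenotype_table` with attribute `n_dropped`.
#' @export
as_phenotype_table <- function(df, fd_threshold = 0.2, filter_fd = TRUE) {
  required <- c("subject_id", "score", "sex", "age", "mean_fd")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  for (col in c("score", "sex", "age", "mean_fd")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]])) stop("missing value in required column ", col)
  }
  if (!all(df$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (any(df$mean_fd < 0)) stop("mean_fd must be non-negative")
  n_dropped <- 0L
  if (filter_fd) {
    keep <- df$mean_fd <= fd_threshold
    n_dropped <- sum(!keep)
    if (n_dropped > 0L)
      message(sprintf("dropped %d subject(s) with mean FD > %g mm",
                      n_dropped, fd_threshold))
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("phenotype_table", "data.frame")
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Construct a channel-to-network map
#'
#' @param channels character vector of channel labels.
#' @param networks character vector (same length) of network names; network
#'   order is first appearance.
#' @return object of class `network_map`: fields `channels`, `network_of`
#'   (named vector channel -> network) and `network_names`.
#' @export
network_map <- function(channels, networks) {
  channels <- as.character(channels)
  networks <- as.character(networks)
  if (length(channels) != length(networks))
    stop("channels and networks must have equal length")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  network_names <- unique(networks)
  if (length(network_names) < 2L) stop("need at least 2 networks")
  structure(list(channels = channels,
                 network_of = stats::setNames(networks, channels),
                 network_names = network_names),
            class = "network_map")
}

#' @export
print.network_map <- function(x, ...) {
  cat(sprintf("network_map: %d channels in %d networks\n",
              length(x$channels), length(x$network_names)))
  invisible(x)
}

#' Read a channel-to-network map from YAML
#'
#' The YAML file is a flat mapping `channel: network`.
#'
#' @param path YAML file path.
#' @return [network_map()] object.
#' @export
read_network_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.list(y) || is.null(names(y))) stop("network map YAML must be a mapping")
  network_map(names(y), unlist(y, use.names = FALSE))
}

#' Write a channel-to-network map to YAML
#' @param map [network_map()] object.
#' @param path output path.
#' @export
write_network_map <- function(map, path) {
  stopifnot(inherits(map, "network_map"))
  yaml::write_yaml(as.list(map$network_of), path)
  invisible(path)
}

#' Write an association result table
#'
#' Writes columns `feature`, `family`, `r`, `p`, `p_fdr`, `significant` with
#' numeric values at 15 significant digits, so write-then-read is the
#' identity up to floating-point formatting.
#'
#' @param results data.frame as returned by [run_association_battery()].
#' @param path output file path.
#' @param delim "tab" or "comma".
#' @export
write_association_table <- function(results, path, delim = c("tab", "comma")) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  required <- c("feature", "r", "p", "p_fdr", "significant")
  if (!all(required %in% names(results)))
    stop("results must have columns ", paste(required, collapse = ", "))
  out <- data.frame(
    feature = results$feature,
    family = if ("family" %in% names(results)) results$family else "other",
    r = sprintf("%.15g", results$r),
    p = sprintf("%.15g", results$p),
    p_fdr = sprintf("%.15g", results$p_fdr),
    significant = results$significant,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep_char(delim), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an association result table written by [write_association_table()]
#' @param path file path.
#' @param delim "tab" or "comma".
#' @return data.frame with typed columns.
#' @export
read_association_table <- function(path, delim = c("tab", "comma")) {
  df <- utils::read.table(path, header = TRUE, sep = sep_char(delim),
                          check.names = FALSE, stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  df
}

#' Align a list of time series with a phenotype table by subject ID
#'
#' Subjects present in only one of the two inputs are reported and dropped;
#' nothing is imputed.
#'
#' @param ts_list list of [parcellated_ts()] objects.
#' @param phenotypes `phenotype_table`.
#' @return list(ts_list, phenotypes) restricted to the common subjects, in
#'   phenotype-table order.
#' @export
align_subjects <- function(ts_list, phenotypes) {
  ids_ts <- vapply(ts_list, function(t) t$subject_id, character(1L))
  common <- intersect(phenotypes$subject_id, ids_ts)
  extra <- c(setdiff(ids_ts, common), setdiff(phenotypes$subject_id, common))
  if (length(extra) > 0L)
    message("excluding unmatched subject(s): ", paste(extra, collapse = ", "))
  if (length(common) == 0L) stop("no subjects in common")
  list(ts_list = ts_list[match(common, ids_ts)],
       phenotypes = {
         ph <- phenotypes[match(common, phenotypes$subject_id), , drop = FALSE]
         rownames(ph) <- NULL
         ph
       })
}
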