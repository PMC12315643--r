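# End-to-end orchestration: simulate -> fit-hmm -> profiles -> variability
# -> associate, with per-stage child seeds, cached intermediates and run
# metadata.

#' Pipeline run configuration
#'
#' Defaults reproduce the reference analysis settings: an 8-state HMM with
#' 10 restarts, non-overlapping windows of length 20-40 in steps of 2,
#' alpha = 0.05, and a 0.2 mm mean-FD exclusion threshold.
#'
#' @param cohort_dir directory with an existing cohort (see
#'   [write_cohort()]); NULL to simulate one.
#' @param simulate a [cohort_config()] used when `cohort_dir` is NULL.
#' @param n_states HMM state count K.
#' @param n_restarts EM restarts.
#' @param seed master seed; stages derive stable child seeds from it.
#' @param tol,max_iter EM settings (see [fit_hmm()]).
#' @param window_lengths variability window lengths.
#' @param alpha significance level.
#' @param fd_threshold motion exclusion threshold (mm).
#' @param top_fc_fraction fraction of positive FC edges kept per state.
#' @param posterior_fo use posterior-weighted FO (default hard-path).
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_dir = NULL, simulate = cohort_config(),
                       n_states = 8, n_restarts = 10, seed = 1,
                       tol = 1e-6, max_iter = 100,
                       window_lengths = seq(20, 40, by = 2), alpha = 0.05,
                       fd_threshold = 0.2, top_fc_fraction = 0.05,
                       posterior_fo = FALSE) {
  structure(list(cohort_dir = cohort_dir, simulate = simulate,
                 n_states = n_states, n_restarts = n_restarts, seed = seed,
                 tol = tol, max_iter = max_iter,
                 window_lengths = window_lengths, alpha = alpha,
                 fd_threshold = fd_threshold,
                 top_fc_fraction = top_fc_fraction,
                 posterior_fo = posterior_fo),
            class = "run_config")
}

serialize_model <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, init = model$init, trans = model$trans,
         means = model$means, covs = model$covs,
         channel_labels = model$channel_labels, loglik = model$loglik,
         restart_logliks = model$restart_logliks),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an HMM model serialized by the pipeline
#' @param path model.json path.
#' @return [hmm_model()] object.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- if (is.array(j$covs) && length(dim(j$covs)) == 3L)
    lapply(seq_len(dim(j$covs)[1L]), function(k) j$covs[k, , ])
  else lapply(j$covs, function(m) do.call(rbind, lapply(m, unlist)))
  m <- hmm_model(j$init, j$trans, j$means, covs,
                 channel_labels = j$channel_labels)
  m$loglik <- j$loglik
  m$restart_logliks <- j$restart_logliks
  m
}

write_tsv15 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's outputs into
#' `output_dir` so later stages (or re-runs of single stages) can read the
#' cached intermediates: `cohort/`, `model.json`, `metrics.tsv`,
#' `profiles/`, `variability.tsv`, `associations.tsv`, `contributions.tsv`,
#' `metadata.json`. Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param output_dir run directory (created if absent).
#' @param stages subset of
#'   `c("simulate", "fit-hmm", "profiles", "variability", "associate")`.
#' @return (invisibly) list with the in-memory stage results that were
#'   computed.
#' @export
run_pipeline <- function(config = run_config(), output_dir,
                         stages = c("simulate", "fit-hmm", "profiles",
                                    "variability", "associate")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "fit-hmm", "profiles", "variability", "associate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  counts <- list()
  cohort_dir <- config$cohort_dir %||% file.path(output_dir, "cohort")

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if ("simulate" %in% stages && is.null(config$cohort_dir)) {
    run_stage("simulate", {
      cohort <- simulate_cohort(config$simulate,
                                seed = stage_seed(config$seed, "simulate"))
      write_cohort(cohort, cohort_dir)
      results$cohort <- cohort
      counts$n_subjects_simulated <- length(cohort$timeseries)
    })
  }

  load_cohort <- function() {
    if (!is.null(results$cohort))
      return(list(timeseries = results$cohort$timeseries,
                  phenotypes = results$cohort$phenotypes,
                  network_map = results$cohort$network_map))
    read_cohort(cohort_dir, filter_fd = FALSE)
  }

  if ("fit-hmm" %in% stages) {
    run_stage("fit-hmm", {
      co <- load_cohort()
      netts <- lapply(co$timeseries, network_average, map = co$network_map)
      cc <- standardize_and_concatenate(netts)
      model <- fit_hmm(cc, K = config$n_states,
                       n_restarts = config$n_restarts,
                       seed = stage_seed(config$seed, "hmm"),
                       tol = config$tol, max_iter = config$max_iter)
      serialize_model(model, file.path(output_dir, "model.json"))
      write_tsv15(data.frame(restart = seq_along(model$restart_logliks),
                             loglik = model$restart_logliks),
                  file.path(output_dir, "restarts.tsv"))
      metrics <- cohort_dynamics(model, cc,
                                 posterior_fo = config$posterior_fo)
      write_tsv15(metrics, file.path(output_dir, "metrics.tsv"))
      results$model <- model
      results$metrics <- metrics
      counts$n_subjects_decoded <- nrow(metrics)
    })
  }

  get_model <- function() {
    results$model %||% read_model(file.path(output_dir, "model.json"))
  }

  if ("profiles" %in% stages) {
    run_stage("profiles", {
      model <- get_model()
      metrics <- results$metrics %||%
        utils::read.table(file.path(output_dir, "metrics.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
      fo_cols <- grep("^fo_state", names(metrics), value = TRUE)
      fo_weights <- colMeans(metrics[, fo_cols, drop = FALSE])
      pdir <- file.path(output_dir, "profiles")
      dir.create(pdir, showWarnings = FALSE)
      profs <- lapply(seq_len(model$K), function(k) {
        pr <- state_profile(model, k, fraction = config$top_fc_fraction,
                            weights = fo_weights)
        write_tsv15(data.frame(channel = model$channel_labels %||%
                                 seq_along(pr$mean_activation),
                               activation = as.numeric(pr$mean_activation)),
                    file.path(pdir, sprintf("state%02d_activation.tsv", k)))
        write_tsv15(pr$top_edges,
                    file.path(pdir, sprintf("state%02d_edges.tsv", k)))
        pr
      })
      results$profiles <- profs
      counts$n_states_profiled <- model$K
    })
  }

  if ("variability" %in% stages) {
    run_stage("variability", {
      co <- load_cohort()
      vt <- cohort_variability(co$timeseries, co$network_map,
                               lengths = config$window_lengths)
      write_tsv15(vt, file.path(output_dir, "variability.tsv"))
      results$variability <- vt
      counts$n_variability_features <- ncol(vt) - 1L
    })
  }

  if ("associate" %in% stages) {
    run_stage("associate", {
      co <- load_cohort()
      metrics <- results$metrics %||%
        utils::read.table(file.path(output_dir, "metrics.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
      vt <- results$variability %||%
        utils::read.table(file.path(output_dir, "variability.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
      features <- merge(metrics, vt, by = "subject_id", sort = FALSE)
      ph <- co$phenotypes
      keep <- ph$mean_fd <= config$fd_threshold
      if (any(!keep)) {
        message(sprintf("associate: excluding %d subject(s) with mean FD > %g mm",
                        sum(!keep), config$fd_threshold))
        ph <- ph[keep, , drop = FALSE]
        features <- features[features$subject_id %in% ph$subject_id, ,
                             drop = FALSE]
      }
      assoc <- run_association_battery(features, ph, alpha = config$alpha)
      write_association_table(assoc, file.path(output_dir, "associations.tsv"))
      contrib <- network_contribution(assoc, co$network_map$network_names)
      write_tsv15(contrib, file.path(output_dir, "contributions.tsv"))
      results$associations <- assoc
      results$contributions <- contrib
      counts$n_association_tests <- nrow(assoc)
      counts$n_significant <- sum(assoc$significant)
    })
  }

  cfg_plain <- unclass(config)
  cfg_plain$simulate <- unclass(cfg_plain$simulate)
  cfg_json <- as.character(jsonlite::toJSON(cfg_plain, auto_unbox = TRUE,
                                            digits = NA, null = "null"))
  jsonlite::write_json(
    list(config = cfg_plain, config_hash = fnv1a_hash(cfg_json),
         seed = config$seed, stages = stages, counts = counts,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("statedyn")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(output_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(results)
}
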