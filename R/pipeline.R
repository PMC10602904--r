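# End-to-end orchestration: synthetic cohort -> preprocessing -> coherence
# -> feature matrix -> feature ranking -> classification, from one config.

#' Default pipeline configuration
#'
#' @param synth named list of [synth_spec()] arguments (defaults used for
#'   the rest).
#' @param grid named list of [frequency_grid()] arguments.
#' @param lag_window_ms lag search window, ms.
#' @param aggregate trial aggregation mode for [cohort_coherence()].
#' @param ufs_method `"mi"` or `"loo_entropy"`.
#' @param tasks character vector of task names for [task_spec()].
#' @param feature_subsets subsets to run per task.
#' @param folds cross-validation folds.
#' @param holdout_fraction per-group hold-out fraction.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @return config list (class `pipeline_config`).
#' @export
pipeline_config <- function(synth = list(), grid = list(),
                            lag_window_ms = c(0, 1000),
                            aggregate = "mean",
                            ufs_method = "mi",
                            tasks = c("group_a_condition",
                                      "group_b_condition",
                                      "four_class", "direct_only_group"),
                            feature_subsets = "amplitude_and_time",
                            folds = 10, holdout_fraction = 0.2,
                            seed = 1L) {
  known <- c("synth", "grid", "lag_window_ms", "aggregate", "ufs_method",
             "tasks", "feature_subsets", "folds", "holdout_fraction",
             "seed")
  cfg <- list(synth = synth, grid = grid, lag_window_ms = lag_window_ms,
              aggregate = aggregate, ufs_method = ufs_method,
              tasks = tasks, feature_subsets = feature_subsets,
              folds = folds, holdout_fraction = holdout_fraction,
              seed = as.integer(seed))
  structure(cfg[known], class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are a schema error (raised before any compute).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' Run the full pipeline from a configuration
#'
#' Stages: synthetic cohort generation, preprocessing + trial-aggregated
#' coherence, region averaging, feature-matrix assembly, per-task feature
#' ranking, and the cross-validated classifier battery with participant
#' hold-out. Deterministic given `(config, seed)`. Stage outputs are
#' written under `out_dir` (resolved config, feature matrix CSV + sidecar,
#' ranking CSVs, accuracy summary CSV).
#'
#' @param config a `pipeline_config` (or YAML path).
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param progress print stage progress.
#' @return list with `cohort_meta`, `coherence`, `feature_matrix`,
#'   `rankings`, `classification` (from [run_tasks()]), `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         progress = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (progress) message(sprintf(...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir,
                                                "config_resolved.yaml"))
  }
  say("stage 1/5: synthetic cohort")
  spec <- do.call(synth_spec, c(config$synth,
                                list(seed = derive_seed(config$seed,
                                                        "synth"))))
  cohort <- make_cohort(spec)
  say("stage 2/5: preprocessing + coherence (%d instances)",
      nrow(cohort$meta))
  grid <- do.call(frequency_grid, config$grid)
  coh <- cohort_coherence(cohort, grid, config$lag_window_ms,
                          aggregate = config$aggregate,
                          progress = progress)
  say("stage 3/5: feature matrix")
  keys <- paste(cohort$meta$participant, cohort$meta$condition, sep = "_")
  specs <- lapply(keys, function(k) {
    sub <- coh[paste(coh$participant, coh$condition, sep = "_") == k, ]
    region_average(sub)
  })
  fm <- assemble(specs, cohort$meta)
  say("stage 4/5: feature ranking")
  rankings <- list()
  for (tk in config$tasks) {
    ts <- task_spec(tk)
    rows <- which(ts$select(fm$instances))
    labs <- ts$labels(fm$instances[rows, , drop = FALSE])
    fmz <- zscale(fm)            # global scaling for the descriptive ranking
    rankings[[tk]] <- ufs_rank(fmz$values[rows, , drop = FALSE],
                               labels = labs, method = config$ufs_method)
  }
  say("stage 5/5: classification battery")
  tasks <- list()
  for (tk in config$tasks) {
    for (fs in config$feature_subsets) {
      tasks[[length(tasks) + 1]] <- task_spec(tk, feature_subset = fs)
    }
  }
  cls <- run_tasks(fm, tasks, make_battery(), folds = config$folds,
                   seed = derive_seed(config$seed, "classify"),
                   holdout_fraction = config$holdout_fraction)
  if (!is.null(out_dir)) {
    write_feature_matrix(fm, file.path(out_dir, "feature_matrix.csv"))
    utils::write.csv(coh, file.path(out_dir, "coherence_long.csv"),
                     row.names = FALSE)
    for (tk in names(rankings)) {
      write_ranking_csv(rankings[[tk]],
                        file.path(out_dir, sprintf("ufs_%s.csv", tk)))
    }
    utils::write.csv(cls$summary, file.path(out_dir,
                                            "accuracy_summary.csv"),
                     row.names = FALSE)
  }
  res <- list(cohort_meta = cohort$meta, coherence = coh,
              feature_matrix = fm, rankings = rankings,
              classification = cls, config = config, out_dir = out_dir)
  if (!is.null(out_dir)) {
    writeLines(pipeline_report(res), file.path(out_dir, "report.md"))
  }
  res
}

#' Render a human-readable pipeline report
#'
#' Markdown summary: cohort and matrix shape, top-ranked features per task
#' (salience-table layout), and the accuracy table per task.
#'
#' @param run result of [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
pipeline_report <- function(run) {
  if (is.null(run$feature_matrix)) stopf("incomplete run: no feature matrix")
  fm <- run$feature_matrix
  out <- c("# Stimulus-brain coherence pipeline report", "",
           sprintf("- instances: %d (participants x conditions)",
                   nrow(fm$values)),
           sprintf("- features: %d (%s)", ncol(fm$values),
                   "regions x bins x {amplitude, time}"),
           sprintf("- seed: %d", run$config$seed), "")
  for (tk in names(run$rankings)) {
    top <- run$rankings[[tk]]$top
    out <- c(out, sprintf("## Top %d features - task %s", nrow(top), tk),
             "", "| rank | region | parameter | bin (Hz) | score |",
             "|-----:|--------|-----------|---------:|------:|",
             sprintf("| %d | %s | %s | %.1f | %.3f |", top$rank,
                     top$region, top$parameter, top$bin_center_hz,
                     top$score), "")
  }
  if (!is.null(run$classification)) {
    s <- run$classification$summary
    for (tk in unique(s$task)) {
      sub <- s[s$task == tk, ]
      out <- c(out, sprintf("## Accuracy - task %s", tk), "",
               "| algorithm | CV mean | CV sd | hold-out |",
               "|-----------|--------:|------:|---------:|",
               sprintf("| %s | %.3f | %.3f | %s |", sub$algorithm,
                       sub$cv_mean, sub$cv_sd,
                       ifelse(is.na(sub$holdout_acc), "-",
                              sprintf("%.3f", sub$holdout_acc))), "")
    }
  }
  out
}
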