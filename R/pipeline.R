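#' Read and validate a pipeline run configuration
#'
#' A YAML file with optional sections `data`, `preprocessing`, `features`,
#' `filter`, `forest`, `tree`, `evaluation` and a top-level `seed`. Unknown
#' keys are rejected so typos fail fast. Every value has the package default
#' when omitted, so an empty file is a valid configuration.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return Object of class `run_config` (nested list of validated sections).
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- list(
    seed = 1L,
    data = list(n_subjects_per_technique = 19L, n_timestamps = 600L,
                sample_rate = 60, class_shift = 5, hd_base_shift = 2,
                subject_sd = 1, noise_sd = 2, transient_len = 180L,
                transient_amp = 3, htbn_margin = 5,
                hd_extreme_fraction = 8 / 19, hd_extreme_shift = 6,
                ar1_phi = 0),
    preprocessing = list(window_mode = "fixed", window_start = 181L,
                         window_end = 420L, fraction_lo = 0.3,
                         fraction_hi = 0.7),
    features = list(max_features = "standard"),
    filter = list(mode = "designated", alpha = 0.05,
                  sidedness = "two_sided", correction = "none",
                  exclude_flagged = TRUE),
    forest = list(ntree = 500L, mtry = NULL, nodesize = 1L),
    tree = list(threshold_first = "auto", order = "greedy",
                terminal = "PC"),
    evaluation = list(train_fraction = 0.8, n_repetitions = 50L,
                      routed = FALSE))
  check_keys <- function(got, allowed, where) {
    extra <- setdiff(names(got), allowed)
    if (length(extra))
      stop_validation("unknown config key(s) in ", where, ": ",
                      paste(extra, collapse = ", "))
  }
  check_keys(raw, names(known), "top level")
  cfg <- known
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  for (sec in setdiff(names(known), "seed")) {
    if (is.null(raw[[sec]])) next
    check_keys(raw[[sec]], names(known[[sec]]), sec)
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  structure(cfg, class = "run_config")
}

config_window <- function(cfg) {
  p <- cfg$preprocessing
  window_spec(p$window_mode, p$window_start, p$window_end,
              p$fraction_lo, p$fraction_hi)
}

config_filters <- function(cfg) {
  switch(cfg$filter$mode,
         designated = designated_filter_variables(),
         auto = "auto",
         none = "none",
         stop_validation("filter mode must be designated, auto or none"))
}

#' Run the simulate/preprocess/train/evaluate/predict pipeline
#'
#' Executes the requested stages in order, writing each stage's artifact
#' under `out_dir`: `trials.csv` (simulate), `features.csv` (preprocess),
#' `model.json` plus `labels.csv` (train/predict on the full table) and
#' `report/` with `train_table.csv`, `test_table.csv`, `per_repetition.csv`
#' and per-node importance files (evaluate). A `provenance.json` records the
#' realised configuration and seed. Later stages read the artifacts of
#' earlier ones, so a stage can be re-run in isolation; a missing upstream
#' artifact raises an error naming the stage to run first.
#'
#' @param config a [read_run_config()] object (or `NULL` for defaults).
#' @param stages ordered subset of
#'   `c("simulate", "preprocess", "train", "evaluate", "predict")`.
#' @param out_dir artifact directory (created if needed).
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("simulate", "preprocess", "train",
                                    "evaluate", "predict"),
                         out_dir = ".") {
  if (is.null(config)) config <- read_run_config(NULL)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(trials = file.path(out_dir, "trials.csv"),
                features = file.path(out_dir, "features.csv"),
                model = file.path(out_dir, "model.json"),
                labels = file.path(out_dir, "labels.csv"),
                report = file.path(out_dir, "report"))
  need <- function(path, producer) {
    if (!file.exists(path))
      stop_data("missing artifact '", path, "': run the '", producer,
                "' stage first")
    path
  }
  written <- list()
  if ("simulate" %in% stages) {
    d <- config$data
    scfg <- synth_config(d$n_subjects_per_technique, d$n_timestamps,
                         d$sample_rate, d$class_shift, d$hd_base_shift,
                         d$subject_sd, d$noise_sd, d$transient_len,
                         d$transient_amp, d$htbn_margin,
                         d$hd_extreme_fraction, d$hd_extreme_shift,
                         d$ar1_phi, seed = config$seed)
    write_raw_trials(generate_dataset(scfg), paths$trials, "long")
    written$trials <- paths$trials
  }
  if ("preprocess" %in% stages) {
    trials <- read_raw_trials(need(paths$trials, "simulate"), "long",
                              config$data$sample_rate)
    tab <- build_feature_table(trials, config_window(config))
    if (identical(config$features$max_features, "standard"))
      tab <- add_max_features(tab, standard_max_features())
    write_feature_table(tab, paths$features)
    written$features <- paths$features
  }
  forest <- forest_control(config$forest$ntree, config$forest$mtry,
                           config$forest$nodesize)
  tree_args <- function(tab) {
    list(table = tab, threshold_first = config$tree$threshold_first,
         order = config$tree$order, filters = config_filters(config),
         forest = forest, alpha = config$filter$alpha,
         sidedness = config$filter$sidedness,
         correction = config$filter$correction,
         exclude_flagged = config$filter$exclude_flagged,
         terminal = config$tree$terminal)
  }
  if ("train" %in% stages) {
    tab <- read_feature_table(need(paths$features, "preprocess"))
    model <- do.call(build_tree, c(tree_args(tab), list(seed = config$seed)))
    save_model(model, paths$model)
    written$model <- paths$model
  }
  if ("evaluate" %in% stages) {
    tab <- read_feature_table(need(paths$features, "preprocess"))
    spec <- split_spec(config$evaluation$train_fraction,
                       config$evaluation$n_repetitions, config$seed)
    args <- tree_args(tab)
    args$table <- NULL
    evrep <- do.call(repeat_evaluation,
                   c(list(table = tab, spec = spec,
                          routed = config$evaluation$routed), args))
    dir.create(paths$report, showWarnings = FALSE)
    write.csv(evrep$train_summary, file.path(paths$report, "train_table.csv"),
              row.names = FALSE)
    write.csv(evrep$test_summary, file.path(paths$report, "test_table.csv"),
              row.names = FALSE)
    write.csv(evrep$per_repetition,
              file.path(paths$report, "per_repetition.csv"),
              row.names = FALSE)
    if (!is.null(evrep$last_model)) {
      for (i in seq_along(cascade_stages(evrep$last_model))) {
        if (!inherits(cascade_stages(evrep$last_model)[[i]], "cascade_node"))
          next
        write.csv(variable_importance(evrep$last_model, i),
                  file.path(paths$report,
                            sprintf("importance_node%d.csv", i)),
                  row.names = FALSE)
      }
    }
    written$report <- paths$report
  }
  if ("predict" %in% stages) {
    model <- load_model(need(paths$model, "train"))
    tab <- read_feature_table(need(paths$features, "preprocess"))
    det <- predict(model, tab, details = TRUE)
    write.csv(det, paths$labels, row.names = FALSE)
    written$labels <- paths$labels
  }
  jsonlite::write_json(list(package = "plankcascade",
                            version = as.character(utils::packageVersion("plankcascade")),
                            seed = config$seed,
                            stages = stages,
                            config = unclass(config)),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(written)
}
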