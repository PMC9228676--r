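#' Read raw IMU trials from CSV
#'
#' Two dialects are supported. `long`: columns `subject`, `technique`,
#' `timestamp`, `channel`, `value`, one measurement per row. `wide`: columns
#' `subject`, `technique`, `timestamp`, then the 60 canonical channel
#' columns. Rows are grouped by (subject, technique); within a trial,
#' timestamps are sorted ascending and re-indexed 1..T. Each trial must
#' cover all 60 channels with no gaps in its timestamp sequence.
#'
#' @param path CSV file path.
#' @param schema `"long"` or `"wide"`.
#' @param sample_rate samples per second recorded in each trial (default 60).
#' @return List of [raw_trial()] objects.
#' @seealso [write_raw_trials()]
#' @export
read_raw_trials <- function(path, schema = c("long", "wide"),
                            sample_rate = 60) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  chans <- plank_channels()
  need <- if (schema == "long")
    c("subject", "technique", "timestamp", "channel", "value")
  else c("subject", "technique", "timestamp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data("missing column(s) in ", schema, " CSV: ",
              paste(miss, collapse = ", "))
  check_technique(unique(df$technique))
  key <- paste(df$subject, df$technique, sep = "\r")
  trials <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    id <- paste0(g$subject[1], "/", g$technique[1])
    if (schema == "long") {
      got <- unique(g$channel)
      if (!setequal(got, chans))
        stop_data("trial ", id, ": expected 60 channels, found ",
                  length(intersect(got, chans)),
                  if (length(setdiff(got, chans)))
                    paste0(" (unknown: ",
                           paste(head(setdiff(got, chans), 3), collapse = ", "),
                           ")") else "")
      ts <- sort(unique(g$timestamp))
      if (nrow(g) != length(ts) * length(chans))
        stop_data("trial ", id, ": incomplete timestamp x channel grid")
      m <- matrix(NA_real_, length(ts), length(chans),
                  dimnames = list(NULL, chans))
      m[cbind(match(g$timestamp, ts), match(g$channel, chans))] <- g$value
    } else {
      cmiss <- setdiff(chans, names(g))
      if (length(cmiss))
        stop_data("trial ", id, ": missing channel column(s): ",
                  paste(head(cmiss, 3), collapse = ", "),
                  if (length(cmiss) > 3) ", ..." else "")
      g <- g[order(g$timestamp), , drop = FALSE]
      ts <- g$timestamp
      if (anyDuplicated(ts))
        stop_data("trial ", id, ": duplicated timestamps")
      m <- as.matrix(g[, chans, drop = FALSE])
      rownames(m) <- NULL
    }
    if (any(diff(ts) != diff(ts)[1]) || anyNA(m))
      stop_data("trial ", id, ": gaps in timestamp sequence")
    raw_trial(g$subject[1], g$technique[1], m, sample_rate)
  })
  names(trials) <- NULL
  trials
}

#' Write raw trials to CSV
#'
#' @param trials list of [raw_trial()] objects.
#' @param path output CSV path.
#' @param schema `"long"` or `"wide"` (see [read_raw_trials()]).
#' @return `path`, invisibly.
#' @export
write_raw_trials <- function(trials, path, schema = c("long", "wide")) {
  schema <- match.arg(schema)
  chans <- plank_channels()
  blocks <- lapply(trials, function(tr) {
    T_ <- nrow(tr$samples)
    if (schema == "wide") {
      cbind(data.frame(subject = tr$subject_id, technique = tr$technique,
                       timestamp = seq_len(T_), stringsAsFactors = FALSE),
            as.data.frame(tr$samples, check.names = FALSE))
    } else {
      data.frame(subject = tr$subject_id, technique = tr$technique,
                 timestamp = rep(seq_len(T_), times = length(chans)),
                 channel = rep(chans, each = T_),
                 value = as.vector(tr$samples),
                 stringsAsFactors = FALSE)
    }
  })
  write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

#' Read and write feature tables as CSV
#'
#' The CSV starts with `subject` and `technique` columns followed by the
#' feature columns; engineered names such as `"max(Acc-X-S3, Acc-X-S4)"`
#' contain commas and are therefore quoted in the header and preserved
#' verbatim on read. Values round-trip at full double precision.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `read_feature_table()` returns the validated feature table;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- feature_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = c(subject = "character",
                                technique = "character"))
  if (nrow(df) == 0)  # header-only file: type the feature columns
    for (f in setdiff(names(df), c("subject", "technique")))
      df[[f]] <- numeric(0)
  feature_table(df)
}

#' Save and load fitted cascade models
#'
#' The model is stored as a single version-stamped JSON file embedding the
#' threshold node, each node's filter reference values and the full forest
#' ensembles as nested tree arrays. Numbers are written at full precision,
#' so a loaded model predicts identically to the saved one.
#'
#' @param model a [build_tree()] model.
#' @param path JSON file path.
#' @return `load_model()` returns the restored `plank_tree`; `save_model()`
#'   returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "plank_tree"))
    stop_validation("'model' must be a plank_tree")
  payload <- list(
    format = "plankcascade-model",
    version = MODEL_FORMAT_VERSION,
    terminal = model$terminal,
    technique_order = model$technique_order,
    feature_names = model$feature_names,
    params = model$params,
    seed = model$seed,
    root = if (!is.null(model$root)) unclass(model$root),
    nodes = lapply(model$nodes, function(n) {
      list(node_index = n$node_index, d1 = n$d1, d2_set = n$d2_set,
           filter = if (!is.null(n$filter)) unclass(n$filter),
           feature_names = n$feature_names,
           forest = serialize_forest(n$forest))
    }))
  # I(17) = 17 significant digits: doubles survive the decimal round trip
  # bit-exactly, so loaded models predict identically to saved ones
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

serialize_forest <- function(rf) {
  list(ntree = rf$ntree, mtry = rf$mtry, nodesize = rf$nodesize,
       classes = rf$classes, feature_names = rf$feature_names,
       importance = as.list(rf$importance),
       trees = lapply(rf$trees, lapply, as.vector))
}

deserialize_forest <- function(f) {
  trees <- lapply(f$trees, function(t)
    list(var = as.integer(unlist(t$var)), split = as.numeric(unlist(t$split)),
         left = as.integer(unlist(t$left)), right = as.integer(unlist(t$right)),
         pred = as.integer(unlist(t$pred))))
  structure(
    list(trees = trees, ntree = as.integer(f$ntree), mtry = as.integer(f$mtry),
         nodesize = as.integer(f$nodesize),
         classes = unlist(f$classes), feature_names = unlist(f$feature_names),
         importance = unlist(f$importance),
         oob_votes = NULL, oob_pred = NULL, oob_accuracy = NA_real_),
    class = "plank_rf")
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e)
      stop_data("not a readable model file (", conditionMessage(e), ")"))
  if (!identical(payload$format, "plankcascade-model"))
    stop_data("not a plankcascade model file: ", path)
  if (!identical(payload$version, MODEL_FORMAT_VERSION))
    stop_data("incompatible model format version '", payload$version,
              "' (this build reads '", MODEL_FORMAT_VERSION, "')")
  root <- if (!is.null(payload$root))
    structure(list(variable = payload$root$variable,
                   threshold = as.numeric(payload$root$threshold),
                   direction = payload$root$direction,
                   d1 = payload$root$d1),
              class = "threshold_node")
  nodes <- lapply(payload$nodes, function(n) {
    filt <- if (!is.null(n$filter))
      structure(list(node_index = n$filter$node_index,
                     variables = unlist(n$filter$variables),
                     reference_values = lapply(n$filter$reference_values,
                                               function(v) unlist(v)),
                     alpha = as.numeric(n$filter$alpha),
                     sidedness = n$filter$sidedness,
                     correction = n$filter$correction),
                class = "aberrance_filter")
    structure(list(node_index = as.integer(n$node_index), d1 = n$d1,
                   d2_set = unlist(n$d2_set), filter = filt,
                   forest = deserialize_forest(n$forest),
                   feature_names = unlist(n$feature_names)),
              class = "cascade_node")
  })
  params <- payload$params
  params$forest <- lapply(params$forest, function(x) x)
  structure(
    list(root = root, nodes = nodes, terminal = payload$terminal,
         technique_order = unlist(payload$technique_order),
         feature_names = unlist(payload$feature_names),
         params = params, seed = payload$seed,
         version = payload$version),
    class = "plank_tree")
}
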