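#' Construct a raw IMU trial
#'
#' A raw trial is one subject performing one plank technique for `T`
#' timestamps: a `T x 60` matrix whose columns follow the canonical channel
#' order of [plank_channels()]. Timestamps are 1-based, so the default
#' 10-second recording at 60 samples/s has rows `t = 1, ..., 600`.
#'
#' @param subject_id opaque subject identifier (coerced to character).
#' @param technique one of [plank_techniques()].
#' @param samples numeric matrix, timestamps by 60 channels. Column names, if
#'   present, must be the canonical channel names (any order is accepted and
#'   re-ordered); unnamed columns are taken to be in canonical order already.
#' @param sample_rate samples per second (default 60).
#' @return An object of class `raw_trial`.
#' @examples
#' tr <- raw_trial("S01", "PC", matrix(0, 600, 60))
#' dim(tr$samples)
#' @export
raw_trial <- function(subject_id, technique, samples, sample_rate = 60) {
  check_technique(technique)
  samples <- as.matrix(samples)
  chans <- plank_channels()
  if (ncol(samples) != length(chans))
    stop_data("trial ", subject_id, "/", technique, ": expected ",
              length(chans), " channels, got ", ncol(samples))
  if (!is.null(colnames(samples))) {
    if (!setequal(colnames(samples), chans))
      stop_data("trial ", subject_id, "/", technique,
                ": channel names do not match the canonical 60 channels")
    samples <- samples[, chans, drop = FALSE]
  } else {
    colnames(samples) <- chans
  }
  if (anyNA(samples))
    stop_data("trial ", subject_id, "/", technique,
              ": missing values in samples")
  structure(
    list(subject_id = as.character(subject_id),
         technique = technique,
         samples = samples,
         sample_rate = sample_rate),
    class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> subject %s, technique %s (%s), %d timestamps x %d channels @ %g Hz\n",
              x$subject_id, x$technique,
              technique_descriptions()[x$technique],
              nrow(x$samples), ncol(x$samples), x$sample_rate))
  invisible(x)
}

#' Assemble or validate a feature table
#'
#' A feature table holds one row per (subject, technique) pair: the first two
#' columns are `subject` and `technique`, followed by numeric feature columns
#' (the 60 stable-window channel means, plus any engineered `max(...)`
#' columns).
#'
#' @param df data frame with columns `subject`, `technique`, then numeric
#'   features.
#' @return The validated data frame (class `data.frame`).
#' @export
feature_table <- function(df) {
  if (!all(c("subject", "technique") %in% names(df)[1:2]))
    stop_data("feature table must start with columns 'subject', 'technique'")
  check_technique(df$technique)
  if (anyDuplicated(paste(df$subject, df$technique, sep = "\r")))
    stop_data("duplicate (subject, technique) rows in feature table")
  if (anyDuplicated(names(df)))
    stop_data("duplicate column names in feature table")
  feats <- names(df)[-(1:2)]
  for (f in feats)
    if (!is.numeric(df[[f]]))
      stop_data("feature column '", f, "' is not numeric")
  df
}

feature_names <- function(table) setdiff(names(table), c("subject", "technique"))

feature_matrix <- function(table, cols = feature_names(table)) {
  m <- as.matrix(table[, cols, drop = FALSE])
  rownames(m) <- NULL
  storage.mode(m) <- "double"
  m
}
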