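# Shared fixtures: all synthetic, generated in code at test time.

# small, fast world: few subjects, short trials, fractional window
tiny_config <- function(n = 4, T = 60, transient_len = 10L, ...) {
  synth_config(n_subjects_per_technique = n, n_timestamps = T,
               transient_len = transient_len, seed = 42L, ...)
}

tiny_window <- function() window_spec(mode = "fractional")

# cached small feature table used by several files (built once per run)
tiny_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- add_max_features(
        build_feature_table(generate_dataset(tiny_config()), tiny_window()))
    cache
  }
})

# small forests keep tree-building tests fast
fast_forest <- function(ntree = 60L) forest_control(ntree = ntree)

# independent counting oracle for empirical tail p-values
oracle_p_value <- function(x, ref, sidedness, correction) {
  m <- length(ref)
  nle <- 0; nge <- 0
  for (v in ref) {
    if (v <= x) nle <- nle + 1
    if (v >= x) nge <- nge + 1
  }
  if (correction == "add_one") {
    pl <- (nle + 1) / (m + 1); pr <- (nge + 1) / (m + 1)
  } else {
    pl <- nle / m; pr <- nge / m
  }
  if (sidedness == "left") return(min(1, pl))
  if (sidedness == "right") return(min(1, pr))
  min(1, 2 * min(pl, pr))
}

# independent loop re-implementation of the cascade traversal
oracle_traverse <- function(model, row) {
  if (!is.null(model$root)) {
    v <- row[[model$root$variable]]
    hit <- if (model$root$direction == "below_is_d1")
      v < model$root$threshold else v > model$root$threshold
    if (hit) return(model$root$d1)
  }
  for (node in model$nodes) {
    flagged <- FALSE
    if (!is.null(node$filter)) {
      for (fv in node$filter$variables) {
        val <- row[[fv]]
        if (is.null(val)) {  # derive max(A, B) from base channels
          m <- regmatches(fv, regexec("^max\\((.+), (.+)\\)$", fv))[[1]]
          val <- max(row[[m[2]]], row[[m[3]]])
        }
        p <- oracle_p_value(val, node$filter$reference_values[[fv]],
                            node$filter$sidedness, node$filter$correction)
        if (p < node$filter$alpha) { flagged <- TRUE; break }
      }
    }
    if (flagged) return(node$d1)
    x <- matrix(NA_real_, 1, length(node$feature_names),
                dimnames = list(NULL, node$feature_names))
    for (fn in node$feature_names) {
      val <- row[[fn]]
      if (is.null(val)) {
        m <- regmatches(fn, regexec("^max\\((.+), (.+)\\)$", fn))[[1]]
        val <- max(row[[m[2]]], row[[m[3]]])
      }
      x[1, fn] <- val
    }
    if (predict(node$forest, x) == node$d1) return(node$d1)
  }
  model$terminal
}
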