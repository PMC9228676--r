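#' Stable-window specification
#'
#' IMU plank trials settle into a steady hold in the middle of the recording;
#' features are the per-channel means over that stable window. In `fixed`
#' mode the window is the closed timestamp interval `[start, end]` (1-based,
#' both inclusive); the default `[181, 420]` covers the 4th to 7th second of
#' a 10-second, 60 Hz trial and averages exactly 240 timestamps. `fractional`
#' mode generalises to other trial lengths: the realised window is
#' `[floor(fraction_lo * T) + 1, floor(fraction_hi * T)]`, which reproduces
#' `[181, 420]` at `T = 600` with the default fractions 0.3 and 0.7.
#'
#' @param mode `"fixed"` or `"fractional"`.
#' @param start,end fixed-mode window endpoints, timestamps (inclusive).
#' @param fraction_lo,fraction_hi fractional-mode bounds in `[0, 1]`.
#' @return An object of class `window_spec`.
#' @examples
#' window_bounds(window_spec(), 600)                      # 181 420
#' window_bounds(window_spec(mode = "fractional"), 100)   # 31 70
#' @export
window_spec <- function(mode = c("fixed", "fractional"),
                        start = 181L, end = 420L,
                        fraction_lo = 0.3, fraction_hi = 0.7) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (start < 1 || end < start)
      stop_validation("fixed window requires 1 <= start <= end")
  } else {
    if (fraction_lo < 0 || fraction_hi > 1 || fraction_lo >= fraction_hi)
      stop_validation("fractional window requires 0 <= fraction_lo < fraction_hi <= 1")
  }
  structure(list(mode = mode, start = as.integer(start), end = as.integer(end),
                 fraction_lo = fraction_lo, fraction_hi = fraction_hi),
            class = "window_spec")
}

#' @rdname window_spec
#' @param window a `window_spec`.
#' @param n_timestamps trial length `T`.
#' @return `window_bounds()` returns `c(start, end)` realised for a trial of
#'   length `n_timestamps`.
#' @export
window_bounds <- function(window, n_timestamps) {
  if (window$mode == "fixed") {
    b <- c(window$start, window$end)
  } else {
    b <- c(floor(window$fraction_lo * n_timestamps) + 1L,
           floor(window$fraction_hi * n_timestamps))
  }
  if (b[2] > n_timestamps)
    stop_validation("window [", b[1], ", ", b[2], "] exceeds trial length ",
                    n_timestamps)
  as.integer(b)
}

#' Stable-window channel means of one trial
#'
#' Averages each of the 60 channels over the stable window, reducing a
#' `T x 60` trial to a single 60-vector: component `j` is
#' `mean(samples[start:end, j])`, both endpoints inclusive.
#'
#' @param trial a [raw_trial()].
#' @param window a [window_spec()] (default: fixed `[181, 420]`).
#' @return Named numeric vector of length 60 (canonical channel order).
#' @examples
#' tr <- raw_trial("S01", "PC", matrix(rep(1:600, 60), 600, 60))
#' stable_window_mean(tr)[["Euler-X-S1"]]  # (181 + 420) / 2 = 300.5
#' @export
stable_window_mean <- function(trial, window = window_spec()) {
  if (!inherits(trial, "raw_trial"))
    stop_validation("'trial' must be a raw_trial")
  b <- tryCatch(window_bounds(window, nrow(trial$samples)),
                plank_validation_error = function(e)
                  stop_validation("trial ", trial$subject_id, "/",
                                  trial$technique, ": ", conditionMessage(e)))
  colMeans(trial$samples[b[1]:b[2], , drop = FALSE])
}

#' Build a feature table from raw trials
#'
#' One row per trial, 60 feature columns in canonical channel order, values
#' given by [stable_window_mean()]. For the study design this package
#' emulates (19 subjects, 600 timestamps) this reduces each technique's data
#' from 600 x 60 x 19 to 19 x 60.
#'
#' @param trials list of [raw_trial()] objects.
#' @param window a [window_spec()].
#' @return A [feature_table()] data frame with columns `subject`,
#'   `technique`, then the 60 channels.
#' @export
build_feature_table <- function(trials, window = window_spec()) {
  chans <- plank_channels()
  if (length(trials) == 0) {
    df <- cbind(data.frame(subject = character(0), technique = character(0),
                           stringsAsFactors = FALSE),
                as.data.frame(matrix(numeric(0), 0, length(chans),
                                     dimnames = list(NULL, chans)),
                              check.names = FALSE))
    return(feature_table(df))
  }
  rows <- t(vapply(trials, stable_window_mean, numeric(length(chans)),
                   window = window))
  df <- data.frame(subject = vapply(trials, function(tr) tr$subject_id, ""),
                   technique = vapply(trials, function(tr) tr$technique, ""),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df[chans] <- as.data.frame(rows, check.names = FALSE)
  feature_table(df)
}

#' Cross-sensor maximum feature specifications
#'
#' A max-feature takes the row-wise maximum of one base channel and each of
#' one or more partner channels that measure the same quantity on the same
#' axis at a different sensor, capturing relative relationships across
#' sensors (e.g. which of two body segments sits higher). The generated
#' column name is exactly `"max(<base>, <partner>)"`.
#'
#' @param base canonical channel name.
#' @param partners character vector of canonical channel names sharing
#'   measurement and axis with `base` but at different sensors.
#' @return An object of class `max_feature_spec`.
#' @examples
#' max_feature_spec("Acc-X-S3", c("Acc-X-S2", "Acc-X-S4", "Acc-X-S5"))
#' @export
max_feature_spec <- function(base, partners) {
  pb <- parse_channel(base)
  pp <- parse_channel(partners)
  if (any(pp$measurement != pb$measurement) || any(pp$axis != pb$axis))
    stop_validation("max-feature partners must share measurement and axis ",
                    "with base '", base, "'")
  if (any(pp$sensor == pb$sensor))
    stop_validation("max-feature partner sensor must differ from base '",
                    base, "'")
  structure(list(base = base, partners = partners), class = "max_feature_spec")
}

max_feature_name <- function(base, partner) {
  paste0("max(", base, ", ", partner, ")")
}

#' Append cross-sensor maximum features to a feature table
#'
#' For each spec and each of its partners, appends a column
#' `max(base, partner)` holding the row-wise maximum of the two channel
#' columns. Original columns are unchanged.
#'
#' @param table a [feature_table()].
#' @param specs list of [max_feature_spec()] objects (default: the standard
#'   nine of [standard_max_features()]).
#' @return The extended feature table.
#' @export
add_max_features <- function(table, specs = standard_max_features()) {
  table <- feature_table(table)
  if (inherits(specs, "max_feature_spec")) specs <- list(specs)
  for (spec in specs) {
    if (!inherits(spec, "max_feature_spec"))
      stop_validation("'specs' must be max_feature_spec objects")
    if (!spec$base %in% names(table))
      stop_data("base channel '", spec$base, "' not in table")
    for (p in spec$partners) {
      if (!p %in% names(table))
        stop_data("partner channel '", p, "' not in table")
      nm <- max_feature_name(spec$base, p)
      if (nm %in% names(table))
        stop_data("column '", nm, "' already exists")
      table[[nm]] <- pmax(table[[spec$base]], table[[p]])
    }
  }
  table
}

#' The standard engineered max-feature set
#'
#' The nine cross-sensor maxima used by the reference cascade: Euler-Z of the
#' wrist sensor S5 against each other sensor (hands-too-close detection), and
#' the S3 acceleration-X / magnetometer-Z maxima against neighbouring sensors
#' (hip-drop detection).
#'
#' @return List of three [max_feature_spec()] objects (9 columns when
#'   applied).
#' @export
standard_max_features <- function() {
  list(max_feature_spec("Euler-Z-S5",
                        c("Euler-Z-S1", "Euler-Z-S2", "Euler-Z-S3", "Euler-Z-S4")),
       max_feature_spec("Acc-X-S3", c("Acc-X-S2", "Acc-X-S4", "Acc-X-S5")),
       max_feature_spec("Mag-Z-S3", c("Mag-Z-S2", "Mag-Z-S4")))
}

# recompute any missing "max(A, B)" columns from their base channels
ensure_features <- function(table, wanted) {
  missing <- setdiff(wanted, names(table))
  for (nm in missing) {
    m <- regmatches(nm, regexec("^max\\((.+), (.+)\\)$", nm))[[1]]
    if (length(m) == 3 && all(m[2:3] %in% names(table))) {
      table[[nm]] <- pmax(table[[m[2]]], table[[m[3]]])
    } else {
      stop_data("missing feature(s) not derivable from base channels: ",
                paste(setdiff(wanted, names(table)), collapse = ", "))
    }
  }
  table
}
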