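#' @useDynLib plankcascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

CHANNEL_MEASUREMENTS <- c("Euler", "Acc", "Gyr", "Mag")
CHANNEL_AXES <- c("X", "Y", "Z")
CHANNEL_SENSORS <- c("S1", "S2", "S3", "S4", "S5")

#' Canonical IMU channel names
#'
#' Each of five body-worn sensors reports four measurement types (Euler
#' orientation angles, acceleration, gyroscope, magnetometer) on three axes,
#' giving 60 channels. The canonical string form is
#' `"Measurement-Axis-Sensor"`, e.g. `"Euler-Y-S1"`. The canonical column
#' order fixes sensor as the outer index (S1..S5), measurement in the middle
#' (Euler, Acc, Gyr, Mag) and axis innermost (X, Y, Z).
#'
#' @return Character vector of the 60 canonical channel names, in canonical
#'   order.
#' @examples
#' head(plank_channels(), 12)  # the twelve channels of sensor S1
#' @export
plank_channels <- function() {
  out <- character(0)
  for (s in CHANNEL_SENSORS)
    for (m in CHANNEL_MEASUREMENTS)
      out <- c(out, paste(m, CHANNEL_AXES, s, sep = "-"))
  out
}

#' Parse and format channel identifiers
#'
#' @param x character vector of channel names in `"Measurement-Axis-Sensor"`
#'   form.
#' @return `parse_channel()` returns a data frame with columns `measurement`,
#'   `axis`, `sensor`; `format_channel()` returns the canonical string form.
#'   `parse_channel(format_channel(...))` round-trips losslessly.
#' @examples
#' parse_channel("Euler-Y-S1")
#' format_channel("Mag", "Z", "S4")
#' @export
parse_channel <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  m <- vapply(parts, `[`, "", 1L)
  a <- vapply(parts, `[`, "", 2L)
  s <- vapply(parts, `[`, "", 3L)
  bad <- bad | !(m %in% CHANNEL_MEASUREMENTS) | !(a %in% CHANNEL_AXES) |
    !(s %in% CHANNEL_SENSORS)
  if (any(bad))
    stop_validation("invalid channel name(s): ",
                    paste(x[bad], collapse = ", "))
  data.frame(measurement = m, axis = a, sensor = s,
             stringsAsFactors = FALSE)
}

#' @rdname parse_channel
#' @param measurement one of `"Euler"`, `"Acc"`, `"Gyr"`, `"Mag"`.
#' @param axis one of `"X"`, `"Y"`, `"Z"`.
#' @param sensor one of `"S1"` .. `"S5"`.
#' @export
format_channel <- function(measurement, axis, sensor) {
  if (!all(measurement %in% CHANNEL_MEASUREMENTS) ||
      !all(axis %in% CHANNEL_AXES) || !all(sensor %in% CHANNEL_SENSORS))
    stop_validation("invalid channel component")
  paste(measurement, axis, sensor, sep = "-")
}

#' Plank technique labels
#'
#' Seven technique classes: `PC` is the unique acceptable plank; the other
#' six are named deviations from it.
#'
#' @return `plank_techniques()` returns the seven codes in canonical order;
#'   `technique_descriptions()` returns a named character vector mapping each
#'   code to its plain-language description.
#' @examples
#' plank_techniques()
#' technique_descriptions()["HD"]
#' @export
plank_techniques <- function() {
  c("PC", "HTFN", "HTBN", "HC", "HTB", "HD", "BC")
}

#' @rdname plank_techniques
#' @export
technique_descriptions <- function() {
  c(PC   = "acceptable plank",
    HTFN = "head tilted forward at the neck",
    HTBN = "head tilted back at the neck",
    HC   = "hands too close",
    HTB  = "pelvis tilted back",
    HD   = "hip dropped",
    BC   = "back convex")
}

check_technique <- function(x) {
  bad <- !(x %in% plank_techniques())
  if (any(bad))
    stop_data("unknown technique code(s): ",
              paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}

# classed conditions so the CLI can map error families to exit codes
stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("plank_validation_error", "plank_error",
                                "error", "condition")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("plank_data_error", "plank_error",
                                "error", "condition")))
}

stop_fit <- function(..., subclass = character(0)) {
  stop(errorCondition(paste0(...),
                      class = c(subclass, "plank_fit_error", "plank_error",
                                "error", "condition")))
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
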