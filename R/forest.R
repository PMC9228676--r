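#' Random-forest hyperparameters
#'
#' Defaults follow common random-forest practice: 500 trees, `sqrt(p)`
#' candidate features per split, nodes grown to purity (`nodesize = 1`).
#'
#' @param ntree number of trees.
#' @param mtry features tried at each split; `NULL` means
#'   `floor(sqrt(p))` at fit time.
#' @param nodesize minimum node size below which splitting stops.
#' @return An object of class `forest_control`.
#' @export
forest_control <- function(ntree = 500L, mtry = NULL, nodesize = 1L) {
  if (ntree < 1) stop_validation("ntree must be >= 1")
  if (!is.null(mtry) && mtry < 1) stop_validation("mtry must be >= 1")
  if (nodesize < 1) stop_validation("nodesize must be >= 1")
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 nodesize = as.integer(nodesize)),
            class = "forest_control")
}

#' Fit a binary random forest
#'
#' Bootstrap-aggregated CART trees with Gini splitting, grown on all
#' features with `mtry` candidates per split. Reproducible under
#' `set.seed()` (or the `seed` argument). Out-of-bag (OOB) votes are
#' retained as the internal accuracy estimate, and per-feature
#' mean-decrease-Gini importances are accumulated over splits.
#'
#' @param x numeric matrix or data frame of features (columns named).
#' @param y vector of labels with exactly two distinct values.
#' @param positive the label treated as the positive class (`y == positive`).
#' @param control a [forest_control()].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return Object of class `plank_rf` with elements `trees`, `classes`
#'   (negative, positive), `feature_names`, `importance` (named, mean
#'   decrease in Gini), `oob_votes`, `oob_pred`, `oob_accuracy`.
#' @examples
#' x <- cbind(a = c(rnorm(10), rnorm(10, 4)), b = rnorm(20))
#' y <- rep(c("no", "yes"), each = 10)
#' fit <- rf_fit(x, y, positive = "yes", control = forest_control(50), seed = 1)
#' fit$oob_accuracy
#' @export
rf_fit <- function(x, y, positive, control = forest_control(), seed = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    stop_validation("feature columns must be named")
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2)
    stop_fit("rf_fit requires exactly 2 classes, got ",
             length(classes))
  if (!positive %in% classes)
    stop_fit("positive class '", positive, "' absent from y")
  classes <- c(setdiff(classes, positive), positive)  # negative first
  yi <- as.integer(y == positive)
  mtry <- if (is.null(control$mtry)) max(1L, floor(sqrt(ncol(x)))) else control$mtry
  fit <- with_rng_seed(seed,
    rf_fit_cpp(x, yi, control$ntree, mtry, control$nodesize))
  oob_votes <- fit$oob_votes
  colnames(oob_votes) <- classes
  oob_pred <- ifelse(rowSums(oob_votes) == 0, NA_character_,
                     classes[(oob_votes[, 2] > oob_votes[, 1]) + 1L])
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(x)
  structure(
    list(trees = fit$trees, ntree = control$ntree, mtry = mtry,
         nodesize = control$nodesize, classes = classes,
         feature_names = colnames(x), importance = imp,
         oob_votes = oob_votes, oob_pred = oob_pred,
         oob_accuracy = mean(oob_pred == y, na.rm = TRUE)),
    class = "plank_rf")
}

#' Predict from a binary random forest
#'
#' Majority vote over the ensemble; vote ties go to the negative class.
#'
#' @param object a [rf_fit()] forest.
#' @param x feature matrix/data frame containing at least the columns the
#'   forest was fitted on.
#' @param type `"class"` for labels, `"votes"` for the per-class vote counts.
#' @param ... unused.
#' @return Character vector of labels, or an integer matrix of votes.
#' @export
predict.plank_rf <- function(object, x, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  if (is.data.frame(x)) {
    miss <- setdiff(object$feature_names, names(x))
    if (length(miss))
      stop_data("missing feature(s): ", paste(miss, collapse = ", "))
    x <- as.matrix(x[, object$feature_names, drop = FALSE])
  } else {
    x <- x[, object$feature_names, drop = FALSE]
  }
  storage.mode(x) <- "double"
  votes <- rf_votes_cpp(object$trees, x)
  colnames(votes) <- object$classes
  if (type == "votes") return(votes)
  object$classes[(votes[, 2] > votes[, 1]) + 1L]
}

#' @export
print.plank_rf <- function(x, ...) {
  cat(sprintf("<plank_rf> %d trees, mtry %d, classes [%s], OOB accuracy %.3f\n",
              x$ntree, x$mtry, paste(x$classes, collapse = " vs "),
              x$oob_accuracy))
  invisible(x)
}
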