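#' Empirical p-value of a value against a reference sample
#'
#' The aberrance filter judges how extreme an observation is relative to the
#' training values of the classes it is being separated from. With reference
#' sample `v_1, ..., v_m`, the left and right tail probabilities are, with
#' the add-one correction (the default here),
#' `p_left = (#\{v <= x\} + 1) / (m + 1)` and
#' `p_right = (#\{v >= x\} + 1) / (m + 1)`; two-sided combines them as
#' `min(1, 2 * min(p_left, p_right))`. Under `correction = "none"` the raw
#' empirical proportions `#\{v <= x\} / m` etc. are used instead, so a value
#' outside the reference range gets p = 0 — this uncorrected form is what
#' the cascade's filters use by default, since with small references (m = 15
#' at the final node under the standard design) the corrected two-sided
#' p-value can never drop below 2/(m+1) and the filter could flag nothing.
#'
#' @param x numeric vector of values to score.
#' @param reference numeric reference sample (length >= 2).
#' @param sidedness `"two_sided"` (default), `"left"`, or `"right"`.
#' @param correction `"add_one"` (default; p is never exactly 0) or
#'   `"none"` (raw empirical proportion; p can be 0).
#' @return Numeric vector of p-values in `[0, 1]` (in `(0, 1]` under
#'   `"add_one"`).
#' @examples
#' empirical_p_value(-10, 1:19)             # 2 * 1/20 = 0.1
#' empirical_p_value(100, 1:99, "right")    # 1/100
#' empirical_p_value(-10, 1:19, correction = "none")  # 0
#' @export
empirical_p_value <- function(x, reference,
                              sidedness = c("two_sided", "left", "right"),
                              correction = c("add_one", "none")) {
  sidedness <- match.arg(sidedness)
  correction <- match.arg(correction)
  if (length(reference) < 2)
    stop_validation("reference sample must have >= 2 values")
  m <- length(reference)
  nle <- vapply(x, function(xi) sum(reference <= xi), 0)
  nge <- vapply(x, function(xi) sum(reference >= xi), 0)
  if (correction == "add_one") {
    p_left <- (nle + 1) / (m + 1)
    p_right <- (nge + 1) / (m + 1)
  } else {
    p_left <- nle / m
    p_right <- nge / m
  }
  switch(sidedness,
         left = pmin(1, p_left),
         right = pmin(1, p_right),
         two_sided = pmin(1, 2 * pmin(p_left, p_right)))
}

#' Fit a univariate threshold node
#'
#' The root of the cascade: one technique (`d1`) that is perfectly separated
#' from all others on a single feature. The fitted threshold is the midpoint
#' between the two classes' nearest extremes — with `direction =
#' "below_is_d1"`, `(max over d1 + min over the rest) / 2`, which requires
#' `max(d1) < min(rest)` on the training data; fitting fails loudly
#' otherwise rather than fitting a bad threshold.
#'
#' @param table a [feature_table()].
#' @param d1 the technique separated at this node.
#' @param variable the feature name to threshold on.
#' @param direction `"below_is_d1"` (d1 lies below the threshold) or
#'   `"above_is_d1"`.
#' @return Object of class `threshold_node` with fields `variable`,
#'   `threshold`, `direction`, `d1`.
#' @examples
#' tab <- feature_table(data.frame(
#'   subject = c("a", "b", "c", "d"),
#'   technique = c("HTBN", "HTBN", "PC", "HD"),
#'   `Euler-Y-S1` = c(-60, -55, -40, -30), check.names = FALSE))
#' fit_threshold_node(tab, "HTBN", "Euler-Y-S1")$threshold  # -47.5
#' @export
fit_threshold_node <- function(table, d1, variable,
                               direction = c("below_is_d1", "above_is_d1")) {
  direction <- match.arg(direction)
  table <- feature_table(table)
  if (!variable %in% names(table))
    stop_data("variable '", variable, "' not in table")
  v1 <- table[[variable]][table$technique == d1]
  v2 <- table[[variable]][table$technique != d1]
  if (length(v1) == 0 || length(v2) == 0)
    stop_data("threshold node needs rows of '", d1, "' and at least one other class")
  if (direction == "below_is_d1") {
    if (max(v1) >= min(v2))
      stop_fit("classes not separated on '", variable, "': max(", d1, ") = ",
               max(v1), " >= min(rest) = ", min(v2),
               subclass = "plank_separability_error")
    threshold <- (max(v1) + min(v2)) / 2
  } else {
    if (min(v1) <= max(v2))
      stop_fit("classes not separated on '", variable, "': min(", d1, ") = ",
               min(v1), " <= max(rest) = ", max(v2),
               subclass = "plank_separability_error")
    threshold <- (min(v1) + max(v2)) / 2
  }
  structure(list(variable = variable, threshold = threshold,
                 direction = direction, d1 = d1),
            class = "threshold_node")
}

threshold_claims <- function(node, values) {
  if (node$direction == "below_is_d1") values < node$threshold
  else values > node$threshold
}

#' Fit an aberrance filter for one cascade node
#'
#' Stage one of the two-stage node procedure: store, for each filter
#' variable, the training values of the remaining classes (`d2_set`) as an
#' empirical reference distribution. At prediction time an observation is
#' flagged as extremely aberrant — and classified as `d1` without consulting
#' the forest — as soon as ANY filter variable's [empirical_p_value()] falls
#' below `alpha`.
#'
#' With `variables = "auto"`, every feature column is a candidate and a
#' candidate is retained iff, on the training table, it flags at least one
#' `d1` observation at level `alpha` while flagging at most
#' `floor(alpha * |d2|)` of the `d2` observations. Hand-picked variable
#' lists (see [designated_filter_variables()]) bypass the selection. If auto
#' selection retains nothing the node degrades to forest-only
#' (returns `NULL` with a notice).
#'
#' @param table training [feature_table()].
#' @param d1 technique separated at this node.
#' @param d2_set character vector of the remaining techniques.
#' @param variables `"auto"` or a character vector of feature names.
#' @param alpha significance level (default 0.05).
#' @param sidedness tail choice for [empirical_p_value()] (default
#'   two-sided).
#' @param correction p-value correction (default `"none"`; see
#'   [empirical_p_value()]).
#' @param node_index integer position of the node in the cascade (metadata).
#' @return Object of class `aberrance_filter`, or `NULL` if auto selection
#'   retains no variable.
#' @export
fit_filter <- function(table, d1, d2_set, variables = "auto", alpha = 0.05,
                       sidedness = "two_sided", correction = "none",
                       node_index = NA_integer_) {
  table <- feature_table(table)
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  d2_rows <- table$technique %in% d2_set
  d1_rows <- table$technique == d1
  if (sum(d2_rows) < 2)
    stop_data("filter needs >= 2 reference rows in d2_set")
  auto <- identical(variables, "auto")
  cand <- if (auto) feature_names(table) else variables
  miss <- setdiff(cand, names(table))
  if (length(miss))
    stop_data("filter variable(s) not in table: ", paste(miss, collapse = ", "))
  keep <- character(0)
  refs <- list()
  max_d2_flags <- floor(alpha * sum(d2_rows))
  for (v in cand) {
    ref <- table[[v]][d2_rows]
    if (auto) {
      d1_flags <- sum(empirical_p_value(table[[v]][d1_rows], ref,
                                        sidedness, correction) < alpha)
      d2_flags <- sum(empirical_p_value(ref, ref, sidedness, correction) < alpha)
      if (d1_flags < 1 || d2_flags > max_d2_flags) next
    }
    keep <- c(keep, v)
    refs[[v]] <- ref
  }
  if (length(keep) == 0) {
    if (auto)
      message("aberrance filter: auto selection retained no variable; ",
              "node degrades to forest-only")
    return(NULL)
  }
  structure(list(node_index = node_index, variables = keep,
                 reference_values = refs, alpha = alpha,
                 sidedness = sidedness, correction = correction),
            class = "aberrance_filter")
}

#' Apply an aberrance filter to observations
#'
#' @param filter an [fit_filter()] result (or `NULL`, which never flags).
#' @param rows a [feature_table()] (or any data frame containing the filter
#'   variables, possibly derivable `max(...)` columns).
#' @return Logical vector: `TRUE` where any filter variable's empirical
#'   p-value is below `alpha` ("classify as d1 now, skip the forest").
#' @export
apply_filter <- function(filter, rows) {
  if (is.null(filter)) return(rep(FALSE, nrow(rows)))
  rows <- ensure_features(rows, filter$variables)
  flagged <- rep(FALSE, nrow(rows))
  for (v in filter$variables) {
    p <- empirical_p_value(rows[[v]], filter$reference_values[[v]],
                           filter$sidedness, filter$correction)
    flagged <- flagged | (p < filter$alpha)
  }
  flagged
}

#' Fit one two-stage cascade node (filter + random forest)
#'
#' Fits the aberrance filter (per `filter_spec`) and a binary random forest
#' separating `d1` from the union of `d2_set`, using every available feature
#' column. Training rows flagged by the filter are by default excluded from
#' the forest's training sample: flagged extremes sit in regions that
#' complicate the decision boundary, and at prediction time they never reach
#' the forest anyway (the filter short-circuits). Set
#' `exclude_flagged = FALSE` to keep them.
#'
#' @param table training [feature_table()].
#' @param d1 technique separated at this node.
#' @param d2_set remaining techniques at this node.
#' @param filter_spec `"auto"`, `"none"`, or a character vector of filter
#'   variables.
#' @param forest a [forest_control()].
#' @param alpha,sidedness,correction passed to [fit_filter()].
#' @param exclude_flagged drop filter-flagged training rows before fitting
#'   the forest (default `TRUE`).
#' @param node_index integer position in the cascade (metadata).
#' @param seed optional integer seed.
#' @return Object of class `cascade_node` with fields `node_index`, `d1`,
#'   `d2_set`, `filter`, `forest`, `feature_names`, `train_flagged`.
#' @export
fit_node <- function(table, d1, d2_set, filter_spec = "auto",
                     forest = forest_control(), alpha = 0.05,
                     sidedness = "two_sided", correction = "none",
                     exclude_flagged = TRUE, node_index = NA_integer_,
                     seed = NULL) {
  table <- feature_table(table)
  counts <- base::table(factor(table$technique, levels = c(d1, d2_set)))
  if (any(counts == 0))
    stop_data("class(es) with zero rows at node: ",
              paste(names(counts)[counts == 0], collapse = ", "))
  rows <- table[table$technique %in% c(d1, d2_set), , drop = FALSE]
  with_rng_seed(seed, {
    filt <- if (identical(filter_spec, "none")) NULL
            else fit_filter(rows, d1, d2_set, variables = filter_spec,
                            alpha = alpha, sidedness = sidedness,
                            correction = correction, node_index = node_index)
    flagged <- apply_filter(filt, rows)
    forest_rows <- rep(TRUE, nrow(rows))
    if (exclude_flagged && any(flagged)) {
      kept <- rows[!flagged, , drop = FALSE]
      # keep the forest fittable: never let exclusion empty out a class
      if (any(kept$technique == d1) && any(kept$technique %in% d2_set))
        forest_rows <- !flagged
    }
    train <- rows[forest_rows, , drop = FALSE]
    fn <- feature_names(table)
    rf <- rf_fit(feature_matrix(train, fn),
                 ifelse(train$technique == d1, d1, "other"),
                 positive = d1, control = forest)
    structure(list(node_index = node_index, d1 = d1, d2_set = d2_set,
                   filter = filt, forest = rf, feature_names = fn,
                   train_flagged = flagged, forest_rows = forest_rows),
              class = "cascade_node")
  })
}

# node-level decision for each row of `rows`: does this node claim d1?
node_claims <- function(node, rows) {
  rows <- ensure_features(rows, node$feature_names)
  flagged <- apply_filter(node$filter, rows)
  claim <- flagged
  decided_by <- ifelse(flagged, "filter", "forest")
  if (any(!flagged)) {
    pred <- predict(node$forest, rows[!flagged, , drop = FALSE])
    claim[!flagged] <- pred == node$d1
  }
  list(claim = claim, decided_by = decided_by)
}

# two-stage training-accuracy score used to rank candidate node orders:
# flagged rows count as predicted d1, the rest by out-of-bag forest votes
node_order_score <- function(node, rows) {
  flagged <- node$train_flagged
  truth <- rows$technique == node$d1
  pred_d1 <- flagged
  # oob predictions exist only for the rows the forest trained on
  oob_for_row <- rep(NA_character_, nrow(rows))
  oob_for_row[which(node$forest_rows)] <- node$forest$oob_pred
  unflagged <- !flagged
  pred_d1[unflagged] <- !is.na(oob_for_row[unflagged]) &
    oob_for_row[unflagged] == node$d1
  mean(pred_d1 == truth)
}

#' Build the binary-tree cascade classifier
#'
#' Fits the full model: first a univariate [fit_threshold_node()] for the one
#' technique that a single feature separates perfectly; then a chain of
#' two-stage [fit_node()] models, each separating one deviation from the
#' shrinking remainder set; the acceptable technique (`PC`) is the terminal
#' leaf reached when every node has declined to claim an observation.
#'
#' With `threshold_first = "auto"` all (feature, class) pairs are scanned for
#' perfect univariate separation and the pair with the widest standardised
#' gap is used; if none separates, the tree is built entirely from two-stage
#' nodes (with a notice). With `order = "greedy"`, at each level every
#' remaining deviation is tried as the node's target and the candidate whose
#' two-stage node scores the highest training accuracy (out-of-bag for the
#' forest stage) is kept — ties go to canonical technique order. An explicit
#' `order` character vector skips the search.
#'
#' @param table training [feature_table()] (features already engineered; see
#'   [add_max_features()]).
#' @param threshold_first `"auto"`, `"none"`, or `list(variable=, d1=)`.
#' @param order `"greedy"` or an explicit character vector of deviations in
#'   separation order (excluding the threshold class and the terminal class).
#' @param filters `"auto"`, `"none"`, or a named list mapping technique codes
#'   to filter variable vectors (see [designated_filter_variables()]).
#' @param forest a [forest_control()].
#' @param alpha,sidedness,correction filter parameters (see [fit_filter()]).
#' @param exclude_flagged see [fit_node()].
#' @param terminal the acceptable technique forming the final leaf
#'   (default `"PC"`).
#' @param seed optional integer seed making the whole build reproducible.
#' @return Object of class `plank_tree`: fields `root` (threshold node or
#'   `NULL`), `nodes` (list of `cascade_node`), `terminal`,
#'   `technique_order`, `feature_names`, `params`, `version`.
#' @seealso [predict.plank_tree()], [repeat_evaluation()]
#' @export
build_tree <- function(table, threshold_first = "auto", order = "greedy",
                       filters = "auto", forest = forest_control(),
                       alpha = 0.05, sidedness = "two_sided",
                       correction = "none", exclude_flagged = TRUE,
                       terminal = "PC", seed = NULL) {
  table <- feature_table(table)
  classes <- intersect(plank_techniques(), unique(table$technique))
  if (length(classes) < 3)
    stop_data("cascade needs >= 3 classes, got ", length(classes))
  if (!terminal %in% classes)
    stop_data("terminal class '", terminal, "' absent from table")
  with_rng_seed(seed, {
    root <- NULL
    if (is.list(threshold_first)) {
      root <- fit_threshold_node(table, threshold_first$d1,
                                 threshold_first$variable,
                                 threshold_first$direction %||% "below_is_d1")
    } else if (identical(threshold_first, "auto")) {
      root <- scan_threshold_pair(table, setdiff(classes, terminal))
      if (is.null(root))
        message("no perfectly separating (feature, class) pair found; ",
                "building the tree from two-stage nodes only")
    }
    remaining <- setdiff(classes, root$d1)
    nodes <- list()
    filter_for <- function(d1) {
      if (is.list(filters)) filters[[d1]] %||% "none" else filters
    }
    idx <- length(nodes) + if (is.null(root)) 1L else 2L
    if (is.character(order) && !identical(order, "greedy")) {
      if (!setequal(c(order, terminal), remaining))
        stop_validation("explicit order must list every remaining deviation ",
                        "exactly once (terminal '", terminal, "' excluded)")
      for (d1 in order) {
        d2 <- setdiff(remaining, d1)
        nodes[[length(nodes) + 1L]] <-
          fit_node(table, d1, d2, filter_for(d1), forest, alpha, sidedness,
                   correction, exclude_flagged, node_index = idx)
        remaining <- d2
        idx <- idx + 1L
      }
    } else {
      while (length(remaining) > 1) {
        cand <- setdiff(remaining, terminal)
        if (length(cand) > 1) {
          fits <- lapply(cand, function(d1)
            fit_node(table, d1, setdiff(remaining, d1), filter_for(d1),
                     forest, alpha, sidedness, correction, exclude_flagged,
                     node_index = idx))
          rows <- table[table$technique %in% remaining, , drop = FALSE]
          scores <- vapply(fits, node_order_score, 0, rows = rows)
          best <- which.max(scores)  # ties: first, i.e. canonical order
          nodes[[length(nodes) + 1L]] <- fits[[best]]
          remaining <- setdiff(remaining, cand[best])
        } else {
          nodes[[length(nodes) + 1L]] <-
            fit_node(table, cand, setdiff(remaining, cand), filter_for(cand),
                     forest, alpha, sidedness, correction, exclude_flagged,
                     node_index = idx)
          remaining <- setdiff(remaining, cand)
        }
        idx <- idx + 1L
      }
    }
    structure(
      list(root = root, nodes = nodes, terminal = terminal,
           technique_order = c(if (!is.null(root)) root$d1,
                               vapply(nodes, function(n) n$d1, ""),
                               terminal),
           feature_names = feature_names(table),
           params = list(alpha = alpha, sidedness = sidedness,
                         correction = correction,
                         exclude_flagged = exclude_flagged,
                         forest = unclass(forest)),
           seed = seed, version = MODEL_FORMAT_VERSION),
      class = "plank_tree")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scan all (feature, class) pairs for perfect univariate separation; return
# the fitted threshold node with the widest gap in feature-SD units
scan_threshold_pair <- function(table, candidates) {
  best <- NULL
  best_score <- -Inf
  for (v in feature_names(table)) {
    s <- sd(table[[v]])
    if (!is.finite(s) || s == 0) next
    for (cl in candidates) {
      v1 <- table[[v]][table$technique == cl]
      v2 <- table[[v]][table$technique != cl]
      gap <- if (max(v1) < min(v2)) min(v2) - max(v1)
             else if (min(v1) > max(v2)) min(v1) - max(v2)
             else next
      dir <- if (max(v1) < min(v2)) "below_is_d1" else "above_is_d1"
      if (gap / s > best_score) {
        best_score <- gap / s
        best <- fit_threshold_node(table, cl, v, dir)
      }
    }
  }
  best
}

#' Predict plank techniques with a fitted cascade
#'
#' Traverses the binary tree: the root threshold test first; then at each
#' node the aberrance filter (a flag short-circuits to that node's
#' deviation), then the node's forest vote; an observation that every node
#' declines is labelled with the terminal acceptable technique.
#'
#' @param object a [build_tree()] model.
#' @param newdata a [feature_table()] or data frame holding the model's
#'   features (missing `max(...)` columns are recomputed from base
#'   channels).
#' @param details if `TRUE`, return a data frame with columns `subject`,
#'   `technique_predicted`, `decision_node`, `decided_by`
#'   (threshold/filter/forest/terminal).
#' @param ... unused.
#' @return Character vector of technique codes, or the details data frame.
#' @export
predict.plank_tree <- function(object, newdata, details = FALSE, ...) {
  newdata <- ensure_features(newdata, object$feature_names)
  n <- nrow(newdata)
  label <- rep(object$terminal, n)
  node_at <- rep(NA_integer_, n)
  by <- rep("terminal", n)
  undecided <- rep(TRUE, n)
  stage <- 1L
  if (!is.null(object$root)) {
    claim <- threshold_claims(object$root, newdata[[object$root$variable]])
    label[claim] <- object$root$d1
    node_at[claim] <- stage
    by[claim] <- "threshold"
    undecided <- !claim
    stage <- stage + 1L
  }
  for (node in object$nodes) {
    if (!any(undecided)) break
    res <- node_claims(node, newdata[undecided, , drop = FALSE])
    idx <- which(undecided)[res$claim]
    label[idx] <- node$d1
    node_at[idx] <- stage
    by[idx] <- res$decided_by[res$claim]
    undecided[idx] <- FALSE
    stage <- stage + 1L
  }
  if (!details) return(label)
  data.frame(subject = if ("subject" %in% names(newdata)) newdata$subject
                       else seq_len(n),
             technique_predicted = label,
             decision_node = node_at,
             decided_by = by,
             stringsAsFactors = FALSE)
}

#' @export
print.plank_tree <- function(x, ...) {
  cat("<plank_tree> cascade:", paste(x$technique_order, collapse = " -> "),
      "\n")
  if (!is.null(x$root))
    cat(sprintf("  root: %s %s %.4g -> %s\n", x$root$variable,
                if (x$root$direction == "below_is_d1") "<" else ">",
                x$root$threshold, x$root$d1))
  for (n in x$nodes)
    cat(sprintf("  node %d: %s vs {%s}%s\n", n$node_index, n$d1,
                paste(n$d2_set, collapse = ", "),
                if (is.null(n$filter)) "" else
                  paste0(" [filter: ", paste(n$filter$variables,
                                             collapse = ", "), "]")))
  invisible(x)
}

MODEL_FORMAT_VERSION <- "1.0"
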