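#' Repeated stratified hold-out specification
#'
#' @param train_fraction fraction of subjects per technique assigned to the
#'   training set (default 0.8; the train count per class is
#'   `floor(train_fraction * n_class)`, so 19 subjects give 15 train / 4
#'   test).
#' @param n_repetitions independent repetitions (default 50).
#' @param seed master RNG seed; repetition `r` derives its own seed as
#'   `seed + r`.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, n_repetitions = 50L, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_validation("train_fraction must be in (0, 1)")
  if (n_repetitions < 1) stop_validation("n_repetitions must be >= 1")
  structure(list(train_fraction = train_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split of a feature table
#'
#' Per technique, `floor(train_fraction * n)` subjects are sampled without
#' replacement into the training set; the rest form the test set. The split
#' is a deterministic function of `(spec$seed, repetition)`.
#'
#' @param table a [feature_table()].
#' @param spec a [split_spec()].
#' @param repetition 1-based repetition index.
#' @return List with elements `train` and `test` (disjoint feature tables
#'   whose union is `table`).
#' @export
stratified_split <- function(table, spec = split_spec(), repetition = 1L) {
  table <- feature_table(table)
  counts <- base::table(table$technique)
  if (any(counts < 2))
    stop_data("every class needs >= 2 subjects; offending: ",
              paste(names(counts)[counts < 2], collapse = ", "))
  with_rng_seed(spec$seed + as.integer(repetition), {
    in_train <- rep(FALSE, nrow(table))
    for (tech in unique(table$technique)) {
      rows <- which(table$technique == tech)
      k <- floor(spec$train_fraction * length(rows))
      in_train[sample(rows, k)] <- TRUE
    }
    list(train = table[in_train, , drop = FALSE],
         test = table[!in_train, , drop = FALSE])
  })
}

#' Confusion counts and metrics at a cascade node
#'
#' `n_ij` counts observations classified as `D_i` whose actual category is
#' `D_j`, where `D_1` is the technique the node separates and `D_2` the
#' union of the techniques still in play at that node (membership by true
#' label, so the per-node `n1`/`n2` are fixed across repetitions; set
#' `routed = TRUE` to instead count only the rows the fitted cascade
#' actually routes to the node).
#'
#' @param model a [build_tree()] model.
#' @param node_index 1-based stage index (1 = the root threshold node when
#'   present).
#' @param table a [feature_table()] to classify.
#' @param routed if `TRUE`, D-membership follows the cascade's routing
#'   rather than true labels.
#' @return Object of class `confusion_counts`: list with `n11`, `n12`,
#'   `n21`, `n22`, `d1`, `d2_set`.
#' @export
confusion_at_node <- function(model, node_index, table, routed = FALSE) {
  stages <- cascade_stages(model)
  if (node_index < 1 || node_index > length(stages))
    stop_validation("node_index out of range 1..", length(stages))
  stage <- stages[[node_index]]
  table <- ensure_features(feature_table(table), model$feature_names)
  chain <- model$technique_order
  live <- chain[node_index:length(chain)]
  if (routed) {
    det <- predict(model, table, details = TRUE)
    reached <- is.na(det$decision_node) | det$decision_node >= node_index
    rows <- table[reached, , drop = FALSE]
  } else {
    rows <- table[table$technique %in% live, , drop = FALSE]
  }
  d1 <- stage$d1
  actual_d1 <- rows$technique == d1
  if (!any(actual_d1) || all(actual_d1))
    stop_data("node ", node_index, ": empty D1 or D2 among supplied rows")
  claim <- if (inherits(stage, "threshold_node"))
    threshold_claims(stage, rows[[stage$variable]])
  else node_claims(stage, rows)$claim
  structure(list(n11 = sum(claim & actual_d1),
                 n12 = sum(claim & !actual_d1),
                 n21 = sum(!claim & actual_d1),
                 n22 = sum(!claim & !actual_d1),
                 d1 = d1, d2_set = setdiff(live, d1)),
            class = "confusion_counts")
}

cascade_stages <- function(model) {
  c(if (!is.null(model$root)) list(model$root), model$nodes)
}

#' Construct confusion counts directly
#'
#' @param n11,n12,n21,n22 non-negative counts; `n_ij` = classified as `D_i`,
#'   actually `D_j`.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(n11, n12, n21, n22) {
  v <- c(n11, n12, n21, n22)
  if (any(v < 0) || anyNA(v)) stop_validation("counts must be non-negative")
  structure(list(n11 = n11, n12 = n12, n21 = n21, n22 = n22),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy is `(n11 + n22) / (n11 + n12 + n21 + n22)`, sensitivity (for the
#' separated technique) `n11 / (n11 + n21)`, specificity `n22 / (n12 +
#' n22)`. A metric whose denominator is zero is reported as `NA` (undefined),
#' never coerced to 0.
#'
#' @param counts a [confusion_counts()].
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @examples
#' metrics(confusion_counts(3, 2, 1, 18))  # 0.875, 0.75, 0.9
#' @export
metrics <- function(counts) {
  total <- counts$n11 + counts$n12 + counts$n21 + counts$n22
  if (total == 0) stop_data("all-zero confusion counts")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (counts$n11 + counts$n22) / total,
    sensitivity = ratio(counts$n11, counts$n11 + counts$n21),
    specificity = ratio(counts$n22, counts$n12 + counts$n22))
}

#' Repeat the full train/evaluate protocol
#'
#' For each repetition: draw a stratified 80/20 split, fit the full cascade
#' on the training subjects, then compute per-node confusion metrics on both
#' the training and the test set. Results are aggregated per node as mean
#' and SD over repetitions, yielding one table for the training sets and one
#' for the test sets.
#'
#' @param table a [feature_table()] with engineered features already added.
#' @param spec a [split_spec()].
#' @param ... pipeline arguments forwarded to [build_tree()]
#'   (`threshold_first`, `order`, `filters`, `forest`, `alpha`, ...).
#' @param routed see [confusion_at_node()].
#' @return Object of class `plank_eval`: `per_repetition` (long data frame of
#'   every node x repetition x set metric record), `train_summary` and
#'   `test_summary` (per-node mean/SD tables with `n1`, `n2`), `failures`
#'   (data frame of repetitions that failed to fit, with reasons),
#'   `single_repetition` caveat flag, and the `spec`.
#' @export
repeat_evaluation <- function(table, spec = split_spec(), ..., routed = FALSE) {
  table <- feature_table(table)
  recs <- list()
  failures <- data.frame(repetition = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  models <- vector("list", spec$n_repetitions)
  for (r in seq_len(spec$n_repetitions)) {
    sp <- stratified_split(table, spec, r)
    res <- tryCatch({
      model <- with_rng_seed(spec$seed + 100000L + r,
                             build_tree(sp$train, ...))
      models[[r]] <- model
      for (set_name in c("train", "test")) {
        dat <- sp[[set_name]]
        for (i in seq_along(cascade_stages(model))) {
          cc <- confusion_at_node(model, i, dat, routed = routed)
          m <- metrics(cc)
          recs[[length(recs) + 1L]] <- data.frame(
            repetition = r, set = set_name, node = i, d1 = cc$d1,
            n1 = cc$n11 + cc$n21, n2 = cc$n12 + cc$n22,
            accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
            specificity = m[["specificity"]], stringsAsFactors = FALSE)
        }
      }
      NULL
    }, plank_error = function(e) conditionMessage(e))
    if (!is.null(res))
      failures <- rbind(failures,
                        data.frame(repetition = r, reason = res,
                                   stringsAsFactors = FALSE))
  }
  per_rep <- do.call(rbind, recs)
  summarise <- function(set_name) {
    d <- per_rep[per_rep$set == set_name, , drop = FALSE]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    out <- lapply(split(d, d$node), function(g) {
      modal_d1 <- names(sort(base::table(g$d1), decreasing = TRUE))[1]
      data.frame(node = g$node[1], d1 = modal_d1,
                 n1 = round(mean(g$n1)), n2 = round(mean(g$n2)),
                 accuracy_mean = mean(g$accuracy, na.rm = TRUE),
                 accuracy_sd = sd_or_zero(g$accuracy),
                 sensitivity_mean = mean(g$sensitivity, na.rm = TRUE),
                 sensitivity_sd = sd_or_zero(g$sensitivity),
                 specificity_mean = mean(g$specificity, na.rm = TRUE),
                 specificity_sd = sd_or_zero(g$specificity),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }
  structure(list(per_repetition = per_rep,
                 train_summary = summarise("train"),
                 test_summary = summarise("test"),
                 failures = failures,
                 n_completed = spec$n_repetitions - nrow(failures),
                 single_repetition = spec$n_repetitions == 1L,
                 spec = spec,
                 last_model = models[[spec$n_repetitions]]),
            class = "plank_eval")
}

sd_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) 0 else sd(x)
}

#' @export
print.plank_eval <- function(x, ...) {
  cat(sprintf("<plank_eval> %d/%d repetitions completed\n",
              x$n_completed, x$spec$n_repetitions))
  if (x$single_repetition)
    cat("  (single repetition: SDs are reported as 0 by convention)\n")
  for (nm in c("train_summary", "test_summary")) {
    cat("--", sub("_summary", " set", nm), "--\n")
    print(format(x[[nm]], digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Forest variable importance at a cascade node
#'
#' Ranks the features of the node's random forest by mean decrease in Gini
#' impurity: the total Gini decrease contributed by splits on each feature,
#' averaged over trees. Higher means the feature contributed more to node
#' purity across the ensemble.
#'
#' @param model a [build_tree()] model.
#' @param node_index 1-based stage index; must be a two-stage node (the root
#'   threshold node has no forest).
#' @param top_k number of features to return (default 20).
#' @return Data frame with columns `feature`, `mean_decrease_gini`,
#'   descending.
#' @export
variable_importance <- function(model, node_index, top_k = 20L) {
  stages <- cascade_stages(model)
  if (node_index < 1 || node_index > length(stages))
    stop_validation("node_index out of range 1..", length(stages))
  stage <- stages[[node_index]]
  if (!inherits(stage, "cascade_node"))
    stop_validation("node ", node_index,
                    " is a threshold node and has no forest")
  imp <- sort(stage$forest$importance, decreasing = TRUE)
  imp <- imp[seq_len(min(top_k, length(imp)))]
  data.frame(feature = names(imp), mean_decrease_gini = as.numeric(imp),
             stringsAsFactors = FALSE, row.names = NULL)
}
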