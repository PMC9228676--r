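test_that("stratified splits allocate floor(0.8 n) subjects per class", {
  tab <- tiny_table()  # 4 subjects per class
  sp <- stratified_split(tab, split_spec(seed = 2), 1)
  for (tech in plank_techniques()) {
    expect_equal(sum(sp$train$technique == tech), 3)  # floor(0.8 * 4)
    expect_equal(sum(sp$test$technique == tech), 1)
  }
  # conservation and disjointness
  key <- function(d) paste(d$subject, d$technique)
  expect_setequal(c(key(sp$train), key(sp$test)), key(tab))
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
})

test_that("split counts match the 19-subject and 5-subject designs", {
  mk <- function(n) feature_table(data.frame(
    subject = sprintf("s%02d", 1:n), technique = rep("PC", n),
    f = rnorm(n)))
  sp19 <- stratified_split(mk(19), split_spec(seed = 1), 1)
  expect_equal(nrow(sp19$train), 15)
  expect_equal(nrow(sp19$test), 4)
  sp5 <- stratified_split(mk(5), split_spec(seed = 1), 1)
  expect_equal(nrow(sp5$train), 4)
  expect_equal(nrow(sp5$test), 1)
  expect_error(stratified_split(mk(1), split_spec(), 1),
               class = "plank_data_error")
})

test_that("splits are deterministic per (seed, repetition)", {
  tab <- tiny_table()
  a <- stratified_split(tab, split_spec(seed = 5), 3)
  b <- stratified_split(tab, split_spec(seed = 5), 3)
  expect_identical(a, b)
  c <- stratified_split(tab, split_spec(seed = 5), 4)
  expect_false(identical(a$train$subject, c$train$subject))
})

test_that("metrics implement the printed confusion formulas", {
  expect_equal(metrics(confusion_counts(4, 0, 0, 20)),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_equal(metrics(confusion_counts(3, 2, 1, 18)),
               c(accuracy = 21 / 24, sensitivity = 3 / 4,
                 specificity = 18 / 20))
  m <- metrics(confusion_counts(0, 0, 4, 20))
  expect_equal(unname(m), c(20 / 24, 0, 1))
  # undefined denominators surface as NA, never 0
  expect_true(is.na(metrics(confusion_counts(0, 3, 0, 7))[["sensitivity"]]))
  expect_error(metrics(confusion_counts(0, 0, 0, 0)),
               class = "plank_data_error")
})

test_that("metrics match hand arithmetic on random count quadruples", {
  set.seed(17)
  for (i in 1:20) {
    q <- sample(0:30, 4, replace = TRUE)
    if (sum(q) == 0) q[1] <- 1
    m <- metrics(confusion_counts(q[1], q[2], q[3], q[4]))
    expect_equal(m[["accuracy"]], (q[1] + q[4]) / sum(q))
    if (q[1] + q[3] > 0) expect_equal(m[["sensitivity"]], q[1] / (q[1] + q[3]))
    if (q[2] + q[4] > 0) expect_equal(m[["specificity"]], q[4] / (q[2] + q[4]))
    # accuracy decomposes over the two classes
    n1 <- q[1] + q[3]; n2 <- q[2] + q[4]
    if (n1 > 0 && n2 > 0)
      expect_equal(m[["accuracy"]],
                   (n1 * m[["sensitivity"]] + n2 * m[["specificity"]]) /
                     (n1 + n2))
  }
})

test_that("node confusions match a per-row traversal tally", {
  tab <- tiny_table()
  model <- build_tree(tab, filters = designated_filter_variables(),
                      forest = fast_forest(), seed = 7)
  for (i in c(1, 3, 6)) {
    cc <- confusion_at_node(model, i, tab)
    chain <- model$technique_order[i:7]
    rows <- tab[tab$technique %in% chain, ]
    stage <- plankcascade:::cascade_stages(model)[[i]]
    n <- c(n11 = 0, n12 = 0, n21 = 0, n22 = 0)
    for (r in seq_len(nrow(rows))) {
      claimed <- if (inherits(stage, "threshold_node")) {
        v <- rows[[stage$variable]][r]
        if (stage$direction == "below_is_d1") v < stage$threshold
        else v > stage$threshold
      } else {
        plankcascade:::node_claims(stage, rows[r, , drop = FALSE])$claim
      }
      truth_d1 <- rows$technique[r] == cc$d1
      idx <- if (claimed && truth_d1) "n11" else if (claimed) "n12"
             else if (truth_d1) "n21" else "n22"
      n[idx] <- n[idx] + 1
    }
    expect_equal(unlist(cc[c("n11", "n12", "n21", "n22")]), n)
  }
})

test_that("repeated evaluation aggregates cleanly and is reproducible", {
  tab <- tiny_table()
  ev <- repeat_evaluation(tab, split_spec(n_repetitions = 3, seed = 4),
                          filters = designated_filter_variables(),
                          forest = fast_forest())
  expect_equal(nrow(ev$failures), 0)
  expect_equal(nrow(ev$per_repetition), 3 * 2 * 6)
  expect_equal(ev$train_summary$n1, rep(3, 6))
  expect_equal(ev$test_summary$n2, c(6, 5, 4, 3, 2, 1))
  # aggregation equals brute-force recomputation from the records
  d <- ev$per_repetition
  node3 <- d[d$set == "test" & d$node == 3, ]
  expect_equal(ev$test_summary$accuracy_mean[3], mean(node3$accuracy))
  expect_equal(ev$test_summary$accuracy_sd[3], sd(node3$accuracy))
  ev2 <- repeat_evaluation(tab, split_spec(n_repetitions = 3, seed = 4),
                           filters = designated_filter_variables(),
                           forest = fast_forest())
  expect_identical(ev$per_repetition, ev2$per_repetition)
})

test_that("noise-free separable data scores perfectly at every node", {
  cfg <- tiny_config(n = 5, subject_sd = 0, noise_sd = 0,
                     hd_base_shift = 5, hd_extreme_shift = 0)
  tab <- add_max_features(
    build_feature_table(generate_dataset(cfg), tiny_window()))
  ev <- repeat_evaluation(tab, split_spec(n_repetitions = 2, seed = 1),
                          filters = "none", forest = fast_forest())
  for (col in c("accuracy_mean", "sensitivity_mean", "specificity_mean")) {
    expect_equal(ev$train_summary[[col]], rep(1, 6))
    expect_equal(ev$test_summary[[col]], rep(1, 6))
  }
  expect_equal(ev$test_summary$accuracy_sd, rep(0, 6))
})

test_that("a single repetition reports zero SDs with a caveat", {
  tab <- tiny_table()
  ev <- repeat_evaluation(tab, split_spec(n_repetitions = 1, seed = 2),
                          filters = "none", forest = fast_forest(30))
  expect_true(ev$single_repetition)
  expect_equal(ev$test_summary$accuracy_sd, rep(0, 6))
})

test_that("variable importance ranks hip-drop evidence at its node", {
  tab <- tiny_table()
  model <- build_tree(tab, order = c("HTFN", "HTB", "BC", "HC", "HD"),
                      threshold_first = list(variable = "Euler-Y-S1",
                                             d1 = "HTBN"),
                      filters = "none", forest = forest_control(300),
                      seed = 3)
  imp <- variable_importance(model, 6, top_k = 20)
  expect_equal(nrow(imp), 20)
  expect_true(all(diff(imp$mean_decrease_gini) <= 0))
  hd_evidence <- c(hd_designated_channels(),
                   grep("^max\\((Acc-X-S3|Mag-Z-S3)",
                        names(tab), value = TRUE))
  expect_gt(length(intersect(imp$feature[1:5], hd_evidence)), 0)
  expect_error(variable_importance(model, 1),
               class = "plank_validation_error")
  expect_error(variable_importance(model, 99),
               class = "plank_validation_error")
})
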