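test_that("empirical p-values follow the tail-counting formulas", {
  # far below all 19 reference values, two-sided, add-one: 2 * 1/20
  expect_equal(empirical_p_value(-100, 1:19), 0.1)
  # at the center of an odd-sized reference the two-sided p caps at 1
  expect_equal(empirical_p_value(3, 1:5), 1)
  # far above 99 values, right tail: 1/100
  expect_equal(empirical_p_value(1000, 1:99, "right"), 0.01)
  # uncorrected: outside the range gives exactly 0
  expect_equal(empirical_p_value(-100, 1:19, correction = "none"), 0)
  expect_error(empirical_p_value(0, 5), class = "plank_validation_error")
})

test_that("empirical p-values agree with a counting oracle on random draws", {
  set.seed(21)
  for (i in 1:100) {
    m <- sample(2:40, 1)
    ref <- round(rnorm(m), 1)
    x <- round(rnorm(1, sd = 2), 1)
    side <- sample(c("two_sided", "left", "right"), 1)
    corr <- sample(c("add_one", "none"), 1)
    expect_equal(empirical_p_value(x, ref, side, corr),
                 oracle_p_value(x, ref, side, corr))
  }
})

test_that("add-one p-values never reach zero and decrease away from the center", {
  ref <- c(-4, -2, -1, 0, 1, 2, 4)  # symmetric
  xs <- seq(0, 6, by = 0.5)
  ps <- empirical_p_value(xs, ref)
  expect_true(all(ps > 0))
  expect_true(all(diff(ps) <= 0))
})

test_that("threshold nodes fit the midpoint rule and demand separation", {
  tab <- feature_table(data.frame(
    subject = letters[1:4], technique = c("HTBN", "HTBN", "PC", "HD"),
    f = c(-60, -55, -40, -30), check.names = FALSE))
  node <- fit_threshold_node(tab, "HTBN", "f")
  expect_equal(node$threshold, (-55 + -40) / 2)  # -47.5
  expect_identical(node$direction, "below_is_d1")

  overlap <- feature_table(data.frame(
    subject = c("a", "b"), technique = c("HTBN", "PC"), f = c(-50, -50)))
  expect_error(fit_threshold_node(overlap, "HTBN", "f"),
               class = "plank_separability_error")

  up <- fit_threshold_node(tab, "HD", "f", "above_is_d1")
  expect_equal(up$threshold, (-30 + -40) / 2)
})

test_that("the threshold node isolates HTBN exactly on synthetic data", {
  cfg <- tiny_config(n = 5, subject_sd = 0, noise_sd = 0, transient_amp = 0)
  tab <- build_feature_table(generate_dataset(cfg), tiny_window())
  node <- fit_threshold_node(tab, "HTBN", "Euler-Y-S1")
  claims <- plankcascade:::threshold_claims(node, tab[["Euler-Y-S1"]])
  expect_identical(claims, tab$technique == "HTBN")
})

test_that("explicit filter variables are stored with their D2 references", {
  tab <- tiny_table()
  filt <- fit_filter(tab, "HD", setdiff(plank_techniques(), c("HD", "HTBN")),
                     variables = "Euler-Z-S3")
  expect_identical(filt$variables, "Euler-Z-S3")
  expect_length(filt$reference_values[["Euler-Z-S3"]],
                sum(!tab$technique %in% c("HD", "HTBN")))
  expect_error(fit_filter(tab, "HD", "PC", variables = "no-such-channel"),
               class = "plank_data_error")
})

test_that("auto filter selection obeys the flag-count retention rule", {
  # D1 has one clear extreme on f1; f2 is pure noise shared by both classes
  set.seed(8)
  tab <- feature_table(data.frame(
    subject = sprintf("s%02d", 1:40),
    technique = rep(c("HD", "PC"), each = 20),
    f1 = c(rnorm(19), 50, rnorm(20)),
    f2 = rep(0, 40) + rep(c(0.1, -0.1), 20),
    check.names = FALSE))
  filt <- fit_filter(tab, "HD", "PC", variables = "auto")
  expect_true("f1" %in% filt$variables)

  # no D1 value is extreme relative to D2 -> nothing retained
  tab2 <- tab
  tab2$f1 <- rep(0, 40)
  expect_message(
    filt2 <- fit_filter(tab2, "HD", "PC", variables = "auto"),
    "retained no variable")
  expect_null(filt2)
})

test_that("auto selection retains a designated channel for hip-drop extremes", {
  tab <- tiny_table()  # contains the extreme-HD component
  filt <- fit_filter(tab, "HD", "PC", variables = "auto")
  hd_vars <- c(hd_designated_channels(), "max(Acc-X-S3, Acc-X-S4)",
               "max(Acc-X-S3, Acc-X-S2)", "max(Acc-X-S3, Acc-X-S5)",
               "max(Mag-Z-S3, Mag-Z-S4)", "max(Mag-Z-S3, Mag-Z-S2)")
  expect_gt(length(intersect(filt$variables, hd_vars)), 0)
})

test_that("any-variable flagging drives apply_filter", {
  ref <- list(a = 1:20, b = 1:20, c = 1:20)
  filt <- structure(list(node_index = 2L, variables = c("a", "b", "c"),
                         reference_values = ref, alpha = 0.05,
                         sidedness = "two_sided", correction = "none"),
                    class = "aberrance_filter")
  center <- data.frame(a = 10, b = 10, c = 10)
  one_extreme <- data.frame(a = 10, b = 10, c = 99)
  expect_false(apply_filter(filt, center))
  expect_true(apply_filter(filt, one_extreme))   # union rule
  expect_identical(apply_filter(NULL, center), FALSE)
})

test_that("two-stage nodes are exact on separable data and deterministic", {
  cfg <- tiny_config(n = 5, subject_sd = 0.05, noise_sd = 0.05)
  tab <- add_max_features(
    build_feature_table(generate_dataset(cfg), tiny_window()))
  d2 <- c("PC", "HC")
  node <- fit_node(tab, "HTB", d2, filter_spec = "none",
                   forest = fast_forest(), seed = 4)
  rows <- tab[tab$technique %in% c("HTB", d2), ]
  res <- plankcascade:::node_claims(node, rows)
  expect_identical(res$claim, rows$technique == "HTB")

  node2 <- fit_node(tab, "HTB", d2, filter_spec = "none",
                    forest = fast_forest(), seed = 4)
  expect_identical(predict(node2$forest, rows), predict(node$forest, rows))
  expect_no_error(fit_node(tab, "HTB", c("PC", "BC"), "none",
                           forest = fast_forest(30), node_index = 2))
  expect_error(fit_node(tab[tab$technique != "PC", ], "HTB", d2, "none"),
               class = "plank_data_error")
})

test_that("extreme hip-drop training rows are flagged before the forest", {
  cfg <- tiny_config(n = 8)
  trials <- generate_dataset(cfg)
  ext <- attr(trials, "hd_extreme_subjects")
  tab <- add_max_features(build_feature_table(trials, tiny_window()))
  node <- fit_node(tab, "HD", "PC",
                   filter_spec = designated_filter_variables()$HD,
                   forest = fast_forest(), seed = 2)
  rows <- tab[tab$technique %in% c("HD", "PC"), ]
  flagged_subj <- rows$subject[node$train_flagged & rows$technique == "HD"]
  # every generator-designated extreme subject is caught (ordinary HD
  # subjects may also flag occasionally at this small reference size)
  expect_true(all(ext %in% flagged_subj))
  # filter dominance: every flagged training row maps to d1 at the node
  res <- plankcascade:::node_claims(node, rows)
  expect_true(all(res$claim[node$train_flagged]))
  expect_true(all(res$decided_by[node$train_flagged] == "filter"))
})

test_that("the fitted cascade honours the shrinking set chain", {
  tab <- tiny_table()
  model <- build_tree(tab, order = c("HTFN", "HTB", "BC", "HC", "HD"),
                      threshold_first = list(variable = "Euler-Y-S1",
                                             d1 = "HTBN"),
                      filters = designated_filter_variables(),
                      forest = fast_forest(), seed = 6)
  expect_identical(model$technique_order,
                   c("HTBN", "HTFN", "HTB", "BC", "HC", "HD", "PC"))
  # every class appears exactly once across root, nodes, terminal
  expect_setequal(model$technique_order, plank_techniques())
  # the C chain: each node's remainder set drops that node's own target
  for (i in seq_along(model$nodes)[-1])
    expect_setequal(model$nodes[[i]]$d2_set,
                    setdiff(model$nodes[[i - 1]]$d2_set,
                            model$nodes[[i]]$d1))
  expect_identical(model$nodes[[5]]$d2_set, "PC")
})

test_that("greedy ordering separates a planted easy class first", {
  set.seed(31)
  n <- 12
  # HTB is far from everything; BC barely differs from PC
  tab <- feature_table(data.frame(
    subject = sprintf("s%02d", rep(1:n, 3)),
    technique = rep(c("HTB", "BC", "PC"), each = n),
    f1 = c(rnorm(n, 50), rnorm(n, 1.0), rnorm(n)),
    f2 = rnorm(3 * n),
    check.names = FALSE))
  model <- build_tree(tab, threshold_first = "none", order = "greedy",
                      filters = "none", forest = fast_forest(), seed = 3)
  expect_identical(model$nodes[[1]]$d1, "HTB")
  expect_identical(model$technique_order, c("HTB", "BC", "PC"))
})

test_that("greedy builds are deterministic under a fixed seed", {
  tab <- tiny_table()
  m1 <- build_tree(tab, filters = designated_filter_variables(),
                   forest = fast_forest(), seed = 12)
  m2 <- build_tree(tab, filters = designated_filter_variables(),
                   forest = fast_forest(), seed = 12)
  expect_identical(m1$technique_order, m2$technique_order)
  expect_identical(predict(m1, tab), predict(m2, tab))
})

test_that("cascade predictions report their decision path", {
  cfg <- tiny_config(n = 5, subject_sd = 0.05, noise_sd = 0.05)
  tab <- add_max_features(
    build_feature_table(generate_dataset(cfg), tiny_window()))
  model <- build_tree(tab, threshold_first = list(variable = "Euler-Y-S1",
                                                  d1 = "HTBN"),
                      filters = "none", forest = fast_forest(), seed = 8)
  det <- predict(model, tab, details = TRUE)
  expect_identical(det$technique_predicted, tab$technique)
  htbn <- det[tab$technique == "HTBN", ]
  expect_true(all(htbn$decided_by == "threshold"))
  expect_true(all(htbn$decision_node == 1))
  pc <- det[tab$technique == "PC", ]
  expect_true(all(pc$decided_by == "terminal"))
  expect_error(predict(model, tab[, 1:10]), class = "plank_data_error")
})

test_that("extreme hip-drop rows are decided by the filter, not the forest", {
  trials <- generate_dataset(tiny_config(n = 8))
  ext <- attr(trials, "hd_extreme_subjects")
  tab <- add_max_features(build_feature_table(trials, tiny_window()))
  model <- build_tree(tab, filters = designated_filter_variables(),
                      forest = fast_forest(), seed = 2)
  det <- predict(model, tab, details = TRUE)
  rows <- tab$technique == "HD" & tab$subject %in% ext
  expect_true(all(det$technique_predicted[rows] == "HD"))
  expect_true(all(det$decided_by[rows] == "filter"))
})

test_that("prediction derives missing max() columns from base channels", {
  tab <- tiny_table()
  model <- build_tree(tab, filters = designated_filter_variables(),
                      forest = fast_forest(), seed = 5)
  base_only <- tab[, c("subject", "technique", plank_channels())]
  expect_identical(predict(model, base_only), predict(model, tab))
})
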