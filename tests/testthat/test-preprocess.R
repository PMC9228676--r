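test_that("stable-window mean reduces known trials exactly", {
  const <- raw_trial("s", "PC", matrix(3.25, 600, 60))
  expect_equal(unname(stable_window_mean(const)), rep(3.25, 60))

  ramp <- raw_trial("s", "PC", matrix(rep(seq_len(600), 60), 600, 60))
  # arithmetic series over [181, 420]: mean = (181 + 420) / 2
  expect_equal(unname(stable_window_mean(ramp)), rep(300.5, 60))

  expect_error(stable_window_mean(raw_trial("s", "PC", matrix(0, 100, 60))),
               class = "plank_validation_error")
})

test_that("stable-window mean matches brute-force loop summation", {
  set.seed(11)
  w <- window_spec(start = 3, end = 7)
  for (rep in 1:10) {
    tr <- raw_trial("s", "PC", matrix(rnorm(10 * 60), 10, 60))
    got <- stable_window_mean(tr, w)
    for (j in sample(60, 5)) {
      acc <- 0
      for (t in 3:7) acc <- acc + unname(tr$samples[t, j])
      expect_equal(unname(got[j]), acc / 5, tolerance = 1e-12)
    }
  }
})

test_that("stable-window mean is linear per channel", {
  set.seed(12)
  m <- matrix(rnorm(600 * 60), 600, 60)
  a <- 2.5; b <- -7
  f1 <- stable_window_mean(raw_trial("s", "PC", m))
  f2 <- stable_window_mean(raw_trial("s", "PC", a * m + b))
  expect_equal(f2, a * f1 + b)
})

test_that("window bounds cover fixed and fractional modes", {
  expect_identical(window_bounds(window_spec(), 600), c(181L, 420L))
  # default window averages exactly 240 timestamps
  b <- window_bounds(window_spec(), 600)
  expect_identical(b[2] - b[1] + 1L, 240L)
  expect_identical(window_bounds(window_spec(mode = "fractional"), 600),
                   c(181L, 420L))
  expect_identical(window_bounds(window_spec(mode = "fractional"), 100),
                   c(31L, 70L))
  expect_error(window_spec(start = 10, end = 5),
               class = "plank_validation_error")
})

test_that("feature tables have one row per trial and 60 canonical columns", {
  trials <- generate_dataset(tiny_config(n = 2, T = 40))
  tab <- build_feature_table(trials, tiny_window())
  expect_equal(nrow(tab), 2 * 7)
  expect_identical(names(tab), c("subject", "technique", plank_channels()))

  one_class <- trials[vapply(trials, function(t) t$technique, "") == "PC"]
  tab1 <- build_feature_table(one_class, tiny_window())
  expect_equal(dim(tab1), c(2, 62))

  empty <- build_feature_table(list(), tiny_window())
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), c("subject", "technique", plank_channels()))

  expect_error(build_feature_table(c(trials, trials[1]), tiny_window()),
               class = "plank_data_error")
})

test_that("max-features append row-wise maxima with verbatim names", {
  tab <- feature_table(data.frame(
    subject = c("a", "b"), technique = c("PC", "HD"),
    `Euler-Z-S5` = c(-10, 4), `Euler-Z-S1` = c(-25, 4),
    check.names = FALSE))
  out <- add_max_features(tab, max_feature_spec("Euler-Z-S5", "Euler-Z-S1"))
  expect_true("max(Euler-Z-S5, Euler-Z-S1)" %in% names(out))
  expect_equal(out[["max(Euler-Z-S5, Euler-Z-S1)"]], c(-10, 4))
  # equal operands: max is either operand
  expect_equal(out[["max(Euler-Z-S5, Euler-Z-S1)"]][2], 4)
  # original columns untouched
  expect_identical(out[names(tab)], tab)
})

test_that("max-feature values are symmetric in their operands", {
  set.seed(4)
  tab <- tiny_table()
  fwd <- pmax(tab[["Acc-X-S3"]], tab[["Acc-X-S4"]])
  rev <- pmax(tab[["Acc-X-S4"]], tab[["Acc-X-S3"]])
  expect_identical(fwd, rev)
  expect_identical(tab[["max(Acc-X-S3, Acc-X-S4)"]], fwd)
})

test_that("the standard engineered set appends nine columns, five for hip-drop", {
  base <- build_feature_table(generate_dataset(tiny_config(n = 2, T = 40)),
                              tiny_window())
  out <- add_max_features(base, standard_max_features())
  expect_equal(ncol(out) - ncol(base), 9)
  hd_cols <- grep("^max\\((Acc-X-S3|Mag-Z-S3)", names(out), value = TRUE)
  expect_length(hd_cols, 5)  # 3 acceleration + 2 magnetometer maxima
})

test_that("max-feature validation rejects bad partners and collisions", {
  expect_error(max_feature_spec("Euler-Z-S5", "Euler-Y-S1"),
               class = "plank_validation_error")  # axis mismatch
  expect_error(max_feature_spec("Euler-Z-S5", "Acc-Z-S1"),
               class = "plank_validation_error")  # measurement mismatch
  expect_error(max_feature_spec("Euler-Z-S5", "Euler-Z-S5"),
               class = "plank_validation_error")  # same sensor
  tab <- tiny_table()
  expect_error(add_max_features(tab, max_feature_spec("Acc-X-S3", "Acc-X-S4")),
               class = "plank_data_error")        # name collision
})
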