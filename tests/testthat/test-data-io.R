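test_that("the printed prostate sample loads with schema intact", {
  t <- read_feature_table(prostate_fixture())
  expect_equal(dim(t), c(10L, 8L))
  expect_equal(colnames(t$features),
               c("Radius", "Texture", "Perimeter", "Area", "Smoothness",
                 "Compactness", "Symmetry", "Fractal_dimension"))
  expect_equal(t$labels, c("M", "B", "M", "M", "M", "B", "M", "M", "M", "M"))
  expect_equal(t$y, ifelse(t$labels == "M", 1, -1))
  expect_equal(unname(t$features[1, "Perimeter"]), 151)
})

test_that("an unlabelled table (the breast sample columns) parses numerically", {
  path <- system.file("extdata", "breast_sample.csv", package = "genefold")
  t <- read_feature_table(path, label_column = NULL)
  expect_equal(dim(t), c(6L, 7L))
  expect_true(is.numeric(t$features))
  expect_null(t$labels)
})

test_that("the loader rejects bad labels, bad cells and missing values", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b,Diagnosis", "1,2,M", "3,4,X"), bad)
  expect_error(read_feature_table(bad), class = "gf_parse_error")
  expect_error(read_feature_table(bad), "row 2")

  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("a,b,Diagnosis", "1,oops,M", "3,4,B"), bad2)
  expect_error(read_feature_table(bad2), class = "gf_parse_error")

  bad3 <- tempfile(fileext = ".csv")
  writeLines(c("a,b,Diagnosis", "1,,M", "3,4,B"), bad3)
  expect_error(read_feature_table(bad3), class = "gf_parse_error")
  t3 <- read_feature_table(bad3, na_action = "impute_mean")
  expect_equal(unname(t3$features[1, "b"]), 4)

  expect_error(read_feature_table(tempfile()), class = "gf_input_error")
})

test_that("label encoding maps M to +1 and round-trips", {
  expect_equal(encode_labels(c("M", "B", "M")), c(1, -1, 1))
  expect_error(encode_labels(c("M", "Q")), class = "gf_parse_error")

  t <- feature_table(matrix(1:4, 2, 2), c("B", "B"))
  t <- encode_labels(t)
  expect_equal(t$y, c(-1, -1))
  expect_true(attr(t, "single_class"))
  expect_equal(decode_labels(t$y), t$labels)
})

test_that("min-max scaling maps to [0, 1] and reapplies to held-out data", {
  t <- feature_table(cbind(a = c(2, 4, 6), b = c(5, 5, 5)),
                     c("M", "B", "M"))
  s <- minmax_scale(t)
  expect_equal(unname(s$features[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(s$features[, "b"]), c(0, 0, 0))  # constant column
  held <- apply_minmax(cbind(a = 6, b = 7), s$scaling$minmax)
  expect_equal(unname(held[1, "a"]), 1)

  set.seed(20)
  r <- feature_table(matrix(rnorm(200), 40, 5))
  rs <- minmax_scale(r)
  expect_true(all(rs$features >= 0 & rs$features <= 1))
})

test_that("the log transform is log1p, total on non-negative data", {
  t <- feature_table(cbind(v = c(0, exp(1) - 1, 10)))
  lt <- log_transform(t)
  expect_equal(unname(lt$features[1:2, "v"]), c(0, 1))

  set.seed(21)
  col <- sort(runif(30, 0, 50))
  mono <- log_transform(feature_table(cbind(v = col)))
  expect_true(all(diff(mono$features[, "v"]) >= 0))

  expect_error(log_transform(feature_table(cbind(v = c(-1, 2)))),
               class = "gf_transform_error")
  expect_error(log_transform(feature_table(cbind(v = c(0, 2))),
                             shift = FALSE),
               class = "gf_transform_error")
})

test_that("the Z-score filter removes gross outliers in one pass", {
  const <- feature_table(matrix(7, 20, 3), rep(c("M", "B"), 10))
  expect_length(zscore_filter(const)$removed, 0)

  set.seed(22)
  vals <- rnorm(1000); vals[137] <- 10
  t <- feature_table(cbind(v = vals))
  out <- zscore_filter(t, threshold = 3)
  expect_true("S137" %in% out$removed)
  # brute-force z on the pre-filter column agrees on who is removed
  z <- abs((vals - mean(vals)) / sd(vals))
  expect_setequal(out$removed, paste0("S", which(z > 3)))

  expect_length(zscore_filter(t, threshold = Inf)$removed, 0)
  expect_error(zscore_filter(feature_table(matrix(1, 1, 1))),
               class = "gf_input_error")
})

test_that("the filter barely touches well-behaved gaussian data", {
  # 800 standard-normal values carry ~2 expected |z| > 3 excursions, so a
  # handful of removals is the norm; the filter must not cut into the bulk
  set.seed(30)
  removed <- sapply(1:20, function(s) {
    t <- feature_table(matrix(rnorm(800), 100, 8))
    length(zscore_filter(t, threshold = 3)$removed)
  })
  expect_lte(mean(removed) / 100, 0.05)
  # at a looser threshold the tail is essentially never reached
  set.seed(31)
  removed4 <- sapply(1:20, function(s) {
    t <- feature_table(matrix(rnorm(800), 100, 8))
    length(zscore_filter(t, threshold = 4.5)$removed)
  })
  expect_lte(mean(removed4 > 0), 0.2)
})

test_that("stratified folds are balanced, deterministic partitions", {
  labels <- rep(c(1, -1), each = 50)
  f <- kfold_split(labels, k = 5, seed = 3)
  expect_equal(unname(table(f)), rep(20L, 5), ignore_attr = TRUE)
  for (k in 1:5) {
    expect_equal(sum(labels[f == k] == 1), 10)
    expect_equal(sum(labels[f == k] == -1), 10)
  }
  expect_identical(kfold_split(labels, 5, 3), f)
  expect_false(identical(kfold_split(labels, 5, 4), f))
  expect_setequal(unlist(lapply(1:5, function(k) which(f == k))), 1:100)
  expect_error(kfold_split(labels, k = 101), class = "gf_input_error")
  expect_error(kfold_split(labels, k = 1), class = "gf_input_error")
})

test_that("the synthetic generator hits its separability contract", {
  t0 <- synth_dataset(200, 8, separation = 6, seed = 1)
  expect_identical(t0$features, synth_dataset(200, 8, separation = 6,
                                              seed = 1)$features)
  expect_true(all(t0$features > 0))
  expect_equal(sum(t0$labels == "M"), 100)

  folds <- kfold_split(t0$y, 5, 2)
  acc_sep <- genefold:::cv_metrics(gf_preset("linear"), t0, folds)$accuracy
  expect_gte(acc_sep, 95)

  # separation 0: chance-level linear accuracy, averaged over seeds
  accs <- sapply(1:5, function(s) {
    tn <- synth_dataset(120, 6, separation = 0, seed = 400 + s)
    genefold:::cv_metrics(gf_preset("linear"), tn,
                          kfold_split(tn$y, 5, s))$accuracy
  })
  expect_gte(mean(accs), 40); expect_lte(mean(accs), 60)
})

test_that("feature tables round-trip through CSV at full precision", {
  set.seed(23)
  t <- synth_dataset(20, 5, separation = 2, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_feature_table(t, path)
  back <- read_feature_table(path)
  expect_equal(back$features, t$features, tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_equal(back$labels, t$labels)
})
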