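make_noise_table <- function(n = 120, p = 6, seed = 1, balance = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- c(rep("like", round(n * balance)),
         rep("dislike", n - round(n * balance)))
  feature_table(X, y, subject = rep(1:10, length.out = n),
                trial = seq_len(n))
}

test_that("the stratified holdout split is exact, disjoint and seeded", {
  ft <- make_noise_table(n = 1050, seed = 2, balance = 0.524)  # 550/500
  sp <- holdout_split(ft, 0.8, seed = 3)
  expect_equal(nrow(sp$train$matrix), 840)
  expect_equal(nrow(sp$test$matrix), 210)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:1050)
  # class proportions preserved to within one trial
  p_full <- mean(ft$labels == "like")
  expect_lte(abs(sum(sp$test$labels == "like") - p_full * 210), 1)
  expect_lte(abs(sum(sp$train$labels == "like") - p_full * 840), 1)
  sp2 <- holdout_split(ft, 0.8, seed = 3)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_error(holdout_split(ft, 1.2), "train_fraction")
})

test_that("subject-grouped splitting keeps subjects in one fold", {
  ft <- make_noise_table(n = 100, seed = 5)
  sp <- holdout_split(ft, 0.8, seed = 1, by_subject = TRUE)
  expect_length(intersect(unique(sp$train$subject),
                          unique(sp$test$subject)), 0)
})

test_that("confusion-matrix metrics match hand arithmetic", {
  perfect <- metrics_from_confusion(matrix(c(50, 0, 0, 50), 2, byrow = TRUE))
  expect_equal(unlist(perfect), c(accuracy = 1, recall = 1, precision = 1,
                                  f_measure = 1))
  m <- metrics_from_confusion(matrix(c(40, 10, 20, 30), 2, byrow = TRUE))
  expect_equal(m$accuracy, 0.7)
  rec <- 0.5 * (40 / 50) + 0.5 * (30 / 50)
  prec <- 0.5 * (40 / 60) + 0.5 * (30 / 40)
  expect_equal(m$recall, rec)
  expect_equal(m$precision, prec)
  expect_equal(m$f_measure, 2 * prec * rec / (prec + rec), tolerance = 1e-9)
  # constant predictor on balanced truth
  all_one <- metrics_from_confusion(matrix(c(50, 0, 50, 0), 2, byrow = TRUE))
  expect_equal(all_one$accuracy, 0.5)
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "counts")
})

test_that("every classifier solves a linearly separable problem", {
  set.seed(7)
  n <- 80
  y <- rep(c("like", "dislike"), each = n / 2)
  X <- cbind(a = ifelse(y == "like", 3, -3) + rnorm(n, 0, 0.2),
             b = rnorm(n))
  ft <- feature_table(X, y)
  sp <- holdout_split(ft, 0.8, seed = 8)
  for (kind in c("knn", "rf", "lda", "svm_rbf", "mlp_hinge")) {
    r <- train_eval(classifier_spec(kind, seed = 9), sp$train, sp$test)
    expect_equal(r$accuracy, 1, info = kind)
  }
})

test_that("1-nearest-neighbour memorises its training fold", {
  ft <- make_noise_table(n = 60, seed = 10)
  r <- train_eval(classifier_spec("knn", seed = 1), ft, ft)
  expect_equal(r$accuracy, 1)
})

test_that("classifiers sit at chance under shuffled labels", {
  accs <- c()
  for (s in 1:10) {
    set.seed(s)
    ft <- make_noise_table(n = 400, p = 5, seed = s * 100)
    sp <- holdout_split(ft, 0.8, seed = s)
    r <- train_eval(classifier_spec("lda", seed = s), sp$train, sp$test)
    accs <- c(accs, r$accuracy)
  }
  n_test_total <- 10 * 80
  se <- sqrt(0.25 / n_test_total)
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("train/test contracts are enforced", {
  ft <- make_noise_table(n = 40, seed = 11)
  other <- make_noise_table(n = 40, p = 4, seed = 11)
  expect_error(train_eval(classifier_spec("lda"), ft, other),
               "feature names")
  bad <- feature_table(ft$matrix, rep("like", 40))
  expect_error(train_eval(classifier_spec("lda"), bad, ft), "single-class")
})

test_that("the benchmark grid covers the selector-classifier product and is
           deterministic", {
  set.seed(12)
  n <- 80
  y <- rep(c("like", "dislike"), each = n / 2)
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  X[, 1] <- X[, 1] + (y == "like") * 2
  ft <- feature_table(X, y)
  specs <- lapply(c("knn", "lda"), classifier_spec, seed = 3)
  g1 <- benchmark_grid(ft, selectors = c("none", "mrmr", "pca"),
                       specs = specs, k = 4, seed = 3)
  expect_equal(nrow(g1), 3 * 2)
  expect_true(all(g1$accuracy >= 0 & g1$accuracy <= 1))
  g2 <- benchmark_grid(ft, selectors = c("none", "mrmr", "pca"),
                       specs = specs, k = 4, seed = 3)
  expect_identical(g1, g2)
  # "none" ignores k entirely: equal to a direct full-feature run
  sp <- holdout_split(ft, 0.8, seed = 3)
  direct <- train_eval(classifier_spec("lda", seed = 3), sp$train, sp$test)
  expect_equal(g1$accuracy[g1$selector == "none" & g1$classifier == "lda"],
               direct$accuracy)
  expect_error(benchmark_grid(ft, selectors = character(0)), "selector")
})

test_that("selector fitting sees only training rows (canary check)", {
  # canary = the label on test rows, pure noise on train rows: any
  # selector or standardisation leakage would lift test accuracy far
  # above chance
  set.seed(13)
  n <- 200
  y <- rep(c("like", "dislike"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, c(paste0("f", 1:9), "canary")))
  ft0 <- feature_table(X, y)
  seed <- 19
  sp <- holdout_split(ft0, 0.8, seed = seed)   # same split the grid will draw
  X[sp$test_idx, "canary"] <- as.numeric(y[sp$test_idx] == "like")
  ft <- feature_table(X, y)
  g <- benchmark_grid(ft, selectors = c("mrmr", "relieff"),
                      specs = list(classifier_spec("lda", seed = seed)),
                      k = 3, seed = seed)
  expect_true(all(g$accuracy < 0.75))
  # the default selector fit cannot see the canary's test-fold signal,
  # whereas a fit on the full table (legacy mode) picks it up
  safe <- eegpref:::fit_selector("mrmr", sp$train, k = 1)
  expect_false("canary" %in% safe$selected)
  legacy <- eegpref:::fit_selector("mrmr", ft, k = 1)
  expect_identical(legacy$selected, "canary")
})

test_that("benchmark tables serialise as rounded and full-precision text", {
  g <- structure(data.frame(selector = "none", classifier = "lda",
                            accuracy = 0.876, recall = 0.876,
                            precision = 0.88, f_measure = 0.878),
                 class = c("benchmark_grid", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  paths <- write_benchmark(g, f)
  pct <- read.delim(paths[1])
  expect_equal(pct$accuracy, 88)
  full <- read.delim(paths[2])
  expect_equal(full$accuracy, 0.876)
})
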