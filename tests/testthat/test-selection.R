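test_that("mutual information matches direct enumeration", {
  # identical balanced binary variables carry H(y) = 1 bit
  y <- rep(c(0, 1), each = 50)
  expect_equal(mutual_info(y, y), 1)
  # hand-enumerated 2x2 joint [[40,10],[10,40]]
  x <- c(rep(0, 50), rep(1, 50))
  y2 <- c(rep(0, 40), rep(1, 10), rep(0, 10), rep(1, 40))
  hand <- 2 * 0.4 * log2(0.4 / 0.25) + 2 * 0.1 * log2(0.1 / 0.25)
  expect_equal(mutual_info(x, y2), hand, tolerance = 1e-12)
  # large-sample independence null
  set.seed(21)
  xi <- rnorm(10000)
  yi <- rep(c(0, 1), 5000)
  expect_lt(mutual_info(xi, yi), 0.01)
  expect_gte(mutual_info(xi, yi), 0)
  expect_error(mutual_info(1:3, 1:4), "length mismatch")
  expect_error(mutual_info(1:10, 1:10, n_bins = 1), "n_bins")
})

test_that("mRMR picks the most relevant feature first and defers copies", {
  set.seed(22)
  n <- 120
  y <- rep(c("like", "dislike"), each = n / 2)
  f1 <- ifelse(y == "like", 1, 0) + rnorm(n, 0, 0.3)  # informative
  f2 <- f1                                            # exact copy
  f3 <- ifelse(y == "like", 1, 0) + rnorm(n, 0, 1.5)  # weak, independent noise
  ft <- feature_table(cbind(f1 = f1, f2 = f2, f3 = f3), y)
  for (scheme in c("MID", "MIQ")) {
    res <- mrmr_rank(ft, k = 3, scheme = scheme)
    expect_identical(res$selected, c("f1", "f3", "f2"), info = scheme)
  }
  # first pick is always the relevance argmax
  y01 <- as.numeric(y == "like")
  rels <- apply(ft$matrix, 2, mutual_info, y = y01, discretize_y = FALSE)
  expect_identical(mrmr_rank(ft, k = 1)$selected, names(which.max(rels)))
  expect_warning(mrmr_rank(ft, k = 10), "clamped")
})

test_that("mRMR equals an exhaustive greedy-criterion enumeration", {
  set.seed(23)
  n <- 60
  y <- sample(rep(c("like", "dislike"), each = n / 2))
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  X[, 2] <- X[, 2] + (y == "like") * 1.2
  X[, 4] <- X[, 2] + rnorm(n, 0, 0.2)
  ft <- feature_table(X, y)
  for (scheme in c("MID", "MIQ"))
    expect_identical(mrmr_rank(ft, k = 5, scheme = scheme)$selected,
                     oracle_mrmr(X, y, 5, scheme), info = scheme)
})

test_that("ReliefF weights match direct formula evaluation", {
  set.seed(24)
  n <- 20
  y <- rep(c("like", "dislike"), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("r", 1:4)))
  X[, 1] <- X[, 1] + (y == "like") * 2
  ft <- feature_table(X, y)
  res <- relieff_rank(ft, k = 4, n_neighbors = 3)
  expect_equal(unname(attr(res, "weights")),
               unname(oracle_relieff(X, y, 3)), tolerance = 1e-12)
  expect_true(all(abs(attr(res, "weights")) <= 1))
  expect_error(relieff_rank(ft, k = 2, n_neighbors = 10), "n_neighbors")
})

test_that("ReliefF ranks a separating feature first, is affine-invariant,
           and zeroes constant features", {
  set.seed(25)
  n <- 100
  y <- rep(c("like", "dislike"), each = n / 2)
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("v", 1:8)))
  X[, 3] <- ifelse(y == "like", 1, -1)   # perfect separator
  X[, 7] <- 5                            # constant
  ft <- feature_table(X, y)
  res <- relieff_rank(ft, k = 8, n_neighbors = 10)
  expect_identical(res$selected[1], "v3")
  expect_equal(unname(attr(res, "weights")["v7"]), 0)
  # positive and negative affine rescalings leave weights unchanged
  X2 <- X; X2[, 3] <- 100 * X[, 3] + 7; X2[, 1] <- -3 * X[, 1] + 1
  res2 <- relieff_rank(feature_table(X2, y), k = 8, n_neighbors = 10)
  expect_equal(attr(res2, "weights"), attr(res, "weights"),
               tolerance = 1e-10)
})

test_that("random-forest importances are normalised, deterministic and
           permutation-invariant", {
  set.seed(26)
  n <- 80
  y <- rep(c("like", "dislike"), each = n / 2)
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, c("signal", paste0("n", 1:20))))
  X[, "signal"] <- X[, "signal"] + (y == "like") * 2
  ft <- feature_table(X, y)
  imp <- rf_importance(ft, n_trees = 200, seed = 4)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_identical(names(which.max(imp)), "signal")
  expect_equal(rf_importance(ft, n_trees = 200, seed = 4), imp)
  perm <- sample(n)
  ftp <- feature_table(X[perm, ], y[perm])
  expect_equal(rf_importance(ftp, n_trees = 200, seed = 4), imp)
  expect_error(rf_importance(feature_table(X, rep("like", n))),
               "single-class")
})

test_that("recursive elimination keeps the requested count and the signal", {
  set.seed(27)
  n <- 90
  y <- rep(c("like", "dislike"), each = n / 2)
  X <- matrix(rnorm(n * 32), n, 32,
              dimnames = list(NULL, c("s1", "s2", paste0("n", 1:30))))
  X[, "s1"] <- X[, "s1"] + (y == "like") * 2
  X[, "s2"] <- X[, "s2"] - (y == "like") * 2
  ft <- feature_table(X, y)
  # identity when nothing must be eliminated
  all_kept <- rfe_select(ft, n_select = 32, n_trees = 100, seed = 1)
  expect_setequal(all_kept$selected, colnames(X))
  hits <- 0
  for (s in 1:10) {
    surv <- rfe_select(ft, n_select = 5, n_trees = 100, seed = s)$selected
    if (all(c("s1", "s2") %in% surv)) hits <- hits + 1
  }
  expect_gte(hits, 9)
  expect_error(rfe_select(ft, n_select = 0), "n_select")
})

test_that("PCA scores, ordering and loadings are correct", {
  set.seed(28)
  X <- matrix(rnorm(40 * 6), 40, 6)
  ft <- feature_table(X, rep(c("like", "dislike"), 20))
  p <- pca_transform(ft, 3)
  evr <- p$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-9)
  # rank-1 data: one component explains everything
  r1 <- outer(rnorm(30), rnorm(4))
  pr <- pca_transform(feature_table(r1, rep(c("a", "b"), 15)), 2)
  expect_gte(pr$explained_variance_ratio[1], 0.9999)
  # 4x2 toy matrix against the closed-form 2x2 eigenproblem
  toy <- matrix(c(0, 1, 3, 4,
                  0, 2, 1, 3), ncol = 2)
  ftt <- feature_table(toy, c("a", "b", "a", "b"))
  S <- stats::cov(scale(toy, scale = FALSE))
  tr <- S[1, 1] + S[2, 2]; det_ <- S[1, 1] * S[2, 2] - S[1, 2]^2
  lam1 <- (tr + sqrt(tr^2 - 4 * det_)) / 2
  v <- c(S[1, 2], lam1 - S[1, 1]); v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  pt <- pca_transform(ftt, 1)
  expect_equal(unname(pt$rotation[, 1]), v, tolerance = 1e-9)
  expect_equal(pt$explained_variance_ratio[1], lam1 / tr, tolerance = 1e-9)
  expect_error(pca_transform(ftt, 0), "n_components")
})

test_that("selection results serialise to delimited text", {
  res <- selection_result("demo", c("a", "b"), c(0.5, 0.2), 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_selection(res, f)
  back <- read.delim(f)
  expect_equal(back$feature, c("a", "b"))
  expect_equal(back$rank, 1:2)
  expect_error(selection_result("demo", c("a", "a"), c(1, 2), 2))
})
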