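CLASSIFIER_KINDS <- c("knn", "rf", "lda", "svm_rbf", "mlp_hinge")
SELECTOR_KINDS <- c("none", "mrmr", "relieff", "rfe", "importance", "pca")

#' Classifier specification
#'
#' Defaults follow the benchmark configuration: 1-nearest neighbour,
#' 500-tree random forest, single-discriminant LDA, radial-kernel SVM,
#' and a multilayer perceptron trained with the hinge loss on +/-1
#' labels (two hidden layers of 64 and 32 rectified units).
#'
#' @param kind One of \code{"knn"}, \code{"rf"}, \code{"lda"},
#'   \code{"svm_rbf"}, \code{"mlp_hinge"}.
#' @param seed Integer seed controlling any fit randomness.
#' @param ... Kind-specific overrides: \code{k} (knn), \code{n_trees}
#'   (rf), \code{hidden}, \code{epochs}, \code{learning_rate} (mlp).
#' @return An object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(kind = CLASSIFIER_KINDS, seed = 1L, ...) {
  kind <- match.arg(kind)
  hp <- switch(kind,
    knn = list(k = 1),
    rf = list(n_trees = 500),
    lda = list(n_components = 1),
    svm_rbf = list(),
    mlp_hinge = list(hidden = c(64, 32), epochs = 200, learning_rate = 0.01))
  dots <- list(...)
  hp[names(dots)] <- dots
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("Classifier: %s (%s)\n", x$kind,
              paste(names(x$hyperparameters), x$hyperparameters,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Stratified holdout split
#'
#' Shuffles within each class and assigns \code{round((1 - train_fraction)
#' * n_class)} trials (at least one) to the test fold, so class
#' proportions in both folds are within one trial of the full table.
#' With \code{by_subject = TRUE} whole subjects are assigned to folds
#' instead (no subject appears in both folds).
#'
#' @param table A \code{feature_table}.
#' @param train_fraction Proportion of trials to train on (default 0.8).
#' @param seed Integer seed.
#' @param by_subject Split at the subject level instead of the trial
#'   level.
#' @return List with \code{train} and \code{test} feature tables and the
#'   integer row indices \code{train_idx}, \code{test_idx}.
#' @export
holdout_split <- function(table, train_fraction = 0.8, seed = 1L,
                          by_subject = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  set.seed(seed)
  if (by_subject) {
    subj <- unique(table$subject)
    n_test <- max(1, round((1 - train_fraction) * length(subj)))
    test_subj <- sample(subj, n_test)
    test_idx <- which(table$subject %in% test_subj)
  } else {
    test_idx <- integer(0)
    for (cl in sort(unique(table$labels))) {
      rows <- which(table$labels == cl)
      n_test <- max(1, round((1 - train_fraction) * length(rows)))
      test_idx <- c(test_idx, sample(rows, n_test))
    }
    test_idx <- sort(test_idx)
  }
  train_idx <- setdiff(seq_len(nrow(table$matrix)), test_idx)
  list(train = subset_table(table, train_idx),
       test = subset_table(table, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' Rows are truth, columns are predictions. Accuracy is the trace over
#' the total; precision, recall and the F-measure are per-class values
#' aggregated with class-frequency weights (under which weighted recall
#' equals accuracy), and the F-measure is the harmonic mean of the
#' aggregated precision and recall.
#'
#' @param cm 2x2 numeric matrix of counts, classes in identical row and
#'   column order.
#' @return Named list: \code{accuracy}, \code{recall}, \code{precision},
#'   \code{f_measure}, all in [0, 1].
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (any(cm < 0) || sum(cm) == 0) stop("confusion matrix must hold counts")
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  w <- rowSums(cm) / total
  rec_c <- ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), 0)
  prec_c <- ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), 0)
  rec <- sum(w * rec_c)
  prec <- sum(w * prec_c)
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = acc, recall = rec, precision = prec, f_measure = f)
}

# ---- hinge-loss multilayer perceptron -------------------------------------

# Forward pass; returns activations for backprop.
mlp_forward <- function(params, X) {
  a <- list(X)
  n_layers <- length(params$W)
  for (l in seq_len(n_layers)) {
    z <- a[[l]] %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(a[[l]]), length(params$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- if (l < n_layers) pmax(z, 0) else z
  }
  a
}

# Full-batch Adam on the mean hinge loss max(0, 1 - y f(x)), y in {-1, +1}.
mlp_fit <- function(X, y_pm, hidden = c(64, 32), epochs = 200,
                    learning_rate = 0.01, seed = 1L, patience = 20,
                    tol = 1e-5) {
  set.seed(seed)
  sizes <- c(ncol(X), hidden, 1)
  params <- list(W = list(), b = list())
  for (l in seq_len(length(sizes) - 1)) {
    params$W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                         sd = sqrt(2 / sizes[l])),
                            sizes[l], sizes[l + 1])
    params$b[[l]] <- numeric(sizes[l + 1])
  }
  mW <- lapply(params$W, function(w) w * 0); vW <- mW
  mb <- lapply(params$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  best <- Inf; stall <- 0L
  for (ep in seq_len(epochs)) {
    a <- mlp_forward(params, X)
    f <- a[[length(a)]][, 1]
    margin <- 1 - y_pm * f
    loss <- mean(pmax(margin, 0))
    if (loss < best - tol) { best <- loss; stall <- 0L } else stall <- stall + 1L
    if (loss == 0 || stall >= patience) break
    # backprop
    dL <- matrix(ifelse(margin > 0, -y_pm, 0) / n, ncol = 1)
    grads_W <- vector("list", length(params$W))
    grads_b <- vector("list", length(params$b))
    delta <- dL
    for (l in rev(seq_along(params$W))) {
      grads_W[[l]] <- t(a[[l]]) %*% delta
      grads_b[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(params$W[[l]])) * (a[[l]] > 0)
    }
    for (l in seq_along(params$W)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * grads_W[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * grads_W[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * grads_b[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * grads_b[[l]]^2
      mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
      mhb <- mb[[l]] / (1 - beta1^ep); vhb <- vb[[l]] / (1 - beta2^ep)
      params$W[[l]] <- params$W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
      params$b[[l]] <- params$b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
    }
  }
  params
}

mlp_predict <- function(params, X) {
  f <- mlp_forward(params, X)[[length(params$W) + 1]][, 1]
  ifelse(f >= 0, 1, -1)
}

# ---------------------------------------------------------------------------

#' Train one classifier and evaluate it on a test fold
#'
#' Features are z-scored using training-fold statistics only (the random
#' forest, being scale-invariant, is exempt); the classifier is fitted on
#' the training fold and evaluated on the test fold. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec A \code{classifier_spec}.
#' @param train,test \code{feature_table}s sharing feature names.
#' @return A list: \code{selector} (NA here), \code{classifier}, the four
#'   metrics of \code{\link{metrics_from_confusion}}, and the confusion
#'   matrix as attribute \code{"confusion"}.
#' @export
train_eval <- function(spec, train, test) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "feature_table"),
            inherits(test, "feature_table"))
  if (!identical(train$feature_names, test$feature_names))
    stop("train and test feature names differ")
  if (length(unique(train$labels)) < 2) stop("single-class training fold")
  cls <- sort(unique(c(train$labels, test$labels)))
  Xtr <- train$matrix; Xte <- test$matrix
  if (spec$kind != "rf") {
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  }
  ytr <- factor(train$labels, levels = cls)
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  pred <- switch(spec$kind,
    knn = as.character(class::knn(Xtr, Xte, ytr, k = hp$k)),
    lda = {
      fit <- MASS::lda(Xtr, grouping = ytr)
      as.character(stats::predict(fit, Xte)$class)
    },
    svm_rbf = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", scale = FALSE)
      as.character(stats::predict(fit, Xte))
    },
    rf = {
      df <- as.data.frame(Xtr); names(df) <- sprintf("f%05d", seq_len(ncol(df)))
      df$.y <- ytr
      fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                            num.trees = hp$n_trees, seed = spec$seed,
                            num.threads = 1)
      dfe <- as.data.frame(Xte); names(dfe) <- sprintf("f%05d", seq_len(ncol(dfe)))
      as.character(stats::predict(fit, dfe)$predictions)
    },
    mlp_hinge = {
      y_pm <- ifelse(ytr == cls[2], 1, -1)
      params <- mlp_fit(Xtr, y_pm, hidden = hp$hidden, epochs = hp$epochs,
                        learning_rate = hp$learning_rate, seed = spec$seed)
      ifelse(mlp_predict(params, Xte) == 1, cls[2], cls[1])
    })
  truth <- factor(test$labels, levels = cls)
  pred <- factor(pred, levels = cls)
  cm <- table(truth, pred)
  out <- c(list(selector = NA_character_, classifier = spec$kind),
           metrics_from_confusion(cm))
  attr(out, "confusion") <- cm
  out
}

# Fit a selector on the training fold only; return a function mapping any
# feature table with the same columns into the selected feature space.
fit_selector <- function(name, train, k = 10, pca_components = 1,
                         seed = 1L) {
  name <- match.arg(name, SELECTOR_KINDS)
  k <- min(k, ncol(train$matrix))
  switch(name,
    none = list(transform = identity, selected = train$feature_names),
    mrmr = {
      res <- mrmr_rank(train, k = k)
      list(transform = function(ft) subset_table(ft, features = res$selected),
           selected = res$selected)
    },
    relieff = {
      nn <- min(10, min(table(train$labels)) - 1)
      res <- relieff_rank(train, k = k, n_neighbors = nn)
      list(transform = function(ft) subset_table(ft, features = res$selected),
           selected = res$selected)
    },
    rfe = {
      res <- rfe_select(train, n_select = k, seed = seed)
      list(transform = function(ft) subset_table(ft, features = res$selected),
           selected = res$selected)
    },
    importance = {
      imp <- rf_importance(train, seed = seed)
      sel <- names(sort(imp, decreasing = TRUE))[seq_len(k)]
      list(transform = function(ft) subset_table(ft, features = sel),
           selected = sel)
    },
    pca = {
      fitp <- pca_transform(train, n_components = pca_components)
      list(transform = function(ft) {
        sc <- sweep(ft$matrix, 2, fitp$center) %*% fitp$rotation
        colnames(sc) <- colnames(fitp$rotation)
        feature_table(sc, ft$labels, ft$subject, ft$trial)
      }, selected = colnames(fitp$rotation))
    })
}

#' Selector x classifier benchmark grid
#'
#' For every selector (including \code{"none"}) crossed with every
#' classifier, performs one stratified 80/20 holdout evaluation and
#' returns one metric row per combination. By default selectors are
#' fitted on the training fold only and then applied to both folds
#' (leakage-safe); \code{legacy_mode = TRUE} instead fits each selector
#' on the full table before splitting, mirroring pipelines that select
#' features ahead of validation.
#'
#' @param table A \code{feature_table}.
#' @param selectors Character vector from \code{"none"}, \code{"mrmr"},
#'   \code{"relieff"}, \code{"rfe"}, \code{"importance"}, \code{"pca"}.
#' @param specs List of \code{classifier_spec}s (default: all five kinds).
#' @param k Features kept by the name-selecting methods (default 10).
#' @param pca_components Components kept by PCA (default 1).
#' @param train_fraction Train proportion (default 0.8).
#' @param seed Master seed; the split and all fits derive from it.
#' @param legacy_mode Fit selectors on the full table before splitting.
#' @param by_subject Split at the subject level.
#' @return A \code{benchmark_grid} data frame with columns
#'   \code{selector}, \code{classifier}, \code{accuracy}, \code{recall},
#'   \code{precision}, \code{f_measure}.
#' @export
benchmark_grid <- function(table,
                           selectors = SELECTOR_KINDS,
                           specs = NULL,
                           k = 10, pca_components = 1,
                           train_fraction = 0.8, seed = 1L,
                           legacy_mode = FALSE, by_subject = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (length(selectors) == 0) stop("empty selector list")
  selectors <- match.arg(selectors, SELECTOR_KINDS, several.ok = TRUE)
  if (is.null(specs))
    specs <- lapply(CLASSIFIER_KINDS, classifier_spec, seed = seed)
  if (length(specs) == 0) stop("empty classifier list")
  split <- holdout_split(table, train_fraction, seed = seed,
                         by_subject = by_subject)
  rows <- list()
  for (s_i in seq_along(selectors)) {
    sname <- selectors[s_i]
    sel_seed <- seed + 1000L * s_i
    sel <- fit_selector(sname,
                        if (legacy_mode) table else split$train,
                        k = k, pca_components = pca_components,
                        seed = sel_seed)
    tr <- sel$transform(split$train)
    te <- sel$transform(split$test)
    for (spec in specs) {
      r <- train_eval(spec, tr, te)
      r$selector <- sname
      rows[[length(rows) + 1]] <-
        data.frame(selector = sname, classifier = r$classifier,
                   accuracy = r$accuracy, recall = r$recall,
                   precision = r$precision, f_measure = r$f_measure)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_grid", "data.frame")
  out
}

#' @export
print.benchmark_grid <- function(x, ...) {
  cat("Selector x classifier holdout benchmark\n")
  y <- as.data.frame(x)
  y[, 3:6] <- round(100 * y[, 3:6], 1)
  names(y)[3:6] <- paste0(names(y)[3:6], "_pct")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark grid as delimited text
#'
#' Writes two tab-separated files: \code{file} with metrics as rounded
#' percentages (0 decimal places) and \code{full_file} (default:
#' \code{file} with a \code{_full} suffix) at full precision.
#'
#' @param grid A \code{benchmark_grid}.
#' @param file Output path for the percentage table.
#' @param full_file Output path for the full-precision table.
#' @return Invisibly, the two paths.
#' @export
write_benchmark <- function(grid, file,
                            full_file = sub("(\\.[^.]*)?$", "_full\\1",
                                            file)) {
  pct <- as.data.frame(grid)
  pct[, 3:6] <- round(100 * pct[, 3:6])
  utils::write.table(pct, file, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(grid), full_file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(file, full_file))
}
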