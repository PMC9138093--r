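#' Trials-by-features table with binary labels
#'
#' The common container passed between extraction, selection and
#' classification. Labels are the two preference states; internally
#' "like" is treated as the positive class.
#'
#' @param matrix Numeric matrix, one row per trial, named columns.
#' @param labels Character or factor vector, one entry per row, with at
#'   most two distinct values.
#' @param subject,trial Optional per-row metadata vectors.
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(matrix, labels, subject = NULL, trial = NULL) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix)))
    colnames(matrix) <- sprintf("f%03d", seq_len(ncol(matrix)))
  if (anyDuplicated(colnames(matrix))) stop("feature names must be unique")
  if (nrow(matrix) != length(labels))
    stop("row count and label count differ")
  if (!all(is.finite(matrix))) stop("feature values must be finite")
  labels <- as.character(labels)
  if (length(unique(labels)) > 2) stop("labels must be binary")
  structure(list(matrix = matrix,
                 feature_names = colnames(matrix),
                 labels = labels,
                 subject = if (is.null(subject)) rep(NA_integer_, nrow(matrix)) else subject,
                 trial = if (is.null(trial)) rep(NA_integer_, nrow(matrix)) else trial),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d trials x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%d %s", as.vector(table(x$labels)),
                            names(table(x$labels))), collapse = " / ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' Subset a feature table by rows and/or named features
#'
#' @param ft A \code{feature_table}.
#' @param rows Row indices to keep (default: all).
#' @param features Feature names to keep, in the given order.
#' @return A \code{feature_table}.
#' @export
subset_table <- function(ft, rows = NULL, features = NULL) {
  m <- ft$matrix; lab <- ft$labels; sub <- ft$subject; tr <- ft$trial
  if (!is.null(rows)) {
    m <- m[rows, , drop = FALSE]; lab <- lab[rows]
    sub <- sub[rows]; tr <- tr[rows]
  }
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  feature_table(m, lab, sub, tr)
}

# Label vector as 0/1 numeric ("like" = 1; otherwise alphabetical order).
binary_labels <- function(labels) {
  u <- sort(unique(labels))
  pos <- if ("like" %in% u) "like" else u[length(u)]
  as.numeric(labels == pos)
}

# Equal-frequency discretisation into at most n_bins levels. An input
# with n_bins or fewer distinct values (e.g. a binary feature) keeps its
# natural levels; otherwise quantile breaks are used, deduplicated when
# heavy ties collapse them.
discretize_ef <- function(x, n_bins = 3) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (length(unique(x)) <= n_bins) return(as.integer(factor(x)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Mutual information between a feature and a target
#'
#' Plug-in estimate in bits. A continuous input is discretised by
#' equal-frequency binning (default 3 bins); the joint distribution is
#' the empirical cell-frequency table and
#' MI = sum p(a,b) log2 p(a,b) / (p(a) p(b)), skipping empty cells.
#'
#' @param x Numeric vector (feature).
#' @param y Vector of the same length (class label or second feature).
#' @param n_bins Bins for discretising continuous inputs (default 3).
#' @param discretize_y Should \code{y} also be binned? Set \code{FALSE}
#'   when \code{y} is already categorical (the default treats any input
#'   with more than \code{n_bins} distinct values as continuous).
#' @return Non-negative scalar, bits.
#' @examples
#' y <- rep(0:1, each = 50)
#' mutual_info(y + 0, y)  # 1 bit: identical balanced binary variables
#' @export
mutual_info <- function(x, y, n_bins = 3, discretize_y = NULL) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  xb <- discretize_ef(as.numeric(x), n_bins)
  yn <- if (is.character(y) || is.factor(y)) as.integer(factor(y)) else as.numeric(y)
  do_y <- if (is.null(discretize_y)) length(unique(yn)) > n_bins else discretize_y
  yb <- if (do_y) discretize_ef(yn, n_bins) else as.integer(factor(yn))
  joint <- table(xb, yb) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  max(mi, 0)
}

#' Ordered feature selection result
#'
#' @param method Method tag.
#' @param selected Feature names in selection order.
#' @param scores Criterion value per selected feature.
#' @param k Requested count.
#' @return An object of class \code{selection_result}.
#' @export
selection_result <- function(method, selected, scores, k) {
  stopifnot(length(selected) == length(scores), !anyDuplicated(selected))
  structure(list(method = method, selected = selected,
                 scores = stats::setNames(scores, selected),
                 k = as.integer(k)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection (%s), %d feature(s):\n", x$method,
              length(x$selected)))
  for (i in seq_along(x$selected))
    cat(sprintf("  %2d. %-20s %+.5f\n", i, x$selected[i], x$scores[i]))
  invisible(x)
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward selection under the mutual-information criterion. The
#' first pick maximises relevance I(x; y); each later pick maximises
#' either the difference I(x; y) - mean_b I(x; x_b) (\code{scheme = "MID"})
#' or the quotient I(x; y) / mean_b I(x; x_b) (\code{scheme = "MIQ"}, the
#' default) over features already chosen. Ties break on ascending feature
#' index, and pairwise feature MI values are cached across steps.
#'
#' @param table A \code{feature_table}.
#' @param k Number of features to select (clamped, with a warning, to the
#'   feature count).
#' @param scheme \code{"MIQ"} (quotient) or \code{"MID"} (difference).
#' @param n_bins Discretisation bins for the MI estimates.
#' @return A \code{selection_result}; scores are the criterion values at
#'   the step each feature was picked.
#' @export
mrmr_rank <- function(table, k = 10, scheme = c("MIQ", "MID"), n_bins = 3) {
  stopifnot(inherits(table, "feature_table"), k >= 1)
  scheme <- match.arg(scheme)
  p <- ncol(table$matrix)
  if (p < 2) stop("need at least 2 features")
  if (k > p) {
    warning("k exceeds feature count; clamped to ", p)
    k <- p
  }
  y <- binary_labels(table$labels)
  rel <- vapply(seq_len(p), function(j)
    mutual_info(table$matrix[, j], y, n_bins, discretize_y = FALSE),
    numeric(1))
  pair_mi <- matrix(NA_real_, p, p)   # cache of feature-feature MI
  sel <- integer(0)
  scores <- numeric(0)
  avail <- seq_len(p)
  for (step in seq_len(k)) {
    if (step == 1) {
      crit <- rel[avail]
    } else {
      red <- vapply(avail, function(a) {
        mis <- vapply(sel, function(b) {
          if (is.na(pair_mi[a, b])) {
            v <- mutual_info(table$matrix[, a], table$matrix[, b], n_bins,
                             discretize_y = TRUE)
            pair_mi[a, b] <<- v; pair_mi[b, a] <<- v
          }
          pair_mi[a, b]
        }, numeric(1))
        mean(mis)
      }, numeric(1))
      crit <- if (scheme == "MID") rel[avail] - red
              else rel[avail] / pmax(red, .Machine$double.eps)
    }
    best <- avail[which.max(crit)]   # which.max takes the first => index tie-break
    scores <- c(scores, max(crit))
    sel <- c(sel, best)
    avail <- setdiff(avail, best)
  }
  selection_result(paste0("mrmr_", tolower(scheme)),
                   table$feature_names[sel], scores, k)
}

#' ReliefF feature weighting
#'
#' Instance-based weighting: every instance contributes its
#' \code{n_neighbors} nearest same-class hits and, per other class, its
#' nearest misses weighted by the class prior. Features are min-max
#' normalised internally; neighbour search uses the Manhattan metric on
#' the normalised features; all instances are used (no sampling). Weights
#' lie in [-1, 1]; a constant feature gets exactly 0.
#'
#' @param table A \code{feature_table}.
#' @param k Number of top-weighted features to return.
#' @param n_neighbors Nearest hits/misses per instance (default 10).
#' @return A \code{selection_result}; scores are the ReliefF weights. The
#'   full weight vector is attached as attribute \code{"weights"}.
#' @export
relieff_rank <- function(table, k = 10, n_neighbors = 10) {
  stopifnot(inherits(table, "feature_table"), k >= 1)
  X <- table$matrix
  n <- nrow(X); p <- ncol(X)
  k <- min(k, p)
  lab <- table$labels
  cls <- sort(unique(lab))
  cnt <- table(lab)
  if (any(cnt <= n_neighbors))
    stop("every class needs more than n_neighbors members")
  # min-max normalisation; constant features stay 0 so diff() is 0
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  Xn <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  # full Manhattan distance matrix
  D <- matrix(0, n, n)
  for (j in seq_len(p)) D <- D + abs(outer(Xn[, j], Xn[, j], "-"))
  diag(D) <- Inf
  prior <- as.numeric(cnt) / n
  names(prior) <- names(cnt)
  W <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(lab == lab[i])
    hits <- same[order(D[i, same])[seq_len(n_neighbors)]]
    W <- W - colSums(abs(Xn[hits, , drop = FALSE] -
                         matrix(Xn[i, ], n_neighbors, p, byrow = TRUE))) /
      (n * n_neighbors)
    for (cl in setdiff(cls, lab[i])) {
      oth <- which(lab == cl)
      miss <- oth[order(D[i, oth])[seq_len(n_neighbors)]]
      wcl <- prior[[cl]] / (1 - prior[[lab[i]]])
      W <- W + wcl * colSums(abs(Xn[miss, , drop = FALSE] -
                                 matrix(Xn[i, ], n_neighbors, p, byrow = TRUE))) /
        (n * n_neighbors)
    }
  }
  names(W) <- table$feature_names
  ord <- order(-W, seq_len(p))   # descending weight, index tie-break
  top <- ord[seq_len(k)]
  res <- selection_result("relieff", table$feature_names[top], W[top], k)
  attr(res, "weights") <- W
  res
}

#' Random-forest impurity importance
#'
#' Gini impurity-decrease importances from a random forest (default 500
#' trees), normalised to sum to one. Rows are put in a canonical order
#' (sorted by label then feature values) before fitting, so the scores
#' are deterministic given (table, seed) and invariant to row
#' permutations of the input.
#'
#' @param table A \code{feature_table}.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed for the forest.
#' @return Named numeric vector of importances summing to 1.
#' @export
rf_importance <- function(table, n_trees = 500, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$labels)) < 2) stop("labels are single-class")
  ord <- do.call(order, c(list(table$labels),
                          lapply(seq_len(ncol(table$matrix)),
                                 function(j) table$matrix[, j])))
  df <- as.data.frame(table$matrix[ord, , drop = FALSE])
  safe_names <- sprintf("f%05d", seq_len(ncol(df)))
  names(df) <- safe_names
  df$.y <- factor(table$labels[ord])
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = n_trees, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance[safe_names]
  imp[is.na(imp)] <- 0
  imp <- pmax(imp, 0)
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  stats::setNames(as.numeric(imp), table$feature_names)
}

#' Recursive feature elimination with a random-forest ranker
#'
#' Repeatedly fits \code{\link{rf_importance}} on the surviving features
#' and drops the lowest-importance \code{ceiling(step_fraction * remaining)}
#' until \code{n_select} remain (default 10). Survivors are returned
#' ranked by their importance in the final fit.
#'
#' @param table A \code{feature_table}.
#' @param n_select Number of features to keep (default 10).
#' @param step_fraction Fraction eliminated per iteration (default 0.1).
#' @param n_trees Trees per forest fit.
#' @param seed Integer seed.
#' @return A \code{selection_result}; scores are final-fit importances.
#' @export
rfe_select <- function(table, n_select = 10, step_fraction = 0.1,
                       n_trees = 500, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (n_select < 1) stop("n_select must be >= 1")
  p <- ncol(table$matrix)
  if (n_select > p) stop("n_select exceeds feature count")
  surv <- table$feature_names
  cur <- table
  iter <- 0L
  while (length(surv) > n_select) {
    iter <- iter + 1L
    imp <- rf_importance(cur, n_trees = n_trees, seed = seed + iter)
    n_drop <- min(ceiling(step_fraction * length(surv)),
                  length(surv) - n_select)
    drop_idx <- order(imp, seq_along(imp))[seq_len(n_drop)]
    surv <- surv[-drop_idx]
    cur <- subset_table(table, features = surv)
  }
  final_imp <- rf_importance(cur, n_trees = n_trees, seed = seed)
  ord <- order(-final_imp, seq_along(final_imp))
  selection_result("rf_rfe", surv[ord], final_imp[ord], n_select)
}

#' Principal component transform
#'
#' Mean-centres the columns and projects onto the leading eigenvectors of
#' the covariance matrix. Used here as an unsupervised dimensionality
#' reducer whose scores feed the classifiers directly (it does not select
#' original feature names). Sign convention: within each component the
#' largest-magnitude loading is positive.
#'
#' @param table A \code{feature_table}.
#' @param n_components Number of components to keep.
#' @return List with \code{table} (a \code{feature_table} of component
#'   scores named PC1, PC2, ...), \code{rotation}, \code{center} and
#'   \code{explained_variance_ratio} (non-increasing, sums to <= 1).
#' @export
pca_transform <- function(table, n_components) {
  stopifnot(inherits(table, "feature_table"))
  if (n_components < 1) stop("n_components must be >= 1")
  n_components <- as.integer(min(n_components, nrow(table$matrix),
                                 ncol(table$matrix)))
  pc <- stats::prcomp(table$matrix, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest |loading| positive
  for (j in seq_len(ncol(rot))) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(table$matrix, 2, pc$center) %*% rot
  colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(table = feature_table(scores, table$labels, table$subject,
                             table$trial),
       rotation = rot, center = pc$center,
       explained_variance_ratio = evr[seq_len(n_components)])
}

#' Write a selection result as delimited text
#'
#' Columns: rank, feature, score, method.
#'
#' @param res A \code{selection_result}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_selection <- function(res, file) {
  stopifnot(inherits(res, "selection_result"))
  utils::write.table(
    data.frame(rank = seq_along(res$selected), feature = res$selected,
               score = as.numeric(res$scores), method = res$method),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
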