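#' One-way ANOVA F statistic per feature
#'
#' For each feature, the between-group mean square over the within-group
#' mean square across the two preference classes (computed vectorised
#' over features; for two groups F equals the squared pooled-variance t
#' statistic).
#'
#' @param table A \code{feature_table} with at least 2 trials per class.
#' @return Named numeric vector of F statistics (>= 0).
#' @export
anova_f <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  lab <- table$labels
  cls <- unique(lab)
  if (length(cls) < 2) stop("need both classes")
  if (any(table(lab) < 2)) stop("each class needs at least 2 trials")
  X <- table$matrix
  n <- nrow(X)
  gm <- colMeans(X)
  ss_between <- numeric(ncol(X))
  ss_within <- numeric(ncol(X))
  for (cl in cls) {
    Xc <- X[lab == cl, , drop = FALSE]
    nc <- nrow(Xc)
    mc <- colMeans(Xc)
    ss_between <- ss_between + nc * (mc - gm)^2
    ss_within <- ss_within + colSums(sweep(Xc, 2, mc)^2)
  }
  df1 <- length(cls) - 1
  df2 <- n - length(cls)
  f <- (ss_between / df1) / (ss_within / df2)
  f[ss_within == 0 & ss_between == 0] <- 0
  stats::setNames(f, table$feature_names)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau between two numeric vectors, as needed when
#' correlating continuous features against a massively tied binary label.
#' Wraps the standard implementation in \code{stats::cor}.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Scalar in [-1, 1].
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("both inputs have zero variance")
  stats::cor(x, y, method = "kendall")
}

#' Kendall correlation matrix of top features and the class label
#'
#' Pairwise tau-b over the requested features plus the label (encoded
#' like = 1, dislike = 0); symmetric with unit diagonal. This is the
#' numeric table behind a feature-importance correlation heatmap.
#'
#' @param table A \code{feature_table}.
#' @param features Feature names to include.
#' @return A \code{correlation_matrix}: symmetric numeric matrix with a
#'   final row/column named \code{label}.
#' @export
correlation_heatmap_table <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  miss <- setdiff(features, table$feature_names)
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  M <- cbind(table$matrix[, features, drop = FALSE],
             label = binary_labels(table$labels))
  p <- ncol(M)
  out <- diag(1, p)
  dimnames(out) <- list(colnames(M), colnames(M))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    v <- suppressWarnings(stats::cor(M[, i], M[, j], method = "kendall"))
    if (is.na(v)) v <- 0   # zero-variance column
    out[i, j] <- v; out[j, i] <- v
  }
  structure(out, class = c("correlation_matrix", "matrix"))
}

#' Write a correlation matrix as delimited text
#'
#' @param cm A \code{correlation_matrix}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_correlation_matrix <- function(cm, file) {
  utils::write.table(cbind(name = rownames(cm), as.data.frame(cm)),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Heatmap of a feature correlation matrix
#'
#' Base-graphics rendering of \code{\link{correlation_heatmap_table}}.
#'
#' @param cm A \code{correlation_matrix}.
#' @param ... Passed to \code{image}.
#' @return Invisibly, \code{cm}.
#' @export
plot_correlation_heatmap <- function(cm, ...) {
  p <- ncol(cm)
  pal <- grDevices::hcl.colors(51, "Blue-Red 2")
  graphics::image(seq_len(p), seq_len(p), t(cm[p:1, ]), zlim = c(-1, 1),
                  col = pal, axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(p), labels = colnames(cm), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(p), labels = rev(rownames(cm)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(cm)
}
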