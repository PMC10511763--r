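# Agreement statistics between score vectors obtained by two routes
# (training vs validation dataset, or two normalization methods): Spearman
# correlation, regression slopes with/without intercept combined into a
# geometric-mean coefficient k, and sign-change stability curves.

#' Per-class median expression profiles
#'
#' @param matrix \code{ExpressionMatrix}.
#' @param labels Class per sample (named by sample id, or in column order).
#' @return Matrix genes x classes of per-gene medians.
#' @export
median_profiles <- function(matrix, labels) {
  if (!is.null(names(labels))) {
    unknown <- setdiff(names(labels), colnames(matrix))
    if (length(unknown))
      stop("unknown sample(s) in labels: ", paste(unknown, collapse = ", "))
    labels <- labels[colnames(matrix)]
  }
  if (length(labels) != ncol(matrix))
    stop("labels must cover every sample exactly once")
  labels <- as.factor(labels)
  x <- unclass(matrix)
  out <- vapply(levels(labels), function(cl) {
    apply(x[, labels == cl, drop = FALSE], 1, stats::median)
  }, numeric(nrow(x)))
  rownames(out) <- rownames(x)
  out
}

#' Concordance statistics between two score vectors
#'
#' Computes the Spearman correlation and the combined linear regression
#' coefficient k: k1 is the ordinary least-squares slope of
#' \code{v2 = k1 * v1 + b}, k2 the slope of the through-origin fit
#' \code{v2 = k2 * v1}, and \code{k = sign(k1) * sqrt(k1 * k2)} when
#' \code{k1 * k2 > 0}, else \code{k = 0}.
#'
#' @param v1,v2 Equal-length numeric vectors (length >= 3); \code{v1} must
#'   not be constant.
#' @return List of class \code{ConcordanceResult}: rho, k1, k2, b, k.
#' @export
concordance_stats <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("v1 and v2 must have equal length")
  if (length(v1) < 3) stop("need at least 3 components")
  if (stats::sd(v1) == 0) stop("v1 is constant: regression slope undefined")
  rho <- stats::cor(v1, v2, method = "spearman")
  k1 <- stats::cov(v1, v2) / stats::var(v1)
  b <- mean(v2) - k1 * mean(v1)
  k2 <- sum(v1 * v2) / sum(v1^2)
  k <- if (k1 * k2 > 0) sign(k1) * sqrt(k1 * k2) else 0
  structure(list(rho = rho, k1 = k1, k2 = k2, b = b, k = k),
            class = "ConcordanceResult")
}

#' Sign-change stability curve
#'
#' A component i is sign-changing at threshold width w when
#' \code{v1[i] < -w/2} and \code{v2[i] > w/2}, or vice versa.  Widths are
#' expressed in units of the median absolute value of the pooled scores
#' \code{c(v1, v2)}.  In mode "divided_by_k", v2 is replaced by v2 / k
#' before counting, compensating a global rescaling between the two routes.
#'
#' @param v1,v2 Equal-length score vectors.
#' @param w_grid Non-negative widths in median-absolute-score units.
#' @param mode "as_is" or "divided_by_k".
#' @param k Combined regression coefficient (required, non-zero, for
#'   "divided_by_k"); defaults to \code{concordance_stats(v1, v2)$k}.
#' @return List of class \code{SignChangeCurve}: w_grid, pct (percentage of
#'   sign-changed components at each width), mode, unit (the median
#'   absolute score used as width unit).
#' @export
sign_change_curve <- function(v1, v2, w_grid = seq(0, 10, by = 0.25),
                              mode = c("as_is", "divided_by_k"), k = NULL) {
  mode <- match.arg(mode)
  if (length(v1) != length(v2)) stop("v1 and v2 must have equal length")
  if (any(w_grid < 0)) stop("w_grid must be non-negative")
  unit <- stats::median(abs(c(v1, v2)))
  if (mode == "divided_by_k") {
    if (is.null(k)) k <- concordance_stats(v1, v2)$k
    if (k == 0) stop("divided_by_k mode requires a non-zero k")
    v2 <- v2 / k
  }
  pct <- vapply(w_grid, function(w) {
    half <- w * unit / 2
    flip <- (v1 < -half & v2 > half) | (v1 > half & v2 < -half)
    100 * sum(flip) / length(v1)
  }, numeric(1))
  structure(list(w_grid = w_grid, pct = pct, mode = mode, unit = unit),
            class = "SignChangeCurve")
}

#' Marker genes by two-class ROC AUC
#'
#' Per-gene rank-based AUC between two sample classes, orientation-folded as
#' \code{max(AUC, 1 - AUC)}; genes strictly above the threshold are markers.
#'
#' @param matrix \code{ExpressionMatrix}.
#' @param binary_labels Logical or two-level factor per sample.
#' @param threshold AUC cut-off (strict inequality).
#' @return Data.frame gene/auc/marker, ordered by decreasing AUC.
#' @export
marker_genes_auc <- function(matrix, binary_labels, threshold = 0.8) {
  labels <- as.factor(binary_labels)
  if (nlevels(labels) != 2) stop("binary_labels must have exactly 2 levels")
  if (length(labels) != ncol(matrix))
    stop("binary_labels must cover every sample")
  if (any(table(labels) == 0)) stop("both classes must be non-empty")
  x <- unclass(matrix)
  is_b <- labels == levels(labels)[2]
  n_a <- sum(!is_b); n_b <- sum(is_b)
  auc <- apply(x, 1, function(v) {
    r <- rank(v, ties.method = "average")
    (sum(r[is_b]) - n_b * (n_b + 1) / 2) / (n_a * n_b)
  })
  auc <- pmax(auc, 1 - auc)
  out <- data.frame(gene = rownames(x), auc = auc, marker = auc > threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$auc), ]
}
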