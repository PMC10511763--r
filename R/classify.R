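# Transfer-learning tissue classifiers: a model is trained on harmonized
# profiles from one dataset/platform and validated on another.  Feature
# space is the Euclidean space of per-gene log expression (kNN) or of 20
# principal components fitted on the training set (linear SVM).

knn_predict <- function(train, train_labels, val, k) {
  # columns are samples; ties: equally distant neighbors resolved by the
  # smallest training index, vote ties by the nearest neighbor's class
  vapply(seq_len(ncol(val)), function(i) {
    d <- sqrt(colSums((train - val[, i])^2))
    nn <- order(d)[seq_len(min(k, length(d)))]        # order() is stable
    votes <- table(train_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) top <- intersect(as.character(train_labels[nn]),
                                          top)[1]
    top
  }, character(1))
}

#' Project expression profiles onto training-set principal components
#'
#' Components are fitted on the training samples only (per-gene centering,
#' no scaling) and the validation samples are projected with the training
#' loadings, avoiding information leakage from validation to training.
#'
#' @param train,val \code{ExpressionMatrix} objects over the same genes.
#' @param n_components Number of components (<= min(n_train - 1, genes)).
#' @return List with \code{train} and \code{val} feature matrices
#'   (samples x components) and the \code{prcomp} fit.
#' @export
pca_project <- function(train, val, n_components = 20) {
  if (!identical(rownames(train), rownames(val)))
    stop("train and val must share an identical gene list")
  if (n_components > min(ncol(train) - 1, nrow(train)))
    stop("n_components = ", n_components, " exceeds min(n_train - 1, genes)")
  fit <- stats::prcomp(t(unclass(train)), center = TRUE, scale. = FALSE,
                       rank. = n_components)
  list(train = fit$x[, seq_len(n_components), drop = FALSE],
       val = stats::predict(fit, t(unclass(val)))[, seq_len(n_components),
                                                  drop = FALSE],
       fit = fit)
}

#' Transfer-learning classification accuracy
#'
#' Trains a tissue-type classifier on one dataset and reports per-class and
#' total accuracy on an independent validation dataset.  Methods: "knn1"
#' and "knn11" (majority vote among Euclidean nearest training profiles in
#' gene space) and "svm_pca20" (linear-kernel SVM, C = 1, one-vs-one
#' multiclass, on 20 training-set principal components).
#'
#' @param train,val \code{ExpressionMatrix} objects over the same genes.
#' @param train_labels,val_labels Class per sample (column order).
#' @param method "knn1", "knn11" or "svm_pca20".
#' @param seed Integer seed (SVM training is deterministic for fixed data;
#'   the seed guards any internal randomness).
#' @return List of class \code{AccuracyReport}: method, total_accuracy,
#'   per_class_accuracy, n_train, n_val, predictions.
#' @export
transfer_accuracy <- function(train, train_labels, val, val_labels,
                              method = c("knn1", "knn11", "svm_pca20"),
                              seed = 1L) {
  method <- match.arg(method)
  if (!identical(rownames(train), rownames(val)))
    stop("train and val must share an identical gene list")
  train_labels <- as.factor(train_labels)
  val_labels <- factor(val_labels)
  if (length(train_labels) != ncol(train) ||
      length(val_labels) != ncol(val))
    stop("labels must cover every sample")
  missing_cls <- setdiff(levels(val_labels), levels(train_labels))
  if (length(missing_cls))
    stop("validation class(es) absent from training: ",
         paste(missing_cls, collapse = ", "))
  pred <- if (method %in% c("knn1", "knn11")) {
    k <- if (method == "knn1") 1L else 11L
    knn_predict(unclass(train), train_labels, unclass(val), k)
  } else {
    if (ncol(train) < 21)
      stop("svm_pca20 needs >= 21 training samples")
    feats <- pca_project(train, val, n_components = 20)
    fit <- with_seed(seed,
      e1071::svm(feats$train, train_labels, kernel = "linear", cost = 1,
                 scale = FALSE))
    as.character(stats::predict(fit, feats$val))
  }
  correct <- pred == as.character(val_labels)
  per_class <- vapply(levels(val_labels), function(cl) {
    mean(correct[val_labels == cl])
  }, numeric(1))
  structure(list(method = method,
                 total_accuracy = mean(correct),
                 per_class_accuracy = per_class,
                 n_train = table(train_labels),
                 n_val = table(val_labels),
                 predictions = stats::setNames(pred, colnames(val))),
            class = "AccuracyReport")
}
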