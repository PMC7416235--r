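#' Feature construction from per-sample decompositions
#'
#' Each sample's channel vector is decomposed by circle-EMD and the feature
#' vector is assembled from selected IMFs.  Modes:
#' \describe{
#'   \item{`original`}{the raw channel vector (no decomposition).}
#'   \item{`imf`}{the k-th IMF (`which = k`); samples whose decomposition
#'     has fewer than k IMFs contribute a zero vector (counted and noted).}
#'   \item{`imf_sum`}{elementwise sum of the IMFs in `which` (missing
#'     indices contribute zeros).}
#'   \item{`all_imfs`}{sum of every IMF — the input minus its residual
#'     trend.}
#' }
#' The feature dimension always equals the channel count.
#'
#' @param dataset a `"study_dataset"` (or any samples x channels matrix).
#' @param mode one of `"original"`, `"imf"`, `"imf_sum"`, `"all_imfs"`.
#' @param which IMF index/indices (1-based) for modes `imf` / `imf_sum`.
#' @param config a [sift_config()] for the per-sample decompositions.
#' @return feature matrix (samples x channels); attribute `"n_missing"`
#'   counts samples lacking a requested IMF index.
#' @export
build_features <- function(dataset, mode = c("original", "imf", "imf_sum",
                                             "all_imfs"),
                           which = 1L, config = sift_config()) {
  mode <- match.arg(mode)
  X <- if (inherits(dataset, "study_dataset")) dataset$samples else
    as.matrix(dataset)
  if (nrow(X) == 0L) stop("dataset is empty")
  if (mode == "original") {
    attr(X, "n_missing") <- 0L
    return(X)
  }
  n_missing <- 0L
  out <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    fit <- circle_emd(X[i, ], config)
    k <- nrow(fit$imfs)
    sel <- switch(mode,
      imf = as.integer(which)[1L],
      imf_sum = as.integer(which),
      all_imfs = seq_len(k))
    present <- sel[sel <= k]
    if (length(present) < length(sel)) n_missing <- n_missing + 1L
    if (length(present))
      out[i, ] <- colSums(fit$imfs[present, , drop = FALSE])
  }
  if (n_missing > 0L)
    message(n_missing, " sample(s) lacked a requested IMF index; zeros used")
  attr(out, "n_missing") <- n_missing
  out
}

#' The three reference classifiers
#'
#' Thin, uniformly-shaped wrappers used by [run_cross_validation()]:
#' `train_svm_rbf` fits a one-vs-one C-classification SVM with the Gaussian
#' kernel `K(x1, x2) = exp(-||x1 - x2||^2 / (2 sigma^2))` with
#' `1/(2 sigma^2) = 1/d` (the libsvm default for d features), cost 1 and
#' termination tolerance 1e-3; `train_logistic` fits multinomial softmax
#' regression by maximum likelihood.  Both return objects with a standard
#' `predict` method.  The network classifier lives in [train_mlp()].
#'
#' @param x feature matrix (samples x features).
#' @param y factor of class labels (>= 2 classes).
#' @param ... passed through to the underlying fitter.
#' @return fitted model object.
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
train_svm_rbf <- function(x, y, ...) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  e1071::svm(x = as.matrix(x), y = y, type = "C-classification",
             kernel = "radial", gamma = 1 / ncol(x), cost = 1,
             tolerance = 1e-3, scale = FALSE, ...)
}

#' @rdname classifiers
#' @param max_iters iteration cap for the likelihood optimiser.
#' @export
train_logistic <- function(x, y, max_iters = 200L, ...) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  df <- data.frame(.y = y, as.data.frame(as.matrix(x)))
  nw <- (ncol(x) + 1L) * nlevels(y) + nlevels(y)
  nnet::multinom(.y ~ ., data = df, maxit = max_iters, trace = FALSE,
                 MaxNWts = max(1000L, nw + 10L), ...)
}

predict_any <- function(model, x) {
  if (inherits(model, "mlp_model")) return(predict(model, x))
  if (inherits(model, "svm")) return(predict(model, as.matrix(x)))
  ## multinom predicts from a data.frame with the training column names
  predict(model, newdata = as.data.frame(as.matrix(x)))
}

#' Classifier specification for cross-validation
#'
#' @param kind `"svm_rbf"`, `"logistic"` or `"mlp"`.
#' @param seed integer seed (controls the network's initialisation,
#'   shuffling and dropout, and makes every kind reproducible).
#' @param mlp_epochs,mlp_hidden,mlp_dropout,mlp_lr,mlp_batch_size network
#'   hyperparameters (defaults: 200 epochs, 300/200/100 units, dropout 0.5,
#'   learning rate 1e-3, batches of 32).
#' @return list of class `"classifier_spec"`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "logistic", "mlp"),
                            seed = 1L, mlp_epochs = 200L,
                            mlp_hidden = c(300L, 200L, 100L),
                            mlp_dropout = 0.5, mlp_lr = 1e-3,
                            mlp_batch_size = 32L) {
  structure(list(kind = match.arg(kind), seed = as.integer(seed),
                 mlp_epochs = as.integer(mlp_epochs),
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_dropout = mlp_dropout, mlp_lr = mlp_lr,
                 mlp_batch_size = as.integer(mlp_batch_size)),
            class = "classifier_spec")
}

train_classifier <- function(spec, x, y) {
  set.seed(spec$seed)
  switch(spec$kind,
    svm_rbf = train_svm_rbf(x, y),
    logistic = train_logistic(x, y),
    mlp = train_mlp(x, y, hidden = spec$mlp_hidden,
                    dropout = spec$mlp_dropout,
                    batch_size = spec$mlp_batch_size,
                    epochs = spec$mlp_epochs, lr = spec$mlp_lr,
                    seed = spec$seed))
}

#' Weighted precision, recall and F1 from a confusion matrix
#'
#' Rows are true classes, columns predictions.  Per-class precision,
#' recall and F1 are averaged with weights proportional to true-class
#' support; an empty predicted column contributes precision 0 with a
#' warning.  For balanced classes the weighted and macro averages coincide,
#' and weighted recall equals pooled accuracy.
#'
#' @param confusion square nonnegative count matrix.
#' @return list: `accuracy`, `precision`, `recall`, `f1` (weighted), and
#'   the `per_class` table.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0))
    stop("confusion must be a square nonnegative count matrix")
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is all zero")
  support <- rowSums(confusion)
  pred_tot <- colSums(confusion)
  tp <- diag(confusion)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  if (any(pred_tot == 0))
    warning("some class was never predicted; its precision counts as 0")
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / total
  list(accuracy = sum(tp) / total,
       precision = sum(w * precision),
       recall = sum(w * recall),
       f1 = sum(w * f1),
       per_class = data.frame(class = rownames(confusion) %||%
                                paste0("class", seq_along(tp)),
                              support = support, precision = precision,
                              recall = recall, f1 = f1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run-wise 10-fold cross-validation
#'
#' The folds are the acquisition runs: each fold trains on the samples of
#' all other runs and tests on one held-out run, cycling through every run
#' (with the canonical 10-run design: 216 training and 24 test samples per
#' fold).  Reports per-fold accuracy, the pooled confusion matrix and
#' weighted precision/recall/F1.  Deterministic given the seed in the
#' classifier specification.
#'
#' @param features feature matrix (samples x features).
#' @param labels factor of class labels per sample.
#' @param run_id fold-defining run identifier per sample.
#' @param spec a [classifier_spec()].
#' @return object of class `"cv_report"`: `per_fold_accuracy` (named by
#'   run), `mean_accuracy`, `confusion` (true x predicted, pooled over
#'   folds), `precision`, `recall`, `f1`, `spec`.
#' @export
run_cross_validation <- function(features, labels, run_id, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  if (nrow(features) != length(labels) || length(labels) != length(run_id))
    stop("features, labels and run_id must agree in length")
  folds <- sort(unique(run_id))
  if (length(folds) < 2L) stop("cross-validation needs at least 2 runs")
  lev <- levels(labels)
  confusion <- matrix(0L, length(lev), length(lev),
                      dimnames = list(true = lev, predicted = lev))
  per_fold <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    test <- run_id == folds[fi]
    model <- train_classifier(spec, features[!test, , drop = FALSE],
                              labels[!test])
    pred <- predict_any(model, features[test, , drop = FALSE])
    pred <- factor(as.character(pred), levels = lev)
    truth <- labels[test]
    per_fold[fi] <- mean(pred == truth)
    confusion <- confusion + table(truth, pred)
  }
  names(per_fold) <- paste0("run", folds)
  met <- compute_metrics(confusion)
  structure(list(per_fold_accuracy = per_fold,
                 mean_accuracy = mean(per_fold),
                 confusion = confusion,
                 precision = met$precision, recall = met$recall,
                 f1 = met$f1, spec = spec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold (run-wise) cross-validation, classifier %s\n",
              length(x$per_fold_accuracy), x$spec$kind))
  cat(sprintf("mean accuracy %.4f  (weighted P %.3f / R %.3f / F1 %.3f)\n",
              x$mean_accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  print(object)
  cat("\nper-fold accuracy:\n")
  print(round(object$per_fold_accuracy, 4))
  cat("\npooled confusion matrix (true x predicted):\n")
  print(object$confusion)
  invisible(object)
}
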