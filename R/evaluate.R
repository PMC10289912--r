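#' Confusion matrix in canonical class order
#'
#' @param truth,predicted Equal-length label vectors over `classes`.
#' @param classes Class order (default [sers_classes()]).
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion <- function(truth, predicted, classes = sers_classes()) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("label vectors differ in length", call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  tab <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Per class `C`, the one-vs-rest collapse gives TP, FP, TN, FN and the
#' four standard metrics: accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1, the harmonic mean of precision
#' and recall. The headline figures are the overall accuracy (pooled
#' fraction correct, `trace/total`) and support-weighted averages of the
#' per-class precision/recall/F1; macro (unweighted) averages are also
#' reported. Division-by-zero cases yield 0 and are flagged.
#'
#' @param cm Square counts matrix from [confusion()].
#' @return An object of class `metrics_report`: `overall_accuracy`,
#'   `per_class` (data frame), `weighted` and `macro` (named vectors).
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  cls <- rownames(cm)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  acc <- (tp + tn) / total
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  support <- rowSums(cm)
  per_class <- data.frame(
    class = cls, tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = acc, precision = prec, recall = rec, f1 = f1,
    support = support,
    zero_division = (tp + fp == 0) | (tp + fn == 0) | (prec + rec == 0),
    row.names = NULL)
  wavg <- function(v) sum(v * support) / sum(support)
  structure(list(
    overall_accuracy = sum(tp) / total,
    per_class = per_class,
    weighted = c(precision = wavg(prec), recall = wavg(rec),
                 f1 = wavg(f1)),
    macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    confusion = cm), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("overall accuracy %.4f\n", x$overall_accuracy))
  cat(sprintf(
    "weighted precision %.4f  recall %.4f  F1 %.4f\n",
    x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  print(x$per_class[, c("class", "accuracy", "precision", "recall", "f1",
                        "support")], digits = 4)
  invisible(x)
}

#' The four one-vs-rest binary groupings
#'
#' Healthy controls versus cancer, and each cancer versus its complement.
#' @return Character vector of grouping names.
#' @export
roc_groupings <- function() c("healthy_vs_cancer", "BC_vs_rest",
                              "AC_vs_rest", "AML_vs_rest")

#' ROC curve and AUC for a one-vs-rest grouping
#'
#' The positive-class score is the healthy-class score for
#' `healthy_vs_cancer` and class X's score for `X_vs_rest`. The ROC curve
#' is a threshold sweep over the unique scores and the AUC its trapezoidal
#' area, which handles tied scores by rank averaging (equivalently, the
#' normalized Mann-Whitney U statistic).
#'
#' @param scores Matrix of per-class scores (columns in canonical order, as
#'   from `predict(..., type = "score")`) or a numeric vector already
#'   holding the positive-class score.
#' @param truth True class labels.
#' @param grouping One of [roc_groupings()].
#' @return List with `roc` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth, grouping = roc_groupings()) {
  grouping <- match.arg(grouping)
  truth <- as.character(truth)
  pos_class <- sub("_vs.*$", "", grouping)
  positive <- if (grouping == "healthy_vs_cancer") truth == "healthy"
              else truth == pos_class
  s <- if (is.matrix(scores)) {
    cn <- if (!is.null(colnames(scores))) colnames(scores)
          else sers_classes()[seq_len(ncol(scores))]
    scores[, match(pos_class, cn)]
  } else as.numeric(scores)
  if (!any(positive) || all(positive))
    stop("AUC undefined: truth contains a single class for ", grouping,
         call. = FALSE)
  thr <- sort(unique(s), decreasing = TRUE)
  np <- sum(positive); nn <- sum(!positive)
  tpr <- vapply(thr, function(t) sum(s >= t & positive) / np, 0)
  fpr <- vapply(thr, function(t) sum(s >= t & !positive) / nn, 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (utils::tail(roc$fpr, 1) < 1 || utils::tail(roc$tpr, 1) < 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Difference of two group-mean spectra
#'
#' @param x A labeled [spectra_set()].
#' @param group_a,group_b Group labels; the result is
#'   `mean(group_a) - mean(group_b)` pointwise.
#' @return A one-spectrum `spectra_set` (no group label).
#' @export
difference_spectrum <- function(x, group_a, group_b) {
  d <- mean_spectrum(x, group_a) - mean_spectrum(x, group_b)
  spectra_set(x$wavenumber, matrix(d, 1L),
              paste0(group_a, "-", group_b))
}

#' Per-peak two-sample t-tests between groups
#'
#' Welch's two-sample t-test on the intensities at the grid point nearest
#' each prominent-peak position, ranked by ascending p value. Peaks where
#' both groups are constant (zero variance) cannot be tested; they are
#' flagged and ranked last.
#'
#' @param x A labeled [spectra_set()].
#' @param group_a,group_b Groups to compare (each needs >= 2 spectra).
#' @param lexicon Peak table as from [peak_lexicon()].
#' @param k Number of top peaks to return (default 5; `Inf` for all).
#' @return Data frame: `position`, `assignment`, `t`, `p`, `degenerate`,
#'   sorted by p.
#' @export
peak_ttests <- function(x, group_a, group_b, lexicon = peak_lexicon(),
                        k = 5L) {
  ia <- which(x$group == group_a); ib <- which(x$group == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs at least two spectra", call. = FALSE)
  res <- lapply(seq_len(nrow(lexicon)), function(j) {
    pt <- which.min(abs(x$wavenumber - lexicon$position[j]))
    a <- x$intensity[ia, pt]; b <- x$intensity[ib, pt]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      data.frame(position = lexicon$position[j],
                 assignment = lexicon$assignment[j],
                 t = 0, p = NA_real_, degenerate = TRUE)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(position = lexicon$position[j],
                 assignment = lexicon$assignment[j],
                 t = unname(tt$statistic), p = tt$p.value,
                 degenerate = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res <- res[order(res$degenerate, res$p), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, k)
}

#' Chemometric baseline classifiers (PCA-LDA, PCA-SVM)
#'
#' PCA is fitted on the training spectra only (no test leakage); an LDA or
#' an RBF-kernel SVM is then fitted on the leading component scores and
#' evaluated on the projected test spectra.
#'
#' @param train,test Labeled, classical-track preprocessed
#'   [spectra_set()]s on one axis.
#' @param method `"pca_lda"` or `"pca_svm"`.
#' @param n_components Number of principal components (default 20).
#' @return List with `metrics` (a [classification_metrics()] report),
#'   `confusion` and `predicted`.
#' @export
baseline_classifiers <- function(train, test,
                                 method = c("pca_lda", "pca_svm"),
                                 n_components = 20L) {
  method <- match.arg(method)
  maxrank <- min(n_spectra(train) - 1L, n_points(train))
  if (n_components > maxrank)
    stop("n_components exceeds feasible rank ", maxrank, call. = FALSE)
  pca <- stats::prcomp(train$intensity, center = TRUE, scale. = FALSE,
                       rank. = n_components)
  ztr <- pca$x
  zte <- predict(pca, test$intensity)[, seq_len(n_components), drop = FALSE]
  ytr <- factor(as.character(train$group), sers_classes())
  yte <- as.character(test$group)
  pred <- if (method == "pca_lda") {
    fit <- MASS::lda(ztr, grouping = ytr)
    as.character(predict(fit, zte)$class)
  } else {
    fit <- e1071::svm(ztr, ytr, kernel = "radial")
    as.character(predict(fit, zte))
  }
  cm <- confusion(yte, pred)
  list(metrics = classification_metrics(cm), confusion = cm,
       predicted = pred)
}

#' Five-fold cross-validated training and evaluation of the 1D-CNN
#'
#' The full deep-learning pipeline at the sample level: the input set (one
#' spectrum per sample, native axis) is resampled to the network input
#' length, partitioned by the fold plan, and for each rotation the three
#' subsets are independently augmented and min-max normalized, the network
#' is trained with validation-based model selection, and the held-out test
#' spectra are predicted. Test predictions are pooled across the rotations
#' into one confusion matrix; per-rotation reports are kept alongside.
#'
#' @param x A labeled per-sample [spectra_set()].
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param plan Optional [make_folds()] plan (default: stratified 5-fold
#'   with `config$seed`).
#' @param factor Augmentation factor (default 10).
#' @param rotations Rotation indices to run (default all).
#' @param keep_models Keep each rotation's fitted model (default `FALSE`).
#' @param verbose Print per-rotation progress.
#' @return An object of class `sers_cv`: `confusion` (pooled), `metrics`,
#'   `auc` (the four one-vs-rest groupings on pooled scores),
#'   `predictions` (data frame), `per_rotation`, `plan`.
#' @export
cross_validate <- function(x, spec = model_spec(), config = train_config(),
                           plan = NULL, factor = 10L,
                           rotations = NULL, keep_models = FALSE,
                           verbose = FALSE) {
  if (is.null(plan))
    plan <- make_folds(x, n_folds = 5L, seed = config$seed,
                       stratified = TRUE)
  if (is.null(rotations)) rotations <- seq_len(plan$n_folds)
  xr <- if (n_points(x) == spec$input_length) x
        else resample_spectra(x, spec$input_length)
  preds <- list(); per_rot <- list(); models <- list()
  for (r in rotations) {
    ds <- build_datasets(xr, plan, r, factor = factor,
                         seed = config$seed)
    fit <- sers_cnn(ds$train, ds$val, spec, config, verbose = verbose)
    pr <- predict(fit, ds$test, type = "both")
    truth <- as.character(ds$test$group)
    preds[[length(preds) + 1L]] <- data.frame(
      rotation = r, sample_id = ds$test$sample_id, truth = truth,
      predicted = as.character(pr$class), pr$score,
      check.names = FALSE)
    per_rot[[length(per_rot) + 1L]] <- list(
      rotation = r,
      metrics = classification_metrics(
        confusion(truth, as.character(pr$class))),
      best_epoch = fit$best_epoch,
      val_accuracy = max(fit$history$val_accuracy))
    if (keep_models) models[[length(models) + 1L]] <- fit
    if (verbose)
      message(sprintf("rotation %d: test acc %.3f", r,
                      per_rot[[length(per_rot)]]$metrics$overall_accuracy))
  }
  preds <- do.call(rbind, preds)
  cm <- confusion(preds$truth, preds$predicted)
  auc <- lapply(roc_groupings(), function(g)
    roc_auc(as.matrix(preds[, sers_classes()]), preds$truth, g)$auc)
  names(auc) <- roc_groupings()
  structure(list(confusion = cm, metrics = classification_metrics(cm),
                 auc = auc, predictions = preds, per_rotation = per_rot,
                 plan = plan, models = if (keep_models) models),
            class = "sers_cv")
}

#' @export
print.sers_cv <- function(x, ...) {
  cat(sprintf("<sers_cv> %d rotations, %d pooled test spectra\n",
              length(x$per_rotation), sum(x$confusion)))
  print(x$metrics)
  cat("AUCs:", paste(sprintf("%s=%.3f", names(x$auc), unlist(x$auc)),
                     collapse = ", "), "\n")
  invisible(x)
}
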