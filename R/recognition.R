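# State classification. Four classifiers over the network-feature table:
# k-nearest neighbour (Euclidean, "moderate" k = 10), random forest,
# gradient-boosted trees, and an RBF-kernel SVM. Evaluation: an outer
# stratified 90/10 split, 10-fold cross-validation on the development 90%,
# and held-out metrics on the reserved 10%. Standardization parameters are
# estimated inside each training portion only.

feature_cols <- function(table) {
  setdiff(names(table), c("label", "subject", "epoch"))
}

task_labels <- function(table, task) {
  if (task == "binary") {
    factor(ifelse(table$label == "normal", "normal", "distracted"),
           levels = c("normal", "distracted"))
  } else {
    factor(table$label, levels = driving_states())
  }
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mu, "-"), 2, st$sd, "/")
}

# Stratified assignment of indices to k folds, seeded by the caller's RNG.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_classifier <- function(X, y, classifier, seed, knn_k = 10) {
  set.seed(seed)
  nclass <- nlevels(y)
  model <- switch(classifier,
    knn = list(X = X, y = y, k = knn_k),
    rf = randomForest::randomForest(X, y, ntree = 500),
    svm = e1071::svm(X, y, kernel = "radial", probability = TRUE,
                     scale = FALSE),
    gboost = {
      params <- if (nclass > 2) {
        list(objective = "multi:softprob", num_class = nclass,
             max_depth = 3, eta = 0.3, nthread = 1, seed = seed,
             tree_method = "exact")
      } else {
        list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
             nthread = 1, seed = seed, tree_method = "exact")
      }
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L),
                         nrounds = 100)
    },
    stop("unknown classifier: ", classifier))
  list(classifier = classifier, model = model, levels = levels(y))
}

# Class-probability predictions as a matrix (rows = samples, cols = levels).
predict_prob <- function(fit, X) {
  lv <- fit$levels
  p <- switch(fit$classifier,
    knn = {
      # vote shares from the k nearest training points
      tr <- fit$model
      d2 <- outer(rowSums(X^2), rowSums(tr$X^2), "+") - 2 * X %*% t(tr$X)
      t(apply(d2, 1, function(row) {
        nb <- tr$y[order(row)[seq_len(min(tr$k, length(row)))]]
        as.numeric(table(factor(nb, levels = lv))) / length(nb)
      }))
    },
    rf = predict(fit$model, X, type = "prob"),
    svm = {
      pr <- predict(fit$model, X, probability = TRUE)
      attr(pr, "probabilities")[, lv, drop = FALSE]
    },
    gboost = {
      raw <- predict(fit$model, xgboost::xgb.DMatrix(X))
      if (length(lv) > 2) {
        matrix(raw, ncol = length(lv), dimnames = list(NULL, lv))
      } else {
        cbind(1 - raw, raw)
      }
    })
  p <- as.matrix(p)
  colnames(p) <- lv
  p
}

predict_class <- function(fit, X) {
  p <- predict_prob(fit, X)
  factor(colnames(p)[max.col(p, ties.method = "first")], levels = fit$levels)
}

confusion_metrics <- function(truth, pred) {
  lv <- levels(truth)
  cm <- table(truth = truth, pred = factor(pred, levels = lv))
  acc <- sum(diag(cm)) / sum(cm)
  prec <- rec <- f1 <- numeric(length(lv))
  for (i in seq_along(lv)) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec[i] <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(confusion = cm, accuracy = acc,
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       per_class = data.frame(class = lv, precision = prec, recall = rec,
                              f1 = f1))
}

roc_auc_ovr <- function(truth, prob) {
  lv <- levels(truth)
  out <- list()
  for (cl in lv) {
    resp <- as.integer(truth == cl)
    if (length(unique(resp)) < 2) {
      out[[cl]] <- list(auc = NA_real_, curve = NULL)
      next
    }
    r <- pROC::roc(resp, prob[, cl], quiet = TRUE, direction = "<")
    out[[cl]] <- list(auc = as.numeric(pROC::auc(r)),
                      curve = data.frame(fpr = 1 - r$specificities,
                                         tpr = r$sensitivities))
  }
  out
}

#' Train and evaluate a driving-state classifier
#'
#' Implements the evaluation protocol in two stages: a stratified outer
#' split reserving `test_fraction` of the data, then `k_folds`-fold
#' stratified cross-validation on the development portion; held-out metrics
#' (confusion matrix, accuracy, macro precision/recall/F1, one-vs-rest ROC
#' AUC) are reported alongside the CV fold accuracies. The binary task
#' relabels cognitive and visual epochs as `distracted`. Standardization is
#' fit on training data only; everything is deterministic given `seed`.
#'
#' @param table Feature table from [build_feature_table()].
#' @param task `"ternary"` (normal/cognitive/visual) or `"binary"`
#'   (normal/distracted).
#' @param classifier One of `"gboost"`, `"rf"`, `"svm"`, `"knn"`.
#' @param seed Integer seed.
#' @param split `"epoch"` (stratified over epochs) or `"subject"` (all
#'   epochs of a subject stay on one side of every split).
#' @param k_folds Number of CV folds (default 10).
#' @param test_fraction Held-out fraction (default 0.1).
#' @param knn_k Neighbourhood size for the KNN classifier (default 10, the
#'   common "medium" preset).
#' @return An object of class `recognition_report`.
#' @export
train_evaluate <- function(table, task = c("ternary", "binary"),
                           classifier = c("gboost", "rf", "svm", "knn"),
                           seed = 1, split = c("epoch", "subject"),
                           k_folds = 10, test_fraction = 0.1, knn_k = 10) {
  task <- match.arg(task)
  classifier <- match.arg(classifier)
  split <- match.arg(split)
  y <- task_labels(table, task)
  X <- as.matrix(table[, feature_cols(table), drop = FALSE])
  if (min(table(y)) < 2) stop("need at least 2 samples per class")

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  # outer split
  if (split == "subject") {
    subj <- unique(table$subject)
    n_test <- max(1, round(length(subj) * test_fraction))
    test_subj <- sample(subj, n_test)
    test_idx <- which(table$subject %in% test_subj)
  } else {
    test_idx <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1, round(length(idx) * test_fraction)))
    }))
  }
  dev_idx <- setdiff(seq_len(nrow(X)), test_idx)
  ydev <- droplevels(y[dev_idx])
  if (nlevels(ydev) < nlevels(y))
    stop("a class is absent from the development split; use more epochs ",
         "per state or a different seed")

  # cross-validation on the development portion
  if (split == "subject") {
    subj_dev <- unique(table$subject[dev_idx])
    sf <- sample(rep_len(seq_len(min(k_folds, length(subj_dev))), length(subj_dev)))
    fold <- sf[match(table$subject[dev_idx], subj_dev)]
  } else {
    fold <- stratified_folds(y[dev_idx], k_folds)
  }
  cv_acc <- rep(NA_real_, max(fold))
  for (f in sort(unique(fold))) {
    tr <- dev_idx[fold != f]
    va <- dev_idx[fold == f]
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < nlevels(y)) stop("a class is absent from fold ", f,
                                        "; increase epochs per state")
    st <- standardizer(X[tr, , drop = FALSE])
    fit <- fit_classifier(apply_standardizer(X[tr, , drop = FALSE], st),
                          y[tr], classifier, seed + f, knn_k)
    pred <- predict_class(fit, apply_standardizer(X[va, , drop = FALSE], st))
    cv_acc[f] <- mean(pred == y[va])
  }

  # final fit on the full development portion, metrics on the reserve
  st <- standardizer(X[dev_idx, , drop = FALSE])
  fit <- fit_classifier(apply_standardizer(X[dev_idx, , drop = FALSE], st),
                        y[dev_idx], classifier, seed, knn_k)
  Xte <- apply_standardizer(X[test_idx, , drop = FALSE], st)
  pred <- predict_class(fit, Xte)
  prob <- predict_prob(fit, Xte)
  metr <- confusion_metrics(y[test_idx], pred)
  roc <- roc_auc_ovr(y[test_idx], prob)

  structure(
    list(task = task, classifier = classifier, seed = seed, split = split,
         cv = list(fold_accuracy = cv_acc, accuracy = mean(cv_acc, na.rm = TRUE)),
         test = c(metr, list(auc = vapply(roc, `[[`, numeric(1), "auc"),
                             roc = lapply(roc, `[[`, "curve"))),
         fit = fit, feature_names = colnames(X),
         config = list(k_folds = k_folds, test_fraction = test_fraction,
                       knn_k = knn_k, n = nrow(X))),
    class = "recognition_report")
}

#' @export
print.recognition_report <- function(x, ...) {
  cat(sprintf("<recognition_report> %s / %s (split by %s)\n", x$task,
              x$classifier, x$split))
  cat(sprintf("  CV accuracy (%d folds): %.3f\n",
              length(x$cv$fold_accuracy), x$cv$accuracy))
  cat(sprintf("  held-out: Acc %.3f  P %.3f  Re %.3f  F1 %.3f\n",
              x$test$accuracy, x$test$precision, x$test$recall, x$test$f1))
  invisible(x)
}

#' Feature-importance ranking of a tree-ensemble report
#'
#' Normalized per-feature importance (gain for gradient boosting, Gini
#' decrease for random forest) with aggregated shares per estimator network
#' (SL/PLV/COH) and per frequency band.
#'
#' @param report A `recognition_report` fitted with `classifier = "gboost"`
#'   or `"rf"`.
#' @return List with `ranking` (data frame, descending importance),
#'   `estimator_share`, `band_share` (named vectors summing to 1).
#' @export
feature_importance <- function(report) {
  if (!inherits(report, "recognition_report")) stop("not a recognition_report")
  fit <- report$fit
  imp <- switch(fit$classifier,
    gboost = {
      tab <- xgboost::xgb.importance(model = fit$model)
      v <- stats::setNames(rep(0, length(report$feature_names)),
                           report$feature_names)
      v[tab$Feature] <- tab$Gain
      v
    },
    rf = {
      v <- randomForest::importance(fit$model)[, 1]
      stats::setNames(as.numeric(v), rownames(randomForest::importance(fit$model)))
    },
    stop("feature importances require a tree-ensemble classifier (gboost, rf)"))
  if (sum(imp) <= 0) stop("model carries no importance scores")
  imp <- imp / sum(imp)
  parts <- strsplit(names(imp), "_", fixed = TRUE)
  est <- toupper(vapply(parts, `[`, character(1), 1))
  band <- vapply(parts, `[`, character(1), 2)
  ranking <- data.frame(feature = names(imp), importance = as.numeric(imp),
                        estimator = est, band = band,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$importance), ]
  rownames(ranking) <- NULL
  list(ranking = ranking,
       estimator_share = tapply(imp, est, sum)[unique(est)],
       band_share = tapply(imp, band, sum)[unique(band)])
}
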