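#' Matthews correlation coefficient and F1 from predictions
#'
#' `mcc = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as
#' 0 when any marginal is empty. `f1 = 2 TP / (2 TP + FP + FN)` with the
#' positive class taken as `positive`.
#'
#' @param truth,pred factors/characters over the same two classes.
#' @param positive positive-class label (default: the minority class in
#'   `truth`, ties broken alphabetically).
#' @export
mcc_score <- function(truth, pred, positive = NULL) {
  cm <- confusion(truth, pred, positive)
  num <- cm$tp * cm$tn - cm$fp * cm$fn
  den <- sqrt(prod(c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fp, cm$tn + cm$fn)))
  if (den == 0) 0 else num / den
}

#' @rdname mcc_score
#' @export
f1_score <- function(truth, pred, positive = NULL) {
  cm <- confusion(truth, pred, positive)
  if (2 * cm$tp + cm$fp + cm$fn == 0) return(0)
  2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn)
}

confusion <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(truth))
  if (is.null(positive)) {
    tab <- table(factor(truth, classes))
    positive <- names(tab)[which.min(tab)]
  }
  list(tp = sum(truth == positive & pred == positive),
       fp = sum(truth != positive & pred == positive),
       fn = sum(truth == positive & pred != positive),
       tn = sum(truth != positive & pred != positive))
}

#' SMOTE class balancing
#'
#' Oversamples the minority class to the majority size: each synthetic
#' observation is a convex combination of a minority observation and one of
#' its `k_neighbors` nearest minority neighbours (Euclidean), with a
#' uniform interpolation weight.
#'
#' @param x feature matrix. @param labels binary labels.
#' @param k_neighbors neighbourhood size (minority count must exceed it).
#' @param seed RNG seed.
#' @return list: `x` (balanced matrix), `labels`, `synthetic` (logical row
#'   mask).
#' @export
smote_balance <- function(x, labels, k_neighbors = 5, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2) stop("labels must be binary")
  if (tab[1] == tab[2])
    return(list(x = x, labels = labels, synthetic = rep(FALSE, nrow(x))))
  minority <- names(tab)[which.min(tab)]
  idx_min <- which(labels == minority)
  n_new <- max(tab) - min(tab)
  if (length(idx_min) <= k_neighbors)
    stop("minority count (", length(idx_min), ") must exceed k_neighbors; use a smaller k")
  xm <- x[idx_min, , drop = FALSE]
  D <- as.matrix(stats::dist(xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k_neighbors)]))
  synth <- withr_seed(seed, {
    base_i <- sample(rep_len(seq_along(idx_min), n_new))
    t(vapply(base_i, function(i) {
      j <- nn[i, sample.int(k_neighbors, 1)]
      w <- stats::runif(1)
      xm[i, ] + w * (xm[j, ] - xm[i, ])
    }, numeric(ncol(x))))
  })
  colnames(synth) <- colnames(x)
  list(x = rbind(x, synth),
       labels = c(labels, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)))
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Algorithms: `svm` (RBF kernel; cost/gamma tuned by inner 5-fold
#' cross-validated MCC on the training fold, features standardised with
#' training-fold statistics), `random_forest` (500 trees, defaults
#' otherwise), `gradient_boosted_trees` (500 rounds, depth 3, eta 0.1).
#' Scores are MCC and F1 on each held-out fold.
#'
#' @param x feature matrix. @param labels binary labels.
#' @param algorithm one of `"svm"`, `"random_forest"`,
#'   `"gradient_boosted_trees"`.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for fold assignment and the learners.
#' @param svm_grid list with `cost` and `gamma` vectors for the SVM search.
#' @return list of class `cv_result`: `algorithm`, `mcc` and `f1` per fold,
#'   `mean_mcc`, `se_mcc`, `mean_f1`, `se_f1`, `tuned` (per-fold chosen
#'   hyperparameters).
#' @export
cross_validate <- function(x, labels, algorithm = c("svm", "random_forest",
                                                    "gradient_boosted_trees"),
                           folds = 10, seed = 1L,
                           svm_grid = list(cost = c(0.1, 1, 10, 100),
                                           gamma = c(0.001, 0.01, 0.1, 1))) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must be binary")
  withr_seed(seed, {
    fold_id <- stratified_folds(y, folds)
    tuned <- list()
    scores <- lapply(seq_len(folds), function(k) {
      tr <- fold_id != k; te <- !tr
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2)
        stop("degenerate fold (single class); reduce folds")
      fit <- train_one(x[tr, , drop = FALSE], y[tr], algorithm, svm_grid)
      tuned[[k]] <<- fit$tuned
      pred <- fit$predict(x[te, , drop = FALSE])
      c(mcc = mcc_score(y[te], pred), f1 = f1_score(y[te], pred))
    })
    m <- do.call(rbind, scores)
    structure(list(algorithm = algorithm, mcc = m[, "mcc"], f1 = m[, "f1"],
                   mean_mcc = mean(m[, "mcc"]), se_mcc = stats::sd(m[, "mcc"]) / sqrt(folds),
                   mean_f1 = mean(m[, "f1"]), se_f1 = stats::sd(m[, "f1"]) / sqrt(folds),
                   tuned = tuned),
              class = "cv_result")
  })
}

stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (min(table(y)) < folds) stop("need at least `folds` subjects per class")
  id
}

train_one <- function(xtr, ytr, algorithm, svm_grid) {
  if (algorithm == "svm") {
    mu <- colMeans(xtr); sdev <- pmax(apply(xtr, 2, stats::sd), 1e-12)
    xs <- scale(xtr, mu, sdev)
    grid <- expand.grid(cost = svm_grid$cost, gamma = svm_grid$gamma)
    inner <- stratified_folds(ytr, 5)
    gscore <- vapply(seq_len(nrow(grid)), function(g) {
      preds <- rep(NA_character_, length(ytr))
      for (k in 1:5) {
        tr <- inner != k
        if (length(unique(ytr[tr])) < 2) return(-2)
        m <- e1071::svm(xs[tr, , drop = FALSE], ytr[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g], scale = FALSE)
        preds[!tr] <- as.character(predict(m, xs[!tr, , drop = FALSE]))
      }
      mcc_score(ytr, preds)
    }, 0)
    best <- grid[which.max(gscore), ]
    m <- e1071::svm(xs, ytr, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
    list(predict = function(xn) predict(m, scale(xn, mu, sdev)),
         tuned = as.list(best),
         decision = function(xn) {
           dv <- attr(predict(m, scale(xn, mu, sdev), decision.values = TRUE),
                      "decision.values")
           drop(dv)
         },
         model = m, center = mu, scale = sdev)
  } else if (algorithm == "random_forest") {
    m <- randomForest::randomForest(xtr, ytr, ntree = 500)
    list(predict = function(xn) predict(m, xn), tuned = list(ntree = 500), model = m)
  } else {
    m <- xgboost::xgboost(xtr, ytr, nrounds = 500, max_depth = 3,
                          learning_rate = 0.1, verbosity = 0, nthreads = 1)
    # predict() returns the probability of the second factor level
    list(predict = function(xn)
           factor(levels(ytr)[(predict(m, xn) > 0.5) + 1], levels = levels(ytr)),
         tuned = list(nrounds = 500, max_depth = 3, learning_rate = 0.1), model = m)
  }
}

#' Published-procedure classification pipeline on one feature table
#'
#' Applies SMOTE to the full table before cross-validation (deliberately
#' replicating the leakage-prone published procedure) unless
#' `leakage_safe = TRUE`, in which case SMOTE runs inside each training
#' fold only. Then cross-validates the requested algorithms.
#'
#' @param ft a [feature_table()].
#' @param algorithms algorithms to run.
#' @param folds,seed,k_neighbors see [cross_validate()] / [smote_balance()].
#' @param leakage_safe balance within training folds instead of up front.
#' @return named list of `cv_result`.
#' @export
classify_features <- function(ft, algorithms = c("svm", "random_forest",
                                                 "gradient_boosted_trees"),
                              folds = 10, seed = 1L, k_neighbors = 5,
                              leakage_safe = FALSE) {
  if (leakage_safe) {
    res <- lapply(algorithms, function(a)
      cross_validate_safe(ft$values, ft$labels, a, folds, seed, k_neighbors))
  } else {
    bal <- smote_balance(ft$values, ft$labels, k_neighbors, seed)
    res <- lapply(algorithms, function(a)
      cross_validate(bal$x, bal$labels, a, folds, seed))
  }
  stats::setNames(res, algorithms)
}

# leakage-safe variant: stratified outer folds on the original subjects,
# SMOTE applied to each training fold only
cross_validate_safe <- function(x, labels, algorithm, folds = 10, seed = 1L,
                                k_neighbors = 5) {
  x <- as.matrix(x)
  y <- factor(labels)
  withr_seed(seed, {
    fold_id <- stratified_folds(y, folds)
    scores <- lapply(seq_len(folds), function(k) {
      tr <- fold_id != k
      bal <- smote_balance(x[tr, , drop = FALSE], as.character(y[tr]),
                           k_neighbors, seed + k)
      fit <- train_one(bal$x, factor(bal$labels, levels(y)), algorithm,
                       list(cost = c(0.1, 1, 10, 100), gamma = c(0.001, 0.01, 0.1, 1)))
      pred <- fit$predict(x[!tr, , drop = FALSE])
      c(mcc = mcc_score(y[!tr], pred), f1 = f1_score(y[!tr], pred))
    })
    m <- do.call(rbind, scores)
    structure(list(algorithm = algorithm, mcc = m[, "mcc"], f1 = m[, "f1"],
                   mean_mcc = mean(m[, "mcc"]), se_mcc = stats::sd(m[, "mcc"]) / sqrt(folds),
                   mean_f1 = mean(m[, "f1"]), se_f1 = stats::sd(m[, "f1"]) / sqrt(folds),
                   tuned = NULL),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: MCC %.3f +/- %.3f, F1 %.3f +/- %.3f (%d folds)\n",
              x$algorithm, x$mean_mcc, x$se_mcc, x$mean_f1, x$se_f1, length(x$mcc)))
  invisible(x)
}

#' Fit one classifier on the full (un-augmented) table for explanation
#'
#' Used by the SHAP stage: attribution explains the best classifier fitted
#' on the original, un-augmented cohort. Returns a continuous decision function
#' (SVM decision values, forest class-1 vote fraction, boosted-tree
#' probability).
#'
#' @inheritParams cross_validate
#' @return list: `predict_value` (matrix -> numeric), `model`.
#' @export
fit_full_model <- function(x, labels, algorithm = "svm", seed = 1L,
                           svm_grid = list(cost = c(0.1, 1, 10, 100),
                                           gamma = c(0.001, 0.01, 0.1, 1))) {
  x <- as.matrix(x)
  y <- factor(labels)
  withr_seed(seed, {
    fit <- train_one(x, y, algorithm, svm_grid)
    pv <- if (algorithm == "svm") {
      fit$decision
    } else if (algorithm == "random_forest") {
      function(xn) predict(fit$model, xn, type = "prob")[, 2]
    } else {
      function(xn) predict(fit$model, as.matrix(xn))
    }
    list(predict_value = pv, model = fit$model, tuned = fit$tuned)
  })
}
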