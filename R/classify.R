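#' Describe a classifier family and its hyperparameters
#'
#' Three families are supported, mirroring common practice for protein
#' subtype prediction:
#' * `"svm"` — RBF-kernel support vector machines combined one-vs-one:
#'   one binary margin classifier per class pair, prediction by vote.
#'   Hyperparameters `cost` (error penalty C) and `gamma` (kernel
#'   width; default 1/d). Optionally a `grid` for nested search.
#' * `"nb"` — Gaussian naive Bayes with the maximum-a-posteriori rule.
#' * `"rf"` — random forest (default 500 trees).
#'
#' @param family `"svm"`, `"nb"` or `"rf"`.
#' @param cost,gamma RBF-SVM hyperparameters (svm only). `gamma = NULL`
#'   means 1/(number of features).
#' @param ntree number of trees (rf only).
#' @param grid optional list with numeric vectors `cost` and `gamma`;
#'   when present, each training fold runs an inner 3-fold search over
#'   the grid (test rows are never touched). The conventional coarse
#'   log grid is available via `svm_default_grid()`.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "nb", "rf"),
                            cost = 1, gamma = NULL, ntree = 500L,
                            grid = NULL) {
  family <- match.arg(family)
  stopifnot(cost > 0, is.null(gamma) || gamma > 0, ntree >= 1)
  if (!is.null(grid)) {
    stopifnot(is.list(grid), all(c("cost", "gamma") %in% names(grid)),
              all(grid$cost > 0), all(grid$gamma > 0))
  }
  structure(list(family = family, cost = cost, gamma = gamma,
                 ntree = as.integer(ntree), grid = grid),
            class = "classifier_spec")
}

#' Conventional coarse log-scale RBF grid
#'
#' C over 2^-5..2^15 and gamma over 2^-15..2^3, coarse steps.
#'
#' @return A list with components `cost` and `gamma`.
#' @export
svm_default_grid <- function() {
  list(cost = 2^seq(-5, 15, by = 4), gamma = 2^seq(-15, 3, by = 4))
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("Classifier:", x$family)
  if (x$family == "svm")
    cat(sprintf(" (cost=%g, gamma=%s%s)", x$cost,
                if (is.null(x$gamma)) "1/d" else format(x$gamma),
                if (is.null(x$grid)) "" else ", grid search"))
  if (x$family == "rf") cat(sprintf(" (%d trees)", x$ntree))
  cat("\n")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Assigns each observation to one of `k` test folds so that class
#' proportions are preserved up to rounding. Deterministic given the
#' seed.
#'
#' @param labels class label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  small <- names(which(table(labels) < k))
  if (length(small))
    stop("class(es) smaller than k=", k, ": ", paste(small, collapse = ", "),
         "; use a smaller k")
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

class_pairs <- function(classes) {
  cmb <- utils::combn(classes, 2L)
  paste(cmb[1L, ], cmb[2L, ], sep = "|")
}

# Train on (train_x, train_y), predict test_x.
# For the svm family also returns the one-vs-one vote matrix and the
# oriented pairwise decision values (positive sign favors the first
# class of the pair in class order).
fit_predict_raw <- function(train_x, train_y, test_x, spec, classes) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x)) stop("feature dimension mismatch")
  train_y <- factor(as.character(train_y), levels = classes)
  if (length(unique(train_y)) < 2L) stop("training data has a single class")

  if (spec$family == "svm") {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    tr <- sweep(sweep(train_x, 2L, mu), 2L, sdv, "/")
    te <- sweep(sweep(test_x, 2L, mu), 2L, sdv, "/")
    hp <- if (!is.null(spec$grid)) grid_search_svm(tr, train_y, spec) else
      list(cost = spec$cost,
           gamma = if (is.null(spec$gamma)) 1 / ncol(tr) else spec$gamma)
    ovo_predict(tr, train_y, te, classes, hp$cost, hp$gamma)
  } else if (spec$family == "nb") {
    fit <- e1071::naiveBayes(train_x, train_y)
    pred <- stats::predict(fit, test_x)
    list(predicted = factor(as.character(pred), levels = classes),
         votes = NULL, dv = NULL)
  } else {
    fit <- randomForest::randomForest(train_x, train_y, ntree = spec$ntree)
    pred <- stats::predict(fit, test_x)
    list(predicted = factor(as.character(pred), levels = classes),
         votes = NULL, dv = NULL)
  }
}

# One-vs-one RBF SVM round: one libsvm binary classifier per class
# pair. Rows of each pair's training subset are ordered with the first
# class of the pair first so that libsvm's decision value is positive
# toward it; the orientation is verified against the reported column
# name and flipped if needed.
ovo_predict <- function(tr, y, te, classes, cost, gamma) {
  m <- length(classes)
  pairs <- utils::combn(classes, 2L)
  npair <- ncol(pairs)
  nte <- nrow(te)
  votes <- matrix(0L, nte, m, dimnames = list(NULL, classes))
  dv <- matrix(NA_real_, nte, npair,
               dimnames = list(NULL, paste(pairs[1L, ], pairs[2L, ], sep = "|")))
  for (p in seq_len(npair)) {
    ci <- pairs[1L, p]; cj <- pairs[2L, p]
    idx <- c(which(y == ci), which(y == cj))
    ysub <- factor(as.character(y[idx]), levels = c(ci, cj))
    fit <- e1071::svm(tr[idx, , drop = FALSE], ysub, scale = FALSE,
                      kernel = "radial", cost = cost, gamma = gamma)
    pr <- stats::predict(fit, te, decision.values = TRUE)
    d <- attr(pr, "decision.values")
    sgn <- if (colnames(d)[1L] == paste(ci, cj, sep = "/")) 1 else -1
    d <- sgn * d[, 1L]
    dv[, p] <- d
    wins_i <- d > 0
    votes[wins_i, ci] <- votes[wins_i, ci] + 1L
    votes[!wins_i, cj] <- votes[!wins_i, cj] + 1L
  }
  # prediction by vote; ties broken by the summed oriented decision
  # values over the tied classes, then by class order
  dvsum <- matrix(0, nte, m, dimnames = list(NULL, classes))
  for (p in seq_len(npair)) {
    dvsum[, pairs[1L, p]] <- dvsum[, pairs[1L, p]] + dv[, p]
    dvsum[, pairs[2L, p]] <- dvsum[, pairs[2L, p]] - dv[, p]
  }
  pred <- character(nte)
  for (r in seq_len(nte)) {
    top <- which(votes[r, ] == max(votes[r, ]))
    if (length(top) > 1L) top <- top[which.max(dvsum[r, top])]
    pred[r] <- classes[top[1L]]
  }
  list(predicted = factor(pred, levels = classes), votes = votes, dv = dv)
}

# Inner 3-fold grid search on the training portion only.
grid_search_svm <- function(tr, y, spec) {
  grid <- expand.grid(cost = spec$grid$cost, gamma = spec$grid$gamma)
  k_in <- min(3L, min(table(y)))
  if (k_in < 2L) stop("too few per-class observations for grid search")
  folds <- stratified_folds(y, k_in, seed = 7L)
  classes <- levels(y)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hits <- 0L
    for (f in seq_len(k_in)) {
      te_i <- folds == f
      res <- ovo_predict(tr[!te_i, , drop = FALSE], y[!te_i],
                         tr[te_i, , drop = FALSE], classes,
                         grid$cost[g], grid$gamma[g])
      hits <- hits + sum(res$predicted == y[te_i])
    }
    acc[g] <- hits / length(y)
  }
  best <- which.max(acc)  # ties -> first grid point
  list(cost = grid$cost[best], gamma = grid$gamma[best])
}

#' Fit on a training split and predict a test split
#'
#' One record per test row; for the one-vs-one SVM family each record
#' carries the per-class vote counts (summing to m(m-1)/2) and the
#' oriented decision value of every class pair.
#'
#' @param train_x,train_y training feature matrix and labels.
#' @param test_x test feature matrix (same columns).
#' @param spec a [classifier_spec()].
#' @param classes ordered class names; defaults to sorted unique
#'   training labels.
#' @param test_ids optional row identifiers for the records.
#' @return A data frame with columns `id`, `predicted`, plus
#'   `vote.<class>` and `dv.<pair>` columns for the svm family.
#' @export
fit_predict_fold <- function(train_x, train_y, test_x, spec,
                             classes = NULL, test_ids = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(train_y)))
  if (is.null(test_ids)) {
    test_ids <- rownames(test_x)
    if (is.null(test_ids)) test_ids <- as.character(seq_len(nrow(test_x)))
  }
  res <- fit_predict_raw(train_x, train_y, test_x, spec, classes)
  out <- data.frame(id = test_ids, predicted = as.character(res$predicted),
                    stringsAsFactors = FALSE)
  if (!is.null(res$votes)) {
    v <- res$votes; colnames(v) <- paste0("vote.", colnames(v))
    d <- res$dv; colnames(d) <- paste0("dv.", colnames(d))
    out <- cbind(out, as.data.frame(v), as.data.frame(d))
  }
  out
}

#' Evaluate a classifier by stratified k-fold cross-validation
#'
#' Global metrics (accuracy, multi-class MCC, macro F-measure) are
#' computed per test fold and averaged over the k folds; per-class
#' precision, recall, MCC and F-measure are computed one-vs-rest from
#' the confusion matrix pooled over folds, which is more stable for
#' small classes.
#'
#' @param features numeric feature matrix (rows = sequences).
#' @param labels class labels, parallel to rows.
#' @param spec a [classifier_spec()].
#' @param k folds (default 5); every class needs at least k members.
#' @param seed integer seed for the fold assignment (and tree/bootstrap
#'   randomness).
#' @param folds optional precomputed fold assignment from
#'   [stratified_folds()]; overrides `k`/`seed` fold drawing.
#' @return An object of class `cv_eval`: list with `global` (named
#'   means over folds), `per_fold`, `per_class`, `confusion` (pooled),
#'   and the settings.
#' @export
evaluate_cv <- function(features, labels, spec = classifier_spec("svm"),
                        k = 5L, seed = 1L, folds = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  classes <- sort(unique(labels))
  if (is.null(folds)) folds <- stratified_folds(labels, k, seed)
  k <- max(folds)
  per_fold <- data.frame(fold = seq_len(k), accuracy = NA_real_,
                         mcc = NA_real_, f = NA_real_)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (f in seq_len(k)) {
    te <- folds == f
    set.seed(seed * 1000L + f)
    res <- fit_predict_raw(features[!te, , drop = FALSE], labels[!te],
                           features[te, , drop = FALSE], spec, classes)
    cm <- confusion_matrix(labels[te], res$predicted, classes)
    pooled <- pooled + unclass(cm)
    per_fold$accuracy[f] <- sum(diag(cm)) / sum(cm)
    per_fold$mcc[f] <- mcc_multiclass(cm)
    per_fold$f[f] <- macro_f(cm)
  }
  structure(
    list(global = c(accuracy = mean(per_fold$accuracy),
                    mcc = mean(per_fold$mcc),
                    f = mean(per_fold$f)),
         per_fold = per_fold,
         per_class = per_class_metrics(pooled),
         confusion = pooled,
         spec = spec, k = k, seed = seed, n = nrow(features)),
    class = "cv_eval")
}

#' @export
print.cv_eval <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold CV of %s on %d sequences\n", x$k, x$spec$family, x$n))
  cat(sprintf("  accuracy %.*f  MCC %.*f  macro-F %.*f (fold means)\n",
              digits, x$global["accuracy"], digits, x$global["mcc"],
              digits, x$global["f"]))
  cat("Per-class (pooled folds):\n")
  print(format(x$per_class, digits = digits), row.names = FALSE)
  invisible(x)
}
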