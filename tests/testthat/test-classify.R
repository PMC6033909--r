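# Synthetic Gaussian blob features for classifier behaviour tests.
make_blobs <- function(n_per_class, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  m <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(m), function(c)
    sweep(matrix(rnorm(n_per_class * ncol(centers), sd = sd),
                 n_per_class), 2, centers[c, ], "+")))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  rownames(x) <- sprintf("b%03d", seq_len(nrow(x)))
  list(x = x, y = rep(rownames(centers), each = n_per_class))
}

test_that("separable two-class data yields zero errors and unanimous votes", {
  b <- make_blobs(20, rbind(a = c(0, 0), b = c(5, 5)), seed = 51)
  tr <- c(1:15, 21:35); te <- c(16:20, 36:40)
  rec <- fit_predict_fold(b$x[tr, ], b$y[tr], b$x[te, ],
                          classifier_spec("svm"))
  expect_equal(rec$predicted, b$y[te])
  winner <- ifelse(rec$predicted == "a", rec$vote.a, rec$vote.b)
  loser <- ifelse(rec$predicted == "a", rec$vote.b, rec$vote.a)
  expect_true(all(winner == 1 & loser == 0))
})

test_that("one-vs-one votes always sum to m(m-1)/2", {
  b <- make_blobs(15, rbind(a = c(0, 0), b = c(3, 0), c = c(0, 3),
                            d = c(3, 3)), sd = 1, seed = 52)
  folds <- stratified_folds(b$y, 3, seed = 5)
  for (f in 1:3) {
    te <- folds == f
    rec <- fit_predict_fold(b$x[!te, ], b$y[!te], b$x[te, ],
                            classifier_spec("svm"))
    vs <- rowSums(rec[, paste0("vote.", c("a", "b", "c", "d"))])
    expect_true(all(vs == choose(4, 2)))
  }
})

test_that("decision values orient positive toward the first class of the pair", {
  b <- make_blobs(25, rbind(a = c(0, 0), b = c(6, 6)), seed = 53)
  rec <- fit_predict_fold(b$x, b$y, rbind(c(0, 0), c(6, 6)),
                          classifier_spec("svm"), test_ids = c("ta", "tb"))
  expect_gt(rec[["dv.a|b"]][1], 0)  # an 'a'-like point
  expect_lt(rec[["dv.a|b"]][2], 0)  # a 'b'-like point
})

test_that("Gaussian NB matches the closed-form posterior rule in 1-D", {
  set.seed(54)
  n <- 400
  x <- matrix(c(rnorm(n, 0, 1), rnorm(n, 2, 1)), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- rep(c("lo", "hi"), each = n)
  grid <- matrix(seq(-1, 3, by = 0.05), ncol = 1,
                 dimnames = list(NULL, "f1"))
  rec <- fit_predict_fold(x, y, grid, classifier_spec("nb"))
  # closed-form MAP rule with the same maximum-likelihood estimates
  mu <- tapply(x[, 1], y, mean); sg <- tapply(x[, 1], y, sd)
  post_lo <- dnorm(grid[, 1], mu["lo"], sg["lo"])
  post_hi <- dnorm(grid[, 1], mu["hi"], sg["hi"])
  oracle <- ifelse(post_lo > post_hi, "lo", "hi")
  # agreement away from the knife-edge crossing point
  margin <- abs(post_lo - post_hi) > 1e-3
  expect_true(all(rec$predicted[margin] == oracle[margin]))
})

test_that("stratified folds partition every class proportionally", {
  y <- rep(c("a", "b", "c"), times = c(20, 15, 10))
  folds <- stratified_folds(y, 5, seed = 55)
  expect_equal(sort(unique(folds)), 1:5)
  expect_length(folds, 45)
  for (cl in c("a", "b", "c")) {
    per_fold <- table(folds[y == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(stratified_folds(c("a", "a", "b"), 3), "smaller than k")
})

test_that("cross-validated evaluation is exact on separable data", {
  b <- make_blobs(15, rbind(a = c(0, 0), b = c(8, 0), c = c(0, 8)),
                  seed = 56)
  for (fam in c("svm", "rf", "nb")) {
    ev <- evaluate_cv(b$x, b$y, classifier_spec(fam, ntree = 100), k = 3,
                      seed = 6)
    expect_equal(unname(ev$global["accuracy"]), 1)
    expect_equal(unname(ev$global["mcc"]), 1)
    expect_equal(unname(ev$global["f"]), 1)
    expect_true(all(ev$per_class$precision == 1 & ev$per_class$recall == 1))
  }
})

test_that("shuffled labels drive the MCC to chance level", {
  set.seed(57)
  n <- 500
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(rep(c("a", "b"), each = n / 2))
  ev <- evaluate_cv(x, y, classifier_spec("svm"), k = 5, seed = 7)
  expect_lt(abs(ev$global["mcc"]), 0.12)
  expect_lt(abs(ev$global["accuracy"] - 0.5), 0.07)
})

test_that("grid search stays inside the training folds (no optimism on noise)", {
  set.seed(58)
  n <- 120
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c("a", "b"), each = n / 2)
  spec <- classifier_spec("svm", grid = list(cost = c(0.1, 10),
                                             gamma = c(0.01, 1)))
  ev <- evaluate_cv(x, y, spec, k = 4, seed = 8)
  # pure-noise features: a leak-free search cannot beat chance materially
  expect_lt(ev$global["accuracy"], 0.5 + 0.17)
})

test_that("degenerate training inputs raise errors", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_error(fit_predict_fold(x, rep("a", 10), x, classifier_spec("svm")),
               "single class")
  expect_error(fit_predict_fold(x, rep(c("a", "b"), 5), x[, 1, drop = FALSE],
                                classifier_spec("svm")), "mismatch")
})
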