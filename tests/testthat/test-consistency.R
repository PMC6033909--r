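small_gen <- function(seed = 61, flip = 0) {
  generate_sequences(m = 3, n_per_class = 10, separation = 3,
                     flip_fraction = flip, seed = seed,
                     length_range = c(60, 120))
}

test_that("repeated CV gives every sequence one test record per iteration", {
  gen <- small_gen()
  fm <- transform_set(gen$sequences, "aac")
  rec <- repeated_cv(fm, gen$sequences$label, classifier_spec("svm"),
                     iterations = 4, k = 5, seed = 3)
  counts <- table(rec$id)
  expect_true(all(counts == 4))
  expect_equal(nrow(rec), length(gen$sequences) * 4)
  # one iteration reduces to a single k-fold pass
  rec1 <- repeated_cv(fm, gen$sequences$label, classifier_spec("svm"),
                      iterations = 1, k = 5, seed = 3)
  expect_equal(nrow(rec1), length(gen$sequences))
  # fold resampling differs across iterations
  expect_false(identical(rec$predicted[rec$iteration == 1],
                         rec$predicted[rec$iteration == 2]) &&
               identical(fold_plan(gen$sequences$label, 2, 5, 3)[[1]],
                         fold_plan(gen$sequences$label, 2, 5, 3)[[2]]))
})

test_that("identical master seeds reproduce the record set exactly", {
  gen <- small_gen()
  fm <- transform_set(gen$sequences, "aac")
  r1 <- repeated_cv(fm, gen$sequences$label, classifier_spec("svm"),
                    iterations = 3, k = 5, seed = 9)
  r2 <- repeated_cv(fm, gen$sequences$label, classifier_spec("svm"),
                    iterations = 3, k = 5, seed = 9)
  expect_identical(r1, r2)
})

test_that("error rate counts misclassified test predictions in percent", {
  classes <- c("a", "b")
  pred <- matrix(c(rep("b", 8), rep("a", 2)), ncol = 1)
  rec <- make_records("s1", "a", pred,
                      list(matrix(c(0L, 1L), 10, 2, byrow = TRUE)),
                      list(matrix(-0.5, 10, 1)), classes)
  expect_equal(unname(error_rate(rec)), 80)
  pred0 <- matrix(rep("a", 10), ncol = 1)
  rec0 <- make_records("s1", "a", pred0,
                       list(matrix(c(1L, 0L), 10, 2, byrow = TRUE)),
                       list(matrix(0.5, 10, 1)), classes)
  expect_equal(unname(error_rate(rec0)), 0)
  # random records against a direct counting oracle
  rr <- random_records(sprintf("s%d", 1:6), c("a", "b", "c"), 12, seed = 62)
  er <- error_rate(rr)
  for (s in unique(rr$id)) {
    sub <- rr[rr$id == s, ]
    expect_equal(unname(er[s]), 100 * sum(sub$predicted != sub$true) / 12)
  }
})

test_that("voting ratio is VT over VP with the documented conventions", {
  classes <- c("a", "b")
  # always correct: modal class is the true class, R = 1
  rec0 <- make_records("s1", "a", matrix(rep("a", 10), ncol = 1),
                       list(matrix(c(1L, 0L), 10, 2, byrow = TRUE)),
                       list(matrix(0.5, 10, 1)), classes)
  expect_equal(voting_ratio(rec0), 1)
  expect_equal(modal_predicted_class(rec0)[["s1"]], "a")
  # VT 30, VP 90 -> R = 1/3, flagged consistent at the default threshold
  classes3 <- c("a", "b", "c")
  votes <- matrix(rep(c(3L, 9L, 0L), each = 10), 10, 3)  # totals 30/90/0
  rec <- make_records("s1", "a", matrix(rep("b", 10), ncol = 1),
                      list(votes), list(matrix(-1, 10, 3)), classes3)
  expect_equal(voting_ratio(rec), 30 / 90)
  expect_true(30 / 90 <= noise_thresholds()$theta_r)
  # random records against an independent summation oracle
  rr <- random_records(sprintf("s%d", 1:5), c("a", "b", "c", "d"), 8,
                       seed = 63)
  modal <- modal_predicted_class(rr)
  for (s in unique(rr$id)) {
    sub <- rr[rr$id == s, ]
    vt <- sum(sub[[paste0("vote.", sub$true[1])]])
    vp <- sum(sub[[paste0("vote.", modal[[s]])]])
    expect_equal(voting_ratio(sub), vt / vp)
  }
})

test_that("cumulative decision value sums the true-vs-modal pair margin", {
  classes <- c("a", "b")
  mk <- function(dv) make_records("s1", "a", matrix(rep("b", 10), ncol = 1),
                                  list(matrix(c(0L, 1L), 10, 2, byrow = TRUE)),
                                  list(matrix(dv, 10, 1)), classes)
  expect_equal(cumulative_decision_value(mk(0)), 0)
  expect_false(abs(cumulative_decision_value(mk(0))) >=
                 noise_thresholds()$theta_cdv)
  cdv <- cumulative_decision_value(mk(-1))
  expect_equal(cdv, -10)
  # at 100 iterations the same margins accumulate past the magnitude gate
  rec100 <- make_records("s1", "a", matrix(rep("b", 100), ncol = 1),
                         list(matrix(c(0L, 1L), 100, 2, byrow = TRUE)),
                         list(matrix(-1, 100, 1)), classes)
  expect_equal(cumulative_decision_value(rec100), -100)
  expect_true(abs(-100) >= noise_thresholds()$theta_cdv)
  # orientation flips when the true class is second in class order
  recb <- make_records("s1", "b", matrix(rep("a", 10), ncol = 1),
                       list(matrix(c(1L, 0L), 10, 2, byrow = TRUE)),
                       list(matrix(0.7, 10, 1)), classes)
  expect_equal(cumulative_decision_value(recb), -7)
  # coinciding classes are an error
  rec0 <- make_records("s1", "a", matrix(rep("a", 10), ncol = 1),
                       list(matrix(c(1L, 0L), 10, 2, byrow = TRUE)),
                       list(matrix(0.5, 10, 1)), classes)
  expect_error(cumulative_decision_value(rec0), "coincide")
  # random records against a summation oracle
  rr <- random_records(sprintf("s%d", 1:5), c("a", "b", "c"), 9, seed = 64)
  modal <- modal_predicted_class(rr)
  pairs <- combn(c("a", "b", "c"), 2)
  for (s in unique(rr$id)) {
    sub <- rr[rr$id == s, ]
    i <- sub$true[1]; j <- modal[[s]]
    if (i == j) next
    col <- paste0("dv.", min(i, j), "|", max(i, j))
    want <- if (i < j) sum(sub[[col]]) else -sum(sub[[col]])
    expect_equal(cumulative_decision_value(sub), want)
  }
})

test_that("consistency statistics are invariant to record order", {
  rr <- random_records(sprintf("s%d", 1:4), c("a", "b", "c"), 10, seed = 65)
  set.seed(66)
  shuf <- rr[sample(nrow(rr)), ]
  attr(shuf, "classes") <- attr(rr, "classes")
  expect_equal(error_rate(rr)[sort(unique(rr$id))],
               error_rate(shuf)[sort(unique(rr$id))])
  p1 <- shortlist(rr); p2 <- shortlist(shuf)
  p2 <- p2[match(p1$id, p2$id), ]
  expect_equal(p1$er, p2$er)
  expect_equal(p1$r, p2$r)
  expect_equal(p1$cdv, p2$cdv)
})

test_that("shortlist applies thresholds and keeps unselected sequences", {
  classes <- c("a", "b")
  mk1 <- function(id, n_wrong, dv) {
    pred <- matrix(c(rep("b", n_wrong), rep("a", 10 - n_wrong)), ncol = 1)
    votes <- matrix(0L, 10, 2); votes[, 1] <- c(rep(0L, n_wrong), rep(1L, 10 - n_wrong))
    votes[, 2] <- 1L - votes[, 1]
    make_records(id, "a", pred, list(votes), list(matrix(dv, 10, 1)), classes)
  }
  rec <- rbind(mk1("half", 5, -0.1), mk1("bad", 10, -7))
  attr(rec, "classes") <- classes
  prof <- shortlist(rec, noise_thresholds())
  expect_setequal(prof$id, c("half", "bad"))
  half <- prof[prof$id == "half", ]
  expect_equal(half$er, 50)
  expect_false(half$selected)
  bad <- prof[prof$id == "bad", ]
  expect_true(bad$selected)
  expect_equal(bad$er, 100)
  expect_equal(bad$r, 0)
  expect_true(bad$consistent)
  expect_equal(bad$cdv, -70)
  expect_true(bad$large)
  # flags recompute from the stored statistics
  th <- noise_thresholds()
  expect_equal(prof$selected, prof$er >= th$theta_er)
  expect_equal(prof$consistent, !is.na(prof$r) & prof$r <= th$theta_r)
  expect_equal(prof$large, !is.na(prof$cdv) & abs(prof$cdv) >= th$theta_cdv)
  # sorted by descending ER
  expect_equal(prof$id, c("bad", "half"))
})

test_that("noise_scan wraps records and profiles with working methods", {
  gen <- small_gen(flip = 0.1)
  scan <- noise_scan(gen$sequences, transform = "aac", iterations = 3,
                     k = 5, seed = 4)
  expect_s3_class(scan, "noise_scan")
  expect_equal(nrow(scan$profiles), length(gen$sequences))
  expect_equal(nrow(scan$records), length(gen$sequences) * 3)
  expect_output(print(scan), "Label-noise scan")
  expect_output(summary(scan), "Shortlist|No sequence")
  expect_silent(grDevices::pdf(NULL))
  expect_invisible(plot(scan))
  grDevices::dev.off()
  df <- as.data.frame(scan)
  expect_true(all(c("er", "r", "cdv", "selected") %in% names(df)))
})

test_that("cross-transform consensus tallies selections per sequence", {
  mkprof <- function(sel_ids, pred) {
    data.frame(id = c("s1", "s2", "s3"), true_class = "a",
               predicted_class = pred, er = 0, r = 1, cdv = NA,
               n_iterations = 10L,
               selected = c("s1", "s2", "s3") %in% sel_ids,
               consistent = FALSE, large = FALSE, stringsAsFactors = FALSE)
  }
  profs <- list(t1 = mkprof(c("s1"), c("b", "a", "a")),
                t2 = mkprof(c("s1", "s2"), c("b", "c", "a")),
                t3 = mkprof(c("s1"), c("b", "a", "a")),
                t4 = mkprof(c("s1"), c("b", "a", "a")),
                t5 = mkprof(c("s1"), c("c", "a", "a")))
  cons <- cross_transform_consensus(profs)
  expect_equal(cons$n_flagged[cons$id == "s1"], 5)
  expect_equal(cons$n_flagged[cons$id == "s2"], 1)
  expect_equal(cons$n_flagged[cons$id == "s3"], 0)
  # the predicted-class multiset is reported across transforms
  expect_match(cons$predicted[cons$id == "s1"], "b x4")
  expect_match(cons$predicted[cons$id == "s1"], "c x1")
  expect_error(cross_transform_consensus(
    list(a = mkprof("s1", c("b", "a", "a")),
         b = mkprof("s1", c("b", "a", "a"))[1:2, ])), "different")
})
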