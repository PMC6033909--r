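#' Shortlisting thresholds for the consistency analysis
#'
#' Defaults follow the three-step screening procedure: a sequence is
#' *selected* when its repeated-CV error rate reaches `theta_er`
#' percent, its error is deemed *consistent* when the voting ratio
#' falls at or below `theta_r`, and *large* when the cumulative
#' decision value reaches `theta_cdv` in absolute value.
#'
#' @param theta_er error-rate threshold in percent, in (0, 100].
#' @param theta_r voting-ratio threshold, positive.
#' @param theta_cdv cumulative-decision-value magnitude threshold,
#'   non-negative.
#' @return A list of class `noise_thresholds`.
#' @export
noise_thresholds <- function(theta_er = 75, theta_r = 0.5, theta_cdv = 60) {
  stopifnot(theta_er > 0, theta_er <= 100, theta_r > 0, theta_cdv >= 0)
  structure(list(theta_er = theta_er, theta_r = theta_r,
                 theta_cdv = theta_cdv),
            class = "noise_thresholds")
}

#' Repeated resampled stratified k-fold cross-validation
#'
#' Runs `iterations` independent rounds of stratified k-fold CV, with
#' fold assignments re-drawn each round from a per-iteration seed, and
#' collects every test-time prediction: each sequence contributes
#' exactly one test record per iteration. For the one-vs-one SVM
#' family the records also carry the per-class vote counts and the
#' oriented pairwise decision values that feed the voting ratio and
#' the cumulative decision value.
#'
#' @param features numeric feature matrix, rownames = sequence ids.
#' @param labels class labels, parallel to rows.
#' @param spec a [classifier_spec()].
#' @param iterations repetitions (default 100).
#' @param k folds per repetition (default 5).
#' @param seed master seed; all per-iteration and per-fold seeds are
#'   derived from it.
#' @param folds optional list of precomputed fold assignments, one
#'   integer vector per iteration (used to share fold plans across
#'   transforms).
#' @return A data frame of class `cv_records` with one row per
#'   (sequence, iteration): columns `id`, `iteration`, `true`,
#'   `predicted`, plus `vote.<class>` and `dv.<pair>` for the svm
#'   family. Attributes: `classes`, `iterations`.
#' @export
repeated_cv <- function(features, labels, spec = classifier_spec("svm"),
                        iterations = 100L, k = 5L, seed = 1L, folds = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels), iterations >= 1L)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  classes <- sort(unique(labels))
  if (is.null(folds)) folds <- fold_plan(labels, iterations, k, seed)
  stopifnot(length(folds) == iterations)

  chunks <- vector("list", iterations * k)
  ci <- 0L
  for (it in seq_len(iterations)) {
    fvec <- folds[[it]]
    for (f in seq_len(max(fvec))) {
      te <- fvec == f
      set.seed((seed %% 1000L) * 1000000L + it * 100L + f)
      rec <- fit_predict_fold(features[!te, , drop = FALSE], labels[!te],
                              features[te, , drop = FALSE], spec,
                              classes = classes, test_ids = ids[te])
      rec <- cbind(data.frame(id = rec$id, iteration = it,
                              true = labels[te], stringsAsFactors = FALSE),
                   rec[, -1L, drop = FALSE])
      ci <- ci + 1L
      chunks[[ci]] <- rec
    }
  }
  out <- do.call(rbind, chunks[seq_len(ci)])
  out <- out[order(out$iteration, match(out$id, ids)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, classes = classes, iterations = iterations,
            class = c("cv_records", "data.frame"))
}

#' Draw per-iteration stratified fold assignments
#'
#' @param labels class labels.
#' @param iterations number of repetitions.
#' @param k folds.
#' @param seed master seed; iteration seeds are drawn from it.
#' @return List of `iterations` integer fold vectors.
#' @export
fold_plan <- function(labels, iterations, k = 5L, seed = 1L) {
  set.seed(seed)
  it_seeds <- sample.int(.Machine$integer.max - 1L, iterations)
  lapply(it_seeds, function(s) stratified_folds(labels, k, seed = s))
}

rec_classes <- function(records) {
  cl <- attr(records, "classes")
  if (is.null(cl)) cl <- sort(unique(c(records$true, records$predicted)))
  cl
}

#' Per-sequence error rate over repeated-CV records
#'
#' The percentage of test-time predictions that disagree with the
#' stored label.
#'
#' @param records a `cv_records` data frame (any subset of sequences).
#' @return Named numeric vector (percent, 0-100), one entry per
#'   sequence id, in first-appearance order.
#' @export
error_rate <- function(records) {
  stopifnot(nrow(records) >= 1L)
  miss <- tapply(records$predicted != records$true, records$id, mean)
  100 * miss[unique(records$id)]
}

#' Modal predicted class per sequence
#'
#' The most frequent predicted label over a sequence's records. Ties
#' are broken toward the tied class with the larger total one-vs-one
#' vote count, then by class order.
#'
#' @param records a `cv_records` data frame.
#' @return Named character vector, one entry per sequence id.
#' @export
modal_predicted_class <- function(records) {
  classes <- rec_classes(records)
  vcols <- paste0("vote.", classes)
  has_votes <- all(vcols %in% names(records))
  out <- vapply(split(records, factor(records$id, levels = unique(records$id))),
    function(r) {
      tab <- table(factor(r$predicted, levels = classes))
      top <- classes[tab == max(tab)]
      if (length(top) > 1L && has_votes) {
        tot <- vapply(top, function(cl) sum(r[[paste0("vote.", cl)]]), 0)
        top <- top[tot == max(tot)]
      }
      top[1L]
    }, character(1L))
  out
}

#' Voting ratio of a single sequence
#'
#' R = VT / VP, the total one-vs-one votes accrued by the true class
#' over those accrued by the most frequently predicted class, summed
#' over all records (all binary classifiers, all iterations). R equals
#' 1 when the modal prediction is the true class; values at or below
#' the threshold signal a consistent classification error.
#'
#' @param records records of one sequence (svm family, with vote columns).
#' @param modal the modal predicted class; computed if missing.
#' @return A non-negative number.
#' @export
voting_ratio <- function(records, modal = NULL) {
  stopifnot(length(unique(records$id)) == 1L)
  true <- records$true[1L]
  if (is.null(modal)) modal <- modal_predicted_class(records)[[1L]]
  vt <- sum(records[[paste0("vote.", true)]])
  vp <- sum(records[[paste0("vote.", modal)]])
  if (vp == 0) stop("modal class received zero votes; records inconsistent")
  vt / vp
}

#' Cumulative decision value of a single sequence
#'
#' The sum over test iterations of the decision value of the binary
#' classifier confronting the true class i with the modal predicted
#' class j. The stored orientation is positive toward the first class
#' of the pair in class order; the returned CDV keeps that sign
#' convention oriented positive toward the true class, so a large
#' negative CDV means the pair classifier confidently sided with the
#' modal (wrong) class throughout.
#'
#' @param records records of one sequence (svm family, with dv columns).
#' @param true_class,modal true and modal predicted class; computed
#'   from the records if missing. Must differ.
#' @return A signed number.
#' @export
cumulative_decision_value <- function(records, true_class = NULL,
                                      modal = NULL) {
  stopifnot(length(unique(records$id)) == 1L)
  classes <- rec_classes(records)
  if (is.null(true_class)) true_class <- records$true[1L]
  if (is.null(modal)) modal <- modal_predicted_class(records)[[1L]]
  if (true_class == modal)
    stop("true and modal predicted class coincide; no opposing pair")
  i <- match(true_class, classes); j <- match(modal, classes)
  if (i < j) sum(records[[paste0("dv.", true_class, "|", modal)]])
  else      -sum(records[[paste0("dv.", modal, "|", true_class)]])
}

#' Per-sequence misclassification profiles and shortlist flags
#'
#' The three-step consistency analysis applied to repeated-CV records:
#' (1) the error rate ER of every sequence, with sequences at or above
#' `theta_er` percent *selected*; (2) the voting ratio R = VT/VP, with
#' R at or below `theta_r` flagging a *consistent* error; (3) the
#' cumulative decision value CDV of the true-vs-modal pair classifier,
#' *large* when `|CDV| >= theta_cdv`. R and CDV are computed for every
#' sequence (CDV is NA when the modal prediction equals the true
#' class) but are meant to be interpreted for selected sequences.
#'
#' @param records a `cv_records` data frame from [repeated_cv()].
#' @param thresholds a [noise_thresholds()].
#' @return A data frame of class `noise_profiles`, one row per
#'   sequence, sorted by decreasing ER then |CDV|: columns `id`,
#'   `true_class`, `predicted_class` (modal), `er`, `r`, `cdv`,
#'   `n_iterations`, `selected`, `consistent`, `large`.
#' @export
shortlist <- function(records, thresholds = noise_thresholds()) {
  stopifnot(inherits(thresholds, "noise_thresholds"))
  ids <- unique(records$id)
  classes <- rec_classes(records)
  has_votes <- all(paste0("vote.", classes) %in% names(records))
  er <- error_rate(records)
  modal <- modal_predicted_class(records)
  by_id <- split(records, factor(records$id, levels = ids))
  r <- cdv <- rep(NA_real_, length(ids))
  for (s in seq_along(ids)) {
    rec <- by_id[[s]]
    if (has_votes) {
      r[s] <- voting_ratio(rec, modal[[ids[s]]])
      if (modal[[ids[s]]] != rec$true[1L])
        cdv[s] <- cumulative_decision_value(rec, rec$true[1L], modal[[ids[s]]])
    }
  }
  prof <- data.frame(
    id = ids,
    true_class = vapply(by_id, function(r) r$true[1L], character(1L)),
    predicted_class = unname(modal[ids]),
    er = unname(er[ids]),
    r = r,
    cdv = cdv,
    n_iterations = as.integer(unname(table(records$id)[ids])),
    stringsAsFactors = FALSE)
  prof$selected <- prof$er >= thresholds$theta_er
  prof$consistent <- !is.na(prof$r) & prof$r <= thresholds$theta_r
  prof$large <- !is.na(prof$cdv) & abs(prof$cdv) >= thresholds$theta_cdv
  ord <- order(-prof$er, -abs(ifelse(is.na(prof$cdv), -Inf, prof$cdv)))
  prof <- prof[ord, , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, thresholds = thresholds,
            class = c("noise_profiles", "data.frame"))
}

#' Screen a labeled collection for suspect class labels
#'
#' The package's central fitting function. Repeated resampled
#' stratified k-fold cross-validation is run on an alignment-free
#' feature representation of the sequences, and every sequence's
#' test-time behaviour is condensed into a misclassification profile:
#' error rate ER (percent of repetitions misclassified), voting ratio
#' R = VT/VP (one-vs-one votes of the true class over the modal
#' predicted class) and cumulative decision value CDV (summed margin
#' of the true-vs-modal pair classifier). Sequences with ER at or
#' above the selection threshold, low R and large |CDV| are the
#' archetype of suspected label noise and are shortlisted for curator
#' review; the function never rewrites labels.
#'
#' @param x a [seqset()], or a numeric feature matrix with rownames
#'   (then `labels` is required).
#' @param labels class labels when `x` is a matrix; ignored for a
#'   `seqset`.
#' @param transform transform applied when `x` is a `seqset`; see
#'   [transform_set()].
#' @param classifier a [classifier_spec()]; the voting ratio and CDV
#'   require the one-vs-one `"svm"` family.
#' @param iterations repeated-CV repetitions (default 100).
#' @param k folds (default 5).
#' @param seed master seed.
#' @param thresholds a [noise_thresholds()].
#' @param ... passed to [transform_set()] (e.g. `max_lag`, `embeddings`).
#' @return An object of class `noise_scan`: list with `profiles`
#'   (the [shortlist()] table), `records` (all test predictions),
#'   `thresholds`, `classifier`, `transform`, `n`, `classes`, `call`.
#' @seealso [shortlist()], [repeated_cv()], [cross_transform_consensus()]
#' @examples
#' gen <- generate_sequences(m = 3, n_per_class = 20, separation = 3,
#'                           flip_fraction = 0.05, seed = 42)
#' scan <- noise_scan(gen$sequences, transform = "aac",
#'                    iterations = 5, seed = 42)
#' summary(scan)
#' @export
noise_scan <- function(x, labels = NULL, transform = "aac",
                       classifier = classifier_spec("svm"),
                       iterations = 100L, k = 5L, seed = 1L,
                       thresholds = noise_thresholds(), ...) {
  cl <- match.call()
  if (inherits(x, "seqset")) {
    labels <- x$label
    features <- transform_set(x, transform = transform, ...)
    tname <- transform
  } else {
    features <- as.matrix(x)
    if (is.null(labels)) stop("labels required when x is a feature matrix")
    tname <- attr(x, "transform")
    if (is.null(tname)) tname <- "precomputed"
  }
  records <- repeated_cv(features, labels, classifier,
                         iterations = iterations, k = k, seed = seed)
  profiles <- shortlist(records, thresholds)
  structure(
    list(profiles = profiles, records = records, thresholds = thresholds,
         classifier = classifier, transform = tname,
         n = nrow(features), classes = rec_classes(records),
         iterations = iterations, k = k, seed = seed, call = cl),
    class = "noise_scan")
}

#' @export
print.noise_scan <- function(x, ...) {
  cat(sprintf("Label-noise scan: %d sequences, %d classes, %s features, %s classifier\n",
              x$n, length(x$classes), x$transform, x$classifier$family))
  cat(sprintf("%d iterations of resampled %d-fold CV (seed %d)\n",
              x$iterations, x$k, x$seed))
  nsel <- sum(x$profiles$selected)
  cat(sprintf("Selected (ER >= %g%%): %d sequence(s)\n",
              x$thresholds$theta_er, nsel))
  invisible(x)
}

#' @export
summary.noise_scan <- function(object, ...) {
  print(object)
  sel <- object$profiles[object$profiles$selected, , drop = FALSE]
  if (nrow(sel)) {
    cat("\nShortlist:\n")
    print(format(sel[, c("id", "true_class", "predicted_class", "er", "r",
                         "cdv", "consistent", "large")],
                 digits = 4), row.names = FALSE)
  } else {
    cat("\nNo sequence reaches the selection threshold.\n")
  }
  invisible(object$profiles)
}

#' @export
as.data.frame.noise_scan <- function(x, ...) as.data.frame(x$profiles)

#' Plot method: error rate against cumulative decision value
#'
#' Each point is a sequence; dashed lines mark the selection and
#' magnitude thresholds. Selected sequences are highlighted.
#'
#' @param x a `noise_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.noise_scan <- function(x, ...) {
  p <- x$profiles
  cdv <- ifelse(is.na(p$cdv), 0, p$cdv)
  graphics::plot(p$er, cdv, xlab = "error rate ER (%)",
                 ylab = "cumulative decision value CDV",
                 pch = ifelse(p$selected, 19, 1),
                 col = ifelse(p$selected, "firebrick", "grey40"),
                 xlim = c(0, 100), ...)
  graphics::abline(v = x$thresholds$theta_er, lty = 2)
  graphics::abline(h = c(-1, 1) * x$thresholds$theta_cdv, lty = 3)
  invisible(x)
}

#' Consensus of shortlists across transformations
#'
#' A sequence consistently misclassified under several independent
#' representations is a stronger label-noise suspect than one flagged
#' by a single representation. Counts, for every sequence, how many of
#' the supplied scans selected it, and collects the predicted classes
#' across transforms.
#'
#' @param scans a named list (length >= 2) of `noise_scan` objects or
#'   `noise_profiles` data frames over the same sequence ids.
#' @return A data frame, one row per sequence, sorted by decreasing
#'   `n_flagged`: columns `id`, `true_class`, `n_flagged`,
#'   `n_transforms`, `predicted` (comma-separated `class xcount`).
#' @export
cross_transform_consensus <- function(scans) {
  stopifnot(length(scans) >= 2L)
  profs <- lapply(scans, function(s)
    if (inherits(s, "noise_scan")) s$profiles else s)
  ids <- sort(unique(profs[[1L]]$id))
  for (p in profs[-1L])
    if (!setequal(p$id, ids)) stop("scans cover different sequence id sets")
  flagged <- sapply(profs, function(p) {
    m <- match(ids, p$id); p$selected[m]
  })
  preds <- sapply(profs, function(p) p$predicted_class[match(ids, p$id)])
  true <- profs[[1L]]$true_class[match(ids, profs[[1L]]$id)]
  pred_str <- apply(as.matrix(preds), 1L, function(r) {
    tab <- sort(table(r), decreasing = TRUE)
    paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", ")
  })
  out <- data.frame(id = ids, true_class = true,
                    n_flagged = as.integer(rowSums(as.matrix(flagged))),
                    n_transforms = length(profs),
                    predicted = pred_str, stringsAsFactors = FALSE)
  out <- out[order(-out$n_flagged, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
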