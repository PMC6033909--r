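#' Compare two releases of a labeled sequence collection
#'
#' Reports, per class, how many records of version A survive unchanged
#' into version B. A record is "preserved" when its match key (the
#' exact primary sequence string by default, or the identifier) occurs
#' in the other version *with the same class label*. Sequence-string
#' matching is the default because accession schemes often change
#' between database releases while the underlying sequence does not.
#' Duplicate keys are matched as multisets (pairwise, up to the
#' smaller multiplicity).
#'
#' @param a,b two [seqset()] objects (version A and version B).
#' @param match_on `"sequence"` (default) or `"id"`.
#' @return A data frame of class `version_diff`, one row per class
#'   (union of both versions' classes, classes absent from a version
#'   counted 0) plus a `total` row: columns `class`, `count_a`,
#'   `count_b`, `intersection`, `percent_preserved` (relative to A; 0
#'   when A has no records of that class).
#' @export
intersect_versions <- function(a, b, match_on = c("sequence", "id")) {
  stopifnot(inherits(a, "seqset"), inherits(b, "seqset"))
  match_on <- match.arg(match_on)
  key_a <- if (match_on == "sequence") a$sequence else a$id
  key_b <- if (match_on == "sequence") b$sequence else b$id
  classes <- unique(c(a$class_names, b$class_names))

  rows <- lapply(classes, function(cl) {
    ka <- key_a[a$label == cl]
    kb <- key_b[b$label == cl]
    shared <- intersect(ka, kb)
    inter <- sum(vapply(shared, function(k)
      min(sum(ka == k), sum(kb == k)), 0))
    data.frame(class = cl, count_a = length(ka), count_b = length(kb),
               intersection = as.integer(inter),
               percent_preserved = if (length(ka)) 100 * inter / length(ka) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot_inter <- sum(out$intersection)
  out <- rbind(out, data.frame(
    class = "total", count_a = sum(out$count_a), count_b = sum(out$count_b),
    intersection = tot_inter,
    percent_preserved = if (sum(out$count_a)) 100 * tot_inter / sum(out$count_a) else 0,
    stringsAsFactors = FALSE))
  structure(out, match_on = match_on,
            class = c("version_diff", "data.frame"))
}

#' @export
print.version_diff <- function(x, ...) {
  cat("Version comparison (match on", attr(x, "match_on"), "):\n")
  y <- x
  y$percent_preserved <- sprintf("%.1f%%", y$percent_preserved)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
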