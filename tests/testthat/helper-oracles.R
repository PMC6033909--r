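# Independent brute-force oracles and tiny fixture builders. These are
# deliberately written as plain loops, independent of the package's
# vectorized implementations.

AA <- aa_alphabet()

random_seq <- function(n, prob = NULL) {
  paste(sample(AA, n, replace = TRUE, prob = prob), collapse = "")
}

oracle_aac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- setNames(numeric(20), AA)
  for (c in ch) out[c] <- out[c] + 1
  out / nchar(s)
}

oracle_digram <- function(s) {
  ch <- strsplit(s, "")[[1]]
  nm <- as.vector(t(outer(AA, AA, paste0)))
  out <- setNames(numeric(400), nm)
  for (t in 1:(length(ch) - 1)) {
    p <- paste0(ch[t], ch[t + 1])
    out[p] <- out[p] + 1
  }
  out / (length(ch) - 1)
}

# Explicit double loop over positions and lags; lag-major output,
# (j,k) lexicographic within lag.
oracle_acc <- function(s, L, table = zscale_table()) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  Z <- matrix(NA_real_, n, 5)
  for (t in 1:n) Z[t, ] <- table[ch[t], ]
  for (j in 1:5) Z[, j] <- Z[, j] - mean(Z[, j])
  out <- numeric(0)
  for (l in 1:L) {
    for (j in 1:5) for (k in 1:5) {
      acc <- 0
      for (t in 1:(n - l)) acc <- acc + Z[t, j] * Z[t + l, k]
      out <- c(out, acc / (n - l))
    }
  }
  out
}

# Hand-built repeated-CV record table for the consistency statistics:
# one row per iteration for each sequence, with vote and decision-value
# columns in the package's layout.
make_records <- function(ids, true, predicted, votes, dvs, classes) {
  n_it <- nrow(predicted)
  rows <- list()
  pairs <- combn(classes, 2)
  for (s in seq_along(ids)) for (k in seq_len(n_it)) {
    row <- data.frame(id = ids[s], iteration = k, true = true[s],
                      predicted = predicted[k, s], stringsAsFactors = FALSE)
    for (ci in seq_along(classes))
      row[[paste0("vote.", classes[ci])]] <- votes[[s]][k, ci]
    for (p in seq_len(ncol(pairs)))
      row[[paste0("dv.", pairs[1, p], "|", pairs[2, p])]] <- dvs[[s]][k, p]
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  structure(out, classes = classes, iterations = n_it,
            class = c("cv_records", "data.frame"))
}

# Random but structurally valid one-vs-one records for m classes:
# votes per row sum to choose(m, 2).
random_records <- function(ids, classes, n_it, seed) {
  set.seed(seed)
  m <- length(classes)
  pairs <- combn(classes, 2)
  true <- sample(classes, length(ids), replace = TRUE)
  predicted <- matrix(sample(classes, n_it * length(ids), replace = TRUE),
                      n_it, length(ids))
  votes <- dvs <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    v <- matrix(0L, n_it, m)
    d <- matrix(round(rnorm(n_it * ncol(pairs)), 3), n_it, ncol(pairs))
    for (k in seq_len(n_it)) {
      for (p in seq_len(ncol(pairs))) {
        w <- if (d[k, p] > 0) pairs[1, p] else pairs[2, p]
        v[k, match(w, classes)] <- v[k, match(w, classes)] + 1L
      }
    }
    votes[[s]] <- v; dvs[[s]] <- d
  }
  make_records(ids, true, predicted, votes, dvs, classes)
}
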