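#' Amino-acid composition of a sequence
#'
#' Frequency of each of the 20 standard residues, giving a fixed
#' 20-dimensional representation regardless of sequence length.
#'
#' @param sequence an amino-acid string over the standard alphabet.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aac <- function(sequence) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 1) stop("empty sequence")
  counts <- tabulate(match(ch, aa_alphabet()), nbins = 20L)
  stats::setNames(counts / n, aa_alphabet())
}

#' Digram (overlapping 2-gram) composition of a sequence
#'
#' Frequency of each of the 400 ordered residue pairs over the
#' `length - 1` overlapping windows.
#'
#' @param sequence an amino-acid string, length at least 2.
#' @return Named numeric vector of length 400 summing to 1; names are
#'   the pairs `"AA"`, `"AC"`, ... (first residue major).
#' @export
digram <- function(sequence) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 2) stop("digram composition needs length >= 2")
  idx <- (match(ch[-n], aa_alphabet()) - 1L) * 20L + match(ch[-1L], aa_alphabet())
  counts <- tabulate(idx, nbins = 400L)
  stats::setNames(counts / (n - 1), digram_names())
}

digram_names <- function() {
  as.vector(t(outer(aa_alphabet(), aa_alphabet(), paste0)))
}

#' Encode a sequence as a matrix of per-residue z-scale descriptors
#'
#' Row t of the result is the 5-dimensional physicochemical descriptor
#' vector of residue t.
#'
#' @param sequence an amino-acid string.
#' @param table a 20 x 5 descriptor matrix; defaults to [zscale_table()].
#' @return A `length x 5` numeric matrix.
#' @export
zscale_encode <- function(sequence, table = zscale_table()) {
  table <- check_zscale_table(table)
  ch <- seq_chars(sequence)
  if (!length(ch)) stop("empty sequence")
  table[ch, , drop = FALSE]
}

#' Auto-cross covariance (ACC) transform of a sequence
#'
#' Maps a variable-length sequence to a fixed vector of length `25 *
#' max_lag`. The sequence is first encoded as five per-residue z-scale
#' descriptor traces, each mean-centered within the sequence. For every
#' descriptor pair (j, k) and lag l in 1..L the term is
#' \deqn{ACC(j,k,l) = \frac{1}{n-l} \sum_{t=1}^{n-l} \tilde z_{j,t}\,
#'   \tilde z_{k,t+l}}
#' Auto-covariance terms have j = k, cross-covariance terms j != k.
#' Output order is lag-major, then (j, k) lexicographic, so for L = 13
#' the vector has 325 entries.
#'
#' @param sequence an amino-acid string of length at least `max_lag + 2`.
#' @param max_lag maximum lag L (default 13).
#' @param table descriptor matrix, see [zscale_encode()].
#' @return Named numeric vector of length `25 * max_lag`.
#' @export
acc_transform <- function(sequence, max_lag = 13L, table = zscale_table()) {
  max_lag <- as.integer(max_lag)
  stopifnot(max_lag >= 1L)
  Z <- zscale_encode(sequence, table)
  n <- nrow(Z)
  if (n <= max_lag + 1L)
    stop("sequence length ", n, " too short for max_lag ", max_lag,
         "; need at least ", max_lag + 2L, " residues")
  Zc <- sweep(Z, 2L, colMeans(Z))
  out <- numeric(25L * max_lag)
  nm <- character(25L * max_lag)
  pairs <- expand.grid(k = 1:5, j = 1:5)  # j major
  for (l in seq_len(max_lag)) {
    M <- crossprod(Zc[1:(n - l), , drop = FALSE],
                   Zc[(l + 1):n, , drop = FALSE]) / (n - l)
    pos <- (l - 1L) * 25L + 1:25
    out[pos] <- as.vector(t(M))  # row-major: j outer, k inner
    nm[pos] <- sprintf("lag%d.z%dz%d", l, pairs$j, pairs$k)
  }
  stats::setNames(out, nm)
}

seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- !(ch %in% aa_alphabet())
  if (any(bad))
    stop("non-standard residue(s): ", paste(unique(ch[bad]), collapse = ", "))
  ch
}

#' Transform a labeled sequence set into a feature matrix
#'
#' Applies one of the package's alignment-free transforms row-wise,
#' preserving record order, and attaches the transform descriptor.
#'
#' @param x a [seqset()].
#' @param transform one of `"aac"`, `"digram"`, `"acc"`, `"prot2vec"`.
#' @param max_lag ACC maximum lag (default 13, giving 325 columns).
#' @param table z-scale table for ACC.
#' @param embeddings an `embedding_table` (required for `"prot2vec"`),
#'   see [train_embeddings()].
#' @param grams 3-gram multiset used by prot2vec summation; see
#'   [prot2vec_embed()].
#' @return A numeric matrix of class `feature_matrix` with one row per
#'   sequence (rownames = ids) and attributes `transform`, `params` and
#'   `labels`.
#' @export
transform_set <- function(x, transform = c("aac", "digram", "acc", "prot2vec"),
                          max_lag = 13L, table = zscale_table(),
                          embeddings = NULL,
                          grams = c("overlapping", "offset")) {
  stopifnot(inherits(x, "seqset"))
  transform <- match.arg(transform)
  grams <- match.arg(grams)
  f <- switch(transform,
    aac = function(s) aac(s),
    digram = function(s) digram(s),
    acc = function(s) acc_transform(s, max_lag = max_lag, table = table),
    prot2vec = {
      if (is.null(embeddings)) stop("prot2vec requires an embedding table")
      function(s) prot2vec_embed(s, embeddings, grams = grams)
    })
  rows <- vector("list", length(x))
  for (i in seq_along(x$id)) {
    rows[[i]] <- tryCatch(f(x$sequence[i]), error = function(e)
      stop("transform failed for '", x$id[i], "': ", conditionMessage(e),
           call. = FALSE))
  }
  m <- do.call(rbind, rows)
  rownames(m) <- x$id
  params <- switch(transform,
    acc = list(max_lag = max_lag),
    prot2vec = list(dim = ncol(m), grams = grams),
    list())
  feature_matrix(m, transform, params, labels = x$label)
}

feature_matrix <- function(m, transform, params = list(), labels = NULL) {
  structure(m, transform = transform, params = params, labels = labels,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d x %d (%s)\n", nrow(x), ncol(x),
              attr(x, "transform")))
  invisible(x)
}
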