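#' Build a 3-gram training corpus from a sequence set
#'
#' Treats each protein as text: every sequence is split into `n`
#' "sentences" of non-overlapping `n`-gram tokens, one per reading
#' offset `0 .. n-1`, with trailing residues shorter than `n`
#' discarded. For the default n = 3 a sequence thus yields three
#' sentences covering all its overlapping 3-grams exactly once.
#'
#' @param x a [seqset()] (labels are ignored; the corpus is unsupervised).
#' @param n token length; 3 is the standard choice.
#' @return A list of character vectors (sentences of tokens), with
#'   attribute `skipped` counting sequences shorter than `n`.
#' @export
build_ngram_corpus <- function(x, n = 3L) {
  stopifnot(inherits(x, "seqset"), n >= 1L)
  n <- as.integer(n)
  sentences <- list()
  skipped <- 0L
  for (s in x$sequence) {
    len <- nchar(s)
    if (len < n) { skipped <- skipped + 1L; next }
    for (o in 0:(n - 1L)) {
      k <- (len - o) %/% n
      if (k < 1L) next
      starts <- o + 1L + n * (seq_len(k) - 1L)
      sentences[[length(sentences) + 1L]] <-
        substring(s, starts, starts + n - 1L)
    }
  }
  if (skipped) message(skipped, " sequence(s) shorter than ", n, " skipped")
  structure(sentences, skipped = skipped)
}

#' Train skip-gram embeddings for sequence n-gram tokens
#'
#' Learns a distributed vector per token with a skip-gram model and
#' negative sampling (the word2vec objective): each token predicts its
#' neighbours within a dynamic window, against `negative` samples drawn
#' from the unigram distribution raised to 3/4. Training is
#' single-threaded stochastic gradient descent with a linearly decaying
#' learning rate and a dedicated seeded RNG, so identical inputs give
#' identical tables.
#'
#' @param corpus sentences from [build_ngram_corpus()].
#' @param dim embedding dimension (default 100).
#' @param window context window radius (default 25; the effective
#'   radius per position is drawn uniformly from 1..window).
#' @param seed integer RNG seed.
#' @param epochs passes over the corpus (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param min_count discard tokens rarer than this (default 1: keep all).
#' @param alpha initial learning rate.
#' @return An object of class `embedding_table`: list with `vectors`
#'   (V x dim matrix, rownames = tokens) and `meta` (parameters).
#' @export
train_embeddings <- function(corpus, dim = 100L, window = 25L, seed = 1L,
                             epochs = 5L, negative = 5L, min_count = 1L,
                             alpha = 0.025) {
  if (!length(corpus)) stop("empty corpus")
  toks <- unlist(corpus, use.names = FALSE)
  freq <- table(toks)
  vocab <- names(freq)[freq >= min_count]
  if (!length(vocab)) stop("no tokens pass min_count")
  vocab <- sort(vocab)
  counts <- as.numeric(freq[vocab])

  enc <- lapply(corpus, function(s) {
    i <- match(s, vocab)
    as.integer(i[!is.na(i)])
  })
  enc <- enc[lengths(enc) > 0L]
  if (!length(enc)) stop("corpus empty after vocabulary pruning")

  vec <- .sg_train(enc, length(vocab), as.integer(dim), as.integer(window),
                   as.integer(epochs), as.integer(negative), alpha,
                   counts^0.75, as.integer(seed))
  rownames(vec) <- vocab
  colnames(vec) <- paste0("d", seq_len(ncol(vec)))
  structure(
    list(vectors = vec,
         meta = list(dim = as.integer(dim), window = as.integer(window),
                     epochs = as.integer(epochs), negative = as.integer(negative),
                     min_count = as.integer(min_count), alpha = alpha,
                     seed = as.integer(seed), corpus_tokens = length(toks))),
    class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("Embedding table: %d tokens x %d dimensions (window %d)\n",
              nrow(x$vectors), x$meta$dim, x$meta$window))
  invisible(x)
}

#' Embed a sequence as the sum of its 3-gram vectors
#'
#' The working fixed-length representation of a sequence: the sum of
#' the embedding vectors of its 3-grams. By default all overlapping
#' 3-grams (stride 1) contribute; `grams = "offset"` instead sums the
#' three non-overlapping offset tokenizations, which weights every
#' overlapping 3-gram once as well but drops up to two trailing tokens
#' per offset. Tokens absent from the table contribute zero and lower
#' the reported coverage.
#'
#' @param sequence amino-acid string of length at least 3.
#' @param table an `embedding_table` from [train_embeddings()].
#' @param grams `"overlapping"` (default) or `"offset"`.
#' @return Numeric vector of length `dim`, with attribute `coverage`:
#'   the fraction of the sequence's 3-grams found in the table.
#' @export
prot2vec_embed <- function(sequence, table,
                           grams = c("overlapping", "offset")) {
  stopifnot(inherits(table, "embedding_table"))
  grams <- match.arg(grams)
  s <- toupper(sequence)
  len <- nchar(s)
  if (len < 3L) stop("sequence shorter than 3 residues")
  toks <- if (grams == "overlapping") {
    starts <- seq_len(len - 2L)
    substring(s, starts, starts + 2L)
  } else {
    unlist(lapply(0:2, function(o) {
      k <- (len - o) %/% 3L
      if (k < 1L) return(character(0))
      st <- o + 1L + 3L * (seq_len(k) - 1L)
      substring(s, st, st + 2L)
    }))
  }
  idx <- match(toks, rownames(table$vectors))
  hit <- !is.na(idx)
  v <- if (any(hit)) colSums(table$vectors[idx[hit], , drop = FALSE])
       else stats::setNames(numeric(ncol(table$vectors)), colnames(table$vectors))
  attr(v, "coverage") <- mean(hit)
  v
}

#' Write an embedding table in word2vec text format
#'
#' First line `"<vocab> <dim>"`, then one line per token:
#' the token followed by its vector components, space-separated.
#'
#' @param table an `embedding_table`.
#' @param path output path.
#' @return `table`, invisibly.
#' @export
write_word2vec <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  v <- table$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(v), ncol(v)), con)
  writeLines(paste(rownames(v),
                   apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))),
             con)
  invisible(table)
}

#' Read an embedding table from word2vec text format
#'
#' @param path input path.
#' @return An `embedding_table` (meta carries only the dimension).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  body <- lapply(strsplit(lines[-1L], " ", fixed = TRUE),
                 function(p) p[nzchar(p)])
  toks <- vapply(body, `[[`, "", 1L)
  vec <- t(vapply(body, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(vec) <- toks
  colnames(vec) <- paste0("d", seq_len(ncol(vec)))
  structure(list(vectors = vec, meta = list(dim = hdr[2L])),
            class = "embedding_table")
}
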