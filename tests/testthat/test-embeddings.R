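test_that("3-gram corpus splits each sequence into three offset sentences", {
  x <- seqset(c("a", "b"), c("MKVLITR", "MKV"), c("c1", "c2"),
              min_length = 1L)
  corp <- build_ngram_corpus(x)
  expect_equal(corp[[1]], c("MKV", "LIT"))
  expect_equal(corp[[2]], c("KVL", "ITR"))
  expect_equal(corp[[3]], "VLI")
  # length-3 sequence: offsets 1 and 2 yield nothing
  expect_length(corp, 4)
  expect_equal(corp[[4]], "MKV")
})

test_that("corpus token count matches the floor((len - o)/3) oracle", {
  set.seed(21)
  lens <- sample(3:40, 100, replace = TRUE)
  x <- seqset(sprintf("s%03d", 1:100),
              vapply(lens, random_seq, ""),
              rep(c("c1", "c2"), 50), min_length = 1L)
  corp <- build_ngram_corpus(x)
  expected <- sum(vapply(lens, function(n) sum((n - 0:2) %/% 3), 0))
  expect_equal(length(unlist(corp)), expected)
})

test_that("corpus token multiset is invariant to record order", {
  set.seed(22)
  x <- seqset(sprintf("s%d", 1:10), vapply(1:10, function(i)
    random_seq(sample(10:30, 1)), ""), rep(c("a", "b"), 5), min_length = 1L)
  perm <- sample(10)
  y <- seqset(x$id[perm], x$sequence[perm], x$label[perm], min_length = 1L)
  t1 <- sort(unlist(build_ngram_corpus(x)))
  t2 <- sort(unlist(build_ngram_corpus(y)))
  expect_identical(t1, t2)
})

test_that("skip-gram training is reproducible and covers the vocabulary", {
  set.seed(23)
  x <- seqset(sprintf("s%d", 1:12), vapply(1:12, function(i)
    random_seq(sample(30:60, 1)), ""), rep(c("a", "b"), 6), min_length = 1L)
  corp <- build_ngram_corpus(x)
  e1 <- train_embeddings(corp, dim = 8, window = 5, seed = 31)
  e2 <- train_embeddings(corp, dim = 8, window = 5, seed = 31)
  expect_identical(e1$vectors, e2$vectors)
  # default window follows the skip-gram setup used for proteins
  expect_equal(formals(train_embeddings)$window, 25L)
  # without min-count pruning the vocabulary is exactly the token set
  expect_setequal(rownames(e1$vectors), unique(unlist(corp)))
  expect_equal(ncol(e1$vectors), 8)
  # a different seed moves the vectors
  e3 <- train_embeddings(corp, dim = 8, window = 5, seed = 32)
  expect_false(identical(e1$vectors, e3$vectors))
  expect_error(train_embeddings(list()), "empty")
})

test_that("sequence embedding is the sum over its 3-gram multiset", {
  set.seed(24)
  x <- seqset(sprintf("s%d", 1:6), vapply(1:6, function(i)
    random_seq(sample(20:40, 1)), ""), rep(c("a", "b"), 3), min_length = 1L)
  emb <- train_embeddings(build_ngram_corpus(x), dim = 6, window = 3, seed = 1)
  V <- emb$vectors
  # single 3-gram
  tok <- rownames(V)[1]
  expect_equal(as.numeric(prot2vec_embed(tok, emb)), unname(V[tok, ]))
  # manual two-token sum
  s4 <- x$sequence[1]
  g <- substring(s4, 1:(nchar(s4) - 2), 3:nchar(s4))
  expect_equal(as.numeric(prot2vec_embed(s4, emb)),
               unname(colSums(V[g, , drop = FALSE])))
  expect_equal(attr(prot2vec_embed(s4, emb), "coverage"), 1)
  # additivity property on random sequences
  for (i in 2:6) {
    s <- x$sequence[i]
    g <- substring(s, 1:(nchar(s) - 2), 3:nchar(s))
    expect_equal(as.numeric(prot2vec_embed(s, emb)),
                 unname(colSums(V[g, , drop = FALSE])))
  }
  expect_error(prot2vec_embed("MK", emb), "shorter")
})

test_that("out-of-vocabulary 3-grams contribute zero with zero coverage", {
  V <- matrix(1:6, 2, 3, dimnames = list(c("AAA", "CCC"), paste0("d", 1:3)))
  emb <- structure(list(vectors = V, meta = list(dim = 3)),
                   class = "embedding_table")
  v <- prot2vec_embed("WWWWW", emb)
  expect_equal(as.numeric(v), c(0, 0, 0))
  expect_equal(attr(v, "coverage"), 0)
  # offset mode counts each overlapping 3-gram once as well
  v2 <- prot2vec_embed("AAAA", emb, grams = "offset")
  expect_equal(as.numeric(v2), unname(2 * V["AAA", ]))
})

test_that("word2vec text format round-trips an embedding table", {
  set.seed(25)
  x <- seqset("s1", random_seq(40), "a", min_length = 1L)
  emb <- train_embeddings(build_ngram_corpus(x), dim = 5, window = 4, seed = 2)
  p <- tempfile()
  write_word2vec(emb, p)
  back <- read_word2vec(p)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-15)
})
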