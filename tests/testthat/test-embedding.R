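test_that("training is reproducible with a fixed seed", {
  docs <- small_docs()[1:40]
  m1 <- spec_embedding(docs, dim = 24L, epochs = 3L, seed = 5L)
  m2 <- spec_embedding(docs, dim = 24L, epochs = 3L, seed = 5L)
  expect_identical(m1$vectors, m2$vectors)
  m3 <- spec_embedding(docs, dim = 24L, epochs = 3L, seed = 6L)
  expect_false(identical(m1$vectors, m3$vectors))
})

test_that("min_count drops rare words from the vocabulary", {
  docs <- list(make_doc(c("a", "b")), make_doc(c("a", "b")),
               make_doc(c("a", "once")))
  m <- spec_embedding(docs, dim = 8L, epochs = 1L, min_count = 2L, seed = 1L)
  expect_true(all(c("a", "b") %in% rownames(m$vectors)))
  expect_false("once" %in% rownames(m$vectors))
  expect_error(spec_embedding(list(), dim = 8L), "empty")
})

test_that("a narrow window triggers a truncation warning", {
  docs <- list(make_doc(letters[1:10]), make_doc(letters[1:4]))
  expect_warning(spec_embedding(docs, dim = 4L, window = 5L, epochs = 1L,
                                seed = 1L), "window")
})

test_that("co-occurring words end up closer than unrelated words", {
  # fragments from the same substructure block appear in the same
  # documents; their word vectors should lie much closer together than
  # vectors of words that rarely share a document
  m <- small_model()
  docs <- small_docs()
  v <- m$vectors
  vn <- v / sqrt(rowSums(v^2))
  counts <- table(unlist(lapply(docs, `[[`, "words")))
  top <- names(sort(counts, decreasing = TRUE))[1:60]
  top <- intersect(top, rownames(v))
  inc <- sapply(top, function(w)
    vapply(docs, function(d) w %in% d$words, logical(1)))
  co <- crossprod(inc)
  n_docs <- colSums(inc)
  jaccard <- co / (outer(n_docs, n_docs, "+") - co)
  cs <- vn[top, ] %*% t(vn[top, ])
  ut <- upper.tri(jaccard)
  high <- jaccard[ut] > 0.5   # words sharing most of their documents
  low <- jaccard[ut] < 0.05   # words almost never co-occurring
  expect_gt(sum(high), 20)
  expect_gt(sum(low), 20)
  expect_gt(mean(cs[ut][high]), mean(cs[ut][low]) + 0.3)
})

test_that("spectrum vectors are exact weighted sums of word vectors", {
  V <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 4))
  m <- fake_model(c("w1", "w2", "w3"), V)
  # single word, weight 1 -> that word's vector
  sv <- spectrum_vector(m, make_doc("w2", 1))
  expect_equal(sv$values, c(0, 2, 0))
  expect_equal(sv$missing_fraction, 0)
  # weighted sum
  sv2 <- spectrum_vector(m, make_doc(c("w1", "w3"), c(1, 0.5)))
  expect_equal(sv2$values, c(1, 0, 2))
  # unknown middle word: weight excluded, missing fraction 0.25
  sv3 <- spectrum_vector(m, make_doc(c("w1", "nope", "w3"), c(1, 0.5, 0.5)))
  expect_equal(sv3$values, c(1, 0, 2))
  expect_equal(sv3$missing_fraction, 0.25)
  expect_error(spectrum_vector(m, make_doc("nope", 1)), "vocabulary")
})

test_that("missing fraction follows the weighted formula and its bounds", {
  m <- fake_model(c("w1", "w2"), rbind(c(1, 0), c(0, 1)))
  expect_equal(missing_fraction(m, make_doc(c("w1", "w2"), c(1, 0.5))), 0)
  expect_equal(missing_fraction(m, make_doc(c("x", "y"), c(1, 0.5))), 1)
  expect_equal(missing_fraction(
    m, make_doc(c("w1", "x", "w2"), c(1.0, 0.5, 0.5))), 0.25)
})

test_that("missing fraction grows monotonically as vocabulary shrinks", {
  words <- paste0("w", 1:8)
  weights <- c(1, 0.9, 0.8, 0.6, 0.5, 0.3, 0.2, 0.1)
  doc <- make_doc(words, weights)
  set.seed(3)
  V <- matrix(rnorm(8 * 4), 8)
  prev <- -1
  for (k in 8:1) {
    m <- fake_model(words[seq_len(k)], V[seq_len(k), , drop = FALSE])
    mf <- missing_fraction(m, doc)
    expect_gte(mf, prev)
    prev <- mf
  }
  expect_equal(prev, 1 - weights[1] / sum(weights))
})

test_that("embedding similarity is a proper cosine with reliability flag", {
  v1 <- structure(list(values = c(1, 2, 3), missing_fraction = 0),
                  class = "spectrum_vector")
  v2 <- structure(list(values = c(2, 4, 6), missing_fraction = 0.2),
                  class = "spectrum_vector")
  v3 <- structure(list(values = c(3, 0, -1), missing_fraction = 0),
                  class = "spectrum_vector")
  expect_equal(embedding_similarity(v1, v1)$score, 1)
  expect_equal(embedding_similarity(v1, v2)$score, 1)  # scale invariance
  expect_equal(embedding_similarity(v1, v3)$score, 0)  # orthogonal
  expect_false(embedding_similarity(v1, v2)$reliable)
  expect_true(embedding_similarity(v1, v2, allowed_missing = 0.2)$reliable)
  zero <- structure(list(values = c(0, 0, 0), missing_fraction = 0),
                    class = "spectrum_vector")
  expect_error(embedding_similarity(v1, zero), "zero-norm")
})

test_that("batch similarity matrix equals pairwise scores entrywise", {
  m <- small_model()
  docs <- small_docs()[1:20]
  mat <- embedding_similarity_matrix(docs, model = m)
  expect_equal(dim(mat), c(20L, 20L))
  expect_equal(unname(diag(mat)), rep(1, 20))
  expect_equal(mat, t(mat))
  vs <- lapply(docs, spectrum_vector, model = m)
  for (i in sample(20, 5)) for (j in sample(20, 5)) {
    expect_equal(mat[i, j],
                 embedding_similarity(vs[[i]], vs[[j]])$score,
                 tolerance = 1e-9)
  }
  expect_equal(dim(embedding_similarity_matrix(list(), docs, m)),
               c(0L, 20L))
})

test_that("training separates same-molecule from random pairs, widening with epochs", {
  # at the benchmark corpus size the separation between same-molecule
  # and random spectrum pairs grows from epoch 1 to epoch 15
  cfg <- benchmark_config()
  gap <- function(seed, epochs) {
    bench <- generate_benchmark(cfg, "library_split", seed = seed)
    docs <- spectra_to_documents(process_spectra(bench$training, "embedding"))
    m <- spec_embedding(docs, dim = 64L, epochs = epochs, seed = seed)
    sim <- embedding_similarity_matrix(docs, model = m)
    owner <- sub("_r[0-9]+$", "", rownames(sim))
    same <- outer(owner, owner, "==") & upper.tri(sim)
    mean(sim[same]) - mean(sim[upper.tri(sim) & !same])
  }
  for (seed in 1:3) {
    g1 <- gap(seed, 1L)
    g15 <- gap(seed, 15L)
    expect_gt(g15, 0)
    expect_gt(g15, g1)
  }
})

test_that("models persist to text and restore identically", {
  m <- small_model()
  path <- withr::local_tempfile()
  write_embedding(m, path)
  back <- read_embedding(path)
  expect_identical(rownames(back$vectors), rownames(m$vectors))
  expect_equal(back$vectors, m$vectors)
  expect_equal(back$meta$dim, m$meta$dim)
  doc <- small_docs()[[1]]
  expect_equal(spectrum_vector(back, doc)$values,
               spectrum_vector(m, doc)$values)
})

test_that("predict returns vectors and missing fractions for many documents", {
  m <- small_model()
  docs <- small_docs()[1:5]
  P <- predict(m, docs)
  expect_equal(dim(P), c(5L, m$meta$dim))
  expect_length(attr(P, "missing_fraction"), 5L)
  expect_equal(P[3, ], spectrum_vector(m, docs[[3]])$values,
               ignore_attr = TRUE)
})
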