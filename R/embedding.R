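#' Fit a word-embedding model on a spectrum-document corpus
#'
#' Trains word vectors for peak/loss words by CBOW or skip-gram with
#' negative sampling. Because fragment peaks have no meaningful order
#' within a spectrum, the context window defaults to 500 words so that
#' the entire document acts as context for every word.
#'
#' Training is single-threaded and internally seeded: the same corpus,
#' parameters and seed reproduce the vector matrix exactly.
#'
#' @param corpus list of [spectrum_document][spectrum_to_document] objects
#'   (or plain character vectors of words).
#' @param dim embedding dimension (default 300).
#' @param window context half-width in words; defaults to 500 so whole
#'   documents form the context. A warning is raised when the corpus
#'   contains documents longer than the window (their context is
#'   truncated).
#' @param mode `"cbow"` (default; generally performs better on spectrum
#'   corpora) or `"skipgram"`.
#' @param negative number of negative samples per target word (default 5).
#' @param epochs training passes over the corpus (default 15).
#' @param min_count words observed fewer than `min_count` times are
#'   dropped from the vocabulary (default 1: every observed word gets a
#'   vector, so missing words arise only from train/apply mismatch).
#' @param alpha,min_alpha initial and floor learning rate; `alpha` decays
#'   linearly to `min_alpha` over the run.
#' @param seed integer seed for the internal generator.
#' @return object of class `ms_embedding`: list with `vocabulary` (named
#'   index vector), `vectors` (vocab x dim matrix, rownames are words)
#'   and `meta` (all training parameters).
#' @examples
#' docs <- list(c("peak@100.00", "peak@150.00"), c("peak@100.00", "peak@200.00"))
#' m <- spec_embedding(docs, dim = 8, epochs = 2, seed = 1)
#' m
#' @export
spec_embedding <- function(corpus, dim = 300L, window = 500L,
                           mode = c("cbow", "skipgram"), negative = 5L,
                           epochs = 15L, min_count = 1L, alpha = 0.025,
                           min_alpha = 1e-4, seed = 1L) {
  mode <- match.arg(mode)
  if (length(corpus) == 0L) stop("cannot train on an empty corpus")
  words_per_doc <- lapply(corpus, doc_words)
  longest <- max(lengths(words_per_doc))
  if (window < longest)
    warning("window (", window, ") is shorter than the longest document (",
            longest, "); context will be truncated")
  counts <- table(unlist(words_per_doc))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L)
    stop("no word occurs at least min_count = ", min_count, " times")
  # vocabulary ordered by descending frequency, ties alphabetical:
  # deterministic and keeps the negative-sampling table well-ordered
  ord <- order(-as.integer(counts), names(counts))
  vocab_words <- names(counts)[ord]
  vocab <- seq_along(vocab_words)
  names(vocab) <- vocab_words
  idx_docs <- lapply(words_per_doc, function(w) {
    i <- vocab[w]
    as.integer(i[!is.na(i)]) - 1L
  })
  idx_docs <- idx_docs[lengths(idx_docs) > 0L]
  vecs <- cpp_train_embedding(idx_docs, length(vocab), as.integer(dim),
                              as.integer(window), as.integer(negative),
                              as.integer(epochs), alpha, min_alpha,
                              as.numeric(seed), mode == "cbow",
                              as.numeric(counts)[ord])
  rownames(vecs) <- vocab_words
  structure(
    list(vocabulary = vocab, vectors = vecs,
         meta = list(dim = as.integer(dim), window = as.integer(window),
                     mode = mode, negative = as.integer(negative),
                     epochs = as.integer(epochs),
                     min_count = as.integer(min_count), alpha = alpha,
                     min_alpha = min_alpha, seed = as.integer(seed),
                     n_documents = length(corpus), workers = 1L)),
    class = "ms_embedding")
}

doc_words <- function(d) {
  if (inherits(d, "spectrum_document")) d$words else as.character(d)
}

doc_weights <- function(d) {
  if (inherits(d, "spectrum_document")) d$weights
  else rep(1, length(as.character(d)))
}

#' @export
print.ms_embedding <- function(x, ...) {
  cat(sprintf("<ms_embedding: %d words x %d dimensions (%s, negative=%d, epochs=%d, seed=%d)>\n",
              nrow(x$vectors), x$meta$dim, x$meta$mode, x$meta$negative,
              x$meta$epochs, x$meta$seed))
  invisible(x)
}

#' @export
summary.ms_embedding <- function(object, ...) {
  norms <- sqrt(rowSums(object$vectors^2))
  res <- list(vocab_size = nrow(object$vectors), meta = object$meta,
              vector_norms = summary(norms),
              n_peak_words = sum(startsWith(rownames(object$vectors), "peak@")),
              n_loss_words = sum(startsWith(rownames(object$vectors), "loss@")))
  class(res) <- "summary.ms_embedding"
  res
}

#' @export
print.summary.ms_embedding <- function(x, ...) {
  cat(sprintf("Embedding model: %d words (%d peak, %d loss), %d dimensions\n",
              x$vocab_size, x$n_peak_words, x$n_loss_words, x$meta$dim))
  cat(sprintf("Training: %s, window %d, negative %d, epochs %d, min_count %d, seed %d, %d documents\n",
              x$meta$mode, x$meta$window, x$meta$negative, x$meta$epochs,
              x$meta$min_count, x$meta$seed, x$meta$n_documents))
  cat("Word-vector norms:\n")
  print(x$vector_norms)
  invisible(x)
}

#' Intensity-weighted fraction of a document missing from the vocabulary
#'
#' `1 - sum(weights of in-vocabulary words) / sum(all weights)`: 0 when
#' every word is known to the model, 1 when none is. Few low-intensity
#' unknown words barely move it; a high-intensity unknown word dominates
#' it.
#'
#' @param model an `ms_embedding`.
#' @param doc a `spectrum_document`.
#' @return fraction in \[0, 1\].
#' @export
missing_fraction <- function(model, doc) {
  w <- doc_weights(doc)
  if (sum(w) <= 0) stop("document weights must sum to > 0")
  known <- doc_words(doc) %in% rownames(model$vectors)
  1 - sum(w[known]) / sum(w)
}

#' Weighted spectrum vector under an embedding model
#'
#' The spectrum vector is the weighted sum of the word vectors of all
#' in-vocabulary document words, with weights the normalized peak
#' intensities (optionally raised to `intensity_power`; the default of 1
#' is the plain weighted sum).
#'
#' @param model an `ms_embedding`.
#' @param doc a `spectrum_document` with at least one in-vocabulary word.
#' @param intensity_power exponent applied to the weights (default 1).
#' @return object of class `spectrum_vector`: list with `values`
#'   (d-dimensional numeric) and `missing_fraction`.
#' @export
spectrum_vector <- function(model, doc, intensity_power = 1) {
  words <- doc_words(doc)
  w <- doc_weights(doc)^intensity_power
  idx <- match(words, rownames(model$vectors))
  known <- !is.na(idx)
  if (!any(known))
    stop("no document word is present in the model vocabulary")
  values <- colSums(model$vectors[idx[known], , drop = FALSE] * w[known])
  structure(list(values = values,
                 missing_fraction = missing_fraction(model, doc)),
            class = "spectrum_vector")
}

#' Embedding similarity between two spectrum vectors
#'
#' The cosine between two intensity-weighted spectrum vectors. When
#' either vector's missing fraction exceeds `allowed_missing` the score
#' is still returned but flagged unreliable, so callers can filter
#' spectra that lie too far outside the learned vocabulary.
#'
#' @param a,b `spectrum_vector` objects (from [spectrum_vector()] or
#'   [predict.ms_embedding()]).
#' @param allowed_missing largest acceptable missing fraction
#'   (default 0.05).
#' @return list with `score` (cosine, in \[-1, 1\]), `reliable` flag and
#'   the two missing fractions.
#' @export
embedding_similarity <- function(a, b, allowed_missing = 0.05) {
  va <- if (inherits(a, "spectrum_vector")) a$values else as.numeric(a)
  vb <- if (inherits(b, "spectrum_vector")) b$values else as.numeric(b)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("cannot take cosine of a zero-norm vector")
  ma <- if (inherits(a, "spectrum_vector")) a$missing_fraction else 0
  mb <- if (inherits(b, "spectrum_vector")) b$missing_fraction else 0
  list(score = sum(va * vb) / (na * nb),
       reliable = ma <= allowed_missing && mb <= allowed_missing,
       missing_a = ma, missing_b = mb)
}

#' Spectrum vectors for a set of documents
#'
#' @param object an `ms_embedding` model.
#' @param newdata list of `spectrum_document` objects.
#' @param intensity_power exponent applied to the weights (default 1).
#' @param ... unused.
#' @return matrix (documents x dimensions) of spectrum vectors, with the
#'   per-document missing fractions in attribute `"missing_fraction"` and
#'   source ids as rownames.
#' @export
predict.ms_embedding <- function(object, newdata, intensity_power = 1, ...) {
  if (inherits(newdata, "spectrum_document")) newdata <- list(newdata)
  vs <- lapply(newdata, spectrum_vector, model = object,
               intensity_power = intensity_power)
  m <- do.call(rbind, lapply(vs, `[[`, "values"))
  rownames(m) <- vapply(newdata, function(d)
    if (inherits(d, "spectrum_document")) d$source_id else NA_character_,
    character(1L))
  attr(m, "missing_fraction") <- vapply(vs, `[[`, numeric(1L),
                                        "missing_fraction")
  m
}

#' All-vs-all embedding similarity matrix
#'
#' Spectrum vectors are computed once per document and compared by
#' cosine; with `refs` missing the comparison is all-vs-all over
#' `queries` (symmetric, unit diagonal).
#'
#' @param queries,refs lists of `spectrum_document`.
#' @param model an `ms_embedding`.
#' @param intensity_power exponent applied to the weights (default 1).
#' @return numeric matrix `length(queries)` x `length(refs)`; attributes
#'   `"missing_query"`/`"missing_ref"` carry the missing fractions.
#' @export
embedding_similarity_matrix <- function(queries, refs = NULL, model,
                                        intensity_power = 1) {
  symmetric <- is.null(refs)
  if (length(queries) == 0L) {
    n <- if (symmetric) 0L else length(refs)
    return(matrix(numeric(0), nrow = 0L, ncol = n))
  }
  Q <- predict(model, queries, intensity_power = intensity_power)
  R <- if (symmetric) Q else predict(model, refs,
                                     intensity_power = intensity_power)
  Qn <- Q / sqrt(rowSums(Q^2))
  Rn <- R / sqrt(rowSums(R^2))
  m <- Qn %*% t(Rn)
  if (symmetric) {
    m <- (m + t(m)) / 2  # symmetrize away rounding noise
    diag(m) <- 1
  }
  attr(m, "missing_query") <- attr(Q, "missing_fraction")
  attr(m, "missing_ref") <- attr(R, "missing_fraction")
  m
}

#' Persist / load an embedding model as plain text
#'
#' The model is written as a single portable text file: a JSON header
#' line with the training metadata, then one line per vocabulary word
#' (`word \t v1 \t ... \t vd`).
#'
#' @param model an `ms_embedding`.
#' @param path file path.
#' @return `write_embedding`: `path` invisibly; `read_embedding`: the
#'   restored `ms_embedding`.
#' @export
write_embedding <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(model$meta, auto_unbox = TRUE,
                                           digits = NA)), con)
  rows <- vapply(seq_len(nrow(model$vectors)), function(i)
    paste(c(rownames(model$vectors)[i],
            sprintf("%.17g", model$vectors[i, ])), collapse = "\t"),
    character(1L))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- jsonlite::fromJSON(lines[1L])
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1L), 1L)
  vecs <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  rownames(vecs) <- words
  vocab <- seq_along(words)
  names(vocab) <- words
  structure(list(vocabulary = vocab, vectors = vecs, meta = meta),
            class = "ms_embedding")
}
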