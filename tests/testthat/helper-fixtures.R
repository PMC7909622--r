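# Shared fixtures, built in code. Expensive objects (small trained
# embedding models, benchmarks) are created lazily and cached for the
# whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

make_spectrum <- function(mz, intensity = rep(1, length(mz)), ...) {
  spectrum(mz, intensity, ...)
}

random_spectrum <- function(n = 15L, precursor = 500) {
  spectrum(sort(runif(n, 50, precursor - 1)), runif(n, 0.01, 1),
           precursor_mz = precursor, spectrum_id = paste0("rnd", n))
}

# a fake embedding model with hand-chosen vectors, for exact arithmetic
# checks of spectrum vectors, missing fractions and cosines
fake_model <- function(words, vectors) {
  rownames(vectors) <- words
  vocab <- seq_along(words)
  names(vocab) <- words
  structure(list(vocabulary = vocab, vectors = vectors,
                 meta = list(dim = ncol(vectors), mode = "cbow",
                             window = 500L, negative = 5L, epochs = 0L,
                             min_count = 1L, seed = 0L)),
            class = "ms_embedding")
}

make_doc <- function(words, weights = rep(1, length(words)),
                     source_id = "doc") {
  structure(list(words = words, weights = weights, n_decimals = 2L,
                 source_id = source_id),
            class = "spectrum_document")
}

small_benchmark <- function() {
  cached("small_benchmark", {
    generate_benchmark(benchmark_config(n_molecules = 40L, n_queries = 20L,
                                        spectra_per_molecule = 3L),
                       "library_split", seed = 7L)
  })
}

small_model <- function() {
  cached("small_model", {
    bench <- small_benchmark()
    docs <- spectra_to_documents(process_spectra(bench$training, "embedding"))
    # small corpora need longer training to escape the early phase in
    # which all vectors share a common direction (cf. using more epochs
    # on smaller spectral datasets)
    spec_embedding(docs, dim = 64L, epochs = 60L, seed = 3L)
  })
}

small_docs <- function() {
  cached("small_docs", {
    bench <- small_benchmark()
    spectra_to_documents(process_spectra(bench$training, "embedding"))
  })
}

# random candidate-pair instances for assignment tests
random_candidates <- function(n_cand, n_peaks = 6L) {
  data.frame(index_a = sample.int(n_peaks, n_cand, replace = TRUE),
             index_b = sample.int(n_peaks, n_cand, replace = TRUE),
             product = runif(n_cand, 0.01, 1),
             dmz = runif(n_cand, 0, 0.005),
             shifted = FALSE)
}
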