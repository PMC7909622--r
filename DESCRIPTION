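Package: specembed
Title: Spectral Similarity for Tandem Mass Spectrometry via Peak-Word Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring the similarity of MS/MS fragmentation spectra.
    Spectra are tokenised into peak and neutral-loss "words", a word-embedding
    model (CBOW or skip-gram with negative sampling) is trained on the spectrum
    corpus, and spectra are compared as the cosine between intensity-weighted
    sums of their word vectors. Classical greedy cosine and modified cosine
    (precursor-shift) scores are provided as baselines, together with
    evaluation workflows: library matching with ppm precursor pre-selection,
    top-k analog search, score-versus-structure percentile analysis, and
    molecular networking with Louvain cluster splitting assessed against
    Tanimoto fingerprint similarity. Includes readers and writers for MGF,
    MSP and GNPS-style JSON spectral libraries and a synthetic benchmark
    generator with analytically exact structural ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
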