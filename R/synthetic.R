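# Synthetic benchmark generator. Molecules are unions of disjoint
# "substructure blocks"; each block owns a disjoint set of fingerprint
# bits and a disjoint set of characteristic fragments. Structural
# (Tanimoto) similarity between molecules is then exactly
# shared_blocks / union_blocks by construction, giving every
# score-vs-structure workflow an analytically exact ground truth without
# any chemistry dependency.

#' Generate a block-structured synthetic molecule set
#'
#' @param n_molecules number of molecules (default 200).
#' @param n_blocks number of available substructure blocks (default 40).
#' @param blocks_per_molecule blocks drawn (without replacement) per
#'   molecule (default 4).
#' @param fragments_per_block characteristic fragments per block
#'   (default 8).
#' @param bits_per_block fingerprint bits owned by each block
#'   (default 24).
#' @param fingerprint_length total fingerprint length (default 2048;
#'   must hold `n_blocks * bits_per_block` bits).
#' @param mz_range m/z range fragments are drawn from (default
#'   `c(50, 450)` Da).
#' @param family_size molecules per structural family (default 4).
#'   Members of a family share a common core block set, emulating
#'   molecular families of closely related analogs; `family_size = 1`
#'   gives fully independent molecules.
#' @param swap_prob probability that a family member swaps one core
#'   block for a random outside block (default 0.5), controlling how
#'   tight the families are.
#' @param seed RNG seed; the set is deterministic per seed.
#' @return list of `synthetic_molecule` objects: `id`, `blocks`,
#'   `family`, `fingerprint`, `fragment_mz`, `fragment_intensity`,
#'   `parent_mass`, `planar_key` (a synthetic 14-letter key standing in
#'   for a planar InChIKey).
#' @export
generate_molecule_set <- function(n_molecules = 200L, n_blocks = 40L,
                                  blocks_per_molecule = 4L,
                                  fragments_per_block = 8L,
                                  bits_per_block = 24L,
                                  fingerprint_length = 2048L,
                                  mz_range = c(50, 450),
                                  family_size = 4L, swap_prob = 0.5,
                                  seed = 1L) {
  if (blocks_per_molecule > n_blocks)
    stop("blocks_per_molecule cannot exceed n_blocks")
  if (n_blocks * bits_per_block > fingerprint_length)
    stop("fingerprint_length too small for n_blocks * bits_per_block")
  withr::with_seed(seed, {
    block_mz <- lapply(seq_len(n_blocks), function(b)
      sort(stats::runif(fragments_per_block, mz_range[1L], mz_range[2L])))
    block_int <- lapply(seq_len(n_blocks), function(b)
      stats::runif(fragments_per_block, 0.05, 1))
    block_bits <- lapply(seq_len(n_blocks), function(b)
      (b - 1L) * bits_per_block + seq_len(bits_per_block))
    n_families <- ceiling(n_molecules / family_size)
    family_core <- lapply(seq_len(n_families), function(f)
      sort(sample.int(n_blocks, blocks_per_molecule)))
    lapply(seq_len(n_molecules), function(i) {
      fam <- ((i - 1L) %/% family_size) + 1L
      blocks <- family_core[[fam]]
      member <- ((i - 1L) %% family_size) + 1L
      if (member > 1L && stats::runif(1L) < swap_prob) {
        # analog: one core block replaced by an outside block
        out <- setdiff(seq_len(n_blocks), blocks)
        blocks[sample.int(length(blocks), 1L)] <-
          out[sample.int(length(out), 1L)]
        blocks <- sort(blocks)
      }
      mz <- unlist(block_mz[blocks])
      intens <- unlist(block_int[blocks])
      ord <- order(mz)
      bits <- rep(FALSE, fingerprint_length)
      bits[unlist(block_bits[blocks])] <- TRUE
      pm <- max(mz) + stats::runif(1L, 21, 180)
      structure(list(id = sprintf("mol_%04d", i), blocks = blocks,
                     family = fam,
                     fingerprint = fingerprint(bits, sprintf("mol_%04d", i)),
                     fragment_mz = mz[ord], fragment_intensity = intens[ord],
                     parent_mass = pm,
                     planar_key = synthetic_planar_key(i)),
                class = "synthetic_molecule")
    })
  })
}

# deterministic 14-uppercase-letter pseudo planar key for molecule i
synthetic_planar_key <- function(i) {
  digits <- integer(11L)
  x <- i
  for (k in 11:1) {
    digits[k] <- x %% 26L
    x <- x %/% 26L
  }
  paste0("SYN", paste(LETTERS[digits + 1L], collapse = ""))
}

#' Simulate a noisy spectrum of a synthetic molecule
#'
#' The molecule's fragment profile is subsampled (dropout), jittered in
#' m/z and intensity, and contaminated with spurious uniform peaks. The
#' precursor m/z is `parent_mass + 1.007276` (singly protonated,
#' positive mode). A floor of `min_peaks` total peaks is guaranteed by
#' restoring the most intense dropped fragments when dropout leaves too
#' few; parameter combinations that cannot reach the floor at all raise
#' an error.
#'
#' @param mol a `synthetic_molecule`.
#' @param dropout per-fragment drop probability (default 0.1).
#' @param intensity_jitter standard deviation of the log-normal
#'   multiplicative intensity noise (default 0.1).
#' @param mz_jitter standard deviation of additive m/z noise in Da
#'   (default 0.002).
#' @param n_spurious number of spurious noise peaks (default 5).
#' @param min_peaks guaranteed minimum total peak count (default 10).
#' @param seed RNG seed; same seed reproduces the spectrum exactly.
#' @param spectrum_id id for the generated spectrum.
#' @return an `ms_spectrum` carrying the molecule's planar key as
#'   `inchikey` (padded to 27 characters).
#' @export
generate_spectrum <- function(mol, dropout = 0.1, intensity_jitter = 0.1,
                              mz_jitter = 0.002, n_spurious = 5L,
                              min_peaks = 10L, seed = 1L,
                              spectrum_id = paste0(mol$id, "_s", seed)) {
  stopifnot(dropout >= 0, dropout < 1)
  nf <- length(mol$fragment_mz)
  if (nf + n_spurious < min_peaks)
    stop("molecule has too few fragments to guarantee ", min_peaks, " peaks")
  withr::with_seed(seed, {
    keep <- stats::runif(nf) >= dropout
    need <- max(min_peaks - n_spurious, 1L)
    if (sum(keep) < need) {
      dropped <- which(!keep)
      restore <- dropped[order(-mol$fragment_intensity[dropped])]
      keep[restore[seq_len(need - sum(keep))]] <- TRUE
    }
    mz <- mol$fragment_mz[keep] + stats::rnorm(sum(keep), 0, mz_jitter)
    intens <- mol$fragment_intensity[keep] *
      exp(stats::rnorm(sum(keep), 0, intensity_jitter))
    if (n_spurious > 0L) {
      mz <- c(mz, stats::runif(n_spurious, 10, mol$parent_mass))
      intens <- c(intens, stats::runif(n_spurious, 0.01, 0.3))
    }
    spectrum(mz, intens,
             precursor_mz = mol$parent_mass + 1.007276,
             parent_mass = mol$parent_mass,
             inchikey = paste0(mol$planar_key, "-SYNTHETICAAA"),
             ionmode = "positive", spectrum_id = spectrum_id)
  })
}

#' Default synthetic benchmark configuration
#'
#' @param ... overrides for any configuration key.
#' @return list of generator settings: molecule-set parameters, spectra
#'   per molecule, noise levels, and query design (`n_queries` for the
#'   library-split mode, `n_query_molecules` for the unknown-molecule
#'   mode).
#' @export
benchmark_config <- function(...) {
  cfg <- list(n_molecules = 200L, n_blocks = 40L, blocks_per_molecule = 4L,
              fragments_per_block = 8L, bits_per_block = 24L,
              fingerprint_length = 2048L, mz_range = c(50, 450),
              family_size = 4L, swap_prob = 0.5,
              spectra_per_molecule = 4L, dropout = 0.1,
              intensity_jitter = 0.1, mz_jitter = 0.002, n_spurious = 5L,
              min_peaks = 10L, n_queries = 100L, n_query_molecules = 20L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a full spectra + fingerprint benchmark
#'
#' Two experimental designs are supported:
#' \describe{
#'   \item{`"library_split"`}{`n_queries` molecules contribute one
#'     spectrum each to the query set while keeping at least one
#'     spectrum in the library, so every query has a same-molecule hit
#'     available — the library-matching scenario.}
#'   \item{`"unknown"`}{all spectra of `n_query_molecules` molecules are
#'     removed from both library and training corpus — the
#'     unknown-compound (analog search) scenario, with no molecular
#'     overlap between queries and the model's training data.}
#' }
#'
#' @param config list from [benchmark_config()].
#' @param mode `"library_split"` or `"unknown"`.
#' @param seed master seed; all internal seeds derive from it, so equal
#'   config + seed reproduces the benchmark exactly.
#' @return list with `library`, `queries` (lists of `ms_spectrum`),
#'   `training` (spectra the embedding model may be trained on),
#'   `truth` (named vector query id -> molecule id),
#'   `library_annotations` (library id -> molecule id),
#'   `molecules`, `fingerprints`.
#' @export
generate_benchmark <- function(config = benchmark_config(),
                               mode = c("library_split", "unknown"),
                               seed = 1L) {
  mode <- match.arg(mode)
  mols <- generate_molecule_set(config$n_molecules, config$n_blocks,
                                config$blocks_per_molecule,
                                config$fragments_per_block,
                                config$bits_per_block,
                                config$fingerprint_length,
                                config$mz_range, config$family_size,
                                config$swap_prob, seed = seed)
  spectra <- list()
  owner <- character(0)
  for (mi in seq_along(mols)) {
    for (r in seq_len(config$spectra_per_molecule)) {
      sid <- sprintf("%s_r%d", mols[[mi]]$id, r)
      sp <- generate_spectrum(mols[[mi]], config$dropout,
                              config$intensity_jitter, config$mz_jitter,
                              config$n_spurious, config$min_peaks,
                              seed = (seed %% 21000L) * 100000L + mi * 100L + r,
                              spectrum_id = sid)
      spectra[[length(spectra) + 1L]] <- sp
      owner <- c(owner, mols[[mi]]$id)
    }
  }
  mol_ids <- vapply(mols, `[[`, character(1L), "id")
  if (mode == "library_split") {
    query_mols <- withr::with_seed(seed,
      sample(mol_ids, min(config$n_queries, length(mol_ids))))
    is_query <- logical(length(spectra))
    for (qm in query_mols) {
      idx <- which(owner == qm)
      is_query[idx[1L]] <- TRUE  # one spectrum to queries, rest stay
    }
    library_sp <- spectra[!is_query]
    queries <- spectra[is_query]
    training <- library_sp
    lib_owner <- owner[!is_query]
    q_owner <- owner[is_query]
  } else {
    query_mols <- withr::with_seed(seed + 1L,
      sample(mol_ids, min(config$n_query_molecules, length(mol_ids))))
    is_query <- owner %in% query_mols
    library_sp <- spectra[!is_query]
    queries <- spectra[is_query]
    training <- library_sp
    lib_owner <- owner[!is_query]
    q_owner <- owner[is_query]
  }
  sp_id <- function(ss) vapply(ss, function(s) s$spectrum_id, character(1L))
  truth <- q_owner
  names(truth) <- sp_id(queries)
  lib_ann <- lib_owner
  names(lib_ann) <- sp_id(library_sp)
  list(library = library_sp, queries = queries, training = training,
       truth = truth, library_annotations = lib_ann, molecules = mols,
       fingerprints = lapply(mols, `[[`, "fingerprint"),
       mode = mode, seed = seed, config = config)
}

#' Write a benchmark to disk as plain-text files
#'
#' Emits `library.mgf`, `queries.mgf`, `fingerprints.tsv` (hex table)
#' and `truth.tsv`, consumable by the readers in this package and by the
#' command-line interface.
#'
#' @param bench list from [generate_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mgf(bench$library, file.path(dir, "library.mgf"))
  write_mgf(bench$queries, file.path(dir, "queries.mgf"))
  write_fingerprints(bench$fingerprints, file.path(dir, "fingerprints.tsv"))
  utils::write.table(
    data.frame(query_id = names(bench$truth), molecule_id = bench$truth),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
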