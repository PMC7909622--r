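# Structural ground truth: Tanimoto (Jaccard) similarity over molecular
# fingerprint bit vectors. Fingerprints can be supplied precomputed (hex
# tables) or derived from structures through an optional OpenBabel
# adapter; no bespoke chemistry is performed here.

#' Construct a fingerprint bit vector
#'
#' @param bits logical or 0/1 vector of fingerprint bits.
#' @param molecule_id identifier (planar InChIKey or synthetic id).
#' @return object of class `fingerprint`: list with `bits` (logical) and
#'   `molecule_id`.
#' @export
fingerprint <- function(bits, molecule_id = NA_character_) {
  bits <- as.logical(bits)
  if (any(is.na(bits))) stop("fingerprint bits must be 0/1")
  structure(list(bits = bits, molecule_id = as.character(molecule_id)),
            class = "fingerprint")
}

fp_bits <- function(p) if (inherits(p, "fingerprint")) p$bits else as.logical(p)

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' @param p,q `fingerprint` objects or logical/0-1 vectors of equal
#'   length, at least one set bit between them.
#' @return `|p AND q| / |p OR q|`, in \[0, 1\].
#' @export
tanimoto <- function(p, q) {
  p <- fp_bits(p)
  q <- fp_bits(q)
  if (length(p) != length(q))
    stop("fingerprint length mismatch: ", length(p), " vs ", length(q))
  u <- sum(p | q)
  if (u == 0L) stop("both fingerprints are empty")
  sum(p & q) / u
}

#' All-vs-all Tanimoto similarity matrix
#'
#' @param fps list of `fingerprint` objects of uniform length.
#' @return symmetric matrix with unit diagonal; rownames/colnames from
#'   molecule ids.
#' @export
structural_similarity_matrix <- function(fps) {
  n <- length(fps)
  if (n == 0L) return(matrix(numeric(0), 0L, 0L))
  M <- do.call(rbind, lapply(fps, function(p) as.numeric(fp_bits(p))))
  if (any(rowSums(M) == 0))
    stop("fingerprints with no set bit cannot enter a similarity matrix")
  inter <- M %*% t(M)
  sizes <- rowSums(M)
  un <- outer(sizes, sizes, "+") - inter
  m <- inter / un
  diag(m) <- 1
  ids <- vapply(fps, function(p)
    if (inherits(p, "fingerprint")) p$molecule_id else NA_character_,
    character(1L))
  rownames(m) <- colnames(m) <- ids
  m
}

#' Fraction of unique off-diagonal pairs above thresholds
#'
#' The tail probability of the all-vs-all similarity distribution: for
#' each threshold, the share of the n(n-1)/2 unique pairs whose score
#' strictly exceeds it. Used to judge how (un)likely a given structural
#' similarity is to arise between randomly chosen molecules.
#'
#' @param m symmetric similarity matrix.
#' @param thresholds numeric vector of cutoffs (default `c(0.6, 0.7)`).
#' @return named numeric vector of fractions.
#' @export
fraction_pairs_above <- function(m, thresholds = c(0.6, 0.7)) {
  v <- m[upper.tri(m)]
  out <- vapply(thresholds, function(t) mean(v > t), numeric(1L))
  names(out) <- as.character(thresholds)
  out
}

#' Path-based fingerprint from a structure string (OpenBabel adapter)
#'
#' Thin adapter around the OpenBabel command-line tool: computes the
#' path-based FP2 fingerprint (1024 bits, daylight-like) for a SMILES or
#' InChI string. Purely a passthrough — every evaluation workflow in
#' this package equally accepts precomputed bit vectors, so the adapter
#' is optional.
#'
#' @param structure SMILES or InChI string (InChI detected by its
#'   `InChI=` prefix).
#' @param molecule_id identifier attached to the result.
#' @return a 1024-bit `fingerprint`.
#' @export
fingerprint_from_structure <- function(structure, molecule_id = NA_character_) {
  if (Sys.which("obabel") == "")
    stop("OpenBabel ('obabel') not found on PATH; supply precomputed ",
         "fingerprint bit vectors instead (see read_fingerprints)")
  informat <- if (startsWith(structure, "InChI=")) "-iinchi" else "-ismi"
  out <- suppressWarnings(
    system2("obabel", c(informat, "-ofpt", "-xfFP2", "-xh"),
            input = structure, stdout = TRUE, stderr = FALSE))
  hexwords <- unlist(strsplit(grep("^[0-9a-fA-F ]+$", out, value = TRUE),
                              "\\s+"))
  hexwords <- hexwords[nzchar(hexwords)]
  if (length(hexwords) == 0L)
    stop("OpenBabel could not parse structure: ", structure)
  bits <- unlist(lapply(hexwords, hex_word_to_bits))
  fingerprint(bits, molecule_id)
}

# one 8-hex-digit word -> 32 logical bits (most significant first)
hex_word_to_bits <- function(h) {
  v <- strtoi(strsplit(h, "")[[1L]], base = 16L)
  unlist(lapply(v, function(x) as.logical(bitwAnd(x, c(8L, 4L, 2L, 1L)))))
}

#' Write / read fingerprints as a hex table
#'
#' Plain-text exchange format: one row per molecule, tab-separated
#' `id <TAB> hex`, where `hex` encodes the bit vector four bits per
#' character (bit vectors are zero-padded to a multiple of four; the
#' original length is recorded in a `# bits=` header line).
#'
#' @param fps list of `fingerprint`.
#' @param path file path.
#' @return `write_fingerprints`: `path` invisibly; `read_fingerprints`:
#'   list of `fingerprint`.
#' @export
write_fingerprints <- function(fps, path) {
  nbits <- unique(vapply(fps, function(p) length(fp_bits(p)), integer(1L)))
  if (length(nbits) > 1L) stop("fingerprints have differing lengths")
  rows <- vapply(fps, function(p) {
    b <- fp_bits(p)
    pad <- (4L - length(b) %% 4L) %% 4L
    b <- c(b, rep(FALSE, pad))
    nib <- matrix(as.integer(b), nrow = 4L)
    hex <- paste(sprintf("%x", colSums(nib * c(8L, 4L, 2L, 1L))),
                 collapse = "")
    paste(p$molecule_id, hex, sep = "\t")
  }, character(1L))
  writeLines(c(sprintf("# bits=%d", nbits), rows), path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# bits=", lines, value = TRUE)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nbits <- if (length(hdr) > 0L)
    as.integer(sub("^# bits=", "", hdr[1L])) else NA_integer_
  lapply(parts, function(p) {
    bits <- unlist(lapply(strsplit(p[2L], "")[[1L]], function(ch) {
      v <- strtoi(ch, base = 16L)
      as.logical(bitwAnd(v, c(8L, 4L, 2L, 1L)))
    }))
    if (!is.na(nbits)) bits <- bits[seq_len(nbits)]
    fingerprint(bits, p[1L])
  })
}
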