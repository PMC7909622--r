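# Readers and writers for the spectral library formats used in practice:
# MGF (BEGIN IONS blocks), NIST-style MSP, and GNPS-style JSON dumps.
# Metadata keys are matched case-insensitively; unparseable records are
# skipped with a warning rather than aborting the whole file.

#' Read spectra from a file
#'
#' @param path file path.
#' @param format one of `"mgf"`, `"msp"`, `"json"` (GNPS-style). When
#'   `NULL`, guessed from the file extension.
#' @return list of `ms_spectrum`, peaks sorted ascending by m/z.
#'   Records that fail to parse produce a warning and are skipped.
#' @export
read_spectra <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", msp = "msp", json = "json",
                     stop("cannot guess spectral format from extension: ", ext))
  }
  format <- tolower(format)
  switch(format,
         mgf = read_mgf(path),
         msp = read_msp(path),
         json = read_gnps_json(path),
         stop("unknown spectral format: ", format))
}

# case-insensitive metadata lookup over a named character vector
meta_get <- function(meta, keys) {
  nm <- tolower(names(meta))
  for (k in tolower(keys)) {
    i <- match(k, nm)
    if (!is.na(i)) return(meta[[i]])
  }
  NA_character_
}

num_or_na <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) == 0L) NA_real_ else v[1L]
}

spectrum_from_meta <- function(mz, intensity, meta, default_id) {
  ionmode <- tolower(meta_get(meta, c("ionmode", "ion_mode")))
  if (is.na(ionmode) || !ionmode %in% c("positive", "negative"))
    ionmode <- "unknown"
  id <- meta_get(meta, c("spectrumid", "spectrum_id", "title", "name", "scans"))
  if (is.na(id)) id <- default_id
  spectrum(mz, intensity,
           precursor_mz = num_or_na(meta_get(meta, c("pepmass", "precursor_mz", "precursormz"))),
           parent_mass = num_or_na(meta_get(meta, c("parentmass", "parent_mass", "exactmass"))),
           inchikey = meta_get(meta, c("inchikey", "inchikey_smiles")),
           ionmode = ionmode, spectrum_id = id)
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\s*BEGIN IONS\\s*$", lines)
  ends <- grep("^\\s*END IONS\\s*$", lines)
  if (length(starts) != length(ends))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[seq(starts[b] + 1L, ends[b] - 1L)]
    s <- tryCatch(parse_mgf_block(block, sprintf("mgf_%d", b)),
                  error = function(e) {
                    warning("skipping MGF record ", b, ": ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(s)) out[[length(out) + 1L]] <- s
  }
  out
}

parse_mgf_block <- function(block, default_id) {
  block <- trimws(block)
  block <- block[nzchar(block)]
  is_kv <- grepl("=", block, fixed = TRUE)
  kv <- strsplit(block[is_kv], "=", fixed = TRUE)
  meta <- vapply(kv, function(p) paste(p[-1L], collapse = "="), character(1L))
  names(meta) <- vapply(kv, `[[`, character(1L), 1L)
  # PEPMASS may carry "mz intensity"; keep the first token
  i <- match("pepmass", tolower(names(meta)))
  if (!is.na(i)) meta[[i]] <- strsplit(trimws(meta[[i]]), "\\s+")[[1L]][1L]
  peaks <- do.call(rbind, lapply(strsplit(block[!is_kv], "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (any(is.na(v))) stop("bad peak line: ", paste(p, collapse = " "))
    v
  }))
  if (is.null(peaks)) peaks <- matrix(numeric(0), ncol = 2L)
  spectrum_from_meta(peaks[, 1L], peaks[, 2L], meta, default_id)
}

#' Write spectra to an MGF file
#'
#' @param spectra list of `ms_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(s$spectrum_id))
      writeLines(paste0("TITLE=", s$spectrum_id), con)
    if (!is.na(s$precursor_mz))
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$parent_mass))
      writeLines(sprintf("PARENTMASS=%.6f", s$parent_mass), con)
    if (!is.na(s$inchikey))
      writeLines(paste0("INCHIKEY=", s$inchikey), con)
    writeLines(paste0("IONMODE=", s$ionmode), con)
    writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' @rdname read_spectra
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # records start at Name: lines
  starts <- grep("^name:", lines, ignore.case = TRUE)
  if (length(starts) == 0L) return(list())
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[seq(bounds[b], bounds[b + 1L] - 1L)]
    s <- tryCatch(parse_msp_block(block, sprintf("msp_%d", b)),
                  error = function(e) {
                    warning("skipping MSP record ", b, ": ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(s)) out[[length(out) + 1L]] <- s
  }
  out
}

parse_msp_block <- function(block, default_id) {
  block <- trimws(block)
  block <- block[nzchar(block)]
  is_kv <- grepl("^[A-Za-z][A-Za-z0-9 _]*:", block)
  kv <- regmatches(block[is_kv], regexpr(":", block[is_kv]), invert = TRUE)
  meta <- vapply(kv, function(p) trimws(p[2L]), character(1L))
  names(meta) <- gsub(" ", "", vapply(kv, `[[`, character(1L), 1L))
  peak_lines <- block[!is_kv]
  peaks <- do.call(rbind, lapply(peak_lines, function(l) {
    p <- strsplit(trimws(gsub(";", " ", l)), "\\s+")[[1L]]
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (any(is.na(v))) stop("bad peak line: ", l)
    v
  }))
  if (is.null(peaks)) peaks <- matrix(numeric(0), ncol = 2L)
  n_declared <- num_or_na(meta_get(meta, "numpeaks"))
  if (!is.na(n_declared) && n_declared != nrow(peaks))
    stop("Num Peaks mismatch: declared ", n_declared, ", found ", nrow(peaks))
  spectrum_from_meta(peaks[, 1L], peaks[, 2L], meta, default_id)
}

#' @rdname read_spectra
#' @export
read_gnps_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (b in seq_along(recs)) {
    s <- tryCatch(parse_gnps_record(recs[[b]], sprintf("json_%d", b)),
                  error = function(e) {
                    warning("skipping JSON record ", b, ": ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(s)) out[[length(out) + 1L]] <- s
  }
  out
}

parse_gnps_record <- function(rec, default_id) {
  meta <- vapply(rec[!vapply(rec, is.list, logical(1L))],
                 function(x) as.character(x)[1L], character(1L))
  pj <- meta_get(meta, "peaks_json")
  if (is.na(pj)) stop("record has no peaks_json")
  peaks <- jsonlite::fromJSON(pj)
  if (length(peaks) == 0L) peaks <- matrix(numeric(0), ncol = 2L)
  spectrum_from_meta(peaks[, 1L], peaks[, 2L], meta, default_id)
}

#' Write spectra as a GNPS-style JSON dump
#'
#' One record per spectrum with `peaks_json` (stringified `[[mz, i], ...]`
#' array), `Precursor_MZ`, `Parent_Mass`, `InChIKey`, `Ion_Mode` and
#' `spectrum_id` keys, mirroring the dialect read by [read_gnps_json()].
#'
#' @param spectra list of `ms_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gnps_json <- function(spectra, path) {
  recs <- lapply(spectra, function(s) {
    r <- list(
      spectrum_id = s$spectrum_id,
      peaks_json = as.character(jsonlite::toJSON(
        unname(Map(c, s$mz, s$intensity)), digits = NA, auto_unbox = FALSE)),
      Ion_Mode = s$ionmode)
    if (!is.na(s$precursor_mz)) r$Precursor_MZ <- as.character(s$precursor_mz)
    if (!is.na(s$parent_mass)) r$Parent_Mass <- as.character(s$parent_mass)
    if (!is.na(s$inchikey)) r$InChIKey <- s$inchikey
    r
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write / read a labeled similarity matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @return `write_similarity_matrix`: `path` invisibly;
#'   `read_similarity_matrix`: the matrix.
#' @export
write_similarity_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1L, check.names = FALSE))
}
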