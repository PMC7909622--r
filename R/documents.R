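#' Encode an m/z value as a peak or loss word
#'
#' Peak positions are binned to `n_decimals` decimals (half-away-from-zero,
#' see [format_mz()]) and rendered as text tokens, e.g. a fragment at m/z
#' 200.445 becomes `"peak@200.45"` at two decimals.
#'
#' @param value positive m/z (or neutral-loss mass) in Da.
#' @param n_decimals binning precision (default 2).
#' @param prefix `"peak"` or `"loss"`.
#' @return word string.
#' @export
mz_to_word <- function(value, n_decimals = 2L, prefix = c("peak", "loss")) {
  prefix <- match.arg(prefix)
  if (any(!is.finite(value) | value <= 0))
    stop("word values must be finite and > 0")
  paste0(prefix, "@", format_mz(value, n_decimals))
}

#' Neutral losses of a spectrum
#'
#' Neutral losses are computed as `precursor_mz - peak_mz` and retained
#' when they fall in the closed window `[low, high]` Da. Each loss carries
#' the intensity of its generating peak. Without a precursor m/z no losses
#' can be formed and an empty set is returned.
#'
#' @param s an `ms_spectrum`.
#' @param low,high loss window in Da (defaults 5.0 and 200.0).
#' @return data.frame with columns `loss` (ascending) and `intensity`.
#' @export
compute_losses <- function(s, low = 5.0, high = 200.0) {
  stopifnot(is_spectrum(s))
  if (is.na(s$precursor_mz))
    return(data.frame(loss = numeric(0), intensity = numeric(0)))
  loss <- s$precursor_mz - s$mz
  keep <- loss >= low & loss <= high
  d <- data.frame(loss = loss[keep], intensity = s$intensity[keep])
  d[order(d$loss), , drop = FALSE]
}

#' Convert a spectrum into a word document
#'
#' The document is the ordered bag of tokens the embedding model trains
#' on: all peak words (ascending m/z) followed by all neutral-loss words
#' (ascending loss). Weights are the generating peaks' intensities
#' normalized to a maximum of 1; losses inherit the weight of the peak
#' they derive from. Duplicate words arising from distinct peaks are kept
#' as separate tokens — collapsing them would silently drop intensity
#' mass.
#'
#' @param s a processed `ms_spectrum` with at least one peak.
#' @param n_decimals m/z binning precision (default 2).
#' @param loss_range closed neutral-loss window in Da (default
#'   `c(5, 200)`).
#' @return object of class `spectrum_document`: list with `words`,
#'   parallel `weights`, `n_decimals` and `source_id`.
#' @export
spectrum_to_document <- function(s, n_decimals = 2L, loss_range = c(5, 200)) {
  stopifnot(is_spectrum(s))
  if (n_peaks(s) == 0L) stop("cannot build a document from an empty spectrum")
  w <- s$intensity / max(s$intensity)
  words <- mz_to_word(s$mz, n_decimals, "peak")
  weights <- w
  losses <- compute_losses(s, loss_range[1L], loss_range[2L])
  if (nrow(losses) > 0L) {
    words <- c(words, mz_to_word(losses$loss, n_decimals, "loss"))
    weights <- c(weights, losses$intensity / max(s$intensity))
  }
  structure(list(words = words, weights = weights,
                 n_decimals = as.integer(n_decimals),
                 source_id = s$spectrum_id),
            class = "spectrum_document")
}

#' @export
print.spectrum_document <- function(x, ...) {
  cat(sprintf("<spectrum_document %s: %d words (%d peaks, %d losses)>\n",
              x$source_id, length(x$words),
              sum(startsWith(x$words, "peak@")),
              sum(startsWith(x$words, "loss@"))))
  invisible(x)
}

#' Convert many spectra to documents
#'
#' @inheritParams spectrum_to_document
#' @param spectra list of processed `ms_spectrum` objects.
#' @return list of `spectrum_document`.
#' @export
spectra_to_documents <- function(spectra, n_decimals = 2L,
                                 loss_range = c(5, 200)) {
  lapply(spectra, spectrum_to_document, n_decimals = n_decimals,
         loss_range = loss_range)
}

#' Serialize / load a document corpus
#'
#' Documents are written one per line, words whitespace-separated, with a
#' sidecar `<path>.weights` table carrying the parallel weights and a
#' `<path>.ids` file with the source spectrum ids — a plain-text exchange
#' format for embedding training.
#'
#' @param docs list of `spectrum_document`.
#' @param path corpus file path.
#' @return `write_corpus`: `path` invisibly; `read_corpus`: list of
#'   `spectrum_document`.
#' @export
write_corpus <- function(docs, path) {
  writeLines(vapply(docs, function(d) paste(d$words, collapse = " "),
                    character(1L)), path)
  writeLines(vapply(docs, function(d)
    paste(sprintf("%.10g", d$weights), collapse = " "), character(1L)),
    paste0(path, ".weights"))
  writeLines(vapply(docs, function(d) d$source_id, character(1L)),
             paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  words <- strsplit(readLines(path, warn = FALSE), "\\s+")
  weights <- lapply(strsplit(readLines(paste0(path, ".weights"),
                                       warn = FALSE), "\\s+"), as.numeric)
  ids <- readLines(paste0(path, ".ids"), warn = FALSE)
  Map(function(w, wt, id) {
    nd <- nchar(sub(".*\\.", "", w[1L]))
    structure(list(words = w, weights = wt, n_decimals = nd,
                   source_id = id), class = "spectrum_document")
  }, words, weights, ids)
}
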