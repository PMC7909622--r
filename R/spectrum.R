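#' Construct an MS/MS spectrum
#'
#' The central container of the package: a fragment peak list (m/z,
#' intensity) plus the metadata needed by the similarity scores. Peaks are
#' stored sorted ascending by m/z; duplicate m/z values are permitted.
#'
#' @param mz numeric vector of fragment m/z values in Da; all > 0.
#' @param intensity numeric vector of non-negative abundances (arbitrary
#'   units), parallel to `mz`.
#' @param precursor_mz precursor ion m/z in Da, or `NA` when unknown.
#' @param parent_mass neutral parent (monoisotopic) mass in Da, or `NA`.
#' @param inchikey full 27-character InChIKey, or `NA`.
#' @param ionmode one of `"positive"`, `"negative"`, `"unknown"`.
#' @param spectrum_id opaque identifier string.
#' @return An object of class `ms_spectrum`.
#' @examples
#' s <- spectrum(c(100.1, 150.2), c(5, 10), precursor_mz = 300.15)
#' n_peaks(s)
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     parent_mass = NA_real_, inchikey = NA_character_,
                     ionmode = "unknown", spectrum_id = NA_character_) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("all mz values must be finite and > 0")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("all intensities must be finite and >= 0")
  if (!is.na(precursor_mz) && precursor_mz <= 0)
    stop("precursor_mz must be > 0 when present")
  ionmode <- match.arg(ionmode, c("positive", "negative", "unknown"))
  ord <- order(mz)
  structure(
    list(mz = mz[ord], intensity = intensity[ord],
         precursor_mz = as.numeric(precursor_mz),
         parent_mass = as.numeric(parent_mass),
         inchikey = as.character(inchikey),
         ionmode = ionmode,
         spectrum_id = as.character(spectrum_id)),
    class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum %s: %d peaks", x$spectrum_id, length(x$mz)))
  if (!is.na(x$precursor_mz))
    cat(sprintf(", precursor m/z %.4f", x$precursor_mz))
  if (!is.na(x$parent_mass))
    cat(sprintf(", parent mass %.4f", x$parent_mass))
  cat(sprintf(", %s mode>\n", x$ionmode))
  invisible(x)
}

#' Number of fragment peaks in a spectrum
#' @param s an `ms_spectrum`.
#' @return integer peak count.
#' @export
n_peaks <- function(s) length(s$mz)

is_spectrum <- function(s) inherits(s, "ms_spectrum")

# replace the peak list, keeping metadata; resorts by mz
set_peaks <- function(s, mz, intensity) {
  ord <- order(mz)
  s$mz <- mz[ord]
  s$intensity <- intensity[ord]
  s
}

#' Planar InChIKey (first 14 characters)
#'
#' The first 14 characters of an InChIKey hash the connectivity ("2D
#' skeleton") of a molecule and are used throughout the evaluation
#' workflows as the molecule identity.
#'
#' @param x character vector of full InChIKeys (or already-planar keys).
#' @return character vector of validated 14-character planar keys.
#' @export
planar_inchikey <- function(x) {
  x <- toupper(substr(as.character(x), 1L, 14L))
  bad <- !is.na(x) & !grepl("^[A-Z]{14}$", x)
  if (any(bad))
    stop("invalid planar InChIKey: ", paste(x[bad], collapse = ", "))
  x
}

#' Round and format a positive number half-away-from-zero
#'
#' Decimal (not binary) rounding: the value is first rendered with nine
#' guard digits, then rounded at `digits` decimals with ties going away
#' from zero, so e.g. 200.445 at two decimals gives "200.45".
#' Used for peak/loss word construction where reproducible decimal
#' binning matters.
#'
#' @param x numeric vector.
#' @param digits number of decimals to keep.
#' @return character vector with exactly `digits` decimals.
#' @export
format_mz <- function(x, digits = 2L) {
  digits <- as.integer(digits)
  vapply(x, function(v) {
    neg <- v < 0
    s <- sprintf("%.*f", digits + 9L, abs(v))
    parts <- strsplit(s, ".", fixed = TRUE)[[1L]]
    dec <- parts[2L]
    keep <- substr(dec, 1L, digits)
    rest <- substr(dec, digits + 1L, nchar(dec))
    scaled <- as.numeric(parts[1L]) * 10^digits +
      (if (digits > 0L) as.numeric(keep) else 0)
    if (as.numeric(rest) >= 5e8) scaled <- scaled + 1  # tie or above: away from zero
    out <- sprintf("%.*f", digits, scaled / 10^digits)
    if (neg) paste0("-", out) else out
  }, character(1L))
}
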