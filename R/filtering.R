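#' Normalize peak intensities to a maximum of 1
#'
#' @param s an `ms_spectrum` with at least one peak of positive intensity.
#' @return the spectrum with intensities divided by their maximum, so the
#'   base peak has intensity exactly 1 and relative intensities are
#'   preserved.
#' @export
normalize_intensities <- function(s) {
  stopifnot(is_spectrum(s))
  if (n_peaks(s) == 0L) stop("cannot normalize an empty spectrum")
  m <- max(s$intensity)
  if (m <= 0) stop("cannot normalize a spectrum whose intensities are all zero")
  s$intensity <- s$intensity / m
  s
}

#' Keep peaks inside a closed m/z window
#'
#' @param s an `ms_spectrum`.
#' @param low,high window bounds in Da; the interval is closed at both
#'   ends, so peaks at exactly `low` or `high` are retained.
#' @return the spectrum restricted to `low <= mz <= high`.
#' @export
filter_mz_range <- function(s, low = 0, high = 1000) {
  stopifnot(is_spectrum(s), low < high)
  keep <- s$mz >= low & s$mz <= high
  set_peaks(s, s$mz[keep], s$intensity[keep])
}

#' Reject spectra with too few peaks
#'
#' Rejection is a value, not an error: sparse spectra carry too little
#' fragment information for similarity scoring and are dropped from the
#' corpus rather than aborting a pipeline.
#'
#' @param s an `ms_spectrum`.
#' @param n minimum peak count (default 10).
#' @return `s` when it has at least `n` peaks, otherwise `NULL`.
#' @export
require_minimum_peaks <- function(s, n = 10L) {
  stopifnot(is_spectrum(s))
  if (n_peaks(s) >= n) s else NULL
}

#' Remove peaks below a relative-intensity threshold
#'
#' Peaks whose intensity relative to the base peak is below `threshold`
#' are discarded; peaks at exactly the threshold are kept.
#'
#' @param s an `ms_spectrum` with at least one peak.
#' @param threshold fraction of the maximum intensity (default 0.01).
#' @return the filtered spectrum.
#' @export
select_by_relative_intensity <- function(s, threshold = 0.01) {
  stopifnot(is_spectrum(s))
  if (n_peaks(s) == 0L) stop("spectrum has no peaks")
  keep <- s$intensity / max(s$intensity) >= threshold
  set_peaks(s, s$mz[keep], s$intensity[keep])
}

#' Cap the peak count at half the parent mass
#'
#' Larger molecules are expected to produce more informative fragments, so
#' the maximum number of retained peaks scales linearly with the estimated
#' parent mass: at most `floor(0.5 * parent_mass)` of the most intense
#' peaks are kept (re-sorted by m/z). Spectra already below the cap pass
#' through unchanged.
#'
#' @param s an `ms_spectrum` whose parent mass is available directly or
#'   via [estimate_parent_mass()].
#' @return the capped spectrum.
#' @export
reduce_to_top_peaks <- function(s) {
  stopifnot(is_spectrum(s))
  pm <- estimate_parent_mass(s)
  cap <- floor(0.5 * pm)
  if (n_peaks(s) <= cap) return(s)
  ord <- order(-s$intensity, s$mz)  # most intense first; ties by m/z
  keep <- sort(ord[seq_len(cap)])
  set_peaks(s, s$mz[keep], s$intensity[keep])
}

#' Estimate the neutral parent mass of a spectrum
#'
#' Returns the stored parent mass when present; otherwise falls back to
#' `precursor_mz - 1.007276` (assuming a singly protonated ion, positive
#' mode). The proton-mass fallback is an explicit assumption of this
#' package; spectra whose adduct is known to differ should carry a
#' corrected `parent_mass`.
#'
#' @param s an `ms_spectrum`.
#' @return parent mass in Da.
#' @export
estimate_parent_mass <- function(s) {
  stopifnot(is_spectrum(s))
  if (!is.na(s$parent_mass)) return(s$parent_mass)
  if (!is.na(s$precursor_mz)) return(s$precursor_mz - 1.007276)
  stop("neither parent_mass nor precursor_mz available for spectrum ",
       s$spectrum_id)
}

#' Process a set of spectra on one of the two filtering tracks
#'
#' Two distinct processing tracks are maintained because the classical and
#' embedding scores have different noise sensitivities:
#' \describe{
#'   \item{`"cosine"`}{m/z window filter, intensity normalization, then
#'     removal of peaks below `intensity_threshold` relative intensity.}
#'   \item{`"embedding"`}{m/z window filter, peak-count cap at
#'     `floor(0.5 * parent_mass)` (skipped with a warning when no parent
#'     mass can be estimated), then intensity normalization. The cap keeps
#'     document lengths comparable across the corpus.}
#' }
#' Both tracks end by dropping spectra with fewer than `min_peaks` peaks.
#'
#' @param spectra list of `ms_spectrum` objects.
#' @param track `"cosine"` or `"embedding"`.
#' @param mz_range closed m/z window in Da (default `c(0, 1000)`).
#' @param min_peaks minimum peak count after filtering (default 10).
#' @param intensity_threshold relative-intensity cutoff for the cosine
#'   track (default 0.01).
#' @return list of processed spectra; attribute `"log"` records counts of
#'   input, rejected and retained spectra.
#' @export
process_spectra <- function(spectra, track = c("cosine", "embedding"),
                            mz_range = c(0, 1000), min_peaks = 10L,
                            intensity_threshold = 0.01) {
  track <- match.arg(track)
  out <- vector("list", length(spectra))
  n_kept <- 0L
  n_uncapped <- 0L
  for (s in spectra) {
    s <- filter_mz_range(s, mz_range[1L], mz_range[2L])
    if (n_peaks(s) == 0L) next
    if (track == "cosine") {
      s <- normalize_intensities(s)
      s <- select_by_relative_intensity(s, intensity_threshold)
    } else {
      pm <- tryCatch(estimate_parent_mass(s), error = function(e) NA_real_)
      if (is.na(pm)) n_uncapped <- n_uncapped + 1L else s <- reduce_to_top_peaks(s)
      s <- normalize_intensities(s)
    }
    s <- require_minimum_peaks(s, min_peaks)
    if (!is.null(s)) {
      n_kept <- n_kept + 1L
      out[[n_kept]] <- s
    }
  }
  if (n_uncapped > 0L)
    warning(n_uncapped, " spectra lacked a parent mass; peak cap skipped")
  out <- out[seq_len(n_kept)]
  attr(out, "log") <- list(track = track, n_in = length(spectra),
                           n_kept = n_kept,
                           n_rejected = length(spectra) - n_kept)
  out
}
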