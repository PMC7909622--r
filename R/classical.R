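# Classical alignment-based spectral similarity: greedy cosine and the
# modified cosine (which additionally allows peak matches shifted by the
# precursor m/z difference). Each peak may be used in at most one matched
# pair, either as-is or in its shifted form.

#' Candidate peak pairs between two spectra
#'
#' Collects all peak pairs whose m/z agree within `tolerance`
#' (inclusive), and — when `shift` is given — additionally pairs agreeing
#' after shifting spectrum B by the precursor m/z difference. With
#' `shift = 0`, shifted candidates duplicating unshifted ones are
#' removed.
#'
#' @param a,b `ms_spectrum` objects.
#' @param tolerance m/z tolerance in Da (default 0.005).
#' @param shift `NULL` for plain matching, or the shift in Da (typically
#'   `precursor_mz(a) - precursor_mz(b)`).
#' @return data.frame with columns `index_a`, `index_b`, `product`
#'   (intensity product), `dmz` (absolute residual), `shifted`.
#' @export
collect_candidate_pairs <- function(a, b, tolerance = 0.005, shift = NULL) {
  stopifnot(is_spectrum(a), is_spectrum(b))
  pairs_within <- function(delta, flag) {
    d <- abs(outer(a$mz, b$mz, "-") - delta)
    hit <- which(d <= tolerance, arr.ind = TRUE)
    if (nrow(hit) == 0L)
      return(data.frame(index_a = integer(0), index_b = integer(0),
                        product = numeric(0), dmz = numeric(0),
                        shifted = logical(0)))
    data.frame(index_a = hit[, 1L], index_b = hit[, 2L],
               product = a$intensity[hit[, 1L]] * b$intensity[hit[, 2L]],
               dmz = d[hit], shifted = flag)
  }
  out <- pairs_within(0, FALSE)
  if (!is.null(shift)) {
    sh <- pairs_within(shift, TRUE)
    if (abs(shift) <= tolerance && nrow(sh) > 0L) {
      dup <- paste(sh$index_a, sh$index_b) %in% paste(out$index_a, out$index_b)
      sh <- sh[!dup, , drop = FALSE]
    }
    out <- rbind(out, sh)
  }
  out[out$product > 0, , drop = FALSE]
}

#' Greedy one-to-one peak assignment
#'
#' Candidates are visited by descending intensity product (ties: smaller
#' m/z residual first, then lower `index_a`) and accepted when neither
#' peak has been used yet — each peak is matched at most once across the
#' shifted and unshifted pools. This greedy scheme runs in near-linear
#' time and is guaranteed to reach at least half the optimal matched
#' product (see [optimal_assignment()] for the exact reference used in
#' validation).
#'
#' @param candidates data.frame from [collect_candidate_pairs()].
#' @return the accepted subset of `candidates`.
#' @export
greedy_assignment <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(-candidates$product, candidates$dmz, candidates$index_a,
               candidates$index_b)
  used_a <- integer(0)
  used_b <- integer(0)
  take <- logical(nrow(candidates))
  for (i in ord) {
    ia <- candidates$index_a[i]
    ib <- candidates$index_b[i]
    if (ia %in% used_a || ib %in% used_b) next
    take[i] <- TRUE
    used_a <- c(used_a, ia)
    used_b <- c(used_b, ib)
  }
  candidates[take, , drop = FALSE]
}

#' Exact maximum-product peak assignment (validation reference)
#'
#' Brute-force maximum-weight matching over candidate subsets. Only
#' intended as an independent reference for validating the greedy
#' assignment on small instances; cost grows exponentially in the number
#' of candidates.
#'
#' @param candidates data.frame from [collect_candidate_pairs()]; at most
#'   `max_candidates` rows.
#' @param max_candidates safety limit (default 20).
#' @return list with `total` (maximal matched product) and `selected`
#'   (row indices of one optimal matching).
#' @export
optimal_assignment <- function(candidates, max_candidates = 20L) {
  n <- nrow(candidates)
  if (n == 0L) return(list(total = 0, selected = integer(0)))
  if (n > max_candidates)
    stop("optimal_assignment is exponential; refusing ", n, " candidates")
  best <- 0
  best_sel <- integer(0)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (anyDuplicated(candidates$index_a[sel]) ||
        anyDuplicated(candidates$index_b[sel])) next
    tot <- sum(candidates$product[sel])
    if (tot > best) {
      best <- tot
      best_sel <- sel
    }
  }
  list(total = best, selected = best_sel)
}

score_from_matching <- function(a, b, matching, min_match) {
  n_matches <- nrow(matching)
  norm <- sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2))
  score <- if (n_matches < min_match) 0 else sum(matching$product) / norm
  list(score = score, n_matches = n_matches)
}

#' Greedy cosine similarity between two spectra
#'
#' Matched peak pairs (within `tolerance`) are selected greedily, each
#' peak at most once; the score is the matched intensity product divided
#' by the product of the full-spectrum intensity norms, so identical
#' spectra score 1. Pairs with fewer than `min_match` matched peaks are
#' forced to score 0, suppressing spurious matches built on a handful of
#' coincidental peaks.
#'
#' @param a,b non-empty `ms_spectrum` objects.
#' @param tolerance m/z tolerance in Da (default 0.005).
#' @param min_match minimum matched-pair count (default 6).
#' @return list with `score` in \[0, 1\] and `n_matches`.
#' @export
cosine_score <- function(a, b, tolerance = 0.005, min_match = 6L) {
  if (n_peaks(a) == 0L || n_peaks(b) == 0L)
    stop("cannot score an empty spectrum")
  matching <- greedy_assignment(collect_candidate_pairs(a, b, tolerance))
  score_from_matching(a, b, matching, min_match)
}

#' Modified cosine similarity (precursor-shift aware)
#'
#' As [cosine_score()], but candidate pairs additionally include peaks
#' aligning after shifting by the precursor m/z difference, so that a
#' single structural modification that displaces a subset of fragments
#' still yields matches. Each peak can be matched either as-is or in its
#' shifted form, never both.
#'
#' @param a,b non-empty `ms_spectrum` objects, both with `precursor_mz`.
#' @param tolerance m/z tolerance in Da (default 0.005).
#' @param min_match minimum matched-pair count (default 10).
#' @return list with `score` in \[0, 1\] and `n_matches`.
#' @export
modified_cosine_score <- function(a, b, tolerance = 0.005, min_match = 10L) {
  if (n_peaks(a) == 0L || n_peaks(b) == 0L)
    stop("cannot score an empty spectrum")
  if (is.na(a$precursor_mz) || is.na(b$precursor_mz))
    stop("modified cosine requires precursor_mz on both spectra")
  shift <- a$precursor_mz - b$precursor_mz
  matching <- greedy_assignment(
    collect_candidate_pairs(a, b, tolerance, shift = shift))
  score_from_matching(a, b, matching, min_match)
}

#' All-vs-all classical score matrix
#'
#' @param queries,refs lists of `ms_spectrum`; with `refs = NULL` the
#'   matrix is all-vs-all over `queries` (symmetric).
#' @param score_fn [cosine_score()] or [modified_cosine_score()] (or any
#'   function returning a list with a `score` element).
#' @param ... passed to `score_fn`.
#' @return numeric matrix of scores, rownames/colnames from spectrum ids.
#' @export
classical_score_matrix <- function(queries, refs = NULL, score_fn = cosine_score,
                                   ...) {
  symmetric <- is.null(refs)
  if (symmetric) refs <- queries
  m <- matrix(0, length(queries), length(refs))
  rownames(m) <- vapply(queries, function(s) s$spectrum_id, character(1L))
  colnames(m) <- vapply(refs, function(s) s$spectrum_id, character(1L))
  for (i in seq_along(queries)) {
    jmax <- if (symmetric) i else length(refs)
    for (j in seq_len(jmax)) {
      m[i, j] <- score_fn(queries[[i]], refs[[j]], ...)$score
      if (symmetric) m[j, i] <- m[i, j]
    }
  }
  m
}
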