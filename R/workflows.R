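# Evaluation and application workflows: score-vs-structure percentile
# analysis, library matching with ppm precursor pre-selection, top-k
# analog search, and molecular networking with Louvain splitting and
# structural cluster quality.

#' Mean structural similarity over the top spectral-score percentiles
#'
#' For each fraction f, the `ceiling(f * n_pairs)` unique off-diagonal
#' pairs with the highest spectral score are selected and the mean of
#' their structural similarities is reported, together with the
#' theoretical maximum (the mean of the f highest structural similarities
#' themselves). A spectral score that tracks structure well produces a
#' curve close to that maximum at small fractions.
#'
#' @param spectral,structural same-shape symmetric similarity matrices
#'   over the same molecules, identically ordered.
#' @param fractions percentile fractions in (0, 1\] (default
#'   `c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2)`).
#' @return data.frame with columns `fraction`, `n_pairs`,
#'   `mean_structural`, `max_possible`.
#' @export
top_percentile_structural_means <- function(spectral, structural,
                                            fractions = c(0.001, 0.005, 0.01,
                                                          0.05, 0.1, 0.2)) {
  if (!all(dim(spectral) == dim(structural)))
    stop("spectral and structural matrices must have the same shape")
  ut <- upper.tri(spectral)
  sp <- spectral[ut]
  st <- structural[ut]
  n <- length(sp)
  ord_sp <- order(-sp)
  st_sorted <- sort(st, decreasing = TRUE)
  res <- lapply(fractions, function(f) {
    k <- min(n, ceiling(f * n))
    data.frame(fraction = f, n_pairs = k,
               mean_structural = mean(st[ord_sp[seq_len(k)]]),
               max_possible = mean(st_sorted[seq_len(k)]))
  })
  do.call(rbind, res)
}

#' Pre-select library spectra by precursor m/z (ppm window)
#'
#' @param query an `ms_spectrum` with `precursor_mz`.
#' @param library list of `ms_spectrum`.
#' @param ppm relative tolerance in parts per million (default 1);
#'   boundary inclusive.
#' @return integer indices into `library` of candidates with
#'   `|precursor_lib - precursor_query| <= ppm * 1e-6 * precursor_query`.
#' @export
precursor_preselect <- function(query, library, ppm = 1) {
  if (is.na(query$precursor_mz))
    stop("query spectrum has no precursor_mz")
  lib_pm <- vapply(library, function(s) s$precursor_mz, numeric(1L))
  which(!is.na(lib_pm) &
          abs(lib_pm - query$precursor_mz) <= ppm * 1e-6 * query$precursor_mz)
}

#' Match query spectra against a library
#'
#' For each query, candidates are pre-selected by precursor m/z (ppm
#' window), scored with `score_fn`, and the highest-scoring candidate is
#' accepted iff its score is strictly larger than `threshold` (ties
#' broken by smaller precursor difference, then lexicographic id).
#'
#' @param queries,library lists of `ms_spectrum`.
#' @param score_fn function of a query index and a candidate library
#'   index returning a similarity score; see [make_embedding_scorer()]
#'   and [make_classical_scorer()] for ready-made scorers.
#' @param threshold minimum (strict) score for a match.
#' @param ppm precursor pre-selection window (default 1).
#' @return data.frame with one row per query: `query_id`,
#'   `matched_library_id` (`NA` when unmatched), `matched_index`,
#'   `score`, `threshold`.
#' @export
library_match <- function(queries, library, score_fn, threshold, ppm = 1) {
  lib_ids <- vapply(library, function(s) s$spectrum_id, character(1L))
  lib_pm <- vapply(library, function(s) s$precursor_mz, numeric(1L))
  rows <- lapply(seq_along(queries), function(qi) {
    q <- queries[[qi]]
    cand <- precursor_preselect(q, library, ppm)
    if (length(cand) > 0L) {
      scores <- vapply(cand, function(ci) score_fn(qi, ci), numeric(1L))
      ord <- order(-scores, abs(lib_pm[cand] - q$precursor_mz),
                   lib_ids[cand])
      best <- ord[1L]
      if (scores[best] > threshold)
        return(data.frame(query_id = q$spectrum_id,
                          matched_library_id = lib_ids[cand[best]],
                          matched_index = cand[best],
                          score = scores[best], threshold = threshold,
                          stringsAsFactors = FALSE))
    }
    data.frame(query_id = q$spectrum_id,
               matched_library_id = NA_character_,
               matched_index = NA_integer_, score = NA_real_,
               threshold = threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scorers for library matching
#'
#' `make_embedding_scorer` precomputes spectrum vectors for query and
#' library documents and returns a closure scoring (query index, library
#' index) pairs by embedding cosine; `make_classical_scorer` wraps a
#' classical pairwise score over the raw spectra.
#'
#' @param model an `ms_embedding`.
#' @param query_docs,library_docs lists of `spectrum_document` parallel
#'   to the query/library spectra.
#' @return function `(qi, ci) -> score`.
#' @export
make_embedding_scorer <- function(model, query_docs, library_docs) {
  Q <- predict(model, query_docs)
  L <- predict(model, library_docs)
  Qn <- Q / sqrt(rowSums(Q^2))
  Ln <- L / sqrt(rowSums(L^2))
  function(qi, ci) sum(Qn[qi, ] * Ln[ci, ])
}

#' @rdname make_embedding_scorer
#' @param queries,library lists of `ms_spectrum`.
#' @param score_pair [cosine_score()] or [modified_cosine_score()].
#' @param ... passed on to `score_pair`.
#' @export
make_classical_scorer <- function(queries, library, score_pair = cosine_score,
                                  ...) {
  function(qi, ci) score_pair(queries[[qi]], library[[ci]], ...)$score
}

#' Evaluate library-match decisions against molecular ground truth
#'
#' A matched query counts as a true positive when the matched library
#' spectrum shares the query's planar InChIKey (or synthetic molecule
#' id), and as a false positive otherwise. Retrieval is the fraction of
#' queries yielding any match; accuracy is TP / (TP + FP), defined as 0
#' when nothing was matched.
#'
#' @param decisions data.frame from [library_match()].
#' @param truth named character vector: query id -> molecule key.
#' @param library_annotations named character vector: library id ->
#'   molecule key. Every matched library id must be annotated.
#' @return list with `tp`, `fp`, `accuracy`, `retrieval`, `n_queries`.
#' @export
evaluate_matches <- function(decisions, truth, library_annotations) {
  matched <- decisions[!is.na(decisions$matched_library_id), , drop = FALSE]
  if (nrow(matched) > 0L &&
      any(!matched$matched_library_id %in% names(library_annotations)))
    stop("matched library spectra lack molecule annotations")
  tp <- sum(library_annotations[matched$matched_library_id] ==
              truth[matched$query_id])
  fp <- nrow(matched) - tp
  n <- nrow(decisions)
  list(tp = tp, fp = fp,
       accuracy = if (tp + fp > 0L) tp / (tp + fp) else 0,
       retrieval = (tp + fp) / n, n_queries = n)
}

#' Sweep the matching threshold
#'
#' Repeats [library_match()] + [evaluate_matches()] over a grid of score
#' thresholds (default 0.95 down to 0 in steps of 0.05). Scores are
#' computed once and reused; lowering the threshold can only add
#' matches, so retrieval is monotone along the sweep.
#'
#' @inheritParams library_match
#' @inheritParams evaluate_matches
#' @param thresholds decreasing vector of thresholds.
#' @return data.frame with one row per threshold: `threshold`, `tp`,
#'   `fp`, `accuracy`, `retrieval`.
#' @export
threshold_sweep <- function(queries, library, score_fn, truth,
                            library_annotations,
                            thresholds = seq(0.95, 0, by = -0.05), ppm = 1) {
  base <- library_match(queries, library, score_fn, threshold = -Inf,
                        ppm = ppm)
  rows <- lapply(thresholds, function(th) {
    d <- base
    drop <- is.na(d$score) | d$score <= th
    d$matched_library_id[drop] <- NA_character_
    d$matched_index[drop] <- NA_integer_
    d$score[drop] <- NA_real_
    ev <- evaluate_matches(d, truth, library_annotations)
    data.frame(threshold = th, tp = ev$tp, fp = ev$fp,
               accuracy = ev$accuracy, retrieval = ev$retrieval)
  })
  do.call(rbind, rows)
}

#' Top-k analog search by embedding similarity
#'
#' Ranks the whole library against one query document by embedding
#' cosine — no precursor pre-filtering, so structurally related
#' molecules of different mass can surface. Ties are broken by id.
#'
#' @param query_doc a `spectrum_document`.
#' @param library_docs list of `spectrum_document`.
#' @param model an `ms_embedding`.
#' @param k number of hits to return (default 10; capped at the library
#'   size).
#' @return data.frame with `library_id`, `index`, `score`, best first.
#' @export
top_k_matches <- function(query_doc, library_docs, model, k = 10L) {
  sims <- embedding_similarity_matrix(list(query_doc), library_docs, model)
  ids <- vapply(library_docs, `[[`, character(1L), "source_id")
  ord <- order(-sims[1L, ], ids)
  top <- ord[seq_len(min(k, length(ids)))]
  data.frame(library_id = ids[top], index = top, score = sims[1L, top],
             stringsAsFactors = FALSE)
}

#' Build a molecular network from a similarity matrix
#'
#' Each spectrum contributes edges to its up-to-`max_links`
#' highest-scoring neighbours whose similarity strictly exceeds
#' `threshold`; the graph is the undirected union of these
#' contributions, so a node's final degree may exceed `max_links`
#' through incoming edges.
#'
#' @param spectral symmetric similarity matrix with row/col names as
#'   node ids.
#' @param threshold minimum (strict) similarity for an edge.
#' @param max_links per-node cap on contributed edges (default 10).
#' @return an [igraph][igraph::graph_from_data_frame] undirected graph
#'   with edge attribute `weight`; isolated nodes are retained.
#' @export
build_network <- function(spectral, threshold, max_links = 10L) {
  n <- nrow(spectral)
  ids <- rownames(spectral)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  edges <- list()
  for (i in seq_len(n)) {
    s <- spectral[i, ]
    s[i] <- -Inf
    qualify <- which(s > threshold)
    if (length(qualify) == 0L) next
    top <- qualify[order(-s[qualify], qualify)]
    top <- top[seq_len(min(max_links, length(top)))]
    edges[[length(edges) + 1L]] <-
      data.frame(from = pmin(i, top), to = pmax(i, top),
                 weight = spectral[cbind(i, top)])
  }
  ed <- if (length(edges) > 0L) unique(do.call(rbind, edges))
        else data.frame(from = integer(0), to = integer(0),
                        weight = numeric(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[ed$from], to = ids[ed$to], weight = ed$weight),
    directed = FALSE,
    vertices = data.frame(name = ids))
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Partition a network, splitting large components by Louvain
#'
#' Connected components up to `size_cutoff` nodes are kept whole; larger
#' components are replaced by their Louvain modularity communities
#' (weighted). Deterministic under a fixed seed.
#'
#' @param g igraph graph from [build_network()].
#' @param size_cutoff component size above which Louvain splitting is
#'   applied (default 30).
#' @param seed RNG seed for the Louvain heuristic (default 1).
#' @return named integer vector: node id -> cluster id.
#' @export
split_clusters_louvain <- function(g, size_cutoff = 30L, seed = 1L) {
  comp <- igraph::components(g)
  membership <- comp$membership
  next_id <- max(membership, 0L)
  for (ci in which(comp$csize > size_cutoff)) {
    nodes <- names(membership)[membership == ci]
    sub <- igraph::induced_subgraph(g, nodes)
    cl <- withr::with_seed(seed, igraph::cluster_louvain(sub))
    sub_m <- igraph::membership(cl)
    membership[names(sub_m)] <- next_id + as.integer(sub_m)
    next_id <- next_id + max(as.integer(sub_m))
  }
  # renumber to consecutive ids
  out <- as.integer(factor(membership))
  names(out) <- names(membership)
  out
}

#' Structural quality of a network partition
#'
#' For every cluster holding at least one internal edge, the mean
#' structural similarity over its internal edges is computed. Nodes in
#' clusters with mean at or above `cutoff` count as well-clustered,
#' below as poorly-clustered; nodes whose cluster has no internal edges
#' (including isolated nodes) count as unclustered. The three fractions
#' are exact counts over all nodes and sum to 1.
#'
#' @param partition named cluster membership from
#'   [split_clusters_louvain()].
#' @param g the network the partition was computed on.
#' @param structural symmetric structural similarity matrix whose
#'   row/col names cover all node ids.
#' @param cutoff well/poor boundary on the mean edge structural
#'   similarity (default 0.5; the mean must be `>= cutoff` to count as
#'   well-clustered).
#' @return list with `cluster_means` (data.frame: cluster, n_nodes,
#'   n_edges, mean_structural), `fractions` (well, poor, unclustered)
#'   and `counts`.
#' @export
cluster_quality <- function(partition, g, structural, cutoff = 0.5) {
  ends <- igraph::as_edgelist(g)
  n <- length(partition)
  well <- poor <- 0L
  cl_rows <- list()
  clustered_nodes <- character(0)
  for (cl in sort(unique(partition))) {
    nodes <- names(partition)[partition == cl]
    internal <- ends[partition[ends[, 1L]] == cl &
                       partition[ends[, 2L]] == cl, , drop = FALSE]
    if (nrow(internal) == 0L) next
    ms <- mean(structural[cbind(internal[, 1L], internal[, 2L])])
    cl_rows[[length(cl_rows) + 1L]] <-
      data.frame(cluster = cl, n_nodes = length(nodes),
                 n_edges = nrow(internal), mean_structural = ms)
    clustered_nodes <- c(clustered_nodes, nodes)
    if (ms >= cutoff) well <- well + length(nodes)
    else poor <- poor + length(nodes)
  }
  unclustered <- n - length(clustered_nodes)
  list(cluster_means = if (length(cl_rows) > 0L) do.call(rbind, cl_rows)
       else data.frame(cluster = integer(0), n_nodes = integer(0),
                       n_edges = integer(0), mean_structural = numeric(0)),
       counts = c(well = well, poor = poor, unclustered = unclustered),
       fractions = c(well = well / n, poor = poor / n,
                     unclustered = unclustered / n))
}

#' Write a network as GraphML and edge-list TSV
#'
#' @param g igraph graph.
#' @param path_prefix output prefix; writes `<prefix>.graphml` and
#'   `<prefix>_edges.tsv`.
#' @return the two paths, invisibly.
#' @export
write_network <- function(g, path_prefix) {
  gml <- paste0(path_prefix, ".graphml")
  tsv <- paste0(path_prefix, "_edges.tsv")
  igraph::write_graph(g, gml, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(ed, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = gml, edges = tsv))
}
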