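# Null calibration of the DS relatedness cutoff, graph construction, and
# connected-component counting.

#' Nearest-rank upper quantile
#'
#' The percentile rule used for the DS cutoff: the `q`-quantile of `x` is the
#' `ceiling(q * N)`-th smallest value. Parameter free and conservative;
#' `-Inf` sentinels participate as the lowest values.
#'
#' @param x numeric vector.
#' @param q quantile in (0, 1].
#' @return the nearest-rank quantile value.
#' @examples
#' nearestRankQuantile(0:99, 0.95)  # 94
#' @export
nearestRankQuantile <- function(x, q) {
  n <- length(x)
  if (n == 0L) stop("cannot take a quantile of an empty vector")
  sort(x)[max(1L, ceiling(q * n))]
}

# All unordered cross-lab pairs of plasmid indices.
.crossLabPairs <- function(corpus) {
  lab <- unname(labs(corpus))
  idx <- utils::combn(corpusSize(corpus), 2L)
  keep <- lab[idx[1, ]] != lab[idx[2, ]]
  idx[, keep, drop = FALSE]
}

#' Calibrate the DS relatedness cutoff from a cross-lab null
#'
#' Samples random plasmid pairs that do not share a depositing lab, scores
#' each pair with DS, and sets the relatedness cutoff at the nearest-rank
#' upper `(1 - fpRate)` quantile of the null distribution, i.e. the score
#' exceeded by about `fpRate` of unrelated pairs. Pairs are drawn uniformly
#' without replacement; when fewer than `nPairs` cross-lab pairs exist, all
#' of them are used. Pairs with no qualifying shared segment score `-Inf`
#' and are included as the lowest scores.
#'
#' @param corpus a [PlasmidCorpus-class] with at least two labs.
#' @param params an [AlignmentParams-class].
#' @param nPairs number of null pairs to sample (default 100000).
#' @param fpRate target false-positive rate (default 0.05).
#' @param seed integer seed for the pair sample.
#' @param cache optional [newSegmentCache()] cache (strongly recommended for
#'   repeated use on one corpus).
#' @param heuristic see [dsScore()].
#' @return a [NullCalibration-class].
#' @export
calibrateCutoff <- function(corpus, params = alignmentParams(),
                            nPairs = 100000L, fpRate = 0.05, seed = 1L,
                            cache = NULL, heuristic = "idf") {
  if (length(unique(unname(labs(corpus)))) < 2L) {
    stop("null calibration requires plasmids from at least 2 labs")
  }
  if (is.null(cache)) cache <- newSegmentCache(corpus, params)
  pool <- .crossLabPairs(corpus)
  npool <- ncol(pool)
  take <- min(npool, as.integer(nPairs))
  sel <- if (take < npool) {
    withSeed(seed, sample.int(npool, take, replace = FALSE))
  } else {
    seq_len(npool)
  }
  ids <- plasmidIDs(corpus)
  a <- ids[pool[1, sel]]
  b <- ids[pool[2, sel]]
  scores <- numeric(take)
  for (i in seq_len(take)) {
    scores[i] <- .dsPair(a[i], b[i], corpus, params, cache, heuristic)
  }
  cutoff <- nearestRankQuantile(scores, 1 - fpRate)
  new("NullCalibration", cutoff = cutoff, nullScores = scores,
      pairs = data.frame(a = a, b = b, stringsAsFactors = FALSE),
      nPairs = take, fpRate = as.numeric(fpRate), seed = as.integer(seed))
}

#' Binarize a DS matrix into a relatedness graph
#'
#' Two plasmids are connected exactly when their DS score meets or exceeds
#' the cutoff (inclusive boundary). The `-Inf` no-evidence sentinel never
#' creates an edge, whatever the cutoff.
#'
#' @param dsMatrix symmetric DS matrix from [pairwiseDS()].
#' @param cutoff calibrated DS threshold (or a [NullCalibration-class]).
#' @return an undirected [igraph::graph] whose vertices are the plasmids.
#' @export
buildAuthorshipGraph <- function(dsMatrix, cutoff) {
  if (is(cutoff, "NullCalibration")) cutoff <- dsCutoff(cutoff)
  adj <- is.finite(dsMatrix) & !is.na(dsMatrix) & dsMatrix >= cutoff
  diag(adj) <- FALSE
  mode(adj) <- "numeric"
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Authorship clusters of a relatedness graph
#'
#' Connected components of the thresholded DS graph. Each component is
#' interpreted as one set of plasmids in which the shared variant has a
#' single origin, so the component count estimates how many times the
#' variant arose independently.
#'
#' @param graph an undirected [igraph::graph] from [buildAuthorshipGraph()].
#' @return list with `membership` (named integer vector: plasmid ->
#'   component index) and `n_components`.
#' @export
countComponents <- function(graph) {
  comp <- igraph::components(graph)
  membership <- comp$membership
  storage.mode(membership) <- "integer"
  list(membership = membership, n_components = as.integer(comp$no))
}
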