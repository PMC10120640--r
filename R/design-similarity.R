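# The Design Similarity score: an inverse-document-frequency-inspired
# measure of shared authorship between two plasmids.

#' Design Similarity score of a plasmid pair
#'
#' Given the ascending corpus frequencies `x` of the segments shared by a
#' plasmid pair and the corpus size `p`, the DS score is
#'
#'     DS = ln(p / x[1]) + (1/n) * sum_{i=2}^{n} ln(p / x[i])
#'
#' the log inverse corpus frequency of the rarest shared segment, plus an
#' extra-score heuristic averaging the remaining segments' terms (applied
#' only when more than one segment is shared). A segment carried by every
#' plasmid contributes nothing (`ln 1 = 0`); a rare segment -- even a short
#' cloning scar -- dominates the score. With no shared segment the pair has
#' no authorship evidence and the score is the `-Inf` sentinel, which
#' compares below every finite score. Natural logarithms are used; the
#' calibrated cutoff is quantile-based, so the base is a pure rescaling.
#'
#' @param x integer vector of per-segment corpus frequencies sorted
#'   ascending; every element must lie in `[2, p]`.
#' @param p corpus size (number of plasmids), at least 2.
#' @param heuristic `"idf"` applies the logarithm to every segment term
#'   (default); `"ratio"` averages the raw ratios `p / x[i]` in the extra
#'   term instead, for sensitivity analysis.
#' @return numeric DS score (`-Inf` when `x` is empty).
#' @examples
#' dsScore(c(2), 200)             # ln(100)
#' dsScore(c(2, 10, 100), 1000)   # ln(500) + (ln(100) + ln(10)) / 3
#' dsScore(integer(0), 200)       # no evidence: -Inf
#' @export
dsScore <- function(x, p, heuristic = c("idf", "ratio")) {
  heuristic <- match.arg(heuristic)
  if (length(p) != 1L || p < 2) stop("p must be a single value >= 2")
  n <- length(x)
  if (n == 0L) return(-Inf)
  if (any(x != round(x))) stop("x must contain integer frequencies")
  if (is.unsorted(x)) stop("x must be sorted ascending")
  if (any(x < 2)) stop("every frequency must be >= 2")
  if (any(x > p)) stop("frequencies cannot exceed the corpus size p")
  head_term <- log(p / x[1])
  if (n == 1L) return(head_term)
  rest <- x[-1]
  extra <- if (heuristic == "idf") sum(log(p / rest)) / n else sum(p / rest) / n
  head_term + extra
}

# DS of one pair of plasmid ids, memoised in the shared cache. Matrix-level
# reimplementation of the findSharedSegments filters without data.frame
# plumbing: this is the hot path of null calibration.
.dsPair <- function(a, b, corpus, params, cache, heuristic = "idf") {
  key <- if (a < b) paste0(a, "\r", b) else paste0(b, "\r", a)
  hit <- cache$pairds[[key]]
  if (!is.null(hit)) return(hit)
  aSeq <- cache$seqs[[a]]
  bSeq <- cache$seqs[[b]]
  m <- cpp_local_matches(aSeq, bSeq, params@matchReward,
                         params@mismatchPenalty, params@gapOpen,
                         params@gapExtend, .minEngineScore(params),
                         params@seedLength, params@bandMargin, TRUE,
                         params@xDrop)
  aspan <- m[, 2L] - m[, 1L]
  bspan <- m[, 4L] - m[, 3L]
  cols <- m[, 7L] + m[, 8L] + m[, 9L]
  ev <- alignmentEvalue(m[, 6L], nchar(aSeq), nchar(bSeq), params)
  keep <- aspan >= params@wordSize &
    abs(aspan - bspan) <= params@maxLengthDiff &
    m[, 7L] >= params@minIdentity * cols &
    ev <= params@maxEvalue
  m <- m[keep, , drop = FALSE]
  # containment suppression (both intervals nested in a longer segment)
  nseg <- nrow(m)
  if (nseg > 1L) {
    len <- m[, 2L] - m[, 1L]
    drop <- logical(nseg)
    for (i in seq_len(nseg)) {
      for (j in seq_len(nseg)) {
        if (i == j || drop[j]) next
        if (len[j] > len[i] &&
            m[i, 1L] >= m[j, 1L] && m[i, 2L] <= m[j, 2L] &&
            m[i, 3L] >= m[j, 3L] && m[i, 4L] <= m[j, 4L]) {
          drop[i] <- TRUE
          break
        }
      }
    }
    m <- m[!drop, , drop = FALSE]
    nseg <- nrow(m)
  }
  freqs <- integer(nseg)
  if (nseg) {
    seqs <- substring(aSeq, m[, 1L] + 1L, m[, 2L])
    for (i in seq_len(nseg)) {
      freqs[i] <- segmentFrequency(seqs[i], params = params, cache = cache)
    }
  }
  val <- dsScore(sort(freqs), cache$p, heuristic)
  cache$pairds[[key]] <- val
  val
}

#' Pairwise DS matrix over the plasmids of a variant group
#'
#' Computes the symmetric DS score matrix over all distinct plasmids carrying
#' the same part variant. Groups larger than the observation cap are refused
#' (callers fall back to the widespread-only rule); the diagonal is `NA`.
#'
#' @param group one row of the [groupVariants()] table (or any list with
#'   `plasmids` and `n_observations` fields).
#' @param corpus a [PlasmidCorpus-class].
#' @param params an [AlignmentParams-class].
#' @param cache optional [newSegmentCache()] cache shared across groups.
#' @param observationCap refuse groups with more observations than this.
#' @param heuristic see [dsScore()].
#' @return numeric matrix with plasmid ids as dimnames; `-Inf` marks pairs
#'   with no shared-segment evidence.
#' @export
pairwiseDS <- function(group, corpus, params = alignmentParams(),
                       cache = NULL, observationCap = 1205L,
                       heuristic = "idf") {
  plasmids <- group$plasmids
  if (is.list(plasmids)) plasmids <- plasmids[[1]]
  nobs <- group$n_observations
  if (length(nobs) && nobs > observationCap) {
    stop("group has ", nobs, " observations, above the DS observation cap ",
         "of ", observationCap)
  }
  if (length(plasmids) < 2L) {
    stop("pairwise DS needs at least 2 distinct plasmids")
  }
  if (is.null(cache)) cache <- newSegmentCache(corpus, params)
  k <- length(plasmids)
  mat <- matrix(NA_real_, k, k, dimnames = list(plasmids, plasmids))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      val <- .dsPair(plasmids[i], plasmids[j], corpus, params, cache,
                     heuristic)
      mat[i, j] <- val
      mat[j, i] <- val
    }
  }
  mat
}
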