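# R-side wrapper of the local alignment engine and Karlin-Altschul
# significance parameters.

.kaCache <- new.env(parent = emptyenv())

#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' Computes the scale parameter lambda and the search-space constant K of the
#' extreme-value model for local alignment scores,
#' `E = K * m * n * exp(-lambda * S)`, for a match/mismatch scoring scheme
#' against uniform base composition. `lambda` is the unique positive root of
#' the moment condition `sum_ij p_i p_j exp(lambda * s_ij) = 1`; `K` is
#' computed from the lattice-case series of the score random walk (binomial
#' convolution of the two-valued step distribution). The statistics are for
#' ungapped alignments; with the default scoring scheme gaps are so costly
#' that reported segments are nearly ungapped, and the E-value filter sits
#' orders of magnitude away from any segment of reportable length, so the
#' approximation is not load bearing.
#'
#' @param match,mismatch integer match reward and (negative) mismatch score.
#' @return list with elements `lambda` and `K`.
#' @examples
#' karlinAltschulParams(2L, -8L)
#' @export
karlinAltschulParams <- function(match = 2L, mismatch = -8L) {
  key <- paste(match, mismatch)
  if (!is.null(.kaCache[[key]])) return(.kaCache[[key]])
  pmatch_ <- 0.25
  pmis <- 0.75
  f <- function(l) pmatch_ * exp(l * match) + pmis * exp(l * mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-8, 10), tol = 1e-14)$root

  # Spitzer-type series over the score walk S_k (steps: +match w.p. 1/4,
  # mismatch w.p. 3/4); terms computed exactly from binomial probabilities.
  sigma <- 0
  for (k in 1:80) {
    j <- 0:k                                   # number of matching steps
    s <- j * match + (k - j) * mismatch        # walk position
    pr <- stats::dbinom(j, k, pmatch_)
    term <- sum(pr[s >= 0]) + sum(pr[s < 0] * exp(lambda * s[s < 0]))
    sigma <- sigma + term / k
    if (term / k < 1e-12) break
  }
  delta <- .gcd(abs(match), abs(mismatch))     # score lattice span
  mustar <- pmatch_ * match * exp(lambda * match) +
    pmis * mismatch * exp(lambda * mismatch)   # E[S1 exp(lambda S1)]
  K <- delta * lambda * exp(-2 * sigma) /
    ((1 - exp(-lambda * delta)) * lambda * mustar)
  res <- list(lambda = lambda, K = K)
  .kaCache[[key]] <- res
  res
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' E-value of a local alignment score
#'
#' @param score raw alignment score.
#' @param m,n lengths of the two sequences compared.
#' @param params an [AlignmentParams-class] object.
#' @return numeric E-value.
#' @export
alignmentEvalue <- function(score, m, n, params = alignmentParams()) {
  ka <- karlinAltschulParams(params@matchReward, params@mismatchPenalty)
  ka$K * as.double(m) * as.double(n) * exp(-ka$lambda * score)
}

# Raw-score floor handed to the engine: a segment shorter than wordSize can
# never be reported, and the lowest-scoring qualifying segment is an exact
# match of wordSize bases.
.minEngineScore <- function(params) params@wordSize * params@matchReward

#' All maximal local alignments between two sequences
#'
#' Low-level interface to the alignment engine: returns every maximal local
#' alignment with raw score at least `minScore` on either strand, without
#' applying the segment filters. Coordinates are 0-based half-open;
#' `b_start`/`b_end` are always on the forward strand of `b`.
#'
#' @param a,b DNA sequences (character).
#' @param params an [AlignmentParams-class] object.
#' @param bothStrands search the reverse complement of `b` as well.
#' @param minScore raw score floor; defaults to `wordSize * matchReward`.
#' @param xdrop score-dip splitting threshold; `0` (the default) reports raw
#'   maximal alignments, a positive value decomposes each alignment at
#'   internal score dips deeper than `xdrop` (see
#'   [AlignmentParams-class]).
#' @return data.frame with columns `a_start`, `a_end`, `b_start`, `b_end`,
#'   `strand` (`"+"`/`"-"`), `score`, `matches`, `mismatches`, `gapcols`.
#' @examples
#' hits <- localMatches(strrep("ACGT", 20), strrep("ACGT", 20))
#' hits[1, c("a_start", "a_end", "score")]
#' @export
localMatches <- function(a, b, params = alignmentParams(),
                         bothStrands = TRUE, minScore = NULL, xdrop = 0L) {
  if (is.null(minScore)) minScore <- .minEngineScore(params)
  m <- cpp_local_matches(as.character(a), as.character(b),
                         params@matchReward, params@mismatchPenalty,
                         params@gapOpen, params@gapExtend,
                         as.integer(minScore), params@seedLength,
                         params@bandMargin, isTRUE(bothStrands),
                         as.integer(xdrop))
  data.frame(a_start = m[, "a_start"], a_end = m[, "a_end"],
             b_start = m[, "b_start"], b_end = m[, "b_end"],
             strand = c("-", "+")[(m[, "strand"] > 0) + 1L],
             score = m[, "score"], matches = m[, "matches"],
             mismatches = m[, "mismatches"], gapcols = m[, "gapcols"],
             stringsAsFactors = FALSE)
}
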