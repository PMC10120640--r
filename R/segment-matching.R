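# Shared-segment search between plasmid pairs and corpus-wide segment
# frequency queries: the inputs of the Design Similarity score.

#' Create a segment-frequency cache for a corpus
#'
#' Frequency queries are the expensive step of DS scoring, and the same
#' segment sequence recurs across many plasmid pairs, so frequencies are
#' cached per segment sequence within a run. The cache also holds an exact
#' k-mer prefilter index over the corpus: a plasmid that shares no seed k-mer
#' with a segment cannot contain a qualifying match and is skipped without
#' alignment. `cache$queries` counts actual (uncached) frequency
#' computations, which makes the caching contract observable.
#'
#' @param corpus a [PlasmidCorpus-class].
#' @param params an [AlignmentParams-class].
#' @return an environment with the index, the frequency and pair-score
#'   caches, and a query counter.
#' @export
newSegmentCache <- function(corpus, params = alignmentParams()) {
  cache <- new.env(parent = emptyenv())
  cache$params <- params
  cache$seqs <- as.character(sequencesOf(corpus))
  cache$freq <- new.env(parent = emptyenv())
  cache$pairds <- new.env(parent = emptyenv())
  cache$queries <- 0L
  cache$p <- length(cache$seqs)
  k <- params@seedLength
  codes <- lapply(cache$seqs, cpp_kmer_codes, k = k, both_strands = FALSE)
  plasmid_of <- rep(seq_along(codes), lengths(codes))
  cache$index <- list2env(split(plasmid_of, unlist(codes, use.names = FALSE)),
                          envir = new.env(parent = emptyenv()))
  cache
}

.candidatePlasmids <- function(cache, sequence) {
  k <- cache$params@seedLength
  codes <- cpp_kmer_codes(sequence, k, both_strands = TRUE)
  if (!length(codes)) return(integer(0))
  hits <- mget(as.character(codes), envir = cache$index,
               ifnotfound = list(NULL))
  sort(unique(unlist(hits, use.names = FALSE)))
}

# Segment filters applied to raw engine alignments; `m`, `n` are the compared
# sequence lengths for the E-value.
.segmentFilter <- function(hits, m, n, params) {
  if (nrow(hits) == 0L) return(hits)
  aspan <- hits$a_end - hits$a_start
  bspan <- hits$b_end - hits$b_start
  cols <- hits$matches + hits$mismatches + hits$gapcols
  ev <- alignmentEvalue(hits$score, m, n, params)
  keep <- aspan >= params@wordSize &
    abs(aspan - bspan) <= params@maxLengthDiff &
    hits$matches >= params@minIdentity * cols &
    ev <= params@maxEvalue
  hits <- hits[keep, , drop = FALSE]
  hits$identity <- hits$matches /
    (hits$matches + hits$mismatches + hits$gapcols)
  hits$length_bp <- hits$a_end - hits$a_start
  hits$evalue <- ev[keep]
  hits
}

# Drop segments wholly contained (both intervals) in a longer segment of the
# same pair, to avoid double-counting context in DS.
.suppressContained <- function(seg) {
  if (nrow(seg) <= 1L) return(seg)
  n <- nrow(seg)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      if (seg$length_bp[j] > seg$length_bp[i] &&
          seg$a_start[i] >= seg$a_start[j] && seg$a_end[i] <= seg$a_end[j] &&
          seg$b_start[i] >= seg$b_start[j] && seg$b_end[i] <= seg$b_end[j]) {
        drop[i] <- TRUE
        break
      }
    }
  }
  seg[!drop, , drop = FALSE]
}

#' Find contiguous shared segments between two plasmids
#'
#' Runs the gapped local alignment engine between two plasmid sequences (both
#' strands) and keeps every maximal match passing the three segment filters:
#' nucleotide identity at least `minIdentity`, E-value at most `maxEvalue`,
#' and aligned-span length difference at most `maxLengthDiff`. Segments
#' wholly contained within a longer reported segment of the same pair are
#' suppressed. The segment sequence is taken from the first plasmid.
#'
#' @param a,b DNA sequences (character), or names into `corpus`.
#' @param params an [AlignmentParams-class].
#' @param corpus optional [PlasmidCorpus-class] when `a`, `b` are plasmid
#'   ids.
#' @return data.frame of segments ordered by `a_start` then `b_start`:
#'   columns `sequence`, `a_start`, `a_end`, `b_start`, `b_end`, `strand_b`,
#'   `identity`, `length_bp`, `evalue`, `score`. Coordinates are 0-based
#'   half-open.
#' @examples
#' blk <- strrep("ACGATTTGCAGGCATCGAAGTCCAGGTCCAA", 2)
#' a <- paste0(strrep("A", 30), blk, strrep("C", 30))
#' b <- paste0(strrep("G", 25), blk, strrep("T", 25))
#' findSharedSegments(a, b)[, c("a_start", "a_end", "identity")]
#' @export
findSharedSegments <- function(a, b, params = alignmentParams(),
                               corpus = NULL) {
  if (!is.null(corpus)) {
    if (identical(a, b)) stop("a and b must be distinct plasmids")
    seqs <- as.character(sequencesOf(corpus))
    a <- seqs[[a]]
    b <- seqs[[b]]
  }
  a <- as.character(a)
  b <- as.character(b)
  hits <- localMatches(a, b, params, xdrop = params@xDrop)
  seg <- .segmentFilter(hits, nchar(a), nchar(b), params)
  seg <- .suppressContained(seg)
  seg <- seg[order(seg$a_start, seg$b_start), , drop = FALSE]
  rownames(seg) <- NULL
  if (nrow(seg) == 0L) {
    return(data.frame(sequence = character(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), strand_b = character(0),
                      identity = numeric(0), length_bp = integer(0),
                      evalue = numeric(0), score = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(sequence = substring(a, seg$a_start + 1L, seg$a_end),
             a_start = seg$a_start, a_end = seg$a_end,
             b_start = seg$b_start, b_end = seg$b_end,
             strand_b = seg$strand, identity = seg$identity,
             length_bp = seg$length_bp, evalue = seg$evalue,
             score = seg$score, stringsAsFactors = FALSE)
}

#' Corpus frequency of a shared segment
#'
#' Counts the number of distinct plasmids in the corpus containing at least
#' one match to the segment sequence passing the same three segment filters
#' as the pairwise search. A plasmid containing the segment twice counts
#' once; reverse-complement matches count. Frequencies are cached per
#' segment sequence in `cache`.
#'
#' @param sequence segment sequence (character).
#' @param corpus a [PlasmidCorpus-class] (may be omitted when `cache` was
#'   built from the corpus).
#' @param params an [AlignmentParams-class].
#' @param cache a cache from [newSegmentCache()]; created on the fly when
#'   `NULL` (no reuse across calls).
#' @return integer count of plasmids containing the segment.
#' @export
segmentFrequency <- function(sequence, corpus = NULL,
                             params = alignmentParams(), cache = NULL) {
  if (is.null(cache)) {
    if (is.null(corpus)) stop("either corpus or cache is required")
    cache <- newSegmentCache(corpus, params)
  }
  key <- sequence
  hit <- cache$freq[[key]]
  if (!is.null(hit)) return(hit)
  params <- cache$params
  cand <- .candidatePlasmids(cache, sequence)
  count <- 0L
  if (length(cand)) {
    ka <- karlinAltschulParams(params@matchReward, params@mismatchPenalty)
    found <- cpp_match_exists(sequence, cache$seqs[cand],
                              params@matchReward, params@mismatchPenalty,
                              params@gapOpen, params@gapExtend,
                              .minEngineScore(params), params@seedLength,
                              params@bandMargin, params@xDrop,
                              params@wordSize,
                              params@minIdentity, params@maxLengthDiff,
                              ka$lambda, ka$K, params@maxEvalue)
    count <- sum(found)
  }
  cache$queries <- cache$queries + 1L
  cache$freq[[key]] <- count
  count
}

#' Build the DS inputs for a plasmid pair
#'
#' Combines [findSharedSegments()] and [segmentFrequency()]: finds the
#' qualifying shared segments of a pair and queries each against the whole
#' corpus, producing the ascending frequency vector `x` the DS score
#' consumes.
#'
#' @param a,b plasmid ids in `corpus`.
#' @param corpus a [PlasmidCorpus-class].
#' @param params an [AlignmentParams-class].
#' @param cache optional cache from [newSegmentCache()] shared across pairs.
#' @return a [SharedSegmentSet-class].
#' @export
buildSegmentSet <- function(a, b, corpus, params = alignmentParams(),
                            cache = NULL) {
  if (is.null(cache)) cache <- newSegmentCache(corpus, params)
  seg <- findSharedSegments(a, b, params, corpus = corpus)
  freqs <- integer(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    freqs[i] <- segmentFrequency(seg$sequence[i], params = params,
                                 cache = cache)
  }
  seg$frequency <- freqs
  new("SharedSegmentSet", plasmidA = a, plasmidB = b, segments = seg,
      x = sort(freqs))
}
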