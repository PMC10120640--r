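# S4 classes for the central data objects.

#' PlasmidCorpus: a set of plasmid sequences with depositor metadata
#'
#' Holds one DNA sequence per plasmid together with the identifier of the
#' depositing lab and the plasmid topology. The depositing lab is the unit of
#' authorship for the relatedness null; topology decides whether annotation
#' searches the sequence doubled back on itself to recover origin-spanning
#' parts.
#'
#' @slot sequences [Biostrings::DNAStringSet] named by plasmid id.
#' @slot lab character vector of depositing-lab identifiers, parallel to
#'   `sequences`.
#' @slot topology character vector, `"circular"` or `"linear"`.
#' @export
setClass("PlasmidCorpus",
  representation(sequences = "DNAStringSet", lab = "character",
                 topology = "character"))

setValidity("PlasmidCorpus", function(object) {
  ids <- names(object@sequences)
  msgs <- character()
  if (length(object@sequences) < 1L) msgs <- c(msgs, "corpus must contain at least one plasmid")
  if (is.null(ids) || any(!nzchar(ids))) msgs <- c(msgs, "every plasmid needs a non-empty id")
  if (anyDuplicated(ids)) {
    msgs <- c(msgs, paste0("duplicate plasmid ids: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(object@lab) != length(object@sequences) ||
      length(object@topology) != length(object@sequences)) {
    msgs <- c(msgs, "lab and topology must be parallel to sequences")
  }
  if (any(!nzchar(object@lab))) msgs <- c(msgs, "lab identifiers must be non-empty")
  if (!all(object@topology %in% c("circular", "linear"))) {
    msgs <- c(msgs, "topology must be 'circular' or 'linear'")
  }
  if (any(Biostrings::width(object@sequences) == 0L)) {
    msgs <- c(msgs, "plasmid sequences must be non-empty")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PlasmidCorpus
#'
#' @param sequences a named character vector or [Biostrings::DNAStringSet];
#'   names are the plasmid ids. Sequences are uppercased; only A/C/G/T/N are
#'   accepted.
#' @param lab character vector of depositing-lab ids (recycled names allowed),
#'   parallel to `sequences`.
#' @param topology `"circular"` or `"linear"`, recycled to the corpus size.
#' @return a `PlasmidCorpus`.
#' @examples
#' corp <- PlasmidCorpus(c(p1 = "ACGTACGTACGT", p2 = "TTTTACGTACGA"),
#'                       lab = c("labA", "labB"), topology = "linear")
#' corpusSize(corp)
#' @export
PlasmidCorpus <- function(sequences, lab, topology = "circular") {
  if (is(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
    sequences <- seqs
  }
  sequences <- vapply(sequences, .checkDNA, character(1), what = "plasmid sequence")
  dss <- Biostrings::DNAStringSet(sequences)
  lab <- rep_len(as.character(lab), length(dss))
  topology <- rep_len(as.character(topology), length(dss))
  new("PlasmidCorpus", sequences = dss, lab = lab, topology = topology)
}

#' PartLibrary: canonical genetic part reference sequences
#'
#' The database of canonical part sequences against which plasmids are
#' annotated. CDS entries are flagged as coding and must have length divisible
#' by three so translation-level identity filtering is well defined.
#'
#' @slot sequences [Biostrings::DNAStringSet] named by part id.
#' @slot partType character vector of part categories (see
#'   [partTypes()]).
#' @export
setClass("PartLibrary",
  representation(sequences = "DNAStringSet", partType = "character"))

setValidity("PartLibrary", function(object) {
  ids <- names(object@sequences)
  msgs <- character()
  if (length(object@sequences) > 0L && (is.null(ids) || any(!nzchar(ids)))) {
    msgs <- c(msgs, "every part needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    msgs <- c(msgs, paste0("duplicate part ids: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(object@partType) != length(object@sequences)) {
    msgs <- c(msgs, "partType must be parallel to sequences")
  }
  bad <- !(object@partType %in% .partTypes)
  if (any(bad)) {
    msgs <- c(msgs, paste0("unknown part type: ",
                           paste(unique(object@partType[bad]), collapse = ", ")))
  }
  cds <- object@partType == "CDS"
  if (any(cds & Biostrings::width(object@sequences) %% 3L != 0L)) {
    msgs <- c(msgs, "CDS part lengths must be divisible by 3")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PartLibrary
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   canonical part sequences (names are part ids).
#' @param partType character vector of part categories, one per part.
#' @return a `PartLibrary`.
#' @export
PartLibrary <- function(sequences, partType) {
  if (is(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
    sequences <- seqs
  }
  sequences <- vapply(sequences, .checkDNA, character(1), what = "part sequence")
  new("PartLibrary", sequences = Biostrings::DNAStringSet(sequences),
      partType = as.character(partType))
}

#' Recognised genetic part categories
#' @return character vector of the part-type vocabulary.
#' @export
partTypes <- function() .partTypes

#' AlignmentParams: scoring scheme and segment filters
#'
#' Parameters of the shared-segment search. The scoring scheme (match +2,
#' mismatch -8, gap open 4, gap extend 6, word size 28) favours long
#' contiguous matches with few point mutations; a reported segment must reach
#' at least 98% nucleotide identity, an E-value of at most 1e-5, and an
#' aligned-span length difference of at most 10 bp.
#'
#' @slot matchReward,mismatchPenalty,gapOpen,gapExtend integer alignment
#'   scores (a gap of length L costs `gapOpen + L * gapExtend`).
#' @slot wordSize integer; the minimum reportable segment length and the
#'   conceptual seed size of the original search procedure.
#' @slot minIdentity,maxEvalue,maxLengthDiff numeric segment filters.
#' @slot xDrop integer; score drop terminating segment extension. A reported
#'   maximal alignment is decomposed at internal score dips deeper than
#'   `xDrop`, so that shared segments separated by non-matching stretches
#'   (e.g. different cloning scars between identical parts) are reported
#'   individually instead of being fused into one low-identity alignment,
#'   matching the extension-termination behaviour of seeded aligners. The
#'   default (70) keeps gaps up to the 10-bp length-difference allowance
#'   (cost 64) inside one segment, so that filter decides their fate, while
#'   severing anything deeper.
#' @slot seedLength,bandMargin integer internals of the banded engine: exact
#'   seed length used to locate candidate diagonals, and the half-width added
#'   around seeded diagonals. With the default filters any qualifying segment
#'   contains an exact run of at least 24 bp, so a 14-bp seed is lossless.
#' @export
setClass("AlignmentParams",
  representation(matchReward = "integer", mismatchPenalty = "integer",
                 gapOpen = "integer", gapExtend = "integer",
                 wordSize = "integer", minIdentity = "numeric",
                 maxEvalue = "numeric", maxLengthDiff = "integer",
                 seedLength = "integer", bandMargin = "integer",
                 xDrop = "integer"))

setValidity("AlignmentParams", function(object) {
  msgs <- character()
  if (object@minIdentity <= 0 || object@minIdentity > 1) msgs <- c(msgs, "minIdentity must be in (0, 1]")
  if (object@wordSize < 1L) msgs <- c(msgs, "wordSize must be >= 1")
  if (object@maxLengthDiff < 0L) msgs <- c(msgs, "maxLengthDiff must be >= 0")
  if (object@matchReward <= 0L) msgs <- c(msgs, "matchReward must be positive")
  if (object@mismatchPenalty >= 0L) msgs <- c(msgs, "mismatchPenalty must be negative")
  if (object@gapOpen < 0L || object@gapExtend <= 0L) msgs <- c(msgs, "gap penalties must be non-negative (extend positive)")
  if (object@seedLength < 1L || object@seedLength > 15L) msgs <- c(msgs, "seedLength must be in 1..15")
  if (object@xDrop <= 0L) msgs <- c(msgs, "xDrop must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct alignment parameters
#'
#' @param matchReward,mismatchPenalty,gapOpen,gapExtend scoring scheme.
#' @param wordSize minimum reportable segment length (bp).
#' @param minIdentity minimum nucleotide identity fraction of a segment.
#' @param maxEvalue maximum Karlin-Altschul E-value of a segment.
#' @param maxLengthDiff maximum |query span - subject span| of a segment (bp).
#' @param seedLength,bandMargin banded-engine internals; see
#'   [AlignmentParams-class].
#' @param xDrop segment-splitting score drop; see [AlignmentParams-class].
#' @return an `AlignmentParams` object.
#' @examples
#' alignmentParams()
#' @export
alignmentParams <- function(matchReward = 2L, mismatchPenalty = -8L,
                            gapOpen = 4L, gapExtend = 6L, wordSize = 28L,
                            minIdentity = 0.98, maxEvalue = 1e-5,
                            maxLengthDiff = 10L, seedLength = 14L,
                            bandMargin = 16L, xDrop = 70L) {
  new("AlignmentParams",
      matchReward = as.integer(matchReward),
      mismatchPenalty = as.integer(mismatchPenalty),
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
      wordSize = as.integer(wordSize), minIdentity = as.numeric(minIdentity),
      maxEvalue = as.numeric(maxEvalue),
      maxLengthDiff = as.integer(maxLengthDiff),
      seedLength = as.integer(seedLength),
      bandMargin = as.integer(bandMargin), xDrop = as.integer(xDrop))
}

#' SharedSegmentSet: qualifying shared segments of one plasmid pair
#'
#' The inputs of the Design Similarity score for one pair of plasmids: every
#' shared segment passing the alignment filters, and the vector `x` of
#' corpus frequencies of those segments sorted ascending (so `x[1]` is the
#' rarest shared context).
#'
#' @slot plasmidA,plasmidB plasmid ids.
#' @slot segments data.frame of segments (coordinates 0-based half-open,
#'   identity, E-value, score, sequence as found on `plasmidA`).
#' @slot x integer vector of per-segment corpus frequencies, ascending.
#' @export
setClass("SharedSegmentSet",
  representation(plasmidA = "character", plasmidB = "character",
                 segments = "data.frame", x = "integer"))

setValidity("SharedSegmentSet", function(object) {
  msgs <- character()
  if (length(object@x) != nrow(object@segments)) msgs <- c(msgs, "x must have one frequency per segment")
  if (is.unsorted(object@x)) msgs <- c(msgs, "x must be sorted ascending")
  if (length(object@x) && any(object@x < 2L)) msgs <- c(msgs, "every frequency must be >= 2 (both source plasmids count)")
  if (length(msgs)) msgs else TRUE
})

#' NullCalibration: cross-lab null distribution and DS cutoff
#'
#' Result of calibrating the plasmid-relatedness threshold: DS scores of a
#' seeded sample of random plasmid pairs from different depositing labs, and
#' the nearest-rank upper quantile of that distribution at the requested
#' false-positive rate. Pairs with no qualifying shared segment enter the
#' distribution as `-Inf` (definitionally unrelated).
#'
#' @slot cutoff numeric DS threshold.
#' @slot nullScores numeric vector of sampled null DS scores.
#' @slot pairs data.frame of the sampled pair ids (`a`, `b`) for audit.
#' @slot nPairs,fpRate,seed calibration settings actually used.
#' @export
setClass("NullCalibration",
  representation(cutoff = "numeric", nullScores = "numeric",
                 pairs = "data.frame", nPairs = "integer",
                 fpRate = "numeric", seed = "integer"))

#' PipelineConfig: settings of the prioritization pipeline
#'
#' @slot minCoverage minimum fraction of a canonical part that a match must
#'   cover to be annotated (default 0.95).
#' @slot minLabsWidespread minimum number of distinct depositing labs for the
#'   widespread call (default 20, inclusive).
#' @slot observationCap maximum group size for which pairwise DS analysis is
#'   run (default 1205); larger groups can only qualify as widespread.
#' @slot alignment an [AlignmentParams-class] object.
#' @slot nullPairs,fpRate null-calibration settings (defaults 100000 pairs,
#'   5% false-positive rate).
#' @slot seed integer root seed for all randomness in a run.
#' @slot dsHeuristic `"idf"` (log applied to every segment term) or `"ratio"`
#'   (unlogged frequency ratios in the extra-segment term).
#' @export
setClass("PipelineConfig",
  representation(minCoverage = "numeric", minLabsWidespread = "integer",
                 observationCap = "integer", alignment = "AlignmentParams",
                 nullPairs = "integer", fpRate = "numeric", seed = "integer",
                 dsHeuristic = "character"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (object@minLabsWidespread < 1L) msgs <- c(msgs, "minLabsWidespread must be >= 1")
  if (object@observationCap < 2L) msgs <- c(msgs, "observationCap must be >= 2")
  if (object@minCoverage <= 0 || object@minCoverage > 1) msgs <- c(msgs, "minCoverage must be in (0, 1]")
  if (object@fpRate <= 0 || object@fpRate >= 1) msgs <- c(msgs, "fpRate must be in (0, 1)")
  if (!object@dsHeuristic %in% c("idf", "ratio")) msgs <- c(msgs, "dsHeuristic must be 'idf' or 'ratio'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a pipeline configuration
#'
#' @param minCoverage,minLabsWidespread,observationCap,nullPairs,fpRate,seed,dsHeuristic
#'   see [PipelineConfig-class].
#' @param alignment an [AlignmentParams-class] object.
#' @return a `PipelineConfig`.
#' @examples
#' pipelineConfig(seed = 7)
#' @export
pipelineConfig <- function(minCoverage = 0.95, minLabsWidespread = 20L,
                           observationCap = 1205L,
                           alignment = alignmentParams(),
                           nullPairs = 100000L, fpRate = 0.05, seed = 1L,
                           dsHeuristic = "idf") {
  new("PipelineConfig", minCoverage = as.numeric(minCoverage),
      minLabsWidespread = as.integer(minLabsWidespread),
      observationCap = as.integer(observationCap), alignment = alignment,
      nullPairs = as.integer(nullPairs), fpRate = as.numeric(fpRate),
      seed = as.integer(seed), dsHeuristic = dsHeuristic)
}
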