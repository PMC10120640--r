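# Generics and accessor methods.

#' @rdname PlasmidCorpus-class
#' @param x a `PlasmidCorpus`.
#' @export
setGeneric("corpusSize", function(x) standardGeneric("corpusSize"))

#' @describeIn PlasmidCorpus-class number of plasmids `p` in the corpus.
#' @export
setMethod("corpusSize", "PlasmidCorpus", function(x) length(x@sequences))

#' @rdname PlasmidCorpus-class
#' @export
setGeneric("plasmidIDs", function(x) standardGeneric("plasmidIDs"))

#' @describeIn PlasmidCorpus-class plasmid identifiers.
#' @export
setMethod("plasmidIDs", "PlasmidCorpus", function(x) names(x@sequences))

#' @rdname PlasmidCorpus-class
#' @export
setGeneric("labs", function(x) standardGeneric("labs"))

#' @describeIn PlasmidCorpus-class depositing-lab id of every plasmid, named
#'   by plasmid id.
#' @export
setMethod("labs", "PlasmidCorpus", function(x) {
  stats::setNames(x@lab, names(x@sequences))
})

#' @rdname PlasmidCorpus-class
#' @export
setGeneric("topologies", function(x) standardGeneric("topologies"))

#' @describeIn PlasmidCorpus-class topology of every plasmid, named by
#'   plasmid id.
#' @export
setMethod("topologies", "PlasmidCorpus", function(x) {
  stats::setNames(x@topology, names(x@sequences))
})

#' @rdname PlasmidCorpus-class
#' @export
setGeneric("sequencesOf", function(x) standardGeneric("sequencesOf"))

#' @describeIn PlasmidCorpus-class sequences as a named
#'   [Biostrings::DNAStringSet].
#' @export
setMethod("sequencesOf", "PlasmidCorpus", function(x) x@sequences)

#' @describeIn PartLibrary-class sequences as a named
#'   [Biostrings::DNAStringSet].
#' @export
setMethod("sequencesOf", "PartLibrary", function(x) x@sequences)

#' @rdname PartLibrary-class
#' @param x a `PartLibrary`.
#' @export
setGeneric("partIDs", function(x) standardGeneric("partIDs"))

#' @describeIn PartLibrary-class part identifiers.
#' @export
setMethod("partIDs", "PartLibrary", function(x) names(x@sequences))

#' @rdname PartLibrary-class
#' @export
setGeneric("partType", function(x) standardGeneric("partType"))

#' @describeIn PartLibrary-class part category of every part, named by part
#'   id.
#' @export
setMethod("partType", "PartLibrary", function(x) {
  stats::setNames(x@partType, names(x@sequences))
})

#' @rdname PartLibrary-class
#' @export
setGeneric("isCoding", function(x) standardGeneric("isCoding"))

#' @describeIn PartLibrary-class TRUE for CDS parts.
#' @export
setMethod("isCoding", "PartLibrary", function(x) {
  stats::setNames(x@partType == "CDS", names(x@sequences))
})

#' @rdname NullCalibration-class
#' @param x a `NullCalibration`.
#' @export
setGeneric("dsCutoff", function(x) standardGeneric("dsCutoff"))

#' @describeIn NullCalibration-class the calibrated DS threshold.
#' @export
setMethod("dsCutoff", "NullCalibration", function(x) x@cutoff)

#' @rdname NullCalibration-class
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))

#' @describeIn NullCalibration-class the sampled null DS scores.
#' @export
setMethod("nullScores", "NullCalibration", function(x) x@nullScores)

#' @rdname SharedSegmentSet-class
#' @param x a `SharedSegmentSet`.
#' @export
setGeneric("segmentFrequencies", function(x) standardGeneric("segmentFrequencies"))

#' @describeIn SharedSegmentSet-class the ascending frequency vector `x`.
#' @export
setMethod("segmentFrequencies", "SharedSegmentSet", function(x) x@x)

#' @rdname SharedSegmentSet-class
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @describeIn SharedSegmentSet-class the segment table.
#' @export
setMethod("segmentTable", "SharedSegmentSet", function(x) x@segments)

setMethod("show", "PlasmidCorpus", function(object) {
  cat("PlasmidCorpus with", corpusSize(object), "plasmids from",
      length(unique(object@lab)), "labs\n")
  cat("  widths:", paste(range(Biostrings::width(object@sequences)),
                         collapse = "-"), "bp;",
      sum(object@topology == "circular"), "circular /",
      sum(object@topology == "linear"), "linear\n")
})

setMethod("show", "PartLibrary", function(object) {
  cat("PartLibrary with", length(object@sequences), "canonical parts\n")
  tab <- table(object@partType)
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = "; "), "\n")
})

setMethod("show", "AlignmentParams", function(object) {
  cat("AlignmentParams: match +", object@matchReward, ", mismatch ",
      object@mismatchPenalty, ", gap ", object@gapOpen, "+",
      object@gapExtend, "/bp, word size ", object@wordSize, "\n", sep = "")
  cat("  segment filters: identity >= ", object@minIdentity,
      ", E <= ", format(object@maxEvalue), ", length diff <= ",
      object@maxLengthDiff, " bp\n", sep = "")
})

setMethod("show", "NullCalibration", function(object) {
  cat("NullCalibration on", length(object@nullScores),
      "cross-lab pairs (seed", object@seed, ")\n")
  cat("  DS cutoff at", format(1 - object@fpRate), "nearest-rank quantile:",
      format(object@cutoff, digits = 6), "\n")
  cat("  no-evidence pairs:", sum(is.infinite(object@nullScores)), "\n")
})

setMethod("show", "SharedSegmentSet", function(object) {
  cat("SharedSegmentSet", object@plasmidA, "vs", object@plasmidB, ":",
      nrow(object@segments), "segments; x = [",
      paste(object@x, collapse = ", "), "]\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: coverage >=", object@minCoverage,
      "; widespread >=", object@minLabsWidespread, "labs; DS cap",
      object@observationCap, "observations\n")
  cat("  null:", object@nullPairs, "pairs at fp rate", object@fpRate,
      "; seed", object@seed, "; heuristic", object@dsHeuristic, "\n")
})
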