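# Internal helpers shared across modules.

#' @useDynLib plasmidDS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Biostrings DNAStringSet
#' @import methods
NULL

# Recognised genetic part categories.
.partTypes <- c("CDS", "origin of replication", "promoter", "terminator",
                "protein binding site", "ncRNA", "other")

# Stream-splitting scheme: all randomness in the package flows from one root
# seed; substream k uses this derived seed (kept below 2^31 - 1).
derivedSeed <- function(seed, k) {
  s <- (as.double(seed) + 1000003 * as.double(k)) %% 2147483647
  as.integer(s) + 1L
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Stable content hash for a variant key
#'
#' Variant identifiers are FNV-1a 64-bit hashes of `part_id` and the exact
#' variant nucleotide sequence, so the same variant always receives the same
#' id across runs and corpora.
#'
#' @param partId character vector of part identifiers.
#' @param sequence character vector of variant sequences.
#' @return character vector of identifiers (`"v"` + 16 hex digits).
#' @export
variantId <- function(partId, sequence) {
  paste0("v", cpp_fnv1a(paste(partId, sequence, sep = "|")))
}

# uppercase + alphabet check for plasmid/part sequences
.checkDNA <- function(x, what = "sequence", allowN = TRUE) {
  x <- toupper(x)
  pat <- if (allowN) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains characters outside ",
         if (allowN) "A/C/G/T/N" else "A/C/G/T",
         " (offending entries: ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")")
  }
  x
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
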