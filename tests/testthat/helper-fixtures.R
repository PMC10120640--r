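# Shared fixture builders: everything is generated in code under fixed
# seeds; no data files.

rdna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# k substitutions at distinct random positions
substitute_bases <- function(s, k, positions = NULL) {
  ch <- strsplit(s, "")[[1]]
  if (is.null(positions)) positions <- sample(length(ch), k)
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# plant `block` into a fresh random sequence of length L at 0-based `at`
with_block <- function(L, block, at) {
  s <- rdna(L)
  substr(s, at + 1, at + nchar(block)) <- block
  s
}

# a small two-lab corpus of unrelated random plasmids
tiny_corpus <- function(n = 6, len = 300, labs = c("labA", "labB"),
                        topology = "linear") {
  seqs <- vapply(seq_len(n), function(i) rdna(len), character(1))
  names(seqs) <- sprintf("p%02d", seq_len(n))
  PlasmidCorpus(seqs, lab = rep_len(labs, n), topology = topology)
}

# default design for fast end-to-end tests (small but structurally complete)
small_design <- function(seed, planted = list(), nLabs = 6L,
                         plasmidsPerLab = 7L) {
  simDesign(nLabs = nLabs, plasmidsPerLab = plasmidsPerLab,
            planted = planted, seed = seed)
}

std_planted_mix <- function() {
  c(lapply(1:4, function(i) plantedVariant(nMutations = 2L, originCount = 1L,
                                           carriersPerOrigin = 1L,
                                           copyLabs = 2L)),
    lapply(5:7, function(i) plantedVariant(nMutations = 2L, originCount = 2L,
                                           carriersPerOrigin = 3L)),
    lapply(8:10, function(i) plantedVariant(nMutations = 2L,
                                            originCount = 3L,
                                            carriersPerOrigin = 3L)))
}
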