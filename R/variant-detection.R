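# Annotation of canonical parts on plasmids and calling of non-canonical
# part variants.

#' Annotate canonical parts on one plasmid
#'
#' Searches every canonical part against the plasmid with the gapped local
#' alignment engine and keeps matches covering at least `minCoverage` of the
#' part's length. Circular plasmids are searched as the sequence concatenated
#' to itself, so parts spanning the sequence origin are recovered; duplicate
#' matches at the same modular start are reported once (the representative
#' with start inside the first copy). Overlapping matches to the same part
#' keep the best scoring one.
#'
#' @param corpus a [PlasmidCorpus-class].
#' @param plasmid a plasmid id in `corpus`.
#' @param parts a [PartLibrary-class]; must be non-empty.
#' @param params an [AlignmentParams-class].
#' @param minCoverage minimum covered fraction of the canonical part length
#'   (inclusive; default 0.95).
#' @return data.frame of part matches: `plasmid_id`, `part_id`,
#'   `plasmid_start`, `plasmid_end` (0-based half-open on the possibly
#'   doubled sequence; start is always within the first copy), `strand`,
#'   `coverage`, `identity`, `matched_sequence` (plasmid subsequence in part
#'   orientation), `covers_ref_start`, `covers_ref_end`, `score`.
#' @export
annotatePlasmid <- function(corpus, plasmid, parts,
                            params = alignmentParams(), minCoverage = 0.95) {
  if (length(partIDs(parts)) == 0L) stop("part database is empty")
  seqs <- as.character(sequencesOf(corpus))
  pseq <- seqs[[plasmid]]
  L <- nchar(pseq)
  circular <- unname(topologies(corpus)[plasmid]) == "circular"
  search_seq <- if (circular) paste0(pseq, pseq) else pseq
  part_seqs <- as.character(sequencesOf(parts))
  out <- vector("list", length(part_seqs))
  for (pi in seq_along(part_seqs)) {
    ps <- part_seqs[[pi]]
    plen <- nchar(ps)
    hits <- localMatches(ps, search_seq, params)
    if (nrow(hits) == 0L) next
    hits$coverage <- (hits$a_end - hits$a_start) / plen
    hits <- hits[hits$coverage >= minCoverage, , drop = FALSE]
    if (nrow(hits) == 0L) next
    if (circular) {
      # modular deduplication: same (start mod L, strand) reported once
      hits <- hits[order(-hits$score, hits$b_start), , drop = FALSE]
      hits <- hits[!duplicated(paste(hits$b_start %% L, hits$strand)), ,
                   drop = FALSE]
      hits <- hits[hits$b_start < L, , drop = FALSE]
      if (nrow(hits) == 0L) next
    }
    # overlapping matches of the same part: best score wins
    hits <- hits[order(-hits$score, hits$b_start), , drop = FALSE]
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(hits))) {
        if (j <= i || !keep[j]) next
        if (hits$b_start[j] < hits$b_end[i] &&
            hits$b_end[j] > hits$b_start[i]) keep[j] <- FALSE
      }
    }
    hits <- hits[keep, , drop = FALSE]
    matched <- substring(search_seq, hits$b_start + 1L, hits$b_end)
    minus <- hits$strand == "-"
    if (any(minus)) matched[minus] <- .revcomp(matched[minus])
    cols <- hits$matches + hits$mismatches + hits$gapcols
    out[[pi]] <- data.frame(
      plasmid_id = plasmid, part_id = partIDs(parts)[pi],
      plasmid_start = hits$b_start, plasmid_end = hits$b_end,
      strand = hits$strand, coverage = hits$coverage,
      identity = hits$matches / cols, matched_sequence = matched,
      covers_ref_start = hits$a_start == 0L,
      covers_ref_end = hits$a_end == nchar(ps),
      score = hits$score, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(plasmid_id = character(0), part_id = character(0),
                      plasmid_start = integer(0), plasmid_end = integer(0),
                      strand = character(0), coverage = numeric(0),
                      identity = numeric(0), matched_sequence = character(0),
                      covers_ref_start = logical(0),
                      covers_ref_end = logical(0), score = integer(0),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$part_id, res$plasmid_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate every plasmid of a corpus
#'
#' @inheritParams annotatePlasmid
#' @return row-bound [annotatePlasmid()] tables for all plasmids.
#' @export
annotateCorpus <- function(corpus, parts, params = alignmentParams(),
                           minCoverage = 0.95) {
  res <- lapply(plasmidIDs(corpus), function(pid) {
    annotatePlasmid(corpus, pid, parts, params, minCoverage)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# translate `seq` in the frame anchored at reference position `refStart`,
# trimming the trailing partial codon.
.translateAnchored <- function(seq, refStart = 0L) {
  lead <- (3L - (refStart %% 3L)) %% 3L
  seq <- substring(seq, lead + 1L, nchar(seq))
  usable <- (nchar(seq) %/% 3L) * 3L
  if (usable < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substring(seq, 1L, usable)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Call a part variant from one annotation match
#'
#' Applies the variant filters to a single part match: the match is not a
#' variant when (i) its sequence equals the canonical nucleotide sequence;
#' (ii) the part is coding and the translation equals the canonical
#' translation (silent changes only); or (iii) the part is coding and the
#' match fails to reach the first or last reference base (a 5' or 3'
#' terminal deletion, which local alignment cannot distinguish from a
#' clipped match). A coding match whose length is incompatible with the
#' reading frame is kept and flagged `frameshifted` rather than dropped.
#'
#' @param match one row of [annotatePlasmid()] output.
#' @param parts the [PartLibrary-class] used for annotation.
#' @return a one-row data.frame (`plasmid_id`, `part_id`,
#'   `variant_sequence`, `frameshifted`) or `NULL` when the match is
#'   filtered out.
#' @export
classifyVariant <- function(match, parts) {
  canonical <- as.character(sequencesOf(parts)[[match$part_id]])
  coding <- unname(isCoding(parts)[match$part_id])
  obs_seq <- match$matched_sequence
  if (obs_seq == canonical) return(NULL)
  frameshifted <- FALSE
  if (coding) {
    if (!isTRUE(match$covers_ref_start) || !isTRUE(match$covers_ref_end)) {
      return(NULL)
    }
    frameshifted <- (nchar(obs_seq) - nchar(canonical)) %% 3L != 0L
    if (!frameshifted &&
        .translateAnchored(obs_seq) == .translateAnchored(canonical)) {
      return(NULL)
    }
  }
  data.frame(plasmid_id = match$plasmid_id, part_id = match$part_id,
             variant_sequence = obs_seq, frameshifted = frameshifted,
             stringsAsFactors = FALSE)
}

#' Call part variants for a whole annotation table
#'
#' @param matches [annotateCorpus()] output.
#' @param parts the [PartLibrary-class] used for annotation.
#' @param corpus the [PlasmidCorpus-class], used to attach the depositing
#'   lab to every observation.
#' @return data.frame of variant observations: `plasmid_id`, `lab`,
#'   `part_id`, `variant_sequence`, `frameshifted`.
#' @export
classifyVariants <- function(matches, parts, corpus) {
  empty <- data.frame(plasmid_id = character(0), lab = character(0),
                      part_id = character(0), variant_sequence = character(0),
                      frameshifted = logical(0), stringsAsFactors = FALSE)
  if (nrow(matches) == 0L) return(empty)
  canon <- stats::setNames(as.character(sequencesOf(parts)), partIDs(parts))
  coding <- isCoding(parts)
  can_seq <- unname(canon[matches$part_id])
  is_cds <- unname(coding[matches$part_id])
  keep <- matches$matched_sequence != can_seq &
    !(is_cds & !(matches$covers_ref_start & matches$covers_ref_end))
  m <- matches[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)
  is_cds <- is_cds[keep]
  can_seq <- can_seq[keep]
  frameshifted <- is_cds &
    (nchar(m$matched_sequence) - nchar(can_seq)) %% 3L != 0L
  # in-frame coding matches: drop when the protein is unchanged (batch
  # translation; canonical translations computed once per part)
  chk <- which(is_cds & !frameshifted)
  if (length(chk)) {
    can_aa <- vapply(canon[unique(m$part_id[chk])], .translateAnchored,
                     character(1))
    obs_aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(m$matched_sequence[chk]),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
    silent <- obs_aa == unname(can_aa[m$part_id[chk]])
    if (any(silent)) {
      drop <- rep(FALSE, nrow(m))
      drop[chk[silent]] <- TRUE
      m <- m[!drop, , drop = FALSE]
      frameshifted <- frameshifted[!drop]
    }
  }
  if (nrow(m) == 0L) return(empty)
  lab_of <- labs(corpus)
  data.frame(plasmid_id = m$plasmid_id, lab = unname(lab_of[m$plasmid_id]),
             part_id = m$part_id, variant_sequence = m$matched_sequence,
             frameshifted = frameshifted, stringsAsFactors = FALSE)
}

#' Group identical variant observations across the corpus
#'
#' Observations are grouped by exact `(part_id, variant_sequence)`; two
#' variant sequences differing anywhere form distinct groups. The group id
#' is a stable content hash of the key (see [variantId()]).
#'
#' @param observations [classifyVariants()] output.
#' @return data.frame with one row per unique variant: `variant_id`,
#'   `part_id`, `variant_sequence`, `n_observations`, `n_labs`, and list
#'   columns `plasmids` and `labs` (distinct carriers), ordered by
#'   `(part_id, variant_id)`.
#' @export
groupVariants <- function(observations) {
  if (nrow(observations) == 0L) {
    return(data.frame(variant_id = character(0), part_id = character(0),
                      variant_sequence = character(0),
                      n_observations = integer(0), n_labs = integer(0),
                      plasmids = I(list()), labs = I(list()),
                      stringsAsFactors = FALSE))
  }
  key <- paste(observations$part_id, observations$variant_sequence,
               sep = "\r")
  idx <- split(seq_len(nrow(observations)), key)
  rows <- lapply(idx, function(ii) {
    o <- observations[ii, , drop = FALSE]
    data.frame(variant_id = variantId(o$part_id[1], o$variant_sequence[1]),
               part_id = o$part_id[1],
               variant_sequence = o$variant_sequence[1],
               n_observations = length(ii),
               n_labs = length(unique(o$lab)),
               plasmids = I(list(sort(unique(o$plasmid_id)))),
               labs = I(list(sort(unique(o$lab)))),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, rows)
  groups <- groups[order(groups$part_id, groups$variant_id), , drop = FALSE]
  rownames(groups) <- NULL
  groups
}
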