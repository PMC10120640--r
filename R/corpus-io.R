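# Reading and writing plasmid corpora, part databases, and the variant
# catalog.

#' Read a plasmid corpus from sequence and metadata files
#'
#' Reads one sequence record per plasmid from FASTA or GenBank flat files and
#' joins a tab-separated metadata table mapping every plasmid to its
#' depositing lab and topology. The file format is detected from the first
#' non-blank character (`>` means FASTA, otherwise a GenBank LOCUS block is
#' expected). Sequences are uppercased on read; only A/C/G/T/N are accepted.
#' GenBank feature tables are ignored deliberately: annotation is recomputed,
#' not trusted.
#'
#' @param seqPath path to a FASTA or GenBank file.
#' @param metadataPath path to a TSV with header columns `plasmid_id`, `lab`,
#'   `topology`.
#' @return a [PlasmidCorpus-class].
#' @export
readCorpus <- function(seqPath, metadataPath) {
  seqs <- .readSeqFile(seqPath)
  if (length(seqs) == 0L) stop("no sequence records in ", seqPath)
  meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("plasmid_id", "lab", "topology")
  if (!all(need %in% names(meta))) {
    stop("metadata must have header columns plasmid_id, lab, topology")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate plasmid ids in ", seqPath, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (anyDuplicated(meta$plasmid_id)) {
    stop("duplicate plasmid ids in metadata: ",
         paste(unique(meta$plasmid_id[duplicated(meta$plasmid_id)]),
               collapse = ", "))
  }
  missing <- setdiff(names(seqs), meta$plasmid_id)
  if (length(missing)) {
    stop("no metadata row for plasmid id(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(meta$plasmid_id, names(seqs))
  if (length(extra)) {
    stop("metadata row without sequence record for plasmid id(s): ",
         paste(extra, collapse = ", "))
  }
  rownames(meta) <- meta$plasmid_id
  meta <- meta[names(seqs), , drop = FALSE]
  PlasmidCorpus(seqs, lab = meta$lab, topology = meta$topology)
}

.readSeqFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) stop("empty sequence file: ", path)
  if (startsWith(trimws(first), ">")) {
    dss <- Biostrings::readDNAStringSet(path)
    seqs <- toupper(as.character(dss))
    names(seqs) <- sub("\\s.*$", "", names(dss))
    seqs
  } else {
    .readGenBankSeqs(lines, path)
  }
}

# Minimal multi-record GenBank flat-file reader: LOCUS name + ORIGIN block.
.readGenBankSeqs <- function(lines, path) {
  ids <- character()
  seqs <- character()
  cur_id <- NA_character_
  in_origin <- FALSE
  buf <- character()
  for (ln in lines) {
    if (grepl("^LOCUS\\s+", ln)) {
      cur_id <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
      in_origin <- FALSE
      buf <- character()
    } else if (grepl("^ORIGIN", ln)) {
      in_origin <- TRUE
    } else if (grepl("^//", ln)) {
      if (is.na(cur_id)) stop("GenBank record without LOCUS line in ", path)
      ids <- c(ids, cur_id)
      seqs <- c(seqs, paste(buf, collapse = ""))
      cur_id <- NA_character_
      in_origin <- FALSE
      buf <- character()
    } else if (in_origin) {
      buf <- c(buf, gsub("[^A-Za-z]", "", ln))
    }
  }
  if (!length(ids)) stop("no GenBank records found in ", path)
  stats::setNames(toupper(seqs), ids)
}

#' Write a plasmid corpus to FASTA + metadata TSV
#'
#' Inverse of [readCorpus()]; writing then reading reproduces ids, sequences,
#' labs, and topology exactly.
#'
#' @param corpus a [PlasmidCorpus-class].
#' @param seqPath,metadataPath output paths.
#' @return invisibly, the corpus.
#' @export
writeCorpus <- function(corpus, seqPath, metadataPath) {
  Biostrings::writeXStringSet(sequencesOf(corpus), seqPath)
  meta <- data.frame(plasmid_id = plasmidIDs(corpus),
                     lab = unname(labs(corpus)),
                     topology = unname(topologies(corpus)),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metadataPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(corpus)
}

#' Read a part reference database from FASTA
#'
#' FASTA headers encode the part id and category, pipe-delimited:
#' `>partId|partType` (e.g. `>bla|CDS`). A part is coding exactly when its
#' type is `CDS`.
#'
#' @param path path to the part FASTA.
#' @return a [PartLibrary-class].
#' @export
readPartLibrary <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("no part records in ", path)
  headers <- names(dss)
  nop <- !grepl("|", headers, fixed = TRUE)
  if (any(nop)) {
    stop("part FASTA header without '|' delimiter: ",
         paste(utils::head(headers[nop], 5), collapse = ", "))
  }
  split_at <- regexpr("|", headers, fixed = TRUE)
  ids <- substr(headers, 1, split_at - 1)
  types <- trimws(substr(headers, split_at + 1, nchar(headers)))
  bad <- !(types %in% .partTypes)
  if (any(bad)) {
    stop("unknown part type token(s): ",
         paste(unique(types[bad]), collapse = ", "),
         " (expected one of: ", paste(.partTypes, collapse = ", "), ")")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate part ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- stats::setNames(toupper(as.character(dss)), ids)
  PartLibrary(seqs, partType = types)
}

#' Write a part reference database to FASTA
#'
#' @param parts a [PartLibrary-class].
#' @param path output path; headers are written as `partId|partType`.
#' @return invisibly, `parts`.
#' @export
writePartLibrary <- function(parts, path) {
  dss <- sequencesOf(parts)
  names(dss) <- paste(partIDs(parts), unname(partType(parts)), sep = "|")
  Biostrings::writeXStringSet(dss, path)
  invisible(parts)
}

.catalogColumns <- c("variant_id", "part_id", "part_type", "variant_sequence",
                     "n_observations", "n_labs", "n_components", "widespread",
                     "recurrent")

#' Write the variant catalog to TSV
#'
#' Produces the final deliverable table: one row per catalogued variant with
#' its classification. Output is sorted by `(part_id, variant_id)` and is
#' byte-deterministic for a fixed input; groups above the observation cap
#' carry `not-tested` in `n_components`.
#'
#' @param entries data.frame of catalog entries (see [runPipeline()]).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCatalog <- function(entries, path) {
  if (is.null(entries) || nrow(entries) == 0L) {
    entries <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.catalogColumns)), .catalogColumns))
  }
  missing <- setdiff(.catalogColumns, names(entries))
  if (length(missing)) {
    stop("catalog entries lack column(s): ", paste(missing, collapse = ", "))
  }
  out <- entries[order(entries$part_id, entries$variant_id),
                 .catalogColumns, drop = FALSE]
  out$n_components <- ifelse(is.na(out$n_components), "not-tested",
                             as.character(out$n_components))
  out$widespread <- ifelse(out$widespread, "true", "false")
  out$recurrent <- ifelse(out$recurrent, "true", "false")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.catalogColumns, collapse = "\t"), con, sep = "\n")
  if (nrow(out)) {
    body <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Write variant observations to TSV
#'
#' Intermediate per-observation table (one row per detected non-canonical
#' part instance).
#'
#' @param observations data.frame from [classifyVariants()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeObservations <- function(observations, path) {
  cols <- c("plasmid_id", "lab", "part_id", "variant_id", "variant_sequence")
  obs <- observations
  obs$variant_id <- variantId(obs$part_id, obs$variant_sequence)
  obs <- obs[order(obs$part_id, obs$variant_id, obs$plasmid_id), cols,
             drop = FALSE]
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
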