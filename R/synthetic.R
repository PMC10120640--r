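# Synthetic multi-lab plasmid corpora with known part provenance and planted
# variant origins, so every pipeline stage is testable without external data.
#
# The generator emulates the structure that makes authorship inference
# possible in real repositories: every lab assembles plasmids from a shared
# part library on top of a lab backbone (origin + selection marker + a
# lab-unique spacer emulating cloning scars), some labs adopt another lab's
# backbone wholesale, plasmids are copied between labs together with their
# scars, and part copies accumulate low-level background substitutions.

#' Default part-library specification
#'
#' Three origin-of-replication types, three CDS selection markers, and ten
#' cargo parts of mixed categories. Cargo parts are deliberately common
#' (every plasmid carries several) so that sharing them carries little
#' authorship signal, while lab spacers are rare.
#'
#' @param nOrigins,nMarkers,nCargo number of parts per role.
#' @param originLength,markerLength cargo-independent part lengths (bp).
#' @param cargoLengthRange min/max cargo part length (bp). Parts are long
#'   enough that a variant differing by a few nucleotides still matches the
#'   canonical copies on other plasmids within the 98% identity tolerance,
#'   as is typical of real part variants; the variant sequence itself then
#'   carries no spurious rarity signal between unrelated carriers.
#' @return data.frame with columns `part_id`, `part_type`, `role`, `length`.
#' @export
defaultPartSpec <- function(nOrigins = 3L, nMarkers = 3L, nCargo = 10L,
                            originLength = 200L, markerLength = 300L,
                            cargoLengthRange = c(180L, 250L)) {
  cargo_types <- rep_len(c("promoter", "terminator", "CDS",
                           "protein binding site", "ncRNA", "other"), nCargo)
  lens <- as.integer(round(seq(cargoLengthRange[1], cargoLengthRange[2],
                               length.out = max(nCargo, 2L))))[seq_len(nCargo)]
  rbind(
    data.frame(part_id = sprintf("ori%02d", seq_len(nOrigins)),
               part_type = "origin of replication", role = "origin",
               length = as.integer(originLength), stringsAsFactors = FALSE),
    data.frame(part_id = sprintf("mkr%02d", seq_len(nMarkers)),
               part_type = "CDS", role = "marker",
               length = as.integer(markerLength), stringsAsFactors = FALSE),
    data.frame(part_id = sprintf("cargo%02d", seq_len(nCargo)),
               part_type = cargo_types, role = "cargo", length = lens,
               stringsAsFactors = FALSE))
}

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random open reading frame: ATG + sense codons + TAA, length L (multiple
# of 3, >= 9)
.randomORF <- function(L) {
  stopifnot(L %% 3L == 0L, L >= 9L)
  stops <- c("TAA", "TAG", "TGA")
  n_codons <- L %/% 3L - 2L
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- .randomDNA(3L)
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Generate a random part library
#'
#' Random sequences of the requested lengths and categories; CDS entries are
#' proper open reading frames (start codon, no internal stops, length a
#' multiple of three -- requested CDS lengths are rounded to the nearest
#' feasible multiple of three). Deterministic for a fixed seed.
#'
#' @param spec a specification as from [defaultPartSpec()].
#' @param seed integer seed.
#' @return a [PartLibrary-class]; the `role` column of `spec` is preserved as
#'   an attribute `roles` (named character vector).
#' @export
generatePartLibrary <- function(spec = defaultPartSpec(), seed = 1L) {
  if (any(spec$part_type == "CDS" & spec$length < 6L)) {
    stop("CDS parts must be at least 6 nt long")
  }
  if (anyDuplicated(spec$part_id)) stop("duplicate part ids in spec")
  seqs <- withSeed(seed, {
    vapply(seq_len(nrow(spec)), function(i) {
      L <- spec$length[i]
      if (spec$part_type[i] == "CDS") {
        L <- max(9L, as.integer(round(L / 3L)) * 3L)
        .randomORF(L)
      } else {
        .randomDNA(L)
      }
    }, character(1))
  })
  names(seqs) <- spec$part_id
  lib <- PartLibrary(seqs, partType = spec$part_type)
  attr(lib, "roles") <- stats::setNames(spec$role, spec$part_id)
  lib
}

#' Introduce substitutions into a part sequence
#'
#' Places exactly `nMutations` substitutions at distinct interior positions.
#' Positions within `edgeBuffer` of either end are never mutated: local
#' alignment clips terminal mismatches, so edge variants are undetectable by
#' construction and would break ground-truth bookkeeping. For coding parts
#' the mutation set is redrawn (deterministically) until at least one
#' substitution is non-synonymous, so the variant survives the
#' amino-acid-identity filter.
#'
#' @param sequence canonical part sequence.
#' @param nMutations number of substitutions (0 returns the input).
#' @param seed integer seed.
#' @param coding is the part a CDS?
#' @param edgeBuffer protected bases at each end.
#' @return the variant sequence.
#' @export
mutatePart <- function(sequence, nMutations, seed = 1L, coding = FALSE,
                       edgeBuffer = 8L) {
  if (nMutations == 0L) return(sequence)
  L <- nchar(sequence)
  lo <- edgeBuffer + 1L
  hi <- L - edgeBuffer
  if (hi - lo + 1L < nMutations) {
    stop("part too short for ", nMutations, " interior substitutions")
  }
  bases <- c("A", "C", "G", "T")
  for (attempt in 1:50) {
    out <- withSeed(derivedSeed(seed, attempt), {
      chars <- strsplit(sequence, "")[[1]]
      pos <- sample(lo:hi, nMutations)
      for (p in pos) {
        chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      }
      paste(chars, collapse = "")
    })
    if (!coding ||
        .translateAnchored(out) != .translateAnchored(sequence)) {
      return(out)
    }
  }
  stop("could not generate a non-synonymous variant in 50 attempts")
}

#' Describe one planted variant
#'
#' @param partId cargo part to mutate (`NA` = auto-assign a distinct cargo
#'   part).
#' @param nMutations substitutions in the variant (default 2).
#' @param originCount number of independent origins: each origin is an
#'   independent mutation event yielding the *same* variant sequence
#'   (convergence) in a lab lineage engineered to share only ubiquitous
#'   parts with the other origins.
#' @param carriersPerOrigin plasmids carrying the variant per origin.
#' @param copyLabs for single-origin variants only: spread the variant by
#'   whole-plasmid copying (backbone, cargo, and scars included) into this
#'   many additional labs, one carrier each -- the copied-lineage scenario.
#' @return a `plantedVariant` list.
#' @export
plantedVariant <- function(partId = NA_character_, nMutations = 2L,
                           originCount = 1L, carriersPerOrigin = 3L,
                           copyLabs = 0L) {
  if (copyLabs > 0L && originCount != 1L) {
    stop("copyLabs spreading requires originCount = 1")
  }
  if (originCount < 1L) stop("originCount must be >= 1")
  structure(list(part_id = partId, n_mutations = as.integer(nMutations),
                 origin_count = as.integer(originCount),
                 carriers_per_origin = as.integer(carriersPerOrigin),
                 copy_labs = as.integer(copyLabs)),
            class = "plantedVariant")
}

#' Define a synthetic corpus design
#'
#' The design fixes the study conditions of a simulated multi-lab
#' repository. Every lab uses a backbone of one origin type, one marker
#' type, and a lab-unique 150-bp spacer; a `backboneSharing` fraction of
#' labs (never the first three, which host planted variant origins) adopt
#' another non-origin lab's backbone wholesale. Plasmids add several common
#' cargo parts separated by plasmid-unique scar spacers, and every part copy
#' accumulates background substitutions at `mutationRate` per base.
#'
#' @param nLabs,plasmidsPerLab corpus dimensions.
#' @param partSpec part-library specification ([defaultPartSpec()]).
#' @param cargoPerPlasmid cargo parts per plasmid (sampled without
#'   replacement).
#' @param labSpacerLength length of the lab-unique backbone spacer (bp).
#' @param interSpacerRange min/max length of the scar spacers between
#'   elements (bp); at least the seed word size so scars are discoverable
#'   segments.
#' @param backboneSharing fraction of labs adopting another lab's backbone.
#' @param mutationRate per-base background substitution probability applied
#'   to every plasmid (planted variant instances exempted so ground truth
#'   stays exact).
#' @param planted list of [plantedVariant()] descriptions.
#' @param seed root seed; all generator randomness derives from it.
#' @return a `SimDesign` list.
#' @export
simDesign <- function(nLabs = 10L, plasmidsPerLab = 20L,
                      partSpec = defaultPartSpec(), cargoPerPlasmid = 5L,
                      labSpacerLength = 150L, interSpacerRange = c(30L, 50L),
                      backboneSharing = 0.3, mutationRate = 0.004,
                      planted = list(), seed = 1L) {
  cargo_ids <- partSpec$part_id[partSpec$role == "cargo"]
  if (cargoPerPlasmid > length(cargo_ids)) {
    stop("cargoPerPlasmid exceeds the number of cargo parts")
  }
  if (backboneSharing < 0 || backboneSharing > 1) {
    stop("backboneSharing must be a probability")
  }
  if (mutationRate < 0 || mutationRate > 1) {
    stop("mutationRate must be a probability")
  }
  if (length(planted) && !all(vapply(planted, inherits, logical(1),
                                     "plantedVariant"))) {
    stop("planted must be a list of plantedVariant() objects")
  }
  structure(list(n_labs = as.integer(nLabs),
                 plasmids_per_lab = as.integer(plasmidsPerLab),
                 part_spec = partSpec,
                 cargo_per_plasmid = as.integer(cargoPerPlasmid),
                 lab_spacer_length = as.integer(labSpacerLength),
                 inter_spacer_range = as.integer(interSpacerRange),
                 backbone_sharing = backboneSharing,
                 mutation_rate = mutationRate,
                 planted = planted, seed = as.integer(seed)),
            class = "SimDesign")
}

# number of labs kept adoption-free to host independent planted origins
.protectedLabs <- function(design) min(3L, design$n_labs)

#' Generate a synthetic plasmid corpus with ground truth
#'
#' Assembles the corpus described by a [simDesign()]: the part library, the
#' lab backbones (with deterministic backbone adoption), per-plasmid cargo
#' and scar spacers, planted variants (independent origins on independent
#' lab lineages; copied-lineage spreading with whole-plasmid copies), and
#' background mutations. Deterministic for a fixed design seed.
#'
#' @param design a [simDesign()].
#' @return list with `corpus` (a [PlasmidCorpus-class]), `parts` (a
#'   [PartLibrary-class]), and `truth` (data.frame with one row per planted
#'   variant: `variant_id`, `part_id`, `variant_sequence`, `origin_count`,
#'   list columns `carriers` and `labs`).
#' @export
generateCorpus <- function(design) {
  stopifnot(inherits(design, "SimDesign"))
  seed <- design$seed
  nl <- design$n_labs
  ppl <- design$plasmids_per_lab
  lib <- generatePartLibrary(design$part_spec, derivedSeed(seed, 1L))
  roles <- attr(lib, "roles")
  part_seq <- stats::setNames(as.character(sequencesOf(lib)), partIDs(lib))
  origin_ids <- names(roles)[roles == "origin"]
  marker_ids <- names(roles)[roles == "marker"]
  cargo_ids <- names(roles)[roles == "cargo"]

  lab_names <- sprintf("lab%02d", seq_len(nl))
  no <- length(origin_ids)
  nm <- length(marker_ids)
  lab_origin <- origin_ids[((seq_len(nl) - 1L) %% no) + 1L]
  lab_marker <- marker_ids[(((seq_len(nl) - 1L) %/% no) %% nm) + 1L]

  # lab spacers and backbone adoption (stream 2)
  protected <- .protectedLabs(design)
  lab_state <- withSeed(derivedSeed(seed, 2L), {
    spacers <- vapply(seq_len(nl), function(i)
      .randomDNA(design$lab_spacer_length), character(1))
    n_adopt <- round(design$backbone_sharing * nl)
    eligible <- setdiff(seq_len(nl), seq_len(protected))
    eligible <- eligible[eligible >= protected + 2L]  # need a source below
    adopters <- sort(sample(eligible, min(n_adopt, length(eligible))))
    source_of <- rep(NA_integer_, nl)
    for (l in adopters) {
      pool <- setdiff(seq.int(protected + 1L, l - 1L), integer(0))
      src <- if (length(pool) == 1L) pool else sample(pool, 1L)
      while (!is.na(source_of[src])) src <- source_of[src]
      source_of[l] <- src
    }
    list(spacers = spacers, source_of = source_of)
  })
  lab_spacer <- lab_state$spacers
  for (l in seq_len(nl)) {
    src <- lab_state$source_of[l]
    if (!is.na(src)) {
      lab_spacer[l] <- lab_spacer[src]
      lab_origin[l] <- lab_origin[src]
      lab_marker[l] <- lab_marker[src]
    }
  }

  # plasmid skeletons (stream 3): element tables per plasmid
  skeletons <- withSeed(derivedSeed(seed, 3L), {
    lapply(seq_len(nl), function(l) {
      lapply(seq_len(ppl), function(i) {
        cargo <- sample(cargo_ids, design$cargo_per_plasmid)
        ids <- c(lab_origin[l], lab_marker[l], ".labspacer", cargo)
        n_el <- length(ids)
        sp_len <- sample(seq(design$inter_spacer_range[1],
                             design$inter_spacer_range[2]), n_el,
                         replace = TRUE)
        spacers <- vapply(sp_len, .randomDNA, character(1))
        data.frame(element = ids, spacer_before = spacers,
                   planted = NA_character_, literal = NA_character_,
                   scar_left = NA_character_, scar_right = NA_character_,
                   stringsAsFactors = FALSE)
      })
    })
  })

  # planting plan (stream 4)
  planted <- design$planted
  nv <- length(planted)
  truth <- NULL
  if (nv > 0L) {
    if (nv > length(cargo_ids)) {
      stop("more planted variants than cargo parts to host them")
    }
    auto <- withSeed(derivedSeed(seed, 4L),
                     sample(cargo_ids, length(cargo_ids)))
    given <- vapply(planted, function(v) v$part_id, character(1))
    if (anyDuplicated(given[!is.na(given)])) {
      stop("planted variants must use distinct parts")
    }
    auto <- setdiff(auto, given[!is.na(given)])
    reserved <- matrix(FALSE, nl, ppl)   # copy-family members: hands off
    t_rows <- vector("list", nv)
    copy_first <- order(vapply(planted, function(v) v$copy_labs,
                               integer(1)) == 0L)
    for (vi in copy_first) {
      v <- planted[[vi]]
      pid <- v$part_id
      if (is.na(pid)) {
        pid <- auto[1L]
        auto <- auto[-1L]
      }
      if (!pid %in% cargo_ids) stop("planted part must be a cargo part: ", pid)
      coding <- unname(isCoding(lib)[pid])
      vseq <- mutatePart(part_seq[[pid]], v$n_mutations,
                         derivedSeed(seed, 400L + vi), coding = coding)
      carriers <- character(0)
      carrier_labs <- character(0)
      if (v$copy_labs > 0L) {
        src_lab <- ((vi - 1L) %% protected) + 1L
        picks <- withSeed(derivedSeed(seed, 500L + vi), {
          src_pl <- sample(which(!reserved[src_lab, ]), 1L)
          rec_pool <- setdiff(seq_len(nl), seq_len(protected))
          rec_labs <- sample(rec_pool, v$copy_labs)
          rec_pl <- vapply(rec_labs, function(rl)
            sample(which(!reserved[rl, ]), 1L), integer(1))
          scars <- c(.randomDNA(50L), .randomDNA(50L))
          list(src_pl = src_pl, rec_labs = rec_labs, rec_pl = rec_pl,
               scars = scars)
        })
        sk <- skeletons[[src_lab]][[picks$src_pl]]
        sk <- .plantInSkeleton(sk, pid, vseq, cargo_ids, picks$scars)
        # whole-plasmid copies carry the source lab's spacer with them
        ls_row <- which(sk$element == ".labspacer")
        sk$literal[ls_row] <- lab_spacer[src_lab]
        skeletons[[src_lab]][[picks$src_pl]] <- sk
        reserved[src_lab, picks$src_pl] <- TRUE
        carriers <- sprintf("%s_p%02d", lab_names[src_lab], picks$src_pl)
        carrier_labs <- lab_names[src_lab]
        for (ci in seq_along(picks$rec_labs)) {
          rl <- picks$rec_labs[ci]
          rp <- picks$rec_pl[ci]
          skeletons[[rl]][[rp]] <- sk   # whole-plasmid copy, scars included
          reserved[rl, rp] <- TRUE
          carriers <- c(carriers, sprintf("%s_p%02d", lab_names[rl], rp))
          carrier_labs <- c(carrier_labs, lab_names[rl])
        }
      } else {
        if (v$origin_count > protected) {
          stop("origin_count exceeds the number of independent origin labs (",
               protected, ")")
        }
        origin_labs <- (((vi - 1L) + seq_len(v$origin_count) - 1L) %%
                          protected) + 1L
        for (ol in origin_labs) {
          pool <- which(!reserved[ol, ])
          if (length(pool) < v$carriers_per_origin) {
            stop("lab ", lab_names[ol], " has too few free plasmids for ",
                 "planting")
          }
          # one cloning event per origin: its carriers share the flanking
          # scars, carriers of other origins do not
          picks <- withSeed(derivedSeed(seed, 600L + vi * 37L + ol), {
            list(sel = sample(pool, v$carriers_per_origin),
                 scars = c(.randomDNA(50L), .randomDNA(50L)))
          })
          for (pl in picks$sel) {
            skeletons[[ol]][[pl]] <- .plantInSkeleton(
              skeletons[[ol]][[pl]], pid, vseq, cargo_ids, picks$scars)
            carriers <- c(carriers, sprintf("%s_p%02d", lab_names[ol], pl))
            carrier_labs <- c(carrier_labs, lab_names[ol])
          }
        }
      }
      t_rows[[vi]] <- data.frame(
        variant_id = variantId(pid, vseq), part_id = pid,
        variant_sequence = vseq, origin_count = v$origin_count,
        carriers = I(list(sort(carriers))),
        labs = I(list(sort(unique(carrier_labs)))), stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, t_rows)
  }
  if (is.null(truth)) {
    truth <- data.frame(variant_id = character(0), part_id = character(0),
                        variant_sequence = character(0),
                        origin_count = integer(0), carriers = I(list()),
                        labs = I(list()), stringsAsFactors = FALSE)
  }

  # realize sequences and apply background mutations (stream 5)
  ids <- character(nl * ppl)
  lab_of <- character(nl * ppl)
  seqs <- character(nl * ppl)
  k <- 0L
  mut_seed <- derivedSeed(seed, 5L)
  idx <- 0L
  for (l in seq_len(nl)) {
    for (i in seq_len(ppl)) {
      k <- k + 1L
      sk <- skeletons[[l]][[i]]
      pieces <- character(0)
      exempt <- integer(0)
      pos <- 0L
      for (r in seq_len(nrow(sk))) {
        sp <- sk$spacer_before[r]
        pieces <- c(pieces, sp)
        pos <- pos + nchar(sp)
        el <- sk$element[r]
        if (!is.na(sk$planted[r]) && !is.na(sk$scar_left[r])) {
          pieces <- c(pieces, sk$scar_left[r])
          pos <- pos + nchar(sk$scar_left[r])
        }
        el_seq <- if (!is.na(sk$planted[r])) {
          sk$planted[r]
        } else if (!is.na(sk$literal[r])) {
          sk$literal[r]
        } else if (el == ".labspacer") {
          lab_spacer[l]
        } else {
          part_seq[[el]]
        }
        pieces <- c(pieces, el_seq)
        if (!is.na(sk$planted[r])) {
          exempt <- c(exempt, seq.int(pos + 1L, pos + nchar(el_seq)))
        }
        pos <- pos + nchar(el_seq)
        if (!is.na(sk$planted[r]) && !is.na(sk$scar_right[r])) {
          pieces <- c(pieces, sk$scar_right[r])
          pos <- pos + nchar(sk$scar_right[r])
        }
      }
      full <- paste(pieces, collapse = "")
      idx <- idx + 1L
      full <- withSeed(derivedSeed(mut_seed, idx), {
        .backgroundMutate(full, design$mutation_rate, exempt)
      })
      ids[k] <- sprintf("%s_p%02d", lab_names[l], i)
      lab_of[k] <- lab_names[l]
      seqs[k] <- full
    }
  }
  names(seqs) <- ids
  corpus <- PlasmidCorpus(seqs, lab = lab_of, topology = "circular")
  list(corpus = corpus, parts = lib, truth = truth)
}

# substitute the variant sequence into the skeleton's slot for `pid`
# (overriding the cargo slot already holding the part, else the first free
# cargo slot)
.plantInSkeleton <- function(sk, pid, vseq, cargo_ids, scars = NULL) {
  slot <- which(sk$element == pid & is.na(sk$planted))
  if (!length(slot)) {
    slot <- which(sk$element %in% cargo_ids & is.na(sk$planted))
    if (!length(slot)) stop("no free cargo slot to plant variant on ", pid)
    sk$element[slot[1L]] <- pid
  }
  sk$planted[slot[1L]] <- vseq
  if (!is.null(scars)) {
    sk$scar_left[slot[1L]] <- scars[1L]
    sk$scar_right[slot[1L]] <- scars[2L]
  }
  sk
}

.backgroundMutate <- function(seq, rate, exempt) {
  if (rate <= 0) return(seq)
  L <- nchar(seq)
  allowed <- setdiff(seq_len(L), exempt)
  n_mut <- stats::rbinom(1L, length(allowed), rate)
  if (n_mut == 0L) return(seq)
  pos <- sample(allowed, n_mut)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Write a simulated corpus to disk
#'
#' Emits the corpus FASTA, the metadata TSV, the part FASTA, and the ground
#' truth as JSON, in the formats [readCorpus()] and [readPartLibrary()]
#' consume.
#'
#' @param sim result of [generateCorpus()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeCorpus(sim$corpus, file.path(dir, "corpus.fasta"),
              file.path(dir, "metadata.tsv"))
  writePartLibrary(sim$parts, file.path(dir, "parts.fasta"))
  truth <- sim$truth
  truth_list <- lapply(seq_len(nrow(truth)), function(i) {
    list(variant_id = truth$variant_id[i], part_id = truth$part_id[i],
         variant_sequence = truth$variant_sequence[i],
         origin_count = truth$origin_count[i],
         carriers = truth$carriers[[i]], labs = truth$labs[[i]])
  })
  jsonlite::write_json(truth_list, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
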