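# End-to-end prioritization pipeline: annotate -> call variants -> group ->
# calibrate -> classify every group as widespread and/or recurrent.

#' Is a variant group widespread?
#'
#' A variant is widespread when plasmids carrying it were deposited by at
#' least `minLabsWidespread` distinct labs (inclusive: exactly 20 labs
#' qualifies under the default).
#'
#' @param group one row of the [groupVariants()] table.
#' @param config a [PipelineConfig-class].
#' @return logical.
#' @export
classifyWidespread <- function(group, config = pipelineConfig()) {
  group$n_labs >= config@minLabsWidespread
}

#' Is a variant group recurrent?
#'
#' Runs the authorship analysis for one variant group: pairwise DS over the
#' group's distinct plasmids, binarization at the calibrated cutoff, and
#' connected-component counting. A group with more observations than the
#' configured cap is not tested (`n_components = NA`, recurrent `FALSE`);
#' a group with a single distinct plasmid is trivially one component.
#' Single-lab multi-plasmid groups are tested like any other group --
#' recurrence within one lab is still informative -- and the run report
#' flags how many such groups were tested.
#'
#' @param group one row of the [groupVariants()] table.
#' @param corpus a [PlasmidCorpus-class].
#' @param cutoff calibrated DS cutoff (numeric or
#'   [NullCalibration-class]).
#' @param config a [PipelineConfig-class].
#' @param cache optional [newSegmentCache()] cache shared across groups.
#' @return list with `recurrent` (logical), `n_components` (integer, `NA`
#'   when not tested), `tested` (logical), and `membership` (component
#'   assignment, `NULL` when not tested).
#' @export
classifyRecurrent <- function(group, corpus, cutoff,
                              config = pipelineConfig(), cache = NULL) {
  if (is(cutoff, "NullCalibration")) cutoff <- dsCutoff(cutoff)
  if (group$n_observations > config@observationCap) {
    return(list(recurrent = FALSE, n_components = NA_integer_,
                tested = FALSE, membership = NULL))
  }
  plasmids <- group$plasmids
  if (is.list(plasmids)) plasmids <- plasmids[[1]]
  if (length(plasmids) < 2L) {
    membership <- stats::setNames(1L, plasmids)
    return(list(recurrent = FALSE, n_components = 1L, tested = TRUE,
                membership = membership))
  }
  mat <- pairwiseDS(group, corpus, config@alignment, cache,
                    observationCap = config@observationCap,
                    heuristic = config@dsHeuristic)
  graph <- buildAuthorshipGraph(mat, cutoff)
  comp <- countComponents(graph)
  list(recurrent = comp$n_components >= 2L,
       n_components = comp$n_components, tested = TRUE,
       membership = comp$membership)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full variant prioritization pipeline
#'
#' Executes the whole procedure on a corpus: annotate canonical parts on
#' every plasmid, call non-canonical part variants, group identical variants,
#' calibrate the DS relatedness cutoff on a cross-lab null, classify every
#' group as widespread and/or recurrent, and assemble the variant catalog
#' (groups that are widespread or recurrent). Fully reproducible for fixed
#' inputs and seed.
#'
#' @param corpus a [PlasmidCorpus-class].
#' @param parts a [PartLibrary-class].
#' @param config a [PipelineConfig-class].
#' @return list with `catalog` (data.frame of catalog entries), `groups`
#'   (all variant groups with classification columns), `observations`,
#'   `calibration` (a [NullCalibration-class]), and `report` (stage counts
#'   and configuration echo).
#' @export
runPipeline <- function(corpus, parts, config = pipelineConfig()) {
  params <- config@alignment
  matches <- .stage("annotate", annotateCorpus(corpus, parts, params,
                                               config@minCoverage))
  observations <- .stage("classify", classifyVariants(matches, parts, corpus))
  groups <- .stage("group", groupVariants(observations))
  cache <- newSegmentCache(corpus, params)
  calibration <- .stage("calibrate", calibrateCutoff(
    corpus, params, nPairs = config@nullPairs, fpRate = config@fpRate,
    seed = config@seed, cache = cache, heuristic = config@dsHeuristic))

  n_groups <- nrow(groups)
  widespread <- logical(n_groups)
  recurrent <- logical(n_groups)
  n_components <- rep(NA_integer_, n_groups)
  tested <- logical(n_groups)
  single_lab_tested <- 0L
  for (i in seq_len(n_groups)) {
    g <- groups[i, , drop = FALSE]
    widespread[i] <- classifyWidespread(g, config)
    res <- .stage("cluster", classifyRecurrent(g, corpus, calibration,
                                               config, cache))
    recurrent[i] <- res$recurrent
    n_components[i] <- res$n_components
    tested[i] <- res$tested
    if (res$tested && g$n_labs == 1L && g$n_observations > 1L) {
      single_lab_tested <- single_lab_tested + 1L
    }
  }
  groups$widespread <- widespread
  groups$recurrent <- recurrent
  groups$n_components <- n_components
  groups$ds_tested <- tested

  sel <- widespread | recurrent
  type_of <- partType(parts)
  catalog <- data.frame(
    variant_id = groups$variant_id[sel], part_id = groups$part_id[sel],
    part_type = unname(type_of[groups$part_id[sel]]),
    variant_sequence = groups$variant_sequence[sel],
    n_observations = groups$n_observations[sel],
    n_labs = groups$n_labs[sel], n_components = groups$n_components[sel],
    widespread = groups$widespread[sel], recurrent = groups$recurrent[sel],
    stringsAsFactors = FALSE)
  catalog <- catalog[order(catalog$part_id, catalog$variant_id), ,
                     drop = FALSE]
  rownames(catalog) <- NULL

  report <- list(
    n_plasmids = corpusSize(corpus),
    n_labs = length(unique(unname(labs(corpus)))),
    n_parts = length(partIDs(parts)),
    n_part_matches = nrow(matches),
    n_variant_observations = nrow(observations),
    n_variant_groups = n_groups,
    n_groups_ds_tested = sum(tested),
    n_single_lab_groups_ds_tested = single_lab_tested,
    n_widespread = sum(widespread),
    n_recurrent = sum(recurrent),
    n_catalog = nrow(catalog),
    ds_cutoff = dsCutoff(calibration),
    null_pairs_used = calibration@nPairs,
    seed = config@seed,
    config = list(
      min_coverage = config@minCoverage,
      min_labs_widespread = config@minLabsWidespread,
      observation_cap = config@observationCap,
      null_pairs = config@nullPairs,
      fp_rate = config@fpRate,
      ds_heuristic = config@dsHeuristic,
      match_reward = params@matchReward,
      mismatch_penalty = params@mismatchPenalty,
      gap_open = params@gapOpen,
      gap_extend = params@gapExtend,
      word_size = params@wordSize,
      min_identity = params@minIdentity,
      max_evalue = params@maxEvalue,
      max_length_diff = params@maxLengthDiff))

  list(catalog = catalog, groups = groups, observations = observations,
       calibration = calibration, report = report)
}
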