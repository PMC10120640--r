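# The synthetic corpus generator and its ground truth.

test_that("part library generation is deterministic and structurally valid", {
  spec <- defaultPartSpec()
  l1 <- generatePartLibrary(spec, seed = 21L)
  l2 <- generatePartLibrary(spec, seed = 21L)
  expect_identical(as.character(sequencesOf(l1)),
                   as.character(sequencesOf(l2)))
  l3 <- generatePartLibrary(spec, seed = 22L)
  expect_false(identical(as.character(sequencesOf(l1)),
                         as.character(sequencesOf(l3))))
  expect_identical(length(partIDs(l1)), nrow(spec))
  expect_false(anyDuplicated(as.character(sequencesOf(l1))) > 0)

  # CDS entries are open reading frames without internal stops
  for (id in partIDs(l1)[unname(isCoding(l1))]) {
    s <- as.character(sequencesOf(l1)[[id]])
    expect_identical(nchar(s) %% 3L, 0L)
    expect_identical(substr(s, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  expect_error(generatePartLibrary(
    data.frame(part_id = "x", part_type = "CDS", role = "cargo",
               length = 3L)), "at least 6")
})

test_that("mutatePart makes exact interior substitution counts", {
  set.seed(801)
  s <- rdna(80)
  expect_identical(mutatePart(s, 0L, seed = 1L), s)
  for (k in 1:3) {
    v <- mutatePart(s, k, seed = k + 5L)
    d <- which(strsplit(s, "")[[1]] != strsplit(v, "")[[1]])
    expect_identical(length(d), as.integer(k))
    expect_true(all(d > 8 & d <= 72))   # edge buffer respected
  }
  # coding: at least one substitution is non-synonymous
  lib <- generatePartLibrary(defaultPartSpec(nCargo = 2L), seed = 3L)
  cds <- as.character(sequencesOf(lib)[["mkr01"]])
  v <- mutatePart(cds, 1L, seed = 9L, coding = TRUE)
  expect_false(identical(
    as.character(Biostrings::translate(Biostrings::DNAString(v))),
    as.character(Biostrings::translate(Biostrings::DNAString(cds)))))
  expect_error(mutatePart("ACGTACGTACGTACGTAC", 5L, seed = 1L), "too short")
})

test_that("generated corpora have the designed shape and are seed-deterministic", {
  des <- simDesign(nLabs = 5L, plasmidsPerLab = 3L, seed = 31L)
  s1 <- generateCorpus(des)
  s2 <- generateCorpus(des)
  expect_identical(as.character(sequencesOf(s1$corpus)),
                   as.character(sequencesOf(s2$corpus)))
  expect_identical(corpusSize(s1$corpus), 15L)
  expect_identical(length(unique(unname(labs(s1$corpus)))), 5L)
  expect_true(all(topologies(s1$corpus) == "circular"))
  s3 <- generateCorpus(simDesign(nLabs = 5L, plasmidsPerLab = 3L,
                                 seed = 32L))
  expect_false(identical(as.character(sequencesOf(s1$corpus)),
                         as.character(sequencesOf(s3$corpus))))
})

test_that("emitted files round-trip through the corpus readers", {
  planted <- list(plantedVariant(nMutations = 2L, originCount = 2L,
                                 carriersPerOrigin = 2L))
  sim <- generateCorpus(small_design(seed = 33L, planted = planted,
                                     nLabs = 4L, plasmidsPerLab = 4L))
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  corp <- readCorpus(file.path(dir, "corpus.fasta"),
                     file.path(dir, "metadata.tsv"))
  expect_identical(as.character(sequencesOf(corp)),
                   as.character(sequencesOf(sim$corpus)))
  expect_identical(labs(corp), labs(sim$corpus))
  lib <- readPartLibrary(file.path(dir, "parts.fasta"))
  expect_identical(as.character(sequencesOf(lib)),
                   as.character(sequencesOf(sim$parts)))
  expect_identical(partType(lib), partType(sim$parts))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(length(truth), nrow(sim$truth))
  expect_identical(truth[[1]]$variant_id, sim$truth$variant_id[1])
})

test_that("planted carriers exist and carry the exact variant sequence", {
  planted <- std_planted_mix()
  sim <- generateCorpus(small_design(seed = 34L, planted = planted))
  seqs <- as.character(sequencesOf(sim$corpus))
  lab_of <- labs(sim$corpus)
  for (i in seq_len(nrow(sim$truth))) {
    carriers <- sim$truth$carriers[[i]]
    expect_true(all(carriers %in% names(seqs)))
    expect_setequal(unique(unname(lab_of[carriers])), sim$truth$labs[[i]])
    hits <- vapply(carriers, function(pl)
      grepl(sim$truth$variant_sequence[i], seqs[[pl]], fixed = TRUE),
      logical(1))
    expect_true(all(hits))
  }
  # origins land on distinct labs for multi-origin variants
  multi <- sim$truth[sim$truth$origin_count > 1, ]
  for (i in seq_len(nrow(multi))) {
    expect_gte(length(multi$labs[[i]]), multi$origin_count[i])
  }
})

test_that("without mutations or planting, variant detection is a clean negative control", {
  des <- simDesign(nLabs = 4L, plasmidsPerLab = 3L, mutationRate = 0,
                   seed = 35L)
  sim <- generateCorpus(des)
  obs <- classifyVariants(annotateCorpus(sim$corpus, sim$parts),
                          sim$parts, sim$corpus)
  expect_identical(nrow(obs), 0L)
  expect_identical(nrow(groupVariants(obs)), 0L)
})

test_that("infeasible designs are refused", {
  expect_error(simDesign(cargoPerPlasmid = 50L), "exceeds")
  expect_error(simDesign(backboneSharing = 1.5), "probability")
  expect_error(plantedVariant(originCount = 2L, copyLabs = 1L), "originCount")
  des <- small_design(seed = 36L, planted = list(
    plantedVariant(originCount = 1L, carriersPerOrigin = 100L)))
  expect_error(generateCorpus(des), "too few free plasmids")
})
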