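# Part annotation and variant calling.

make_lib <- function(seqs, types) PartLibrary(seqs, partType = types)

test_that("an exact part copy annotates with coverage and identity 1", {
  set.seed(601)
  part <- rdna(200)
  lib <- make_lib(c(ori = part), "origin of replication")
  plas <- paste0(rdna(80), part, rdna(90))
  corp <- PlasmidCorpus(c(pl1 = plas), lab = "L", topology = "linear")
  m <- annotatePlasmid(corp, "pl1", lib)
  expect_identical(nrow(m), 1L)
  expect_identical(m$plasmid_start, 80L)
  expect_identical(m$plasmid_end, 280L)
  expect_equal(m$coverage, 1)
  expect_equal(m$identity, 1)
  expect_identical(m$matched_sequence, part)
  expect_true(m$covers_ref_start && m$covers_ref_end)
})

test_that("a 5-prime truncated copy below the coverage threshold is not annotated", {
  set.seed(602)
  part <- rdna(600)
  lib <- make_lib(c(cds = part), "CDS")
  # 40/600 of the 5' end deleted: coverage 560/600 ~ 0.933 < 0.95
  plas <- paste0(rdna(70), substring(part, 41), rdna(70))
  corp <- PlasmidCorpus(c(pl1 = plas), lab = "L", topology = "linear")
  m <- annotatePlasmid(corp, "pl1", lib)
  expect_identical(nrow(m), 0L)
})

test_that("origin-spanning parts on circular plasmids are found once, modulo length", {
  set.seed(603)
  part <- rdna(150)
  lib <- make_lib(c(ori = part), "origin of replication")
  # part split across the sequence origin: last 60 bases at the start
  body <- rdna(400)
  plas <- paste0(substring(part, 91), body, substring(part, 1, 90))
  corp <- PlasmidCorpus(c(pl1 = plas), lab = "L", topology = "circular")
  m <- annotatePlasmid(corp, "pl1", lib)
  expect_identical(nrow(m), 1L)
  L <- nchar(plas)
  expect_identical(m$plasmid_start, 460L)       # within the first copy
  expect_identical(m$plasmid_end, 460L + 150L)  # runs past L on the doubled sequence
  expect_identical(m$matched_sequence, part)
  # the same plasmid linearized loses the wrap-around part
  corp2 <- PlasmidCorpus(c(pl1 = plas), lab = "L", topology = "linear")
  expect_identical(nrow(annotatePlasmid(corp2, "pl1", lib)), 0L)
})

test_that("annotation coordinates agree with the oracle on a small plasmid", {
  set.seed(604)
  part <- rdna(120)
  var <- substitute_bases(part, 2, positions = c(40, 80))
  plas <- paste0(rdna(50), var, rdna(60))
  lib <- make_lib(c(px = part), "promoter")
  corp <- PlasmidCorpus(c(pl = plas), lab = "L", topology = "linear")
  m <- annotatePlasmid(corp, "pl", lib)
  ora <- oracle_local_matches(part, plas, alignmentParams())
  best <- ora[which.max(ora$score), ]
  expect_identical(m$plasmid_start, best$b_start)
  expect_identical(m$plasmid_end, best$b_end)
  expect_equal(m$score, best$score)
})

test_that("variant filters drop silent and terminally deleted coding matches", {
  set.seed(605)
  lib0 <- generatePartLibrary(defaultPartSpec(nCargo = 2L,
                                              markerLength = 900L),
                              seed = 5L)
  cds <- as.character(sequencesOf(lib0)[["mkr01"]])
  lib <- make_lib(c(mkr = cds, ori = rdna(200)),
                  c("CDS", "origin of replication"))

  # synonymous third-position change: CTx codons all encode leucine
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  leu <- which(substr(codons, 1, 2) == "CT")[1]
  expect_false(is.na(leu))
  syn <- cds
  pos <- leu * 3
  substr(syn, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(cds, pos, pos))[1]
  plas_syn <- paste0(rdna(60), syn, rdna(60))

  # 3' deletion: final 30 nt of the 900-nt CDS missing, coverage 0.967
  del <- substring(cds, 1, nchar(cds) - 30)
  plas_del <- paste0(rdna(60), del, rdna(60))

  # non-coding part with one internal substitution: a real variant
  ori <- as.character(sequencesOf(lib)[["ori"]])
  ori_var <- substitute_bases(ori, 1, positions = 100)
  plas_ori <- paste0(rdna(60), ori_var, rdna(60))

  corp <- PlasmidCorpus(
    c(s1 = plas_syn, s2 = plas_del, s3 = plas_ori),
    lab = c("L1", "L2", "L3"), topology = "linear")
  matches <- annotateCorpus(corp, lib)
  obs <- classifyVariants(matches, lib, corp)

  expect_false("s1" %in% obs$plasmid_id)  # amino-acid identical: removed
  expect_false("s2" %in% obs$plasmid_id)  # terminal deletion: removed
  expect_true("s3" %in% obs$plasmid_id)   # passes all filters
  expect_identical(obs$variant_sequence[obs$plasmid_id == "s3"], ori_var)

  # single-match interface agrees
  syn_match <- matches[matches$plasmid_id == "s1", , drop = FALSE]
  expect_null(classifyVariant(syn_match[1, , drop = FALSE], lib))
})

test_that("a non-synonymous coding change is kept and not flagged frameshifted", {
  set.seed(606)
  lib0 <- generatePartLibrary(defaultPartSpec(nCargo = 2L), seed = 7L)
  cds <- as.character(sequencesOf(lib0)[["mkr01"]])
  lib <- make_lib(c(mkr = cds), "CDS")
  var <- mutatePart(cds, 2L, seed = 3L, coding = TRUE)
  corp <- PlasmidCorpus(c(v1 = paste0(rdna(50), var, rdna(50))),
                        lab = "L", topology = "linear")
  obs <- classifyVariants(annotateCorpus(corp, lib), lib, corp)
  expect_identical(nrow(obs), 1L)
  expect_identical(obs$variant_sequence, var)
  expect_false(obs$frameshifted)
})

test_that("grouping keys on exact part and sequence with lab counts", {
  obs <- data.frame(
    plasmid_id = c("a", "b", "c", "d", "e"),
    lab = c("L1", "L1", "L2", "L3", "L3"),
    part_id = c("px", "px", "px", "px", "py"),
    variant_sequence = c("AAAA", "AAAA", "AAAA", "CCCC", "AAAA"),
    frameshifted = FALSE, stringsAsFactors = FALSE)
  g <- groupVariants(obs)
  expect_identical(nrow(g), 3L)
  g1 <- g[g$part_id == "px" & g$variant_sequence == "AAAA", ]
  expect_identical(g1$n_observations, 3L)
  expect_identical(g1$n_labs, 2L)
  expect_setequal(g1$plasmids[[1]], c("a", "b", "c"))
  # same sequence on a different part is a different group
  expect_identical(g$variant_id[g$part_id == "py"],
                   variantId("py", "AAAA"))
  expect_false(variantId("py", "AAAA") == variantId("px", "AAAA"))
  # empty input
  expect_identical(nrow(groupVariants(obs[0, ])), 0L)
})

test_that("reverse-complementing a plasmid leaves variant observations unchanged", {
  set.seed(607)
  part <- rdna(150)
  var <- substitute_bases(part, 1, positions = 70)
  lib <- make_lib(c(px = part), "ncRNA")
  plas <- paste0(rdna(60), var, rdna(80))
  corp <- PlasmidCorpus(c(f = plas, r = revcomp_chr(plas)),
                        lab = c("L", "L"), topology = "linear")
  obs <- classifyVariants(annotateCorpus(corp, lib), lib, corp)
  expect_identical(nrow(obs), 2L)
  expect_identical(obs$variant_sequence[1], obs$variant_sequence[2])
  expect_identical(obs$variant_sequence[1], var)
})

test_that("planting k distinct variants of one part yields exactly k groups", {
  set.seed(608)
  part <- rdna(200)
  lib <- make_lib(c(px = part), "other")
  k <- 4
  vars <- vapply(1:k, function(i)
    substitute_bases(part, 2, positions = sample(10:190, 2)), character(1))
  stopifnot(length(unique(vars)) == k)
  seqs <- stats::setNames(
    vapply(1:k, function(i) paste0(rdna(40), vars[i], rdna(40)),
           character(1)),
    paste0("pl", 1:k))
  corp <- PlasmidCorpus(seqs, lab = paste0("L", 1:k), topology = "linear")
  obs <- classifyVariants(annotateCorpus(corp, lib), lib, corp)
  g <- groupVariants(obs)
  expect_identical(nrow(g), as.integer(k))
  expect_setequal(g$variant_sequence, vars)
  # filter soundness: no group carries the canonical sequence
  expect_false(any(g$variant_sequence == part))
})

test_that("annotation refuses an empty part database", {
  corp <- tiny_corpus(n = 2, len = 100)
  empty <- PartLibrary(character(0), character(0))
  expect_error(annotatePlasmid(corp, "p01", empty), "empty")
})
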