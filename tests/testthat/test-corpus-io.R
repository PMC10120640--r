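# Reading and writing corpora, part databases, and the catalog.

test_that("FASTA + metadata round-trips a corpus exactly", {
  set.seed(101)
  corp <- tiny_corpus(n = 3, len = 120, topology = c("circular", "linear"))
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "c.fasta")
  md <- file.path(dir, "c.tsv")
  writeCorpus(corp, fa, md)
  back <- readCorpus(fa, md)
  expect_equal(corpusSize(back), 3L)
  expect_identical(plasmidIDs(back), plasmidIDs(corp))
  expect_identical(as.character(sequencesOf(back)),
                   as.character(sequencesOf(corp)))
  expect_identical(labs(back), labs(corp))
  expect_identical(topologies(back), topologies(corp))
})

test_that("corpus metadata mismatches are reported by plasmid id", {
  set.seed(102)
  corp <- tiny_corpus(n = 3, len = 100)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "c.fasta")
  md <- file.path(dir, "c.tsv")
  writeCorpus(corp, fa, md)

  # drop one metadata row
  meta <- utils::read.delim(md, colClasses = "character")
  utils::write.table(meta[-2, ], md, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readCorpus(fa, md), "p02")

  # extra row without a record
  meta2 <- rbind(meta, data.frame(plasmid_id = "ghost", lab = "labX",
                                  topology = "linear"))
  utils::write.table(meta2, md, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCorpus(fa, md), "ghost")

  # empty sequence file
  writeLines(character(0), fa)
  utils::write.table(meta, md, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCorpus(fa, md), "empty|no sequence")
})

test_that("GenBank records are parsed and uppercased", {
  set.seed(103)
  s1 <- tolower(rdna(90))
  s2 <- tolower(rdna(45))
  gb <- c(
    "LOCUS       plasA                90 bp    DNA     circular SYN",
    "DEFINITION  synthetic construct.",
    "FEATURES             Location/Qualifiers",
    "     source          1..90",
    "ORIGIN",
    paste("        1", paste(substring(s1, seq(1, 90, 10),
                                       seq(10, 90, 10)), collapse = " ")),
    "//",
    "LOCUS       plasB                45 bp    DNA     linear SYN",
    "ORIGIN",
    paste("        1", paste(substring(s2, c(1, 11, 21, 31, 41),
                                       c(10, 20, 30, 40, 45)),
                             collapse = " ")),
    "//")
  dir <- withr::local_tempdir()
  gbf <- file.path(dir, "two.gb")
  writeLines(gb, gbf)
  md <- file.path(dir, "m.tsv")
  utils::write.table(
    data.frame(plasmid_id = c("plasA", "plasB"), lab = c("l1", "l2"),
               topology = c("circular", "linear")),
    md, sep = "\t", quote = FALSE, row.names = FALSE)
  corp <- readCorpus(gbf, md)
  expect_identical(plasmidIDs(corp), c("plasA", "plasB"))
  expect_identical(as.character(sequencesOf(corp)[["plasA"]]), toupper(s1))
  expect_identical(as.character(sequencesOf(corp)[["plasB"]]), toupper(s2))
})

test_that("part FASTA headers encode id and type; bad input errors", {
  set.seed(104)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "parts.fasta")
  writeLines(c(">bla|CDS", rdna(60), ">ColE1|origin of replication",
               rdna(80)), fa)
  lib <- readPartLibrary(fa)
  expect_identical(partIDs(lib), c("bla", "ColE1"))
  expect_true(unname(isCoding(lib)["bla"]))
  expect_false(unname(isCoding(lib)["ColE1"]))

  writeLines(c(">nopipe", rdna(30)), fa)
  expect_error(readPartLibrary(fa), "delimiter")
  writeLines(c(">x|mystery part", rdna(30)), fa)
  expect_error(readPartLibrary(fa), "unknown part type")
  writeLines(c(">x|promoter", rdna(30), ">x|promoter", rdna(30)), fa)
  expect_error(readPartLibrary(fa), "duplicate")
})

test_that("ambiguity codes other than N are rejected at read time", {
  expect_error(PlasmidCorpus(c(p1 = "ACGTRY"), lab = "l"), "A/C/G/T/N")
  expect_silent(PlasmidCorpus(c(p1 = "ACGTNN"), lab = "l"))
})

test_that("catalog output is byte-deterministic and sorted", {
  entries <- data.frame(
    variant_id = c("v2", "v1"), part_id = c("pB", "pA"),
    part_type = c("promoter", "CDS"), variant_sequence = c("ACGT", "TTTT"),
    n_observations = c(5L, 2L), n_labs = c(3L, 2L),
    n_components = c(NA_integer_, 2L), widespread = c(TRUE, FALSE),
    recurrent = c(FALSE, TRUE), stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "cat1.tsv")
  f2 <- file.path(dir, "cat2.tsv")
  writeCatalog(entries, f1)
  writeCatalog(entries[c(2, 1), ], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  tab <- utils::read.delim(f1, colClasses = "character")
  expect_identical(tab$part_id, c("pA", "pB"))       # sorted
  expect_identical(tab$n_components[2], "not-tested")
  # empty catalog: header only
  f3 <- file.path(dir, "cat3.tsv")
  writeCatalog(entries[0, ], f3)
  expect_identical(length(readLines(f3)), 1L)
})
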