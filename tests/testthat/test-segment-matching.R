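# Shared-segment search, frequency queries, and the DS input builder.

test_that("a planted 50-bp block with one substitution passes at the 98% identity boundary", {
  set.seed(301)
  # identity 49/50 = 0.98 exactly: must pass (inclusive boundary)
  for (rep in 1:5) {
    blk <- rdna(50)
    mid <- substitute_bases(blk, 1, positions = 25)
    a <- with_block(300, blk, 100)
    b <- with_block(300, mid, 150)
    seg <- findSharedSegments(a, b)
    hit <- seg[seg$a_start <= 100 & seg$a_end >= 150, , drop = FALSE]
    expect_equal(nrow(hit), 1L)
    expect_gte(hit$identity, 0.98)
  }
})

test_that("two substitutions in a 50-bp block fail the identity filter", {
  set.seed(302)
  for (rep in 1:5) {
    blk <- rdna(50)
    # identity 48/50 = 0.96 < 0.98: the block itself must not be reported;
    # only clean sub-pieces could be, and those are shorter than 28 bp
    mid <- substitute_bases(blk, 2, positions = c(17, 34))
    a <- with_block(300, blk, 100)
    b <- with_block(300, mid, 150)
    seg <- findSharedSegments(a, b)
    expect_false(any(seg$a_start <= 101 & seg$a_end >= 149))
  }
})

test_that("segment search equals the exhaustive full-matrix oracle on random planted pairs", {
  set.seed(303)
  p <- alignmentParams()
  for (iter in 1:25) {
    La <- sample(120:300, 1)
    Lb <- sample(120:300, 1)
    blk <- rdna(sample(28:60, 1))
    mut <- sample(0:2, 1)
    blk2 <- if (mut) substitute_bases(blk, mut) else blk
    if (runif(1) < 0.3) blk2 <- revcomp_chr(blk2)
    a <- with_block(La, blk, sample(0:(La - nchar(blk)), 1))
    b <- with_block(Lb, blk2, sample(0:(Lb - nchar(blk2)), 1))
    eng <- findSharedSegments(a, b, p)
    ora <- oracle_shared_segments(a, b, p)
    expect_identical(nrow(eng), nrow(ora))
    if (nrow(eng)) {
      expect_equal(eng$a_start, ora$a_start)
      expect_equal(eng$a_end, ora$a_end)
      expect_equal(eng$b_start, ora$b_start)
      expect_equal(eng$b_end, ora$b_end)
      expect_equal(eng$score, ora$score)
      expect_identical(eng$sequence, ora$sequence)
    }
  }
})

test_that("segment frequency counts plasmids, not hits, and respects containment", {
  set.seed(304)
  seg <- rdna(60)
  seqs <- c(
    p1 = with_block(300, seg, 20),
    p2 = with_block(300, seg, 200),
    # two copies in one plasmid: counts once
    p3 = paste0(rdna(40), seg, rdna(60), seg, rdna(40)),
    # reverse complement counts
    p4 = with_block(300, revcomp_chr(seg), 100),
    # half the segment only: does not contain it
    p5 = with_block(300, substr(seg, 1, 30), 100),
    p6 = rdna(300))
  corp <- PlasmidCorpus(seqs, lab = rep(c("A", "B"), 3), topology = "linear")
  expect_identical(segmentFrequency(seg, corp), 4L)
})

test_that("frequency agrees with the oracle on small random corpora", {
  set.seed(305)
  p <- alignmentParams()
  for (iter in 1:8) {
    seg <- rdna(sample(40:70, 1))
    seqs <- vapply(1:10, function(i) {
      s <- rdna(260)
      if (runif(1) < 0.5) {
        segi <- if (runif(1) < 0.4) substitute_bases(seg, 1) else seg
        if (runif(1) < 0.3) segi <- revcomp_chr(segi)
        pos <- sample(0:(260 - nchar(segi)), 1)
        substr(s, pos + 1, pos + nchar(segi)) <- segi
      }
      s
    }, character(1))
    names(seqs) <- paste0("p", 1:10)
    corp <- PlasmidCorpus(seqs, lab = rep(c("A", "B"), 5),
                          topology = "linear")
    expect_identical(segmentFrequency(seg, corp, p),
                     oracle_segment_frequency(seg, seqs, p))
  }
})

test_that("segment search is symmetric for exactly shared blocks", {
  set.seed(306)
  blk <- rdna(60)
  a <- with_block(250, blk, 40)
  b <- with_block(250, blk, 160)
  sab <- findSharedSegments(a, b)
  sba <- findSharedSegments(b, a)
  expect_identical(sort(sab$sequence), sort(sba$sequence))
  expect_identical(sab$a_start, sba$b_start)
  expect_identical(sab$b_start, sba$a_start)
})

test_that("adding a carrier plasmid never decreases a segment's frequency", {
  set.seed(307)
  seg <- rdna(50)
  base <- c(p1 = with_block(250, seg, 30), p2 = with_block(250, seg, 90),
            p3 = rdna(250))
  c1 <- PlasmidCorpus(base, lab = c("A", "B", "A"), topology = "linear")
  f1 <- segmentFrequency(seg, c1)
  c2 <- PlasmidCorpus(c(base, p4 = with_block(250, seg, 10)),
                      lab = c("A", "B", "A", "B"), topology = "linear")
  f2 <- segmentFrequency(seg, c2)
  expect_gte(f2, f1)
  expect_identical(f2, f1 + 1L)
})

test_that("segment sets have ascending x with every frequency in [2, p]", {
  des <- small_design(seed = 31L, nLabs = 4L, plasmidsPerLab = 4L)
  sim <- generateCorpus(des)
  corp <- sim$corpus
  cache <- newSegmentCache(corp)
  ids <- plasmidIDs(corp)
  set.seed(308)
  for (iter in 1:6) {
    ab <- sample(ids, 2)
    ss <- buildSegmentSet(ab[1], ab[2], corp, cache = cache)
    x <- segmentFrequencies(ss)
    expect_false(is.unsorted(x))
    if (length(x)) {
      expect_true(all(x >= 2L))
      expect_true(all(x <= corpusSize(corp)))
    }
  }
})

test_that("frequency queries are cached per segment sequence", {
  set.seed(309)
  seg1 <- rdna(50)
  seg2 <- rdna(50)
  corp <- PlasmidCorpus(
    c(p1 = with_block(250, seg1, 10), p2 = with_block(250, seg1, 50),
      p3 = with_block(250, seg2, 80), p4 = with_block(250, seg2, 120)),
    lab = c("A", "B", "A", "B"), topology = "linear")
  cache <- newSegmentCache(corp)
  segmentFrequency(seg1, cache = cache)
  expect_identical(cache$queries, 1L)
  segmentFrequency(seg1, cache = cache)     # cached: no new computation
  expect_identical(cache$queries, 1L)
  segmentFrequency(seg2, cache = cache)
  expect_identical(cache$queries, 2L)
})
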