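# The Design Similarity score.

# straight-line transcription of the scoring rule, kept deliberately
# independent of the package implementation
ds_reference <- function(x, p, ratio = FALSE) {
  n <- length(x)
  if (n == 0) return(-Inf)
  x <- sort(x)
  total <- log(p / x[1])
  if (n > 1) {
    extra <- 0
    for (i in 2:n) {
      extra <- extra + (if (ratio) p / x[i] else log(p / x[i]))
    }
    total <- total + extra / n
  }
  total
}

test_that("closed-form cases evaluate exactly", {
  expect_identical(dsScore(c(200), 200), 0)          # ubiquitous segment
  expect_equal(dsScore(c(2), 200), log(100))
  expect_equal(dsScore(c(2, 10, 100), 1000),
               log(500) + (log(100) + log(10)) / 3)
  expect_equal(dsScore(c(2, 10, 100), 1000), 8.51719, tolerance = 1e-5)
  expect_identical(dsScore(integer(0), 500), -Inf)
  expect_lt(-Inf, dsScore(c(1000), 1000))  # sentinel below any finite score
})

test_that("invalid frequency vectors are rejected", {
  expect_error(dsScore(c(10, 2), 100), "sorted")
  expect_error(dsScore(c(1, 5), 100), ">= 2")
  expect_error(dsScore(c(2, 200), 100), "exceed")
  expect_error(dsScore(c(2.5), 100), "integer")
  expect_error(dsScore(c(2), 1), "p must")
})

test_that("score matches the independent evaluator on random instances", {
  set.seed(401)
  for (i in 1:1000) {
    p <- sample(10:100000, 1)
    n <- sample(1:12, 1)
    x <- sort(sample(2:p, n, replace = TRUE))
    a <- dsScore(x, p)
    b <- ds_reference(x, p)
    expect_equal(a, b, tolerance = 1e-12)
    r1 <- dsScore(x, p, heuristic = "ratio")
    r2 <- ds_reference(x, p, ratio = TRUE)
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("rarer rarest segment strictly increases the score", {
  set.seed(402)
  for (i in 1:50) {
    p <- sample(100:5000, 1)
    rest <- sort(sample(5:p, sample(0:6, 1), replace = TRUE))
    x1 <- sample(3:4, 1)
    lo <- dsScore(sort(c(x1, rest)), p)
    hi <- dsScore(sort(c(2, rest)), p)
    expect_gt(hi, lo)
  }
})

test_that("score is invariant under common rescaling of p and x", {
  set.seed(403)
  for (i in 1:30) {
    p <- sample(50:500, 1)
    x <- sort(sample(2:p, sample(1:6, 1), replace = TRUE))
    k <- sample(2:20, 1)
    expect_equal(dsScore(x, p), dsScore(x * k, p * k), tolerance = 1e-12)
  }
})

test_that("extra segments move the heuristic term toward their own IDF value", {
  set.seed(404)
  p <- 1000
  for (i in 1:30) {
    x <- sort(sample(2:p, sample(2:8, 1), replace = TRUE))
    rest_terms <- log(p / x[-1])
    mean_term <- sum(rest_terms) / length(x)
    # adding a segment rarer than the current mean raises the heuristic term
    x_rare <- sort(c(x, 2))
    heur <- function(v) dsScore(v, p) - log(p / v[1])
    if (log(p / 2) > mean_term && x_rare[1] == x[1]) {
      expect_gt(heur(x_rare), heur(x))
    }
    # adding a ubiquitous segment (IDF 0 < mean) lowers it
    x_common <- sort(c(x, p))
    if (mean_term > 0) expect_lt(heur(x_common), heur(x))
  }
})

test_that("pairwise DS matrices are symmetric with the diagonal excluded", {
  set.seed(405)
  blk <- rdna(60)
  seqs <- c(p1 = with_block(300, blk, 20), p2 = with_block(300, blk, 120),
            p3 = with_block(300, blk, 200), p4 = rdna(300))
  corp <- PlasmidCorpus(seqs, lab = c("A", "B", "C", "D"),
                        topology = "linear")
  grp <- list(plasmids = list(c("p1", "p2", "p3")), n_observations = 3L)
  mat <- pairwiseDS(grp, corp)
  expect_true(all(is.na(diag(mat))))
  expect_identical(mat[upper.tri(mat)], t(mat)[upper.tri(mat)])
  expect_true(all(is.finite(mat[upper.tri(mat)])))
  # a pair with no shared segment scores the no-evidence sentinel
  grp2 <- list(plasmids = list(c("p1", "p4")), n_observations = 2L)
  mat2 <- pairwiseDS(grp2, corp)
  expect_identical(mat2["p1", "p4"], -Inf)
})

test_that("groups above the observation cap are refused by name", {
  corp <- tiny_corpus(n = 4, len = 200)
  grp <- list(plasmids = list(c("p01", "p02")), n_observations = 2000L)
  expect_error(pairwiseDS(grp, corp, observationCap = 1205L), "1205")
})
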