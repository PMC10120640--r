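# Independent full-matrix reference implementation of the shared-segment
# search, used as the oracle for engine-equivalence tests. Exhaustive
# affine-gap Smith-Waterman over the complete dynamic-programming matrix
# (no seeding, no banding), with the declared deterministic extraction
# rules: endpoints processed by (score desc, i asc, j asc), tie preference
# diagonal > vertical > horizontal (open preferred over extend), and
# Waterman-Eggert cell-disjointness on substitution columns.

.oenc <- function(s) {
  v <- utf8ToInt(toupper(s))
  out <- rep(4L, length(v))
  out[v == utf8ToInt("A")] <- 0L
  out[v == utf8ToInt("C")] <- 1L
  out[v == utf8ToInt("G")] <- 2L
  out[v == utf8ToInt("T")] <- 3L
  out
}

.orc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# all maximal local alignments of one orientation; returns a data.frame in
# 0-based half-open coordinates of (a, b_or)
.oracle_orientation <- function(ea, eb, match, mismatch, go, ge, min_score,
                                xdrop = 0L) {
  m <- length(ea)
  n <- length(eb)
  NEG <- -1e9
  H <- matrix(0, m, n)
  E <- matrix(NEG, m, n)
  F <- matrix(NEG, m, n)
  PH <- matrix(0L, m, n)
  PE <- matrix(0L, m, n)
  PF <- matrix(0L, m, n)
  for (k in 2:(m + n)) {
    ii <- max(1L, k - n):min(m, k - 1L)
    jj <- k - ii
    cells <- cbind(ii, jj)
    left_ok <- jj > 1L
    Hl <- rep(NEG, length(ii)); El <- rep(NEG, length(ii))
    if (any(left_ok)) {
      lcells <- cbind(ii[left_ok], jj[left_ok] - 1L)
      Hl[left_ok] <- H[lcells]
      El[left_ok] <- E[lcells]
    }
    e_open <- ifelse(Hl <= NEG, NEG, Hl - go - ge)
    e_ext <- ifelse(El <= NEG, NEG, El - ge)
    e <- pmax(e_open, e_ext)
    E[cells] <- e
    PE[cells] <- ifelse(e_open >= e_ext, 0L, 1L)

    up_ok <- ii > 1L
    Hu <- rep(NEG, length(ii)); Fu <- rep(NEG, length(ii))
    if (any(up_ok)) {
      ucells <- cbind(ii[up_ok] - 1L, jj[up_ok])
      Hu[up_ok] <- H[ucells]
      Fu[up_ok] <- F[ucells]
    }
    f_open <- ifelse(Hu <= NEG, NEG, Hu - go - ge)
    f_ext <- ifelse(Fu <= NEG, NEG, Fu - ge)
    f <- pmax(f_open, f_ext)
    F[cells] <- f
    PF[cells] <- ifelse(f_open >= f_ext, 0L, 1L)

    sub <- ifelse(ea[ii] == eb[jj] & ea[ii] < 4L, match, mismatch)
    diag_ok <- ii > 1L & jj > 1L
    Hd <- rep(0, length(ii))
    if (any(diag_ok)) Hd[diag_ok] <- H[cbind(ii[diag_ok] - 1L, jj[diag_ok] - 1L)]
    dg <- Hd + sub

    best <- rep(0, length(ii)); ptr <- rep(0L, length(ii))
    upd <- e > best; best[upd] <- e[upd]; ptr[upd] <- 2L
    upd <- f >= best & f > 0; best[upd] <- f[upd]; ptr[upd] <- 3L
    upd <- dg >= best & dg > 0; best[upd] <- dg[upd]; ptr[upd] <- 1L
    H[cells] <- best
    PH[cells] <- ptr
  }

  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      score = integer(0), matches = integer(0),
                      mismatches = integer(0), gapcols = integer(0))
  cand <- which(H >= min_score, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  sc <- H[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used <- matrix(FALSE, m, n)
  res <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    state <- 0L
    # alignment columns collected end -> start: (i, j, type, score) with
    # type 0 substitution, 1 gap-in-a, 2 gap-in-b
    ci <- integer(0); cj <- integer(0); ct <- integer(0); cs <- integer(0)
    cells <- matrix(0L, 0, 2)
    rejected <- FALSE
    repeat {
      if (state == 0L) {
        p <- PH[i, j]
        if (p == 0L) break
        if (p == 1L) {
          if (used[i, j]) { rejected <- TRUE; break }
          cells <- rbind(cells, c(i, j))
          is_match <- ea[i] == eb[j] && ea[i] < 4L
          ci <- c(ci, i); cj <- c(cj, j); ct <- c(ct, 0L)
          cs <- c(cs, if (is_match) match else mismatch)
          i <- i - 1L; j <- j - 1L
          if (i < 1L || j < 1L) break
        } else if (p == 2L) state <- 1L else state <- 2L
      } else if (state == 1L) {
        ext <- PE[i, j]
        ci <- c(ci, i); cj <- c(cj, j); ct <- c(ct, 1L)
        cs <- c(cs, if (ext == 1L) -ge else -(go + ge))
        j <- j - 1L
        state <- if (ext == 1L) 1L else 0L
      } else {
        ext <- PF[i, j]
        ci <- c(ci, i); cj <- c(cj, j); ct <- c(ct, 2L)
        cs <- c(cs, if (ext == 1L) -ge else -(go + ge))
        i <- i - 1L
        state <- if (ext == 1L) 2L else 0L
      }
    }
    if (rejected) next
    if (nrow(cells)) used[cells] <- TRUE
    # to sequence order
    ord2 <- rev(seq_along(ci))
    ci <- ci[ord2]; cj <- cj[ord2]; ct <- ct[ord2]; cs <- cs[ord2]
    spans <- if (xdrop > 0L) {
      .oracle_xdrop_split(cs, xdrop)
    } else if (length(cs)) {
      matrix(c(1L, length(cs)), 1)
    } else {
      matrix(integer(0), 0, 2)
    }
    for (si in seq_len(nrow(spans))) {
      u <- spans[si, 1]; v <- spans[si, 2]
      tt <- ct[u:v]; ss <- cs[u:v]
      score <- sum(ss)
      if (score < min_score) next
      ai <- ci[u:v][tt != 1L]; bj <- cj[u:v][tt != 2L]
      res[[length(res) + 1L]] <- data.frame(
        a_start = min(ai) - 1L, a_end = max(ai), b_start = min(bj) - 1L,
        b_end = max(bj), score = score,
        matches = sum(tt == 0L & ss > 0L),
        mismatches = sum(tt == 0L & ss < 0L), gapcols = sum(tt != 0L))
    }
  }
  do.call(rbind, c(res, list(empty)))
}

# split a column-score sequence at score dips deeper than xdrop (running
# score resets at zero; segments end at their running maximum)
.oracle_xdrop_split <- function(s, xdrop) {
  spans <- matrix(integer(0), 0, 2)
  anchor <- 1L; cum <- 0; best <- 0; bestpos <- 0L
  for (t in seq_along(s)) {
    cum <- cum + s[t]
    if (cum <= 0) {
      if (bestpos >= anchor) spans <- rbind(spans, c(anchor, bestpos))
      anchor <- t + 1L; cum <- 0; best <- 0; bestpos <- 0L
      next
    }
    if (cum > best) { best <- cum; bestpos <- t }
    if (best - cum > xdrop) {
      if (bestpos >= anchor) spans <- rbind(spans, c(anchor, bestpos))
      anchor <- t + 1L; cum <- 0; best <- 0; bestpos <- 0L
    }
  }
  if (bestpos >= anchor) spans <- rbind(spans, c(anchor, bestpos))
  spans
}

oracle_local_matches <- function(a, b, params, min_score = NULL,
                                 xdrop = 0L) {
  if (is.null(min_score)) min_score <- params@wordSize * params@matchReward
  ea <- .oenc(a)
  out <- list()
  fwd <- .oracle_orientation(ea, .oenc(b), params@matchReward,
                             params@mismatchPenalty, params@gapOpen,
                             params@gapExtend, min_score, xdrop)
  if (nrow(fwd)) fwd$strand <- "+"
  rev <- .oracle_orientation(ea, .oenc(.orc(b)), params@matchReward,
                             params@mismatchPenalty, params@gapOpen,
                             params@gapExtend, min_score, xdrop)
  if (nrow(rev)) {
    n <- nchar(b)
    bs <- n - rev$b_end
    be <- n - rev$b_start
    rev$b_start <- bs
    rev$b_end <- be
    rev$strand <- "-"
  }
  out <- rbind(fwd, rev)
  if (nrow(out) == 0L) out$strand <- character(0)
  out
}

# the three segment filters + containment suppression, mirroring the
# documented contract (independent reimplementation)
oracle_shared_segments <- function(a, b, params) {
  hits <- oracle_local_matches(a, b, params, xdrop = params@xDrop)
  ka <- karlinAltschulParams(params@matchReward, params@mismatchPenalty)
  if (nrow(hits)) {
    aspan <- hits$a_end - hits$a_start
    bspan <- hits$b_end - hits$b_start
    cols <- hits$matches + hits$mismatches + hits$gapcols
    ev <- ka$K * nchar(a) * nchar(b) * exp(-ka$lambda * hits$score)
    keep <- aspan >= params@wordSize &
      abs(aspan - bspan) <= params@maxLengthDiff &
      hits$matches >= params@minIdentity * cols &
      ev <= params@maxEvalue
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits) > 1L) {
    len <- hits$a_end - hits$a_start
    drop <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
      for (j in seq_len(nrow(hits))) {
        if (i == j || drop[j]) next
        if (len[j] > len[i] &&
            hits$a_start[i] >= hits$a_start[j] &&
            hits$a_end[i] <= hits$a_end[j] &&
            hits$b_start[i] >= hits$b_start[j] &&
            hits$b_end[i] <= hits$b_end[j]) {
          drop[i] <- TRUE
          break
        }
      }
    }
    hits <- hits[!drop, , drop = FALSE]
  }
  hits <- hits[order(hits$a_start, hits$b_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits$sequence <- if (nrow(hits)) {
    substring(a, hits$a_start + 1L, hits$a_end)
  } else {
    character(0)
  }
  hits
}

oracle_segment_frequency <- function(sequence, corpus_seqs, params) {
  count <- 0L
  for (s in corpus_seqs) {
    seg <- oracle_shared_segments(sequence, s, params)
    # containment: the match must span the query segment within the
    # length-difference allowance
    keep <- (seg$a_end - seg$a_start) >=
      nchar(sequence) - params@maxLengthDiff
    if (any(keep)) count <- count + 1L
  }
  count
}
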