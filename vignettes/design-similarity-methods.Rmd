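---
title: "Classifying genetic part variants by Design Similarity: models and methods"
author: "plasmidDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying genetic part variants by Design Similarity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidDS)
```

## The problem

Engineered plasmids are assembled from a shared vocabulary of genetic parts
— origins of replication, antibiotic-resistance markers, promoters,
fluorescent proteins — and those parts are copied from plasmid to plasmid
with little sequence verification. Fully sequenced plasmid collections
reveal large numbers of *part variants*: observed part sequences that cover
a canonical database entry almost completely but differ from it at one or a
few positions. A variant can be an undocumented engineered allele, a
mutation inherited silently through years of subcloning, or a one-off
accident of the last transformation. Only the first two kinds are worth
cataloguing; the challenge is separating them from one-off noise without
any provenance records.

`plasmidDS` implements a complete decision procedure over a plasmid corpus
with depositor metadata:

1. **Annotate** canonical parts on every plasmid (gapped local alignment,
   coverage ≥ 95 % of the part length).
2. **Call variants**: discard matches identical to the canonical sequence
   at the nucleotide level or — for coding parts — at the protein level, and
   coding matches that fail to reach the first or last reference base
   (local alignment cannot distinguish a true terminal deletion from a
   clipped match, so both are excluded).
3. **Group** identical variants across the corpus by exact
   `(part, sequence)`.
4. **Classify** every group as *widespread* (deposited by at least 20
   distinct labs) and/or *recurrent* (its carriers fall into two or more
   relatedness clusters, suggesting independent origins by convergent
   engineering or evolution).

## The Design Similarity score

Recurrence detection needs a measure of whether two plasmids carrying the
same variant share a construction history. Raw sequence identity is a poor
measure: two unrelated plasmids can share most of their length simply
because both use the most popular backbone. Instead, each pair of plasmids
is reduced to its set of shared segments, and each segment is weighted by
its rarity in the corpus, in direct analogy to inverse document frequency
in text retrieval: a segment found in every plasmid carries no authorship
information, while a rare cloning scar is a strong signature.

Given the corpus frequencies $x_1 \le x_2 \le \dots \le x_n$ of the $n$
segments shared by a pair, and the corpus size $p$:

$$\mathrm{DS} = \ln\frac{p}{x_1} \;+\; \frac{1}{n}\sum_{i=2}^{n} \ln\frac{p}{x_i}$$

The first term is the log inverse frequency of the *rarest* shared
segment; the second is an extra-score heuristic that credits additional
shared context at a discounted, averaged weight. A pair sharing no
qualifying segment has no evidence of relatedness and scores $-\infty$,
below every finite score. Natural logarithms are used throughout; since
the decision threshold is a quantile of the same score distribution, the
base is a pure rescaling and has no effect on any decision.

Two properties shape the score's behaviour. Decreasing $x_1$ strictly
increases DS (rarity of the strongest signal dominates), and multiplying
$p$ and every $x_i$ by a common factor leaves DS unchanged (corpus-size
invariance), so scores are comparable across corpora of different sizes
with similar composition. The extra term is an average rather than a sum,
so piling up common segments cannot masquerade as one rare segment. The
rendered form of the extra term is ambiguous in one respect — whether the
logarithm applies inside the sum. We apply it per segment (an average of
per-segment IDF weights): without the logarithm a single moderately rare
segment in the heuristic term would dwarf the leading term by orders of
magnitude, which contradicts the score's IDF framing. The unlogged variant
remains available (`dsScore(..., heuristic = "ratio")`) for sensitivity
analysis.

```{r ds}
dsScore(c(2), 200)            # one segment found nowhere else: ln(100)
dsScore(c(2, 10, 100), 1000)  # rare lead segment plus discounted extras
dsScore(c(200), 200)          # a ubiquitous segment carries no signal
```

## Shared segments

Segments are maximal gapped local alignments between two plasmid
sequences under a scoring scheme chosen to favour long, contiguous,
nearly exact matches: match +2, mismatch −8, gap open 4, gap extend 6,
word size 28. A reported segment must reach 98 % nucleotide identity, an
E-value of at most $10^{-5}$, and an aligned-span length difference of at
most 10 bp — effectively near-ungapped matches. Segments shorter than the
word size are unreportable by construction, and segments wholly contained
in a longer reported segment of the same pair are suppressed so the same
stretch of context is not counted twice.

The engine is a banded affine-gap Smith–Waterman with exact 14-mer
seeding. Seeding is lossless for this filter set: any alignment of at
least 28 columns at ≥ 98 % identity contains a maximal exact run of at
least 24 bp, so every qualifying segment seeds. Alignments are extracted
from the scoring matrix deterministically — endpoints in score order with
fixed tie-breaking, Waterman–Eggert cell-disjointness between accepted
alignments — and each accepted alignment is then decomposed at internal
score dips deeper than an X-drop threshold (default 50). The
decomposition matters: without it, two identical parts separated by
different 40-bp cloning scars on the two plasmids would fuse into one
long, low-identity alignment and be discarded wholesale, whereas a seeded
aligner terminates extension at such dips and reports the parts
individually. The test suite holds the engine to exact agreement with an
independently coded full-matrix reference implementation on randomized
planted-segment instances, including the identity and length-difference
boundaries.

Each segment is then queried against the whole corpus: its frequency
$x_i$ is the number of distinct plasmids containing a match to the
segment that passes the same filters *and spans the segment within the
10-bp length-difference allowance*. The spanning requirement implements
"contains the segment": without it, a plasmid matching any 28-bp corner
of a long segment would count, and the frequency of a rare plasmid-length
segment would collapse to the frequency of its commonest piece. A plasmid
containing the segment twice counts once; reverse-complement matches
count. Frequencies are cached per segment sequence across all pairs of a
run, and a corpus-wide 14-mer index skips plasmids that cannot contain a
qualifying match.

The E-value uses the Karlin–Altschul extreme-value model
$E = K m n e^{-\lambda S}$ with $\lambda$ solved numerically from the
moment condition of the score distribution at uniform base composition
($\lambda \approx 0.692$ for the default scheme) and $K$ computed from
the lattice-case series of the score random walk ($K \approx 0.74$).
These are ungapped statistics applied to near-ungapped alignments; the
approximation is not load-bearing, because any segment of reportable
length sits many orders of magnitude below the $10^{-5}$ threshold — the
binding filters are identity and length.

## Calibrating the relatedness cutoff

The DS threshold separating "plausibly related" from "background" is
calibrated on the corpus itself: 100,000 random plasmid pairs whose
depositors differ (fewer if fewer exist, in which case all cross-lab
pairs are used) are scored, and the cutoff is set at the nearest-rank
upper 95th percentile of this null distribution, i.e. the score exceeded
by 5 % of nominally unrelated pairs. Nearest-rank is parameter-free and
conservative; no-evidence pairs enter the null as $-\infty$. Pairs are
drawn uniformly without replacement under a fixed seed, so calibration is
reproducible. The cross-lab restriction only *reduces* shared history in
the null — labs do adopt one another's backbones — so the null's upper
tail is genuinely occupied by related pairs, and the resulting cutoff
sits above ordinary common-part sharing.

For every variant group small enough to test (at most 1205 observations
by default — the cap is configuration, reflecting that pairwise scoring
grows quadratically in group size), the pairwise DS matrix over its
distinct carrier plasmids is binarized at the cutoff (boundary inclusive;
the sentinel never forms an edge) and the connected components of the
resulting graph are counted. Each component is interpreted as one
independent origin of the variant; two or more components flag the
variant as recurrent. Groups above the cap fall back to the
widespread-only rule. Single-lab multi-plasmid groups are tested like any
other group — recurrence within one lab is still informative — and the
run report counts how many such groups were tested.

## The synthetic corpus generator

Real repository corpora cannot ship with a package, and no external
corpus comes with known ground truth for variant origins. The generator
(`simDesign()`, `generateCorpus()`) therefore emulates the structural
features that make authorship inference possible, with every planted
variant's origin count recorded:

* a shared **part library** (three origin types, three CDS markers, ten
  cargo parts of mixed categories, 180–250 bp) — cargo parts are common
  (five per plasmid) so sharing them carries little signal;
* **lab backbones**: each lab uses one origin type, one marker type, and
  a lab-unique 150-bp spacer standing in for accumulated cloning scars;
  spacer frequency (one lab's plasmids) is the same-lab relatedness
  signal;
* **backbone adoption**: a fraction of labs (default 0.3) build on
  another lab's backbone verbatim, contaminating the cross-lab null with
  genuinely related pairs exactly as real repositories do — this is what
  places the calibrated cutoff *above* ordinary common-part sharing;
* **plasmid-unique scar spacers** (30–50 bp) between elements, and
  **whole-plasmid copying** between labs for the copied-lineage scenario,
  in which the copy carries the source's backbone, cargo, scars, and lab
  spacer;
* **planted variants**: each variant is one mutated cargo part (default
  two substitutions, placed at least 8 bp from the part ends because
  local alignment clips terminal mismatches, and non-synonymous when the
  part is coding so the variant survives the protein-identity filter).
  Independent origins are independent cloning events that happen to
  produce the *same* variant sequence — convergence — in labs engineered
  to share only ubiquitous parts; each origin's carriers share
  origin-specific 50-bp flanking scars, while carriers of different
  origins share nothing rarer than library parts. This is precisely the
  signal/noise contrast the DS procedure must resolve;
* **background substitutions** at 0.004 per base on every plasmid
  (planted variant instances exempted so ground truth stays exact). The
  rate keeps copies of a part within the 98 % identity tolerance of one
  another while spreading segment frequencies enough that the null DS
  distribution is effectively continuous near its 95th percentile —
  parts are long enough (≥ 180 bp) that a variant's few substitutions
  plus background noise stay well inside the tolerance, so the variant
  sequence itself carries no spurious rarity signal between unrelated
  carriers.

What the generator does **not** emulate: indel variants (substitutions
only), realistic mutation spectra, selection and copy-number effects,
part-family homology (all parts are random sequences, so there are no
partially homologous database entries), and repeated parts within one
plasmid. Passing tests on synthetic corpora therefore demonstrate that
the procedure recovers planted provenance structure under controlled
conditions, not that any particular false-positive rate holds on real
repository data.

## Numerical and design choices

* **Determinism**: all scores are integers inside the engine; candidate
  endpoints are processed in (score, row, column) order with a declared
  diagonal > vertical > horizontal tie preference; every random draw in
  the package flows from one root seed through a declared splitting
  scheme. Two runs with the same inputs and seed produce byte-identical
  catalogs.
* **Circular plasmids** are annotated against the sequence doubled back
  on itself, with duplicate matches removed modulo the plasmid length, so
  parts spanning the sequence origin are recovered exactly once.
* **Variant identity** is a stable 64-bit content hash of
  `(part id, variant sequence)`, reproducible across runs and corpora.
* **Frame handling**: translation-level comparison anchors the reading
  frame at the aligned reference start and trims the trailing partial
  codon; a coding match whose length is incompatible with the frame is
  kept and flagged `frameshifted` rather than silently dropped — only
  terminal deletions are excluded by rule.
* **Degenerate inputs**: `N` bases never match and never seed; empty
  part databases, single-lab corpora (no null to calibrate), and
  above-cap groups produce immediate, named errors or declared
  fallbacks.
* **Problem sizes in the shipped tests** were chosen for a desktop-scale
  run: the null-calibration study uses a 10 × 20-plasmid corpus (18,000
  cross-lab pairs), and the origin-recovery study uses fifty 6 × 7
  corpora with ten planted variants each. These sizes give the binomial
  tolerances quoted in the tests; nothing in the method depends on them.

## Known limitations

* The DS score sees only exact segment frequencies; a variant shared via
  a vector that is itself popular in two labs can still link them
  (false relatedness), and truly convergent origins inside one lab are
  indistinguishable from copying within that lab.
* Very short parts (below the 28-bp reportable-segment floor) are
  invisible to the segment stage, and part variants with mutations at the
  extreme ends of the part are clipped by local alignment and either
  reported with a shortened sequence or excluded by the coding
  terminal-deletion rule — a known blind spot of alignment-based
  annotation.
* E-value statistics are ungapped approximations (see above).
* The frequency cache keys on exact segment sequences; near-identical
  segments extracted from the same part copy against different partners
  are queried separately, which is exact but means runtime grows with
  end-extension diversity, not just with corpus size.
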