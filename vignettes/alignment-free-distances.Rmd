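---
title: "Alignment-free distances from spaced words and k-mismatch common substrings"
author: "afdist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free distances from spaced words and k-mismatch common substrings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdist)
```

## Why alignment-free distances

Distance-based phylogeny reconstruction normally starts from a multiple
alignment, which is expensive and often unreliable for long or rearranged
sequences. Alignment-free methods instead estimate pairwise distances
directly from the word composition of the sequences, in time roughly linear
in their total length. Classic approaches use *exact* word matches — either
frequencies of contiguous k-mers or the average length of the longest exact
common substrings. Exact matches at neighbouring positions are statistically
highly dependent, though, and a single mismatch cuts a long shared region
into short fragments. `afdist` implements two estimators built on *inexact*
word matches that address exactly this weakness.

## Spaced-word frequency distances

A *pattern* is a binary mask such as `11001`: `1` marks a match position,
`0` a don't-care position. Sliding the pattern along a sequence and reading
off only the characters under the `1`s gives the sequence's *spaced words*.
For `S = ATTATGCTAG` under `P = 11001` the six windows yield

```{r}
keys <- extractSpacedWords("ATTATGCTAG", "11001")
formatSpacedWord(keys, "11001")
wordFrequencies(spacedWordProfile("ATTATGCTAG", "11001"))
```

`AT**T` occurs twice among six windows (frequency 2/6), the four other
observed words once each, and every other spaced word has frequency 0.
Two sequences are compared through their relative-frequency profiles with
either the **Euclidean** distance or the **Jensen-Shannon divergence**. We
compute the latter with base-2 entropies, `JS(A,B) = H((A+B)/2) −
(H(A)+H(B))/2`, which is bounded in `[0, 1]`; the square-root variant
(which is a metric) is available via `jsSqrt = TRUE` / `--js-sqrt`. The
divergence itself is the default because it is the more common reporting
convention for word-profile comparison; only the scale, not the ranking,
differs between the two variants.

Because a single pattern makes the estimate depend on the accidental
placement of its don't-care positions, distances are averaged over a whole
set of patterns (`randomPatterns()`), which stabilizes the estimate. The
default is 10 patterns — accuracy tends to keep improving up to roughly
50–70 patterns, at proportionally higher cost, so the default favours run
time.

### Pattern-set choices

Random patterns are drawn with fixed first and last `1`: leading or
trailing don't-cares only shift the extraction window without changing the
induced word multiset, so fixing the ends removes redundant duplicates from
the sampling space. User-supplied pattern files are exempt from the
trailing-`1` rule (masks of different weight and length are allowed); a
leading `0` is still canonicalized away with a warning.

The default weight is derived from the mean input length `L`: a random
spaced word of weight `w` has `|Σ|^w` possible values, so `w ≈ log_|Σ|(L)`
makes a background match expected about once per position. We use
`ceil(log4 L) + 2` clamped to `[4, 14]` for DNA and `ceil(log20 L) + 1`
clamped to `[2, 6]` for proteins, with as many don't-care positions as
match positions (pattern length `2w`). A small epsilon is subtracted inside
the `ceil` so that lengths that are exact powers of the alphabet size do
not overshoot by one through floating-point rounding.

### Ambiguity codes

Windows with a non-alphabet character (`N`, `X`, ...) at a *match* position
are skipped entirely; don't-care positions accept anything. Profiles
therefore stay over the clean alphabet. Words are counted on the given
strand only, with no reverse-complement folding.

## The kmacs distance

For each position `i` of sequence `x`, the *k-mismatch matching statistic*
is the length of the longest substring of `x` starting at `i` that matches
some substring of `y` with at most `k` Hamming mismatches. The mean of
these lengths, `L(x, y)`, measures similarity; `k = 0` gives the classic
average common substring statistic. The directed distance applies the usual
log-length normalization

```
d(x, y) = ln(|y|) / L(x, y) − ln(|x|) / L(x, x),
```

where the self term uses the analytic `L(x, x) = (|x| + 1)/2` (the mean of
the suffix lengths), so `d(x, x) = 0` holds exactly rather than to rounding;
the reported distance is the symmetrized `(d(x,y) + d(y,x))/2`, in natural
log units (a scale convention only). If the sequences share no character at
all, `L = 0`; the distance is then capped at `2 ln(max(|x|, |y|))` with a
warning rather than returning infinity.

Two computation modes are exposed:

* **exact** — scans every diagonal of the comparison; on a diagonal the
  statistic from any start runs to the `(k+1)`-th mismatch, so one pass per
  diagonal gives all positions. Quadratic time, linear memory. Default for
  inputs below 1 Mb total.
* **heuristic** — finds the longest *exact* match per position, then chains
  longest-common-extension steps across up to `k` mismatches starting from
  the positions that attain the longest exact match. At most
  `maxCandidates = 50` such positions are extended, which keeps the cost
  near-linearithmic while in practice losing little: ties deeper than that
  occur essentially only in low-complexity sequence. Every chained
  extension is a genuine ≤ k-mismatch match, so the heuristic can never
  exceed the exact statistic, and at `k = 0` the two coincide by
  construction.

`k` ranges from 0 to 100 with default 5; larger `k` (> 10) tends to improve
tree quality slightly at higher cost. Ambiguity codes count as mismatching
every character, including themselves (implemented by sentinel-encoding the
two sequences differently before comparison).

```{r}
x <- c(a = "ACGTACGTACGT"); y <- c(b = "ACGTACGAACGT")
msLengths(matchingStatistics(x, y, k = 0))
kmacsDistance(x, y, k = 0)
msLengths(matchingStatistics(x, y, k = 1))  # one mismatch absorbs the SNP
kmacsDistance(x, y, k = 1)                  # ... giving distance 0
```

## Trees and formats

`neighborJoining()` implements Saitou–Nei agglomeration with the
Studier–Keppler Q-criterion, joining until three nodes remain and attaching
them to a trifurcating root (the unrooted convention of Phylip's
`neighbor`). Ties in Q are broken by the lexicographically smallest index
pair, making the output deterministic; negative branch-length estimates —
which NJ produces on non-additive input — are clamped to zero, the simplest
defensible policy, with a message. On additive matrices NJ is consistent:
the generating topology and branch lengths are recovered exactly, which the
test suite exercises against random additive fixtures
(`randomAdditiveMatrix()`).

Distance matrices are written in *relaxed* Phylip format: full names
(spaces replaced by `_`, padded to at least 10 characters) followed by the
row of values at 6 decimals. Trees are written as Newick with 6-decimal
branch lengths. Both round-trip to 1e-6, which bounds the precision of
anything downstream of the text formats.

## The simulator, and what it does not show

`simulateSequences()` draws i.i.d. uniform sequences; `mutateSequence()`
substitutes each site independently with a uniformly chosen *different*
symbol, so the rate parameter equals the expected Hamming fraction, and can
optionally delete sites (default off). This is deliberately the simplest
model that makes distance recovery testable: the package's tests show that
both distances increase monotonically with the substitution rate (Spearman
rank correlation above 0.9 across rates 0.05–0.40 on a 5 kb ancestor with
10 replicates per rate). Real sequences have skewed composition, indels,
repeats, and rate heterogeneity, none of which the generator emulates —
passing these tests demonstrates correct implementation and rank-level
sensitivity, not state-of-the-art accuracy on biological data. Benchmarks
on real data belong to comparisons against curated reference trees, which
are outside the package's scope.

Problem sizes in the test suite (sequence lengths of a few hundred for
oracle comparisons, 5 kb for rate recovery, 8-leaf trees for NJ
consistency) were chosen so the whole suite completes in a few minutes
while keeping every estimate's sampling error far from the asserted
thresholds.

## Numerical and degenerate-input choices

* Profile distances operate on the sparse union of observed words;
  mathematically identical to dense `|Σ|^w` vectors (verified against a
  dense k-mer counter for all-`1` patterns).
* `0 log 0 := 0` in the entropy; the JS value is clipped to `[0, 1]` to
  absorb last-ulp excursions.
* A sequence shorter than a pattern has no windows and is an error for
  profile construction (named in the message), as is a zero-weight mask.
* FASTA input is uppercased; gap (`-`, `.`) and stop (`*`) characters are
  stripped, since the methods are alignment-free. Duplicate names are
  uniquified (`_2`, `_3`, ...) with a warning.
* An unset CLI seed is drawn from entropy and printed, so any run can be
  reproduced after the fact; a fixed seed makes all outputs byte-identical
  across runs.

## Limitations

* The exact kmacs mode is quadratic; for inputs beyond a few Mb use the
  heuristic (the CLI warns when a run is expected to need much memory, but
  imposes no hard input limits).
* Jensen-Shannon and Euclidean profile distances are ad-hoc measures, not
  model-based estimators of evolutionary distance; their value is in
  ranking, i.e. tree reconstruction, not in absolute substitution-rate
  units.
* No reverse-complement folding and no additional profile distances
  (d2, d2*, chi-square) are provided.
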