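---
title: "Building the BWT from a prefix-free parse, and the r-index on top of it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building the BWT from a prefix-free parse, and the r-index on top of it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfpindex)
```

## The problem

A collection of genomes of one species is huge but highly redundant: two
human haplotypes differ at roughly one position in a thousand. Classical
suffix-array construction treats every one of the `n` suffixes
individually, so both its working memory and the index it produces scale
with `n` rather than with the amount of *distinct* sequence. This package
implements the construction that sidesteps that: parse the text into a
small dictionary of repeated phrases, then compute the BWT, the suffix
array, or just the run-boundary SA sample directly from the parse; and
assemble the sampled outputs into an r-index that counts and locates
patterns without ever holding a full suffix array.

## Prefix-free parsing

Given window size `w` and modulus `p`, a length-`w` window of the text is a
*trigger* when its rolling hash is ≡ 0 (mod `p`); the first and last
windows are triggers by fiat. Phrases run from one trigger to the end of
the next, so consecutive phrases overlap by exactly `w` characters and an
average phrase has length about `p + w`. The dictionary `D` is the sorted
set of distinct phrases; the parse `P` rewrites the text as the sequence of
their lexicographic ranks. For repetitive input the same phrases recur, so
`|D| ≪ |P| ≪ n`.

Choices the formulation leaves open, and what this package does:

* **Sentinels.** Exactly `w` copies of `'$'` are appended; every
  construction output is defined over the extended text `S' = S·$^w`. This
  guarantees every suffix other than the `w` sentinel-only ones has a
  phrase suffix longer than `w` as a prefix. The sentinel-only suffixes are
  emitted by a closed form (`sentinel_block()`): they are the `w`
  lexicographically smallest suffixes, shortest first, and their BWT
  characters are `w − 1` sentinels plus the input's final character. The
  brute-force oracles are applied to the same `S'`, so the convention is
  validated by element-wise agreement rather than by fiat.
* **The hash.** Any deterministic window function works, because the
  BWT/SA of the text are invariant to the parse (a tested property). We
  use a polynomial hash with base 256 modulo the prime 2^31 − 1, evaluated
  by vectorized Horner steps; all intermediates stay below 2^53, so plain
  doubles are exact. The base and modulus are recorded in the index
  header. An explicit-set trigger mode exists so that worked examples and
  tests are deterministic and readable.
* **Symbol order.** `'#'` (dictionary separator) < `'$'` (sentinel) < data
  characters. This coincides with byte order for DNA (`A < C < G < N < T`),
  so every sort in the package is a plain radix byte sort; generic test
  alphabets are allowed provided all bytes exceed `'$'`.
* **Coordinates.** 0-based positions and half-open intervals everywhere.
  Phrase ranks are stored 1-based (R's native indexing); the parse-BWT
  terminator is 0, ordered below every rank.
* **Degenerate inputs.** `w ≥ 1` is required, `n ≥ 1`; an input shorter
  than `w` is still parseable because the forced first/last windows always
  delimit at least one phrase covering all of `S'`.

## From parse to BWT, SA, and SA sample

Each non-sentinel suffix of `S'` is prefixed by exactly one suffix `α`
(length > `w`) of a dictionary phrase — its *representative prefix* — so
the suffix array splits into contiguous blocks, one per `α`, in
lexicographic order of `α`. Scanning the suffix array of the
`'#'`-separated dictionary string enumerates the candidate `α`s (dictionary
suffixes up to the next `'#'`, discarding those of length ≤ `w`) already
sorted, with equal strings adjacent.

Within one block, the order of the text suffixes equals the order in which
the occurrences of the phrases ending with `α` appear in the BWT of the
parse: a position in the parse BWT is ranked by the parse suffix *after*
it, which is exactly what distinguishes two text suffixes sharing `α`. The
builder therefore keeps, per phrase, three aligned arrays ordered by
parse-BWT position — the inverted list of positions, the character
preceding each occurrence in the text (circularly, so the first phrase is
preceded by the final sentinel), and the 0-based text position where each
occurrence ends. Merging the member phrases' lists by parse-BWT position
yields, per merged element, the BWT character (the stored preceding
character when `α` is the whole phrase, otherwise the dictionary character
just before `α` inside the phrase) and the SA value `end − |α| + 1`. In R
the "merge" is a single vectorized ordering of all (block, position) pairs,
so construction cost is a few radix sorts over arrays of length `n`.

One wrinkle the clean statement of the method misses: a phrase *can* be a
proper suffix of another phrase, in exactly one way. The opening phrase of
the text begins at a forced trigger, not a content-defined one, so its
string may recur inside some other phrase without triggering there. Its
block then mixes full-phrase occurrences with proper-suffix occurrences.
The merge handles the two kinds per occurrence (each row knows which source
it came from), and the builder asserts the provable invariant — only the
parse's opening phrase may collide this way. Randomized corpora hit this
case routinely, and the outputs still agree with brute force element-wise.

`"samples"` mode keeps the pairs ⟨position, SA⟩ at both boundaries of every
BWT run. In this implementation the full SA vector is materialized and the
boundary pairs extracted from it: the package is explicitly an in-memory,
desk-scale artifact, and a streaming iterator would buy nothing here while
complicating every consumer.

## The r-index

The index stores the BWT as runs (`run_heads`, `run_starts`), the character
count table `C`, per-run cumulative character counts (rank in `O(log r)` by
binary search — no succinct machinery, which at this scale would be
overhead without benefit), and the two boundary sample arrays.

Backward search maintains the interval `[s, e)` of the current suffix of
the query and one SA value, the *toehold* `SA[e−1]`. On prepending `c`: if
`BWT[e−1] = c` the bottom row survives and the toehold just decreases by
one (mod `n`); otherwise the new bottom row corresponds to the last run of
`c` inside `[s, e)`, whose end position is sampled by construction — the
toehold is repaired from that sample. The toehold is kept at the bottom of
the interval and enumeration proceeds upward with φ; the mirrored
top/φ⁻¹ scheme would work identically.

φ and φ⁻¹ map an SA value to its neighbor entry via a predecessor query:
`φ(x) = sat(pred(x)) + (x − pred(x))`, arithmetic modulo `n`, falling back
circularly to the largest key when `x` is below all keys. The φ⁻¹ keys are
the SA values at run **ends** (satellite: SA at the following BWT
position); the φ keys are the SA values at run **starts** (satellite: SA at
the preceding position). Descriptions of this structure sometimes attach
the φ⁻¹ satellite to run *beginnings*; on worked examples that assignment
fails the oracle check, while the ends-based assignment passes — consistent
with constructions that store both boundary sets, which is what the builder
emits. The tests pin this down by traversing the entire oracle SA in both
directions through φ/φ⁻¹.

Parameters that matter:

* `w` (window, characters; default 10) and `p` (modulus; default 100):
  average phrase length ≈ `p + w`. Larger `p` shrinks the parse but grows
  the dictionary's share of distinct text; the defaults suit inputs from
  tens of kilobases to megabases. Results are invariant to both — only
  construction internals change.
* Queries accept any string free of `'$'`/`'#'`; characters absent from
  the indexed alphabet simply produce zero hits.

## The synthetic collection generator

`synth_collection()` emulates a haplotype panel: one uniform-random base
sequence over `{A,C,G,T}` and `m − 1` copies carrying independent
substitutions (rate 0.001 by default, uniform over the three other bases)
and short indels (initiation rate 1e-4, geometric lengths with mean 3,
insertion/deletion equiprobable). Those defaults approximate within-species
divergence between human haplotypes, the regime where `n/r` grows almost
linearly in `m`. What it deliberately does not model: transition/transversion
bias, structural variants, repeat families within the base sequence, or `N`
runs from assembly gaps. Passing tests on these collections therefore
demonstrates correctness of the algorithms and the expected compression
*trend*, not the absolute `n/r` of any real pan-genome.

## Validation strategy and problem sizes

Every construction path is checked element-wise against deliberately naive
oracles (suffix sort by direct substring comparison; Eq.-style BWT;
sliding-window locate), and the two suffix-array routes — prefix doubling
in the builder, brute-force sort in the test kit — are checked against each
other. The suite uses ~200 random texts up to 5 kb across four trigger
policies for construction equivalence, 500+ (text, pattern) query cases
including absent patterns and the full text, 50-text φ-traversals, `n/r`
scaling on 50 kb × {1,2,5,10} collections, and an end-to-end FASTA →
build → save → load → locate run with 1000 sampled 100-mers over a five
record × 20 kb two-strand collection; these sizes exercise every branch
while keeping the whole suite in the low minutes on one core.

## Limitations

* In-memory only: no external-memory or streaming construction, no
  parallel parsing; desk scale means megabases, not terabases.
* Exact matching only; no approximate search or read alignment. Reverse
  complements are handled at build time (index both strands), not at query
  time.
* Rank is `O(log r)` binary search, predecessor is `O(log r)`; the
  constant-factor-optimal succinct structures are out of scope.
* Records are concatenated without separators, matching the
  concatenated-genomes model; `locate_in_collection()` filters the phantom
  matches that span a record boundary.
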