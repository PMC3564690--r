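---
title: "Exact two-stage discovery of structured DNA motifs"
author: "StructuredMotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact two-stage discovery of structured DNA motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StructuredMotifs)
```

## The model

Many cis-regulatory signals are composite: two or more transcription
factor binding sites that co-occur in a fixed order at loosely
constrained distances. We model such a signal as a **structured motif**
over the DNA alphabet $\Sigma = \{A, C, G, T\}$: an ordered tuple of
$b \ge 2$ *boxes*, where box $i$ is a consensus word $w_i$ of length
$\ell_i$ matched with at most $e_i$ substitutions
($0 \le e_i < \ell_i$), and the number of bases strictly between boxes
$i$ and $i+1$ must lie in $[d_i, D_i]$. A compact template string
describes the search problem, e.g. `(3,1)-[1,1]-(5,2)-[1,200]-(9,1)`.
A structured motif is *valid* for a sequence set $S$ when at least a
fraction $q \in (0,1]$ of the sequences (the **quorum**; integer
threshold $\lceil q|S|\rceil$) each contain at least one occurrence
tuple satisfying all box and gap constraints.

The package enumerates **all** valid structured motifs, exactly — no
heuristic pruning, no significance filtering. Filtering by
over-representation is deliberately left out of the enumeration: a
structured motif can reach quorum precisely because it combines
individually weak boxes, so discarding weak simple motifs early would
lose valid results. Scoring, if wanted, belongs downstream.

## The two-stage algorithm

**Stage 1** enumerates, per distinct box template $(\ell, e)$, every
simple motif meeting the quorum, with its complete occurrence list
sorted by (sequence, position). The engine spells candidate words base
by base over the set of sequence windows, pruning a prefix as soon as
its support drops below the quorum threshold (support is
non-increasing under extension). Two modes are supported:

* `"unconstrained"`: consensus words range over all of
  $\Sigma^\ell$;
* `"frequent"`: additionally, each box word must occur *exactly*
  (zero mismatches) somewhere in the input. Exactness is enforced per
  box, not jointly for a whole structured occurrence; per-box
  filtering is the semantics consistent with treating stage 1 as a
  pluggable simple-motif finder, and it is what the frequent-mode
  counts we reproduce reflect.

The per-window branching factor is the Hamming neighborhood size
$\nu(e,\ell) = \sum_{i=0}^{e} \binom{\ell}{i} 3^i \le \ell^e 4^e$
(`neighborhoodSize()`), which is also what makes an instance easy or
hard. Boxes sharing an $(\ell, e)$ pair share a single enumeration
run (`buildCandidateSets()`).

**Stage 2** assembles the per-box candidate sets $K_1, \dots, K_b$
into structured motifs by extending prefixes one box at a time. For
each prefix occurrence, the compatible occurrences of the next box in
a sequence are located by binary search on the sorted start list
(lower gap bound) and taken until the upper bound is violated
(`compatibleRange()`); the extended prefix is discarded as soon as its
support falls below the threshold. Because every step only intersects
complete, sorted occurrence lists, the final result is exact.

Two options trade time for memory without affecting results:

* **Box-order selection** (`boxOrderSelection = TRUE`): boxes are
  assembled in ascending order of total occurrence mass
  $B_i = \sum_{t: m_t \in K_i} |occ_{i,t}|$ rather than left to right,
  which limits the number of intermediate prefixes that are doomed to
  be discarded. When two placed boxes sandwich unplaced ones, the
  compound gap between them is constrained to the sum of the
  intervening gap bounds plus intervening box lengths; when a hole is
  later filled, both flanking constraints are checked exactly. This
  compound-bound rule is the unique semantics under which option
  combinations stay result-invariant, which is how we settled it.
* **Space-saving slicing** (`spaceSaving = v`): each $K_i$ is
  partitioned into $\lceil |K_i|/v \rceil$ slices of at most $v$
  motifs and stage 2 is run once per cell of the Cartesian product of
  slices, bounding the number of intermediate prefixes in memory at
  the cost of re-deriving shared prefixes per cell. Results are the
  deduplicated union over cells. Single-box prefixes are built once
  per assembly call and shared across cells; the per-cell cost is the
  join work itself.

Stage 1 holding all candidate occurrence lists in memory is the one
genuine failure mode of the design; the package signals it as a
distinct condition class (`stage1MemoryError`) so drivers can report
it apart from invalid input.

## Coordinates and conventions

Positions are 1-based and inclusive, the R/Bioconductor convention.
The gap between boxes ending at base $p$ (its last base) and starting
at base $s$ is $s - p - 1$, the count of bases strictly between them;
`[1,1]` means exactly one spacer base, `[0,0]` means abutting boxes.
Boxes may not overlap ($d_i \ge 0$). Sequences are normalized to
uppercase; characters outside $\{A,C,G,T\}$ (including IUPAC `N`) are
rejected with the offending record named rather than silently matched,
because the Hamming model is defined only over the four-letter
alphabet. Only the forward strand is searched. Output ordering is
lexicographic by concatenated box words, so result files are
deterministic given input and configuration.

## The planted-motif benchmark generator

`plantDataset()` reproduces the planted-motif experimental design used
to validate exact finders: $N$ background sequences with i.i.d.
uniform bases (probability 0.25 per symbol; defaults $N = 20$,
$L = 600$ in our experiments), and exactly one structured occurrence
planted per sequence. Per sequence, each box instance is the consensus
with $e_i$ positions substituted by uniform redraws over all four
letters — so the realized distance is *at most* $e_i$, and the
consensus itself can be re-drawn with probability $1/4$ per position;
`forceDistance = TRUE` draws from the three other letters instead.
Gap values are uniform in $[d_i, D_i]$ and the leftmost start uniform
over feasible positions, drawn independently per sequence. The
template must satisfy $\sum_i \ell_i + \sum_i D_i \le L$ so any gap
draw fits. With `plantExact = TRUE`, sequence 1 keeps the unmutated
words, which guarantees at least one exact structured occurrence (as
frequent-mode benchmarks require). A single seeded RNG stream drives
background, consensus choice, gaps, starts and mutations in a fixed
documented order, so datasets are bit-reproducible.

What the generator does *not* emulate: biologically realistic
backgrounds (Markov dependence, GC bias), multiple or missing
occurrences per sequence, and insertions/deletions. Recovery results
on planted data therefore demonstrate algorithmic correctness — the
planted tuple is guaranteed by construction to be a valid result at
$q = 1$ — not biological sensitivity.

`expectedMotifCount()` grades instance difficulty: under an
independence approximation across the $L - \ell + 1$ windows of a
sequence,
$$E(\ell, e) = 4^\ell\left[1 - \left(1 -
\nu(e,\ell)/4^\ell\right)^{L-\ell+1}\right]^N$$
estimates how many $(\ell,e)$ words meet full quorum by chance.
The formula is a stand-in for the unpublished model it approximates
and ignores window overlap, which makes it a mild overestimate for
hard boxes (Monte-Carlo on $(9,2)$, $20 \times 600$: simulated mean
about 1.45 against a predicted 1.60); it agrees to well under 1% for
saturated boxes such as $(3,1)$. It is used only to label instances
easy ($E \gg 1$) or hard ($E \approx 1$), never to filter output.

## Numerical and design choices

* Quorum threshold: $\lceil q N \rceil$, with a $10^{-9}$ guard
  against floating-point noise in $qN$; this reproduces the reference
  thresholds 7 of 10 at 70%, 4 of 5 at 80%, and 16 of 23 at 68%.
* Ties in box-order selection are broken by ascending box index, so
  the assembly order is deterministic.
* Occurrence tuples are keyed by (sequence, all $b$ starts); multiple
  occurrences of one motif in one sequence are all enumerated but
  the sequence counts once toward support.
* Gap bounds larger than any sequence are legal; the distance check
  truncates naturally.
* Stage-1 enumeration is implemented in C++ (a window-set spelling
  walk); the naive per-word window scan (`scanOccurrences()`) is kept
  in R as a readable reference back-end and cross-check.

## Problem sizes used by the test suite

The shipped tests pit the pipeline against independent brute-force
oracles: an exhaustive per-word scan for stage 1, and an exhaustive
word-tuple enumerator with per-sequence chain checks for the full
pipeline. Oracle-equivalence runs use 200 randomized instances with
$b \in \{2,3\}$, $\ell_i \le 3$, $N \le 5$, $L \le 40$, biased toward
exact boxes when $b = 3$ because the oracle's tuple space — and the
$v = 1$ space-saving battery, which runs one assembly per candidate
tuple — grows as $\prod_i |K_i|$. Planted-recovery runs use 50 seeded
datasets at the study conditions ($20 \times 600$, $b \in 2..5$,
boxes drawn from (9,2), (10,2), (11,2), (11,3), (12,3), (13,3),
$q = 1$), a scaled-down replicate count chosen so the whole suite
stays comfortably interactive. Option invariance (basic vs box-order
selection vs space-saving $v \in \{1, 2, 5\}$ and off) is asserted on
every one of these instances.

## Limitations

* The Hamming model has no insertions/deletions and no
  position-weight scoring; degenerate (IUPAC) consensus letters are
  out of scope.
* Reverse-complement search is not performed; search both strands by
  adding reverse-complemented sequences to the input if needed.
* Exhaustive enumeration with permissive short boxes produces very
  large outputs by design; the space-saving option bounds memory but
  not output size.
* Stage 1 can exhaust memory on extreme instances (many long boxes
  with large $e$); this is reported as `stage1MemoryError` rather
  than worked around.
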