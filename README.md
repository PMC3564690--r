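# StructuredMotifs

Exact enumeration of **structured motifs** in DNA sequence sets:
ordered tuples of b ≥ 2 mismatch-tolerant consensus words ("boxes")
separated by bounded gaps, the standard model for composite
transcription factor binding sites such as dyads in promoter regions.

A search problem is a template string

```
(ℓ1,e1)-[d1,D1]-(ℓ2,e2)-…-(ℓb,eb)
```

— box i is a word of length ℓi matched with at most ei substitutions
(Hamming distance), and the number of bases strictly between boxes i
and i+1 must lie in [di, Di] — together with a quorum q ∈ (0,1], the
minimum fraction of input sequences that must contain a full
occurrence. The package reports **every** motif satisfying the
constraints, with no heuristic pruning and no significance filtering
(weak boxes can combine into valid structured motifs, so nothing is
discarded early).

Discovery runs in two stages:

1. **Simple-motif enumeration** — for each distinct box template
   (ℓ, e), every consensus word meeting the quorum is enumerated with
   its complete occurrence list, sorted by sequence and position, by
   a spelling walk over the sequence windows with quorum pruning
   (C++ core). Modes: *unconstrained* (words range over all of Σ^ℓ)
   or *frequent* (each box word must occur exactly somewhere in the
   input).
2. **Assembly** — per-box candidate sets are combined by successive
   intersection of sorted occurrence lists under the gap constraints
   (binary search for the lower gap bound, scan to the upper), with
   prefixes discarded as soon as their support falls below ⌈qN⌉.
   Optional, result-invariant resource controls: assembling boxes in
   ascending order of total occurrence count, and slicing candidate
   sets into size-v subsets run per Cartesian-product cell to bound
   memory.

A planted-motif benchmark generator (`plantDataset()`) produces
i.i.d.-uniform background sequences with one constraint-respecting
motif occurrence planted per sequence and full ground truth, for
recovery experiments.

## Worked example

Plant a two-box motif `(9,2)-[5,10]-(10,2)` in 20 random sequences of
600 bases, then recover it at full quorum:

```r
library(StructuredMotifs)

tpl <- parseTemplate("(9,2)-[5,10]-(10,2)", quorum = 1.0)
pd  <- plantDataset(20, 600, tpl, seed = 7)
pd
#> PlantedMotifData: 20 sequence(s) of 600 base(s), template (9,2)-[5,10]-(10,2)
#>   planted words: TGAACATGA-TTTCCTCAGG

res <- discoverMotifs(pd, tpl, verbose = TRUE)
#> box 1 (9,2): |K| = 4, B = 132
#> box 2 (10,2): |K| = 1, B = 20
#> stage 1: 0.13s
#> stage 2: 0.01s; 1 structured motif(s)

as.data.frame(res)
#>        box1       box2                motif support
#> 1 TGAACATGA TTTCCTCAGG TGAACATGA-TTTCCTCAGG      20
```

Stage 1 found 4 candidate words for the (9,2) box (132 occurrences in
total) and a single candidate for the (10,2) box; assembly left
exactly one structured motif — the planted pair, present in all 20
sequences. The (9,2) box is a deliberately hard planted-motif
instance: `expectedMotifCount(9, 2, 20, 600)` ≈ 1.6, so only a couple
of chance candidates are expected beside the planted word, and the
quorum check removes them during assembly.

`findSimpleMotifs()`, `buildCandidateSets()`, `assembleMotifs()`,
`scanOccurrences()` expose the stages individually;
`readFastaSequences()` / `writeMotifTable()` handle files, and
`inst/scripts/structured-motif-finder.R` wraps the pipeline for the
shell (`discover` and `generate` subcommands).

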