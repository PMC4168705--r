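---
title: "Assembly with multi-step bi-directed de Bruijn graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly with multi-step bi-directed de Bruijn graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msgasm)
```

## The model

DNA is double-stranded, so a k-mer and its reverse complement are the same
observation. `msgasm` works on *k-molecules*: unordered pairs
{k-mer, reverse complement}, represented by the lexicographically larger
strand (A < C < G < T). The word size k must be odd, which guarantees no
k-mer equals its own reverse complement, so the representative is always
well defined. Note the convention: the *larger* strand represents the
molecule, which is the opposite of the smaller-canonical convention used by
several k-mer counters; the two are isomorphic, but printed vertex names
differ.

Vertices of the assembly graph are the k-molecules of the reads; a
*bi-directed edge*

    (from, to, d_from, d_to, label)

records that traversing `from` in orientation `d_from` and appending `label`
lands on `to` in orientation `d_to`:

    suffix_k(oriented(from, d_from) o label) == oriented(to, d_to).

Every edge has exactly one equivalent *twin* seen from the other endpoint
(endpoints swapped, both orientations negated, label reverse-complemented
from the leading prefix). Graphs store whichever representation has the
smaller sort key, so each physical edge exists once and strand-symmetric
inputs build bit-identical graphs (`build_graph(reads)` equals
`build_graph(revcomp(reads))` exactly; this is a tested invariant).

```{r}
g <- build_graph(c("TAGTCG", "AGTCGA", "TCGAGG"), k = 3)
g
g$edges
```

This worked example shows the one genuinely tricky structure: the window
pair TCG/CGA maps both k-mers to the same molecule, producing a
*palindromic self-twin edge* `(TCG, TCG, +, -, A)` that is its own twin and
contributes two attachments to one side of TCG.

## Merging as a semigroup

Two edges meeting at a molecule with matching traversal orientation merge
into a multi-step edge: labels concatenate, step counts add, and coverage is
the label-length-weighted mean of the operands (the model itself does not
dictate a merged coverage; the weighted mean makes coverage the average
observation depth per spelled base and is exactly associative up to
floating-point rounding). All failure cases return a distinguished zero
edge, making the edge set closed and the operation total and associative —
`merge_edges` is tested for associativity on thousands of random triples.

Associativity is what makes the schedule irrelevant to the result: any order
of merging the edges of a unanimous path (a maximal chain of degree-2
molecules) yields the same full-extended edge. `reduce_graph` exploits this
with a round-synchronous schedule: each round it enumerates all mergeable
pairs (`enumerate_sigma`), selects a conflict-free subset, and applies it
atomically. Two operations conflict exactly when they share an edge — the
"small world" a merge touches is its two edges, its center, and the far
endpoints' attachment slots, and any overlap between two degree-2 pairs
implies a shared edge. This emulates, in one process, a distributed
lock-compute-unlock protocol; logical partitions are tracked for
bookkeeping but cannot change results (a tested invariant).

Because every edge belongs to at most two pairs, the conflict graph is a
union of paths and cycles. The deterministic scheduler walks each component
and keeps alternate pairs, which is a maximum matching: a pure path of E
edges halves every round and finishes in ceiling(log2 E) rounds. A plain
greedy order (the randomized mode, which emulates random backoff winners)
only guarantees a maximal matching, so its round count may exceed the bound
— but by associativity its final graph is identical. Both facts are tested:
round counts on random paths with E from 2 to 256, and final-contig
invariance across modes, seeds, and partition counts.

`schedule_cost` isolates the cost model behind this design: for two linked
paths of 3 and 5 k-molecules, one-at-a-time merging needs 6 operations,
path-parallel merging 4 rounds, and pairwise concurrent merging 2 rounds.

Circular chains need a convention the model does not supply: a cycle of
degree-2 molecules collapses to a multi-step self-loop that can no longer
pair (its two attachments belong to one edge). Reduction therefore
terminates naturally, and `emit_contigs` flags such a loop `circular` only
when its anchor molecule has no other edges — a loop hanging off a junction
is spelled as an ordinary linear contig, matching what a path-walking unitig
decomposition produces. The spelled sequence of a circular contig carries a
k-base wrap overlap, and its anchor rotation depends on merge order; the
rotation, not the cycle, is the arbitrary part.

## Cleaning

Sequencing errors produce k-mers seen once or twice; correct k-mers recur
with the sequencing depth. `clean_graph` removes molecules below a frequency
threshold with their edges, then low-coverage edges, then molecules that
lost their last edge in the process (molecules that never had an edge are
kept, which makes thresholds (0, 0) the identity and the operation
idempotent). `auto_threshold` defaults to 5% of the mean molecule frequency
— the middle of the customary 3–10% band — rounded up and clamped at 2 so
singleton error k-mers are always removable. Frequency counts every window
occurrence, and edge coverage every adjacent-window occurrence, on either
strand; the counting basis is a package choice, as the model only requires
"low frequency".

## Contig extension

After reduction, four local structures block further extension and are
resolved heuristically, in this order within each pass:

1. **Self-loops** (`resolve_self_loops`): a loop merges with its
   highest-coverage direction-compatible neighbour (degree requirement
   waived), otherwise it is deleted. Palindromic junctions are the main
   customer: the self-twin edge keeps its molecule at degree 4 and stalls
   reduction until it is folded into a neighbour.
2. **Tips** (`remove_tips`): an edge with one degree-1 endpoint, a branching
   (degree >= 3) far endpoint, and a label shorter than `tip_max_label`
   (default k) is a dead-end artifact and is deleted. Tip length is the
   label length (step count), the conservative reading for one-step spurs.
3. **Multiple edges** (`resolve_multiple_edges`): among parallel edges
   (same endpoints, same orientations, twins identified) only the
   highest-coverage one survives; ties keep the smaller stored label.
4. **Cross vertices** (`resolve_cross_vertices`) and **virtual cross
   vertices** (`resolve_virtual_cross`): at a vertex (or an edge treated
   with its endpoints as one virtual vertex) carrying at least two distinct
   edges on each side, edges are sorted by coverage and greedily paired
   across; a pair whose relative coverage difference
   |c1 - c2| / max(c1, c2) is below `coverage_tolerance` (default 20%) is
   merged through a cloned center. Matching depth is the evidence that the
   two edges are halves of one genomic path crossing a repeat. The greedy
   two-pointer pairing (drop the larger top when it cannot match) is a
   package choice; the model prescribes only the sort and the 20% rule.
   Requiring two *distinct* edges per side (not merely two attachments)
   keeps a palindromic self-twin loop, which is one edge with two
   attachments, from masquerading as a cross.

Two deliberate deviations from the presentation order tips-first: self-loops
are resolved *before* tips, and a tip must hang off a branch. Both are
forced by palindromic junctions: next to one, the legitimate chain end
remains a short (here 2-step) edge after reduction, and a tip rule keyed
only to "short edge at a terminal vertex" would delete genuine sequence.
With the adopted order the three-read example above assembles to the
expected nine-base reference, which is part of the acceptance tests:

```{r}
st <- assemble(reads = c("TAGTCG", "AGTCGA", "TCGAGG"), k = 3,
               molecule_threshold = 0, min_contig_len = 3)
st$contigs
```

`assemble_loop` iterates reduction and the four heuristics until a full pass
changes nothing (`max_rounds` 16 caps pathological inputs with a warning).
With every heuristic disabled it reproduces `reduce_graph` exactly.
Contigs are the remaining edges, spelled as the traversed source strand plus
the label, canonicalized to the larger strand, ordered by decreasing length;
the default emission cutoff of 2k - 1 bases reports only contigs that
extend beyond a single unmerged window junction (k for toy examples).

## The simulator, and what passing tests do not show

`random_genome`, `repeat_free_genome`, `tile_reads`, `sample_reads` and
`inject_errors` generate the study conditions for every test: uniform
coverage, optional strand flipping, and i.i.d. substitutions.
`repeat_free_genome` guarantees distinct canonical (k-1)-mers, hence a
single unanimous path — the round-trip acceptance check (a 10 kb repeat-free
genome, k = 31, error-free 100 bp reads tiled every 10 bp, recovered as
exactly one contig equal to the canonical genome) exercises construction,
reduction and emission end to end with a known answer.

The simulator does not model real data's hard parts: indels, quality-biased
and position-biased errors, non-uniform (GC-dependent) coverage, long
repeats, heterozygosity, or paired ends. Passing tests therefore demonstrate
correctness of the graph algebra, the scheduler and the heuristics under
their stated assumptions — not assembly quality on real libraries, which in
this model class is dominated by repeat structure and error correction
upstream.

## Numerical and degenerate-input choices

* String comparisons that define representatives and canonical edge keys use
  only uppercase-letter alphabets (orientations are encoded as letters in
  sort keys) and radix sorting, so results are independent of the session
  locale.
* Graph dumps render coverage with 17 significant digits; dump/load
  round-trips are bit-exact and dumps are the graph-equality predicate in
  tests.
* Merged coverage is a weighted mean; re-associated merges can differ by
  ~1e-16, so dumps, not floating-point identity, define equality of
  independently scheduled reductions' sequences, and coverage comparisons in
  tests use the default numeric tolerance.
* Degenerate inputs: reads shorter than k contribute nothing; windows with
  ambiguity characters are skipped (a read is effectively split at every N,
  keeping the graph alphabet pure); k must be odd and at least 3; an empty
  graph cleans, reduces and emits to empty results; `n50` of an empty
  length set is 0.
* Problem sizes in the test suite were chosen to finish in minutes on one
  core: the 10 kb round trip, 20 invariance graphs of 200 bp, 1000
  associativity triples, paths up to 256 edges, and 50 oracle-comparison
  graphs of 60–210 bp at k = 7, cross-checked against an independent
  path-walking unitig decomposition written only for the tests.

## Known limitations

* Single process; the lock protocol is emulated as independent-set
  selection. Partitioning is bookkeeping only.
* No bubble popping by alignment, no scaffolding, no paired-end
  constraints, no gap filling.
* The cross-vertex heuristics can, by design, join the wrong pair when
  distinct genomic paths happen to have coverage within the tolerance;
  the 20% default trades contiguity against occasional misjoins.
* Coverage of a merged edge is a summary statistic, not a per-base track.
* k is limited by memory in the plain string representation (no 2-bit
  packing); the intended regime is k up to ~63 on desk-scale data.
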