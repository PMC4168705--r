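# msgasm

Short-read genome assembly with **multi-step bi-directed de Bruijn
graphs**, in R.

De novo assembly collapses the *unanimous paths* of a de Bruijn graph into
contigs. `msgasm` models both DNA strands at once: each vertex is a
*k-molecule* — the pair {k-mer α, reverse complement α′}, represented by the
lexicographically larger strand (k odd, so α ≠ α′) — and each edge is
bi-directed, `e = (α̂, β̂, d_α, d_β, c)`, carrying an orientation at both
ends and a label `c` with the invariant

    suf_k( oriented(α̂, d_α) ∘ c ) = oriented(β̂, d_β).

Edges meeting at a degree-2 molecule with matching traversal orientation
merge: `e_αβ ⊗ e_βγ = e_αγ` with labels concatenated, and all failing cases
map to an absorbing zero edge `0`. The edge set together with `⊗` is a
semigroup, so merges along a path may be applied in any order — `msgasm`
applies them in round-synchronous, conflict-free batches (an in-process
emulation of a lock–compute–unlock scheduler), collapsing a path of `E`
edges in `⌈log₂ E⌉` rounds instead of `E − 1` sequential joins. Frequency
cleaning removes error k-mers; heuristics resolve tips, self-loops (the cure
for palindromic junctions), parallel edges, and coverage-balanced cross
vertices; remaining edges are emitted as contigs with N50/length statistics.

## Worked example

The nine-base reference `w = "TAGTCGAGG"` read as `{"TAGTCG", "AGTCGA",
"TCGAGG"}` exercises every interesting structure, including the palindromic
self-twin edge `(TCG, TCG, +, −, A)`:

```r
library(msgasm)
g <- build_graph(c("TAGTCG", "AGTCGA", "TCGAGG"), k = 3)
g
#> <msg_graph> k=3, 6 k-molecules, 6 edges
mol_degree(g, "TCG")        # 4: chain-in, self-twin twice, chain-out
#> [1] 4
st <- assemble(reads = c("TAGTCG", "AGTCGA", "TCGAGG"), k = 3,
               molecule_threshold = 0, min_contig_len = 3)
st$contigs
#>         id  sequence length coverage circular
#> 1 contig_1 TAGTCGAGG      9      1.5    FALSE
```

The single contig equals the reference: reduction collapses the two plain
chains, self-loop resolution folds the palindromic junction into its
neighbour, and a final merge spells all nine bases. Plain reduction alone
(`extension = NULL`) stalls at the junction and returns three pieces.

A synthetic round trip at realistic word size:

```r
gen <- repeat_free_genome(10000, 31, seed = 7)
st  <- assemble(reads = tile_reads(gen, 100, 10), k = 31,
                molecule_threshold = 0, min_contig_len = 31)
st
#> <assembly_stats> 1 contigs, 10000 bases, N50=10000, max=10000 (k=31)
st$rounds$rounds            # ⌈log₂ 9970⌉ merging rounds
#> [1] 14
```

## Command line

```sh
exec/msgasm simulate --genome-length 10000 --repeat-free -k 31 \
    --tile-step 10 --read-length 100 --output reads.fa.gz --genome-out truth.fa
exec/msgasm assemble -i reads.fa.gz -k 31 --threshold auto \
    -o contigs.fa --stats stats.json
exec/msgasm stats contigs.fa
```

`--threshold auto` takes 5% of the mean k-molecule frequency (clamped at 2);
`--scheduler {deterministic,randomized}`, `--seed`, and `--partitions`
control the merge schedule, which by associativity never changes the
contigs.

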