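# exactpoa

Progressive multiple sequence alignment (MSA) via **partial order
alignment (POA)** with a per-sequence **optimality guarantee**. The package
is aimed at workflows that align sets of homologous sequences — gene
clusters, amplicons, long-read consensus, pangenome loci — onto a growing
character-labeled DAG, and that cannot afford the dense dynamic-programming
tables of conventional POA: a gap-affine alignment of a 500 kbp query
against a 500k-node graph would need three 32-bit state matrices of
|V| × (m+1) cells, about 3 TB of RAM.

## The method

A POA graph `G = (V, E)` is a DAG whose nodes carry one symbol each,
bracketed by a virtual start node ν and end node τ; edges record which
sequences use them, and alignment classes partition nodes into MSA columns.
Aligning a query `Q` (length `m`) to `G` is a shortest-path problem on the
*alignment graph*: states `⟨v, i⟩` pair a graph node with a query offset,
and weighted edges are the alignment operations under a gap-linear
(`C = Nx·Δx + Ng·Δg`) or gap-affine (`C = Nx·Δx + No·Δo + Ng·Δe`) cost
model with the match cost fixed at zero. The lowest-cost path
`⟨ν,0⟩ → ⟨τ,m⟩` is the optimal alignment.

`exactpoa` finds that path with A* search accelerated by three devices,
none of which sacrifices optimality:

1. **Minimum remaining gap cost heuristic.** A reverse topological sweep
   stores, per node, the shortest and longest path lengths to τ
   (`d_min`, `d_max`). Comparing them with the unaligned suffix length
   `l_r = m − i` bounds the number of indel edges any completion must still
   traverse:

   `Ng_min = l_r − (d_max − 1)` if `d_max − 1 < l_r`;
   `(d_min − 1) − l_r` if `d_min − 1 > l_r`; else `0`,

   and `h⟨v,i⟩ = Ng_min · Δg` (layer-aware open/extend bound under affine
   costs). The bound is admissible, so A* returns the optimum.

2. **Depth-first greedy match extension.** Matches cost zero, so when a
   state is popped the aligner follows chains of match edges depth-first,
   finalizing them immediately — even across branches — and only queues
   insertion/deletion states at mismatch frontiers.

3. **Superbubble pruning.** Superbubbles (single-entrance/single-exit
   substructures — the alleles at a locus) are detected up front and every
   contained node is indexed with its min/max path length to the bubble
   exit. A state inside a bubble can reach the exit, at best, at offsets
   `i + d_min … i + d_max` at its current cost; if every such best case is
   already beaten by an *implicitly opened gap* from a previously reached
   state (cost `k·Δg`, or `Δo + k·Δe` affine, for a gap of `k`), the state
   cannot be on an optimal path and is pruned.

A plain dense DP aligner (`dp_align()`) with the same semantics is included
as an independent oracle and as a fallback engine, and a homolog-set
simulator (`simulate_homologs()`) generates test data at configurable
substitution/indel rates.

## Worked example

```r
library(exactpoa)

seqs <- simulate_homologs(ancestor_length = 40, n_seqs = 4,
                          sub_rate = 0.08, indel_rate = 0.04, seed = 33)
res <- build_msa(seqs, model = cost_model("linear", mismatch = 4, gap = 2))
res$msa
#> POA multiple sequence alignment: 4 sequences x 53 columns
#> seq1_sub4_ind2 CT-CTA--CTTATA--AT-AGCTTA-C--ATAGCTCAG--G-AC-A-GCGTGT
#> seq2_sub3_ind2 CT-CTA--CTTA-A--ATTAGCT-C-CCCA-AGCTC-G--GGAC---TCGCGT
#> seq3_sub1_ind0 AT-CTA--CTTA-A--AT-AGCT-CTC--CTAGCTCAG--G-ACTAAGCGCGT
#> seq4_sub5_ind3 CTGGTAGACTTA-AGGA---GCT-C-CCC-TAGCT-AGTCG-ACTAAGCGCGT
res$stats
#>             name length cost states_expanded states_pruned dfs_steps
#> 1 seq2_sub3_ind2     38   30             125             0       173
#> 2 seq3_sub1_ind0     40   14              75            21       144
#> 3 seq4_sub5_ind3     44   26             178            47       248
```

Each row of `stats` is one progressive step: the optimal cost of aligning
that sequence to the current graph, how many A* states were expanded, how
many were pruned via superbubbles, and how many states the zero-cost match
DFS consumed. De-gapping any MSA row reproduces its input sequence exactly.

Single alignments expose the operation list:

```r
g <- poa_graph("AGGT", "ref")
a <- poa_align(g, "ACGT", cost_model("linear", mismatch = 3, gap = 2))
a
#> POA alignment: cost 3 (3 match, 1 mismatch, 0 insert, 0 delete)
#>   states expanded 2, pruned 0, DFS steps 5
a$ops
#>         op node qpos
#> 1    match    3    1
#> 2 mismatch    4    2
#> 3    match    5    3
#> 4    match    6    4
```

The cost of 3 is the single C→G substitution; at `mismatch = 5` the
aligner would instead report an insertion/deletion pair of cost 4.

A command-line front end lives in `inst/scripts/exactpoa.R`
(`align` and `fixture` subcommands; `--engine dp`, `--no-prune`, `--no-dfs`
expose the oracle and the accelerator toggles; graphs can be written to and
extended from GFA v1, plus DOT and per-sequence TSV statistics).

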