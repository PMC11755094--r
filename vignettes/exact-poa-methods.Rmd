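---
title: "Exact partial order alignment: model, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact partial order alignment: model, search, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exactpoa)
```

## The model

Partial order alignment represents a multiple sequence alignment as a
character-labeled DAG: each node is one residue, edges record adjacency in
at least one sequence, and a virtual start node ν and end node τ bracket the
graph. Alignment classes partition nodes into MSA columns — two nodes in one
class are alternative alleles of a column and never lie on a common directed
path. Progressive MSA aligns each new sequence against the current graph and
merges it in; each per-sequence alignment is optimal for its graph, while
the joint sum-of-pairs score of the final MSA is (as for all progressive
POA) not guaranteed optimal, and can depend on how cost ties are resolved.

Alignment of a query $Q$ of length $m$ to the graph is shortest-path search
on the *alignment graph*: states $\langle v, i\rangle$ with $i \in
\{0,\dots,m\}$, edges for match/mismatch (advance both cursors), deletion
(advance the graph cursor), and insertion (advance the query cursor). Costs
are non-negative integers with matches fixed at zero:
$C = N_x\Delta_x + N_g\Delta_g$ (gap-linear) or
$C = N_x\Delta_x + N_o\Delta_o + N_g\Delta_e$ (gap-affine, with
$\Delta_o > \Delta_e$ enforced). Under affine costs the states carry a
Gotoh-style layer M/I/D: opening costs $\Delta_o + \Delta_e$, extending
$\Delta_e$, and closing back into M is free. Matches and mismatches exist
only in the M layer. Keeping all costs integral permits exact equality
tests everywhere — there is no floating point in the search.

One boundary convention matters. The edge toward τ carries no operation and
consumes no query character (which is why the heuristic below subtracts one
from path lengths), and it may be traversed at any offset; any unconsumed
query suffix is then inserted *at τ*. This is not cosmetic: the depth-first
match rule discussed below skips insertion edges whenever an unvisited
match successor exists, and that skip is only safe because a deferred
insertion can always be performed later — including after the last labeled
node. Restricting τ-entry to $i = m$ breaks optimality in rare
end-of-query configurations (we observed a one-extension excess under
affine costs on randomized instances before adopting this convention).

## The heuristic

A reverse topological sweep stores for every node the shortest and longest
path length to τ, $d^{\min}_{v,\tau}$ and $d^{\max}_{v,\tau}$ (O(V) memory).
With $l_r = m - i$ the minimum number of indel edges on any completion is

$$N_g^{\min} = \begin{cases}
l_r - (d^{\max}-1) & d^{\max}-1 < l_r\\
(d^{\min}-1) - l_r & d^{\min}-1 > l_r\\
0 & \text{otherwise,}
\end{cases}$$

and $h\langle v,i\rangle = N_g^{\min}\,\Delta_g$ under linear costs. Each
branch identifies the forced gap direction (insertions when the suffix is
too long for the longest path, deletions when too short for the shortest).
Under affine costs we use a layer-aware bound: from M,
$\Delta_o + N_g^{\min}\Delta_e$ when $N_g^{\min} > 0$; from an I (resp. D)
layer whose direction agrees with the forced direction, the opening is
already paid and the bound is $N_g^{\min}\Delta_e$; otherwise
$\Delta_o + N_g^{\min}\Delta_e$. Every gap edge costs at least $\Delta_e$
and a direction-changing continuation must open at least once, so the bound
never exceeds the true remaining cost. The test suite verifies this
*exhaustively* — every reachable state of small random alignment graphs is
compared against a backward-relaxation cost-to-go table — rather than
relying on the argument above.

Admissibility is proven; consistency is not. The search therefore reopens a
state whenever its recorded cost improves after it was queued or closed,
and skips stale queue entries lazily. With reopening, admissibility alone
guarantees that the terminal state pops at the optimal cost.

## Search organization

The priority queue is a binary heap keyed by
$(f, -i, \text{layer } M<D<I, \text{node id})$: lowest $f = g + h$ first,
then deeper query offsets, mirroring the intuition that states near the
terminal finish the job. A bucket queue keyed by integer $f$ would be
asymptotically cheaper but cannot express the secondary ordering; at the
problem sizes this package targets the heap is not a bottleneck, and the
explicit composite key makes pop order platform-independent and fully
deterministic. Ties in *cost* between structurally different alignments
(e.g. one mismatch vs. an insertion+deletion pair at
$\Delta_x = 2\Delta_g$) are resolved by whichever optimal path reaches a
state first under this pop order; the cost is guaranteed, the op list is
deterministic but not canonical.

When an M-layer state pops, a depth-first search consumes chains of
zero-cost match edges, finalizing each state immediately and pushing its
match successors — across branch points too, so one DFS can traverse a
whole allele. At a mismatch frontier the mismatch successor and the
adjacent insertion and deletion states are queued; at an already-visited
match successor only the indel states are queued. Because matches are free
and all other edges cost at least zero, finalizing match chains early never
loses optimality (and any rare suboptimal finalization is healed by the
reopening rule).

## Superbubble pruning

A superbubble $(s, t)$ is an acyclic single-entrance/single-exit
substructure in which every path from $s$ ends at $t$ and no outside path
has an endpoint inside; in POA graphs these are the alleles at a locus.
Detection runs one entrance-candidate sweep per node: from each candidate
$s$, nodes are admitted once all their predecessors are validated, and the
sweep succeeds when the frontier collapses to a single vertex — the
(minimal) exit. This is O(V) per entrance in the worst case rather than the
linear-time bound achievable with the dedicated algorithm from the
assembly-graph literature; at desk scale the simpler procedure is fast, and
its correctness is enforced by a brute-force definitional checker in the
test suite (all ordered node pairs, reachability/closure/minimality checks)
on random DAGs. Nested bubbles index their nodes against every enclosing
exit, innermost first; trivial (empty-interior) bubbles are detected but
not used for pruning, since they offer no alternative paths.

During alignment, every finalized M-layer state $(w, p, C)$ is recorded in
a per-node store of non-dominated (offset, cost) pairs — an entry is
dominated when another entry plus an *implicitly opened gap*
($k\Delta_g$, or $\Delta_o + k\Delta_e$ for $k>0$) reaches its offset at no
greater cost. When a state $\langle v,i\rangle$ inside an indexed bubble
pops with cost $c$, its best-case continuations reach the exit $t$ at
offsets $j \in [i+d^{\min}_{v,t},\, i+d^{\max}_{v,t}]$ at cost $c$. Each
scenario is tested against the recorded entries at $t$; a scenario not
directly dominated is extended along further zero-cost match chains beyond
the exit (bounded by the query remainder), comparing at each node against
implicit gaps from entries recorded there, with every branch required to be
dominated. Only if **all** scenarios are dominated is the state pruned;
domination on equality is allowed, because an equal-cost alternative path
is then known to exist. Two deliberate conservatisms: scenarios whose exit
offset would exceed $m$ (unrealizable by pure matches) block pruning of
that state, and under affine costs only M-layer states are ever pruned.
Soundness is enforced empirically as well: on the randomized suites,
alignment costs with pruning on and off are identical, and no pruned state
ever appears on a reported optimal path.

## The reference DP and its role

`dp_align()` fills dense per-node cost rows in topological order — a single
table under linear costs, M/I/D tables under affine — with the insertion
recurrence vectorized as a prefix-minimum along each row. It shares no code
with the A* engine (which is compiled C++), and refuses instances above
$10^7$ cells: it exists to verify, not to scale. The oracle-equivalence
suite runs 500 randomized progressive instances (2–6 homologs, up to 60 bp,
substitution rate ≤ 25%, indel rate ≤ 10%, both cost models, randomized
cost parameters) and requires exact cost agreement at every progressive
step. Instance sizes were chosen so the full suite runs in well under a
minute on one CPU while still exercising branching graphs, nested bubbles,
and both gap regimes; the same generator at larger settings produces
arbitrarily bigger problems for the A* engine alone.

## Graph update and MSA extraction

Merging an aligned sequence follows classic POA semantics: a match reuses
the node; a mismatch places a new node in the aligned node's column class —
or reuses an existing class member with the query's label, guarded by a
reachability check so the shortcut can never create a cycle; an insertion
opens a fresh class; deletions are skipped by the sequence's path. Columns
are ordered by a topological sort of the class-contracted DAG with the
minimum topological rank of each class as priority. Plain min-rank ordering
is *not* always a linear extension of the column partial order once classes
hold several nodes, so the contracted-graph sort is used, which coincides
with min-rank whenever the latter is consistent; every extraction asserts
strictly increasing columns along every sequence path.

## The homolog simulator

`simulate_homologs()` draws a uniform ancestor and mutates independent
descendants: per-site substitutions at `sub_rate`, per-site indel events at
`indel_rate` with geometric lengths (parameter `indel_geom_p`, mean
$1/p$), insertions and deletions equiprobable. Defaults (5% substitutions,
2% indels, mean length 2) emulate the 82–100% identity regime of bacterial
gene homolog sets at desk scale. What it does *not* emulate: phylogenetic
correlation between descendants (all are independent draws from the
ancestor), compositional bias, tandem repeats, and inversions or
translocations — POA cannot represent the latter at all. Tests passing on
these fixtures therefore certify the algorithmic contracts (optimality,
soundness, round-trips), not alignment quality on any particular biological
dataset.

## Degenerate inputs and numerical choices

Empty queries and empty sequences are rejected; a graph with no labeled
nodes yields the trivial all-insertion alignment without search. Characters
are uppercased on input and compared by strict equality, so IUPAC ambiguity
codes match only themselves, and query characters absent from the graph
alphabet act as guaranteed mismatches. All costs are integers; `DP_INF` is
$10^9$, far above any reachable cost yet safe under addition. Node ids are
dense integers with ν = 1 and τ = 2 fixed; determinism everywhere comes
from explicit orderings (FIFO Kahn topological sort, sorted predecessor
scans in the DP traceback, the composite heap key), never from hash or
platform order.

## Known limitations

Sum-of-pairs optimality of the progressive MSA is out of scope, as are
banded or otherwise inexact modes, two-piece (dual) affine penalties, match
bonuses, bi-directional search, and cyclic or inversion-aware graphs. The
GFA writer emits one single-character segment per node — deliberately naive
so node ids stay stable — and GFA cannot carry column classes, so a re-read
graph restores topology, labels and paths but assigns each node its own
class. Alignment quality (as opposed to cost optimality) depends on the
cost parameters the user chooses; the defaults are a common edit-cost
regime for nucleotide POA, not a tuned scoring scheme.
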