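Package: exactpoa
Title: Exact Partial Order Alignment with A* Search and Superbubble Pruning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Progressive multiple sequence alignment via partial order
    alignment (POA) with per-sequence optimality guarantees. Sequences are
    aligned to a character-labeled DAG by A* search over the alignment graph
    under gap-linear or gap-affine costs, guided by an admissible minimum
    remaining gap cost heuristic, accelerated by depth-first greedy extension
    of zero-cost matches, and by superbubble-informed pruning of alignment
    states that cannot improve on implicitly opened gaps from already reached
    bubble exits. A full dynamic-programming sequence-to-DAG aligner is
    included as an independent oracle, together with a homolog-set simulator,
    FASTA/GFA/DOT input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
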