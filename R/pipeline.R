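#' Align one more sequence into a growing POA graph
#'
#' Convenience wrapper: [poa_align()] followed by [insert_alignment()].
#'
#' @inheritParams poa_align
#' @param name Identifier for the new sequence.
#' @return The updated `poa_graph`, with the alignment attached as attribute
#'   `"last_alignment"`.
#' @export
add_sequence <- function(g, query, name, model = cost_model(),
                         engine = c("astar", "dp"), ...) {
  aln <- poa_align(g, query, model = model, engine = engine, ...)
  g <- insert_alignment(g, query, name, aln)
  attr(g, "last_alignment") <- aln
  g
}

#' Progressive multiple sequence alignment
#'
#' Builds the POA graph from the first sequence and aligns and merges each
#' following one in turn. Every per-sequence alignment is cost-optimal
#' against the current graph; the joint sum-of-pairs score of the progressive
#' MSA is, as for all progressive POA, not guaranteed optimal.
#'
#' @param seqs Named character vector of sequences (>= 1).
#' @param model A [cost_model()].
#' @param engine `"astar"` or `"dp"`.
#' @param order `"input"` or `"length-desc"` (align longest first).
#' @param ... Further arguments to [poa_align()] (e.g. `use_prune = FALSE`).
#' @return List with `graph` (the final `poa_graph`), `msa` (a `poa_msa`),
#'   and `stats` (one row per aligned sequence: name, length, cost, states
#'   expanded/pruned, DFS steps).
#' @export
build_msa <- function(seqs, model = cost_model(), engine = c("astar", "dp"),
                      order = c("input", "length-desc"), ...) {
  engine <- match.arg(engine)
  order <- match.arg(order)
  if (length(seqs) < 1L) stop("need at least one sequence", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names", call. = FALSE)
  if (order == "length-desc") {
    seqs <- seqs[base::order(-nchar(seqs), seq_along(seqs))]
  }

  g <- poa_graph(seqs[[1L]], names(seqs)[1L])
  stats <- list()
  for (k in seq_along(seqs)[-1L]) {
    aln <- poa_align(g, seqs[[k]], model = model, engine = engine, ...)
    g <- insert_alignment(g, seqs[[k]], names(seqs)[k], aln)
    st <- aln$stats
    stats[[length(stats) + 1L]] <- data.frame(
      name = names(seqs)[k],
      length = nchar(seqs[[k]]),
      cost = aln$cost,
      states_expanded = if (is.null(st)) NA_real_ else st$states_expanded,
      states_pruned = if (is.null(st)) NA_real_ else st$states_pruned,
      dfs_steps = if (is.null(st)) NA_real_ else st$dfs_steps)
  }
  stats <- if (length(stats)) do.call(rbind, stats) else
    data.frame(name = character(0), length = integer(0), cost = integer(0),
               states_expanded = numeric(0), states_pruned = numeric(0),
               dfs_steps = numeric(0))
  list(graph = g, msa = poa_msa(g), stats = stats)
}

#' Run the full alignment pipeline from files
#'
#' Reads a FASTA file (or a GFA graph to extend plus a FASTA of queries),
#' computes the progressive MSA, and writes the requested outputs. This is
#' the programmatic core of the command-line interface.
#'
#' @param input Input FASTA path.
#' @param output Output MSA FASTA path (optional).
#' @param graph_in Optional GFA v1 graph to extend instead of starting from
#'   the first sequence.
#' @param graph_out,dot_out,stats_out Optional GFA/DOT/TSV output paths.
#' @param model A [cost_model()].
#' @param engine,order,... As in [build_msa()].
#' @param verbose Log per-sequence costs to stderr.
#' @return Invisibly, the [build_msa()] result list.
#' @export
run_msa <- function(input, output = NULL, graph_in = NULL, graph_out = NULL,
                    dot_out = NULL, stats_out = NULL, model = cost_model(),
                    engine = c("astar", "dp"), order = c("input", "length-desc"),
                    verbose = FALSE, ...) {
  engine <- match.arg(engine)
  order <- match.arg(order)
  seqs <- read_fasta(input)
  if (is.null(graph_in)) {
    res <- build_msa(seqs, model = model, engine = engine, order = order, ...)
  } else {
    g <- read_gfa(graph_in)
    if (anyDuplicated(c(g$seq_names, names(seqs)))) {
      stop("duplicate sequence names between graph and input", call. = FALSE)
    }
    stats <- list()
    for (k in seq_along(seqs)) {
      aln <- poa_align(g, seqs[[k]], model = model, engine = engine, ...)
      g <- insert_alignment(g, seqs[[k]], names(seqs)[k], aln)
      st <- aln$stats
      stats[[k]] <- data.frame(name = names(seqs)[k], length = nchar(seqs[[k]]),
                               cost = aln$cost,
                               states_expanded = if (is.null(st)) NA_real_ else st$states_expanded,
                               states_pruned = if (is.null(st)) NA_real_ else st$states_pruned,
                               dfs_steps = if (is.null(st)) NA_real_ else st$dfs_steps)
    }
    res <- list(graph = g, msa = poa_msa(g), stats = do.call(rbind, stats))
  }
  if (verbose && nrow(res$stats)) {
    for (r in seq_len(nrow(res$stats))) {
      message(sprintf("aligned %s (%d bp): cost %d, %s states expanded",
                      res$stats$name[r], res$stats$length[r], res$stats$cost[r],
                      format(res$stats$states_expanded[r])))
    }
  }
  if (!is.null(output)) write_fasta(res$msa, output)
  if (!is.null(graph_out)) write_gfa(res$graph, graph_out)
  if (!is.null(dot_out)) write_dot(res$graph, dot_out)
  if (!is.null(stats_out)) write_stats(res$stats, stats_out)
  invisible(res)
}
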