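OP_NAMES <- c("match", "mismatch", "insert", "delete")

make_alignment_ <- function(ops_mat, cost, stats = NULL) {
  ops <- data.frame(
    op = factor(OP_NAMES[ops_mat[, 1] + 1L], levels = OP_NAMES),
    node = ops_mat[, 2],
    qpos = ops_mat[, 3]
  )
  structure(list(ops = ops, cost = as.integer(cost), stats = stats),
            class = "poa_alignment")
}

#' @export
print.poa_alignment <- function(x, ...) {
  tab <- table(x$ops$op)
  cat(sprintf("POA alignment: cost %d (%s)\n", x$cost,
              paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", ")))
  if (!is.null(x$stats)) {
    cat(sprintf("  states expanded %d, pruned %d, DFS steps %d\n",
                x$stats$states_expanded, x$stats$states_pruned, x$stats$dfs_steps))
  }
  invisible(x)
}

encode_alphabet_ <- function(labels, qchars) {
  alpha <- sort(unique(c(labels[!is.na(labels)], qchars)))
  list(
    labels = ifelse(is.na(labels), -1L, match(labels, alpha) - 1L),
    query = match(qchars, alpha) - 1L
  )
}

flatten_sb_index_ <- function(idx, n) {
  # CSR of (exit, dmin, dmax) entries per node, non-trivial bubbles only,
  # preserving the innermost-first entry order of the index
  ptr <- integer(n + 1L)
  ex <- integer(0); dmn <- integer(0); dmx <- integer(0)
  nontrivial <- vapply(idx$bubbles, function(b) length(b$interior) > 0L, logical(1))
  for (v in seq_len(n)) {
    e <- idx$entries[[v]]
    keep <- which(nontrivial[e[, "bubble"]])
    ptr[v + 1L] <- ptr[v] + length(keep)
    if (length(keep)) {
      ex <- c(ex, vapply(e[keep, "bubble"], function(b) idx$bubbles[[b]]$t, integer(1)))
      dmn <- c(dmn, e[keep, "dmin"])
      dmx <- c(dmx, e[keep, "dmax"])
    }
  }
  list(ptr = ptr, exit = ex, dmin = dmn, dmax = dmx)
}

#' Align a query sequence to a POA graph
#'
#' Computes a cost-optimal alignment of `query` against the graph as the
#' lowest-cost path in the alignment graph from `<nu, 0>` to `<tau, m>`.
#' The default engine is A* with the minimum remaining gap cost heuristic,
#' depth-first greedy extension of zero-cost matches, and superbubble
#' pruning; each component can be disabled independently (the result cost is
#' unchanged -- they are accelerators, not approximations). `engine = "dp"`
#' runs the full dynamic-programming formulation instead ([dp_align()]).
#'
#' @param g A `poa_graph`.
#' @param query Single non-empty character string. Characters outside the
#'   graph alphabet are legal and simply never match.
#' @param model A [cost_model()].
#' @param engine `"astar"` or `"dp"`.
#' @param use_heuristic,use_dfs,use_prune Toggle the A* accelerators.
#' @param sb_index Optional precomputed [superbubble_index()] (recomputed per
#'   call otherwise when pruning is enabled).
#' @param debug If `TRUE`, record the individual pruned states in
#'   `stats$pruned_states`.
#' @return A `poa_alignment`: `ops` data frame (`op`, `node`, `qpos`),
#'   `cost`, and `stats` (states expanded/pruned, DFS steps).
#' @examples
#' g <- poa_graph("AGGT", "s1")
#' a <- poa_align(g, "ACGT", cost_model("linear", mismatch = 4, gap = 2))
#' a$cost  # 4: one mismatch beats two gaps
#' @export
poa_align <- function(g, query, model = cost_model(), engine = c("astar", "dp"),
                      use_heuristic = TRUE, use_dfs = TRUE, use_prune = TRUE,
                      sb_index = NULL, debug = FALSE) {
  stopifnot(inherits(g, "poa_graph"), inherits(model, "poa_cost_model"))
  engine <- match.arg(engine)
  query <- check_sequence_(query)
  if (engine == "dp") return(dp_align(g, query, model))
  qchars <- strsplit(query, "", fixed = TRUE)[[1]]
  m <- length(qchars)
  n <- n_nodes(g)

  if (n == 2L) {  # no labeled nodes: trivial all-insert alignment
    ops_mat <- cbind(rep(2L, m), rep(NA_integer_, m), seq_len(m))
    aln <- make_alignment_(ops_mat, 0L)
    aln$cost <- alignment_cost(aln$ops, model)
    aln$stats <- list(states_expanded = 0, states_pruned = 0, dfs_steps = 0)
    return(aln)
  }

  d <- dist_to_tau(g)
  enc <- encode_alphabet_(g$labels, qchars)
  if (use_prune) {
    if (is.null(sb_index)) sb_index <- superbubble_index(g)
    sb <- flatten_sb_index_(sb_index, n)
  } else {
    sb <- list(ptr = integer(n + 1L), exit = integer(0),
               dmin = integer(0), dmax = integer(0))
  }
  res <- .astar_engine(g$succ, enc$labels, NU, TAU, d[, "dmin"], d[, "dmax"],
                       enc$query, unclass(model), sb$ptr, sb$exit, sb$dmin,
                       sb$dmax, use_heuristic, use_dfs, use_prune, debug)
  stats <- list(states_expanded = res$expanded, states_pruned = res$pruned,
                dfs_steps = res$dfs_steps)
  if (debug) {
    stats$pruned_states <- res$pruned_states
    colnames(stats$pruned_states) <- c("node", "qpos")
  }
  make_alignment_(res$ops, res$cost, stats)
}
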