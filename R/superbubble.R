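#' Detect all superbubbles of a POA graph
#'
#' A superbubble `(s, t)` is an acyclic single-entrance/single-exit
#' substructure: every path leaving `s` ends in `t`, no path from outside has
#' an endpoint in the interior, and `t` is the nearest such exit for `s`
#' (minimality). In a POA graph superbubbles are the alleles at a locus.
#' Detection runs one entrance-candidate validation sweep per node: starting
#' from each `s`, nodes are admitted once all their predecessors are
#' validated, and the sweep terminates at the first node at which the
#' explored frontier collapses to a single vertex -- its exit. Empty-interior
#' (trivial) bubbles are included.
#'
#' @param g A `poa_graph` (a DAG; cyclic input is rejected by construction).
#' @return List of superbubbles, each a list with `s`, `t` (internal node
#'   ids) and `interior` (integer vector, possibly empty).
#' @export
find_superbubbles <- function(g) {
  stopifnot(inherits(g, "poa_graph"))
  n <- n_nodes(g)
  out <- list()
  seen <- integer(n)     # stamped with the current entrance id
  visited <- integer(n)
  for (s in g$topo) {
    if (length(g$succ[[s]]) == 0L) next
    # sweep from entrance candidate s: a node is admitted (pushed) once all
    # its predecessors are validated; the sweep succeeds at the first point
    # where the frontier collapses to a single yet-unexplored vertex -- the
    # exit t of the (minimal) superbubble with entrance s.
    stack <- s
    seen[s] <- s
    n_seen <- 1L
    t <- NA_integer_
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      visited[v] <- s
      seen[v] <- 0L
      n_seen <- n_seen - 1L
      ch <- g$succ[[v]]
      if (length(ch) == 0L) break  # tip: a path ends before reconverging
      abort <- FALSE
      for (u in ch) {
        if (u == s) { abort <- TRUE; break }
        if (seen[u] != s) {
          seen[u] <- s
          n_seen <- n_seen + 1L
        }
        if (all(visited[g$pred[[u]]] == s)) stack <- c(stack, u)
      }
      if (abort) break
      if (length(stack) == 1L && n_seen == 1L && seen[stack[1L]] == s) {
        t <- stack[1L]
        break
      }
    }
    if (!is.na(t)) {
      interior <- setdiff(which(visited == s), c(s, t))
      out[[length(out) + 1L]] <- list(s = s, t = t,
                                      interior = as.integer(sort(interior)))
    }
  }
  out
}

#' Index nodes by their enclosing superbubbles
#'
#' For every node contained in a superbubble (its entrance and interior; the
#' exit itself is not indexed), stores the minimum and maximum path length in
#' edges to that bubble's exit, computed by a reverse sweep restricted to the
#' bubble. Nodes in nested bubbles are indexed against every enclosing exit,
#' innermost first.
#'
#' @param g A `poa_graph`.
#' @param bubbles Output of [find_superbubbles()]; computed if omitted.
#' @return A `superbubble_index`: list with `bubbles` and `entries` (per
#'   node, an integer matrix with columns `bubble`, `dmin`, `dmax`).
#' @export
superbubble_index <- function(g, bubbles = find_superbubbles(g)) {
  n <- n_nodes(g)
  entries <- replicate(n, list())
  sizes <- vapply(bubbles, function(b) length(b$interior) + 1L, integer(1))
  for (bi in order(sizes, seq_along(bubbles))) {  # innermost first
    b <- bubbles[[bi]]
    members <- c(b$s, b$interior)
    inside <- c(members, b$t)
    dmin <- rep.int(NA_integer_, n)
    dmax <- rep.int(NA_integer_, n)
    dmin[b$t] <- 0L
    dmax[b$t] <- 0L
    ord <- g$topo[g$topo %in% members]
    for (v in rev(ord)) {
      sc <- intersect(g$succ[[v]], inside)
      sc <- sc[!is.na(dmin[sc])]
      if (length(sc) == 0L) next
      dmin[v] <- 1L + min(dmin[sc])
      dmax[v] <- 1L + max(dmax[sc])
    }
    for (v in members) {
      if (is.na(dmin[v])) next
      entries[[v]][[length(entries[[v]]) + 1L]] <-
        c(bubble = bi, dmin = dmin[v], dmax = dmax[v])
    }
  }
  entries <- lapply(entries, function(e) {
    if (length(e)) do.call(rbind, e)
    else matrix(integer(0), ncol = 3, dimnames = list(NULL, c("bubble", "dmin", "dmax")))
  })
  structure(list(bubbles = bubbles, entries = entries),
            class = "superbubble_index")
}

#' @export
print.superbubble_index <- function(x, ...) {
  nt <- sum(vapply(x$bubbles, function(b) length(b$interior) > 0L, logical(1)))
  cat(sprintf("superbubble index: %d bubbles (%d non-trivial)\n",
              length(x$bubbles), nt))
  invisible(x)
}

#' Range of exit states reachable by zero-cost matches
#'
#' From alignment state `<v, i>` inside a superbubble, assuming best-case
#' traversal of zero-cost match edges, the bubble exit `t` is reachable at
#' query offsets `i + dmin` through `i + dmax`.
#'
#' @param idx A [superbubble_index()].
#' @param v Node id (entrance or interior of `bubble`).
#' @param i Query offset.
#' @param bubble Index of the bubble in `idx$bubbles`.
#' @return Integer vector `c(jmin, jmax)` (not clamped to the query length;
#'   callers discard scenarios beyond `m`).
#' @export
reachable_exit_range <- function(idx, v, i, bubble) {
  e <- idx$entries[[v]]
  row <- which(e[, "bubble"] == bubble)
  if (length(row) != 1L) {
    stop("node ", v, " is not indexed in bubble ", bubble, call. = FALSE)
  }
  c(jmin = i + e[row, "dmin"], jmax = i + e[row, "dmax"])
}

#' Dump superbubbles as a TSV-ready data frame
#'
#' @param g A `poa_graph`.
#' @param idx A [superbubble_index()]; computed if omitted.
#' @return Data frame with columns `s`, `t`, `interior_size`, `dmin`, `dmax`
#'   (entrance-to-exit path-length bounds).
#' @export
superbubble_table <- function(g, idx = superbubble_index(g)) {
  rows <- lapply(seq_along(idx$bubbles), function(bi) {
    b <- idx$bubbles[[bi]]
    e <- idx$entries[[b$s]]
    r <- which(e[, "bubble"] == bi)
    data.frame(s = b$s, t = b$t, interior_size = length(b$interior),
               dmin = e[r, "dmin"], dmax = e[r, "dmax"])
  })
  do.call(rbind, rows)
}
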