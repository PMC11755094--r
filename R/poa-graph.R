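#' @useDynLib exactpoa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rgeom runif
#' @importFrom utils head tail
"_PACKAGE"

# Node ids are dense integers; the virtual start node nu is always 1 and the
# virtual end node tau is always 2. Labeled nodes start at 3.
NU <- 1L
TAU <- 2L

new_poa_graph <- function() {
  structure(list(
    labels    = c(NA_character_, NA_character_),
    succ      = list(integer(0), integer(0)),
    pred      = list(integer(0), integer(0)),
    # edge_seqs[[from]][[k]]: integer vector of sequence ids using edge
    # from -> succ[[from]][k]
    edge_seqs = list(list(), list()),
    topo      = c(NU, TAU),
    rank      = c(1L, 2L),
    seq_names = character(0),
    seq_paths = list(),
    class_of  = c(NA_integer_, NA_integer_),
    classes   = list()
  ), class = "poa_graph")
}

n_nodes <- function(g) length(g$labels)

real_nodes <- function(g) setdiff(seq_len(n_nodes(g)), c(NU, TAU))

add_node_ <- function(g, label, class_id = NULL) {
  id <- n_nodes(g) + 1L
  g$labels[id] <- label
  g$succ[[id]] <- integer(0)
  g$pred[[id]] <- integer(0)
  g$edge_seqs[[id]] <- list()
  if (is.null(class_id)) {
    class_id <- length(g$classes) + 1L
    g$classes[[class_id]] <- id
  } else {
    g$classes[[class_id]] <- c(g$classes[[class_id]], id)
  }
  g$class_of[id] <- class_id
  list(g = g, id = id)
}

add_edge_ <- function(g, from, to, seq_id = integer(0)) {
  k <- match(to, g$succ[[from]])
  if (is.na(k)) {
    g$succ[[from]] <- c(g$succ[[from]], to)
    g$edge_seqs[[from]][[length(g$succ[[from]])]] <- as.integer(seq_id)
    g$pred[[to]] <- c(g$pred[[to]], from)
  } else {
    g$edge_seqs[[from]][[k]] <- union(g$edge_seqs[[from]][[k]], as.integer(seq_id))
  }
  g
}

edge_seq_ids <- function(g, from, to) {
  k <- match(to, g$succ[[from]])
  if (is.na(k)) integer(0) else g$edge_seqs[[from]][[k]]
}

# Deterministic FIFO Kahn topological sort; nu is forced first, tau last.
recompute_topo_ <- function(g) {
  n <- n_nodes(g)
  indeg <- vapply(g$pred, length, integer(1))
  queue <- integer(n)
  head_i <- 1L
  tail_i <- 0L
  for (v in seq_len(n)) {
    if (indeg[v] == 0L) {
      tail_i <- tail_i + 1L
      queue[tail_i] <- v
    }
  }
  out <- integer(n)
  cnt <- 0L
  while (head_i <= tail_i) {
    v <- queue[head_i]
    head_i <- head_i + 1L
    cnt <- cnt + 1L
    out[cnt] <- v
    for (w in g$succ[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) {
        tail_i <- tail_i + 1L
        queue[tail_i] <- w
      }
    }
  }
  if (cnt != n) {
    stop("POA graph contains a cycle; invariant violated", call. = FALSE)
  }
  # pin tau to the final position (it is always a sink, but FIFO order may
  # emit it before other sinks' ancestors are exhausted -- it cannot, since
  # tau's indegree only reaches zero when all predecessors are emitted; still,
  # other sinks do not exist in a valid graph)
  g$topo <- out
  g$rank <- integer(n)
  g$rank[out] <- seq_len(n)
  g
}

check_sequence_ <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("sequence must be a single non-empty character string", call. = FALSE)
  }
  toupper(seq)
}

#' Build a POA graph from a single sequence
#'
#' The base case of progressive partial order alignment: a chain graph
#' `nu -> v1 -> ... -> vn -> tau` whose labeled nodes spell `seq`, with one
#' MSA column class per node. Characters are uppercased; any single-character
#' symbol (including IUPAC ambiguity codes) is carried literally and matches
#' only itself during alignment.
#'
#' @param seq Single non-empty character string over the alphabet.
#' @param name Sequence identifier (single string).
#' @return A `poa_graph` object.
#' @examples
#' g <- poa_graph("ACGT", "seq1")
#' length(g$topo)  # 6: nu, 4 labeled nodes, tau
#' @export
poa_graph <- function(seq, name = "seq1") {
  seq <- check_sequence_(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  g <- new_poa_graph()
  prev <- NU
  path <- integer(length(chars))
  for (j in seq_along(chars)) {
    res <- add_node_(g, chars[j])
    g <- res$g
    g <- add_edge_(g, prev, res$id, 1L)
    prev <- res$id
    path[j] <- res$id
  }
  g <- add_edge_(g, prev, TAU, 1L)
  g$seq_names <- as.character(name)
  g$seq_paths <- list(path)
  recompute_topo_(g)
}

#' Build a POA graph from explicit labels and edges
#'
#' Low-level constructor used to realize specific DAG topologies (e.g. when
#' reading GFA, or building test graphs with a known superbubble structure).
#' Nodes are numbered `1..length(labels)` externally; sources are attached to
#' the virtual start node and sinks to the virtual end node automatically.
#'
#' @param labels Character vector of single-character node labels.
#' @param edges Two-column integer matrix of directed edges between external
#'   node ids.
#' @param paths Optional list of integer vectors (external ids), one per
#'   sequence threading the graph; used to populate edge sequence sets and to
#'   extract an MSA.
#' @param seq_names Optional character vector naming `paths`.
#' @return A `poa_graph`; element `node_map[k]` gives the internal id of
#'   external node `k`.
#' @export
poa_graph_from_edges <- function(labels, edges, paths = NULL, seq_names = NULL) {
  labels <- toupper(as.character(labels))
  n <- length(labels)
  if (n == 0L) stop("need at least one labeled node", call. = FALSE)
  if (any(nchar(labels) != 1L)) stop("labels must be single characters", call. = FALSE)
  g <- new_poa_graph()
  map <- integer(n)
  for (k in seq_len(n)) {
    res <- add_node_(g, labels[k])
    g <- res$g
    map[k] <- res$id
  }
  if (!is.null(edges) && length(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2)
    for (r in seq_len(nrow(edges))) {
      g <- add_edge_(g, map[edges[r, 1]], map[edges[r, 2]])
    }
  }
  # attach sources/sinks to the virtual terminals
  for (k in seq_len(n)) {
    id <- map[k]
    if (length(g$pred[[id]]) == 0L) g <- add_edge_(g, NU, id)
    if (length(g$succ[[id]]) == 0L) g <- add_edge_(g, id, TAU)
  }
  if (!is.null(paths)) {
    if (is.null(seq_names)) seq_names <- paste0("seq", seq_along(paths))
    for (s in seq_along(paths)) {
      p <- map[paths[[s]]]
      full <- c(NU, p, TAU)
      for (j in seq_len(length(full) - 1L)) {
        g <- add_edge_(g, full[j], full[j + 1L], s)
      }
      g$seq_paths[[s]] <- p
    }
    g$seq_names <- as.character(seq_names)
  }
  g <- recompute_topo_(g)
  g$node_map <- map
  g
}

#' Shortest and longest path lengths to the end node
#'
#' For every node `v`, the minimum and maximum number of edges on a directed
#' path from `v` to the virtual end node tau, computed in a single reverse
#' topological sweep. These per-node bounds feed the minimum remaining gap
#' cost heuristic.
#'
#' @param g A `poa_graph`.
#' @return Integer matrix with one row per node and columns `dmin`, `dmax`;
#'   the tau row is `(0, 0)`.
#' @export
dist_to_tau <- function(g) {
  n <- n_nodes(g)
  dmin <- rep.int(NA_integer_, n)
  dmax <- rep.int(NA_integer_, n)
  dmin[TAU] <- 0L
  dmax[TAU] <- 0L
  for (v in rev(g$topo)) {
    if (v == TAU) next
    s <- g$succ[[v]]
    if (length(s) == 0L) next  # malformed sink; left NA
    dmin[v] <- 1L + min(dmin[s])
    dmax[v] <- 1L + max(dmax[s])
  }
  cbind(dmin = dmin, dmax = dmax)
}

#' Merge an aligned sequence into a POA graph
#'
#' Applies classic POA merge semantics: a match reuses the graph node (the
#' edge sequence sets are extended), a mismatch creates -- or reuses, when the
#' aligned node's column class already holds a node with the query's label --
#' a node in the same MSA column class, and an insertion creates a node in a
#' fresh class. Deleted graph nodes are skipped by the new sequence's path.
#' Acyclicity and the topological order are restored afterwards.
#'
#' @param g A `poa_graph`.
#' @param seq The query sequence that was aligned (single string).
#' @param name Its identifier; must not duplicate an existing one.
#' @param alignment A `poa_alignment` (from [poa_align()] or [dp_align()])
#'   of `seq` against `g`.
#' @return The updated `poa_graph`.
#' @export
insert_alignment <- function(g, seq, name, alignment) {
  stopifnot(inherits(g, "poa_graph"))
  seq <- check_sequence_(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- length(chars)
  if (name %in% g$seq_names) {
    stop("duplicate sequence name: ", name, call. = FALSE)
  }
  ops <- alignment$ops
  validate_alignment_ops_(g, ops, m)

  seq_id <- length(g$seq_names) + 1L
  prev <- NU
  path <- integer(0)
  new_edges <- list()
  for (r in seq_len(nrow(ops))) {
    kind <- ops$op[r]
    if (kind == "delete") next
    qc <- chars[ops$qpos[r]]
    if (kind == "match") {
      nd <- ops$node[r]
      if (!identical(g$labels[nd], qc)) {
        stop("match op against node with different label", call. = FALSE)
      }
    } else if (kind == "mismatch") {
      u <- ops$node[r]
      cls <- g$class_of[u]
      members <- g$classes[[cls]]
      cand <- members[!is.na(g$labels[members]) & g$labels[members] == qc]
      nd <- NA_integer_
      if (length(cand)) {
        # reuse-within-class, guarded against creating a cycle
        for (w in cand) {
          if (!reaches_(g, w, prev)) { nd <- w; break }
        }
      }
      if (is.na(nd)) {
        res <- add_node_(g, qc, cls)
        g <- res$g
        nd <- res$id
      }
    } else { # insert
      res <- add_node_(g, qc)
      g <- res$g
      nd <- res$id
    }
    g <- add_edge_(g, prev, nd, seq_id)
    prev <- nd
    path <- c(path, nd)
  }
  g <- add_edge_(g, prev, TAU, seq_id)
  g$seq_names <- c(g$seq_names, as.character(name))
  g$seq_paths[[seq_id]] <- path
  recompute_topo_(g)
}

# Is `to` reachable from `from` via directed edges? (small-graph DFS)
reaches_ <- function(g, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(n_nodes(g))
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    s <- g$succ[[v]]
    if (to %in% s) return(TRUE)
    stack <- c(stack, s[!seen[s]])
  }
  FALSE
}

validate_alignment_ops_ <- function(g, ops, m) {
  if (!is.data.frame(ops) || !all(c("op", "node", "qpos") %in% names(ops))) {
    stop("alignment ops must be a data frame with op/node/qpos", call. = FALSE)
  }
  consumed <- ops$qpos[ops$op %in% c("match", "mismatch", "insert")]
  if (!identical(as.integer(consumed), seq_len(m))) {
    stop("alignment does not consume query offsets 1..m exactly once, in order",
         call. = FALSE)
  }
  nd <- ops$node[ops$op %in% c("match", "mismatch", "delete")]
  if (any(is.na(nd)) || any(nd < 3L) || any(nd > n_nodes(g))) {
    stop("alignment references unknown or virtual node ids", call. = FALSE)
  }
  # nodes traversed (match/mismatch/delete) must follow graph edges
  if (length(nd) > 1L) {
    for (j in seq_len(length(nd) - 1L)) {
      if (!(nd[j + 1L] %in% g$succ[[nd[j]]])) {
        stop("alignment path is not a path in the graph", call. = FALSE)
      }
    }
  }
  if (length(nd)) {
    if (!(nd[1L] %in% g$succ[[NU]])) {
      stop("alignment path does not start at a successor of nu", call. = FALSE)
    }
    if (!(TAU %in% g$succ[[nd[length(nd)]]])) {
      stop("alignment path does not end at a predecessor of tau", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Extract the MSA encoded by a POA graph
#'
#' Each MSA column corresponds to one alignment class of the graph. Columns
#' are ordered by a topological sort of the class-contracted DAG, with the
#' minimum topological rank of a class's member nodes as priority (ties by
#' class creation order), so column order is always consistent with the
#' partial order of every sequence path.
#'
#' @param g A `poa_graph` with at least one threaded sequence.
#' @return A `poa_msa`: list with `rows` (named character vector of gapped
#'   sequences) and `column_count`.
#' @export
poa_msa <- function(g) {
  stopifnot(inherits(g, "poa_graph"))
  if (length(g$seq_paths) == 0L) {
    stop("graph has no threaded sequences; nothing to extract", call. = FALSE)
  }
  nc <- length(g$classes)
  minrank <- vapply(g$classes, function(mem) min(g$rank[mem]), integer(1))
  # class-contracted edges
  cin <- rep.int(0L, nc)
  cadj <- vector("list", nc)
  for (v in real_nodes(g)) {
    cv <- g$class_of[v]
    for (w in g$succ[[v]]) {
      if (w == TAU) next
      cw <- g$class_of[w]
      if (cw != cv && !(cw %in% cadj[[cv]])) {
        cadj[[cv]] <- c(cadj[[cv]], cw)
        cin[cw] <- cin[cw] + 1L
      }
    }
  }
  key <- minrank * (nc + 1) + seq_len(nc)  # priority: min rank, then class id
  active <- cin == 0L
  order_cls <- integer(nc)
  kk <- key
  kk[!active] <- Inf
  for (pos in seq_len(nc)) {
    c0 <- which.min(kk)
    if (!is.finite(kk[c0])) {
      # contracted graph cyclic (not expected); fall back to min-rank order
      order_cls <- order(key)
      break
    }
    order_cls[pos] <- c0
    kk[c0] <- Inf
    for (cw in cadj[[c0]]) {
      cin[cw] <- cin[cw] - 1L
      if (cin[cw] == 0L) kk[cw] <- key[cw]
    }
  }
  col_of <- integer(nc)
  col_of[order_cls] <- seq_len(nc)

  rows <- character(length(g$seq_paths))
  for (s in seq_along(g$seq_paths)) {
    p <- g$seq_paths[[s]]
    row <- rep.int("-", nc)
    cols <- col_of[g$class_of[p]]
    if (is.unsorted(cols, strictly = TRUE)) {
      stop("internal error: MSA column order inconsistent with a sequence path",
           call. = FALSE)
    }
    row[cols] <- g$labels[p]
    rows[s] <- paste(row, collapse = "")
  }
  names(rows) <- g$seq_names
  structure(list(rows = rows, column_count = nc), class = "poa_msa")
}

#' @export
print.poa_msa <- function(x, ...) {
  cat(sprintf("POA multiple sequence alignment: %d sequences x %d columns\n",
              length(x$rows), x$column_count))
  nm <- format(names(x$rows))
  for (i in seq_along(x$rows)) cat(nm[i], " ", x$rows[i], "\n", sep = "")
  invisible(x)
}

#' @export
print.poa_graph <- function(x, ...) {
  ne <- sum(vapply(x$succ, length, integer(1)))
  cat(sprintf("POA graph: %d labeled nodes, %d edges, %d sequences\n",
              n_nodes(x) - 2L, ne, length(x$seq_names)))
  invisible(x)
}

#' Check the structural invariants of a POA graph
#'
#' Verifies acyclicity (complete topological order with all edges forward),
#' the virtual-node contract (nu has no predecessors and covers all sources,
#' tau has no successors and covers all sinks), label presence, and that
#' sequence de-threading matches the recorded paths.
#'
#' @param g A `poa_graph`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_poa <- function(g) {
  n <- n_nodes(g)
  stopifnot(length(g$topo) == n)
  r <- g$rank
  for (v in seq_len(n)) {
    for (w in g$succ[[v]]) {
      if (r[w] <= r[v]) stop("edge against topological order", call. = FALSE)
    }
  }
  if (length(g$pred[[NU]])) stop("nu has predecessors", call. = FALSE)
  if (length(g$succ[[TAU]])) stop("tau has successors", call. = FALSE)
  for (v in real_nodes(g)) {
    if (is.na(g$labels[v])) stop("unlabeled non-virtual node", call. = FALSE)
    if (length(g$pred[[v]]) == 0L) stop("orphan source not attached to nu", call. = FALSE)
    if (length(g$succ[[v]]) == 0L) stop("orphan sink not attached to tau", call. = FALSE)
  }
  for (s in seq_along(g$seq_paths)) {
    p <- g$seq_paths[[s]]
    full <- c(NU, p, TAU)
    for (j in seq_len(length(full) - 1L)) {
      if (!(s %in% edge_seq_ids(g, full[j], full[j + 1L]))) {
        stop("sequence path edge missing its sequence id", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Recover an input sequence from its graph path
#'
#' @param g A `poa_graph`.
#' @param which Sequence index or name.
#' @return The stored sequence spelled by the path (character string).
#' @export
poa_sequence <- function(g, which) {
  if (is.character(which)) which <- match(which, g$seq_names)
  paste(g$labels[g$seq_paths[[which]]], collapse = "")
}
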