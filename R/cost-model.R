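#' Alignment cost model
#'
#' Costs are non-negative integers with the match cost fixed at zero, so the
#' optimal alignment is the lowest-cost path in the alignment graph and
#' zero-cost match edges can be consumed greedily. Under the gap-linear model
#' every gap position costs `gap`; under the gap-affine model each distinct
#' gap costs `gap_open` once plus `gap_extend` per position, with
#' `gap_open > gap_extend` required.
#'
#' Defaults (`mismatch = 4`, `gap = 2`, `gap_open = 6`, `gap_extend = 2`) are
#' the edit-cost regime commonly used for nucleotide POA.
#'
#' @param kind `"linear"` or `"affine"`.
#' @param mismatch Mismatch cost (>= 0).
#' @param gap Per-position gap cost (linear model).
#' @param gap_open Gap opening cost (affine model).
#' @param gap_extend Gap extension cost (affine model).
#' @return A `poa_cost_model`.
#' @export
cost_model <- function(kind = c("linear", "affine"), mismatch = 4L, gap = 2L,
                       gap_open = 6L, gap_extend = 2L) {
  kind <- match.arg(kind)
  chk <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x)) {
      stop(nm, " must be a single non-negative integer", call. = FALSE)
    }
    as.integer(x)
  }
  mismatch <- chk(mismatch, "mismatch")
  out <- list(kind = kind, dm = 0L, dx = mismatch)
  if (kind == "linear") {
    out$dg <- chk(gap, "gap")
  } else {
    out$do <- chk(gap_open, "gap_open")
    out$de <- chk(gap_extend, "gap_extend")
    if (out$do <= out$de) {
      stop("affine model requires gap_open > gap_extend", call. = FALSE)
    }
  }
  structure(out, class = "poa_cost_model")
}

#' @export
print.poa_cost_model <- function(x, ...) {
  if (x$kind == "linear") {
    cat(sprintf("gap-linear cost model: mismatch %d, gap %d (match 0)\n", x$dx, x$dg))
  } else {
    cat(sprintf("gap-affine cost model: mismatch %d, gap open %d, gap extend %d (match 0)\n",
                x$dx, x$do, x$de))
  }
  invisible(x)
}

#' Total cost of an alignment operation list
#'
#' Counts matches, mismatches and gap positions from `ops` and applies the
#' model: `Nx * dx + Ng * dg` (linear) or `Nx * dx + No * do + Ng * de`
#' (affine), where a maximal run of consecutive same-direction gap operations
#' counts as one distinct gap for `No`.
#'
#' @param ops Data frame with columns `op` (`match`/`mismatch`/`insert`/
#'   `delete`), `node`, `qpos`, as produced by [poa_align()].
#' @param model A [cost_model()].
#' @return Integer total cost.
#' @export
alignment_cost <- function(ops, model) {
  kinds <- as.character(ops$op)
  nx <- sum(kinds == "mismatch")
  is_gap <- kinds %in% c("insert", "delete")
  ng <- sum(is_gap)
  if (model$kind == "linear") {
    return(nx * model$dx + ng * model$dg)
  }
  # distinct gaps: runs of identical consecutive gap kinds
  runs <- rle(kinds)
  no <- sum(runs$values %in% c("insert", "delete"))
  nx * model$dx + no * model$do + ng * model$de
}

#' Minimum number of indel edges to alignment termination
#'
#' Given the shortest/longest path lengths `dmin`/`dmax` from a node to the
#' end node tau and the unaligned query length `lr = m - i`, the minimum
#' number of indel edges any completion must traverse is
#' `lr - (dmax - 1)` when `dmax - 1 < lr` (insertions required),
#' `(dmin - 1) - lr` when `dmin - 1 > lr` (deletions required),
#' and 0 otherwise. One is subtracted from `dmin`/`dmax` because the final
#' edge into tau consumes no query character.
#'
#' @param dmin,dmax Path-length bounds to tau (edges), `dmin >= 1`.
#' @param lr Unaligned query length, `>= 0`. All arguments recycle.
#' @return Integer vector of minimum indel-edge counts.
#' @export
min_indel_edges <- function(dmin, dmax, lr) {
  stopifnot(all(dmin >= 1L), all(dmax >= dmin), all(lr >= 0L))
  ifelse(dmax - 1L < lr, lr - (dmax - 1L),
         ifelse(dmin - 1L > lr, (dmin - 1L) - lr, 0L))
}

# Direction of the forced indels: "ins", "del" or "none".
indel_direction_ <- function(dmin, dmax, lr) {
  if (dmax - 1L < lr) "ins" else if (dmin - 1L > lr) "del" else "none"
}

#' Precompute the heuristic tables for a graph/query pair
#'
#' Stores the per-node shortest/longest path lengths to tau (one reverse
#' topological sweep, O(V) memory) and the query length.
#'
#' @param g A `poa_graph`.
#' @param m Query length.
#' @return A `poa_heuristic_tables` list with `dmin`, `dmax`, `m`.
#' @export
heuristic_tables <- function(g, m) {
  d <- dist_to_tau(g)
  structure(list(dmin = d[, "dmin"], dmax = d[, "dmax"], m = as.integer(m)),
            class = "poa_heuristic_tables")
}

#' Minimum remaining gap cost heuristic
#'
#' Admissible lower bound on the remaining alignment cost from state
#' `<v, i>`: the minimum number of indel edges still to traverse
#' ([min_indel_edges()]) times the per-position gap cost. Under the affine
#' model the bound is layer-aware: from the match layer a positive indel
#' count costs at least one gap opening plus extensions; from an open
#' insertion (resp. deletion) layer whose direction agrees with the forced
#' indels, the opening is already paid and only extensions are counted.
#'
#' @param v Node id (internal; tau is 2).
#' @param i Query offset, `0..m`.
#' @param tables From [heuristic_tables()].
#' @param model A [cost_model()].
#' @param layer `"M"`, `"I"` or `"D"` (ignored under the linear model).
#' @return Non-negative integer lower bound; 0 at tau.
#' @export
gap_heuristic <- function(v, i, tables, model, layer = "M") {
  if (v == TAU) {  # only trailing insertions remain
    lr <- tables$m - i
    if (lr == 0L) return(0L)
    if (model$kind == "linear") return(as.integer(lr * model$dg))
    return(as.integer(if (layer == "I") lr * model$de else model$do + lr * model$de))
  }
  dmin <- tables$dmin[v]
  dmax <- tables$dmax[v]
  lr <- tables$m - i
  ng <- min_indel_edges(dmin, dmax, lr)
  if (model$kind == "linear") return(as.integer(ng * model$dg))
  if (ng == 0L) return(0L)
  dir <- indel_direction_(dmin, dmax, lr)
  open_paid <- (layer == "I" && dir == "ins") || (layer == "D" && dir == "del")
  as.integer(if (open_paid) ng * model$de else model$do + ng * model$de)
}

#' Upper-bound cost of an implicitly opened gap
#'
#' Cost of hypothesizing a gap of `k` positions from an already reached
#' alignment state: `k * dg` (linear) or `do + k * de` for `k > 0` (affine).
#' Used by superbubble pruning as an on-the-fly upper bound for yet-to-visit
#' states.
#'
#' @param k Gap length(s), `>= 0`.
#' @param model A [cost_model()].
#' @return Integer vector of costs; 0 where `k == 0`.
#' @export
implicit_gap_cost <- function(k, model) {
  stopifnot(all(k >= 0L))
  if (model$kind == "linear") return(as.integer(k * model$dg))
  as.integer(ifelse(k == 0L, 0L, model$do + k * model$de))
}

#' Enumerate the successors of an alignment state
#'
#' Reference semantics of the alignment graph: from `<u, i>` in the match
#' layer, each graph successor `v` contributes a (mis)match edge to
#' `<v, i+1>` (cost 0 or `dx`) and a deletion edge (cost `dg`, or a gap
#' opening into the D layer under the affine model); an insertion edge leads
#' to `<u, i+1>`. The edge toward tau is free and consumes nothing; any
#' unconsumed query suffix is inserted at tau, so the terminal `<tau, m>`
#' (which has no successors) is always reachable. Affine I/D layers extend
#' with `de` and close into the match layer at zero cost.
#'
#' @param g A `poa_graph`.
#' @param state List with `v`, `i` and (affine) `layer`.
#' @param query Query string.
#' @param model A [cost_model()].
#' @return Data frame of successors: `v`, `i`, `layer`, `cost`, `op`.
#' @export
expand_state <- function(g, state, query, model) {
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  m <- length(q)
  v <- state$v
  i <- state$i
  layer <- if (is.null(state$layer) || model$kind == "linear") "M" else state$layer
  out <- list()
  emit <- function(v2, i2, l2, cost, op) {
    out[[length(out) + 1L]] <<- list(v = v2, i = i2, layer = l2,
                                     cost = as.integer(cost), op = op)
  }
  if (v == TAU) {
    # at tau only trailing insertions remain; <tau, m> is terminal
    if (layer == "M" && i < m) {
      if (model$kind == "linear") emit(TAU, i + 1L, "M", model$dg, "insert")
      else emit(TAU, i + 1L, "I", model$do + model$de, "insert")
    } else if (layer == "I") {
      emit(TAU, i, "M", 0L, "close")
      if (i < m) emit(TAU, i + 1L, "I", model$de, "insert")
    }
  } else if (layer == "M") {
    for (v2 in g$succ[[v]]) {
      if (v2 == TAU) {
        # the edge toward tau carries no operation and consumes nothing
        emit(TAU, i, "M", 0L, "end")
        next
      }
      if (i < m) {
        hit <- identical(g$labels[v2], q[i + 1L])
        emit(v2, i + 1L, "M", if (hit) 0L else model$dx,
             if (hit) "match" else "mismatch")
      }
      if (model$kind == "linear") {
        emit(v2, i, "M", model$dg, "delete")
      } else {
        emit(v2, i, "D", model$do + model$de, "delete")
      }
    }
    if (i < m) {
      if (model$kind == "linear") {
        emit(v, i + 1L, "M", model$dg, "insert")
      } else {
        emit(v, i + 1L, "I", model$do + model$de, "insert")
      }
    }
  } else if (layer == "D") {
    emit(v, i, "M", 0L, "close")
    for (v2 in g$succ[[v]]) {
      if (v2 != TAU) emit(v2, i, "D", model$de, "delete")
    }
  } else { # I
    emit(v, i, "M", 0L, "close")
    if (i < m) emit(v, i + 1L, "I", model$de, "insert")
  }
  if (length(out) == 0L) {
    return(data.frame(v = integer(0), i = integer(0), layer = character(0),
                      cost = integer(0), op = character(0)))
  }
  do.call(rbind, lapply(out, as.data.frame))
}

#' Memory footprint of the full dynamic-programming formulation
#'
#' Bytes needed to materialize the dense DP cost tables for a graph of
#' `nodes` nodes and a query of length `m`: `nodes * (m + 1) * layers *
#' bytes_per_cell` (one row per node, `m + 1` query offsets, one table per
#' alignment layer).
#'
#' @param nodes Number of graph nodes.
#' @param m Query length.
#' @param layers Number of state matrices (3 for gap-affine).
#' @param bytes_per_cell Bytes per stored cost (4 for 32-bit integers).
#' @return Estimated bytes (double, to allow terabyte-scale values).
#' @export
dp_memory_estimate <- function(nodes, m, layers = 3, bytes_per_cell = 4) {
  stopifnot(nodes > 0, m > 0, layers > 0, bytes_per_cell > 0)
  as.numeric(nodes) * (as.numeric(m) + 1) * layers * bytes_per_cell
}
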