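DP_INF <- 1e9
DP_MAX_CELLS <- 1e7

#' Full dynamic-programming sequence-to-DAG alignment
#'
#' The conventional O(|V| m) formulation: dense per-layer cost tables filled
#' in topological order, each cell the minimum over its incoming
#' alignment-graph edges (a single table under gap-linear costs, Gotoh-style
#' M/I/D tables under gap-affine costs), followed by a deterministic
#' traceback. Deliberately simple -- no heuristic, no pruning -- it serves as
#' the correctness oracle for the A* engine and refuses inputs above
#' `1e7` cells.
#'
#' @param g A `poa_graph`.
#' @param query Single non-empty character string.
#' @param model A [cost_model()].
#' @return A `poa_alignment` (as [poa_align()], `stats = NULL`).
#' @export
dp_align <- function(g, query, model = cost_model()) {
  stopifnot(inherits(g, "poa_graph"), inherits(model, "poa_cost_model"))
  query <- check_sequence_(query)
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  m <- length(q)
  n <- n_nodes(g)
  if (as.double(n) * (m + 1) > DP_MAX_CELLS) {
    stop("DP table would exceed ", format(DP_MAX_CELLS, scientific = FALSE),
         " cells; use the A* engine", call. = FALSE)
  }
  if (n == 2L) {
    ops_mat <- cbind(rep(2L, m), rep(NA_integer_, m), seq_len(m))
    aln <- make_alignment_(ops_mat, 0L)
    aln$cost <- alignment_cost(aln$ops, model)
    return(aln)
  }
  if (model$kind == "linear") dp_linear_(g, q, m, n, model)
  else dp_affine_(g, q, m, n, model)
}

dp_linear_ <- function(g, q, m, n, model) {
  dx <- model$dx; dg <- model$dg
  idx <- 0:m
  S <- matrix(DP_INF, n, m + 1L)
  S[NU, ] <- idx * dg
  for (v in g$topo) {
    if (v == NU || v == TAU) next
    subv <- ifelse(g$labels[v] == q, 0, dx)
    best <- rep.int(DP_INF, m + 1L)
    for (u in g$pred[[v]]) {
      best <- pmin(best, c(DP_INF, S[u, 1:m] + subv))  # (mis)match arrival
      best <- pmin(best, S[u, ] + dg)                  # deletion arrival
    }
    # chains of insertions within the row: prefix-minimum relaxation
    pref <- c(DP_INF, cummin(best - idx * dg)[1:m])
    S[v, ] <- pmin(best, pref + idx * dg)
  }
  # tau row: entered free from any predecessor, trailing insertions within
  preds_tau <- sort(g$pred[[TAU]])
  btau <- rep.int(DP_INF, m + 1L)
  for (u in preds_tau) btau <- pmin(btau, S[u, ])
  pref_tau <- c(DP_INF, cummin(btau - idx * dg)[1:m])
  S[TAU, ] <- pmin(btau, pref_tau + idx * dg)
  cost <- S[TAU, m + 1L]

  # traceback (preference: consume query, then delete, then insert)
  ops <- list()
  emit <- function(op, node, qpos) {
    ops[[length(ops) + 1L]] <<- c(op, node, qpos)
  }
  v <- TAU
  i <- m
  while (!(v == NU && i == 0L)) {
    if (v == TAU) {
      val <- S[TAU, i + 1L]
      if (i >= 1L && S[TAU, i] + dg == val) {
        emit(2L, NA_integer_, i)
        i <- i - 1L
      } else {
        nxt <- NA_integer_
        for (u in preds_tau) if (S[u, i + 1L] == val) { nxt <- u; break }
        if (is.na(nxt)) stop("internal error: DP traceback stuck", call. = FALSE)
        v <- nxt
      }
      next
    }
    val <- S[v, i + 1L]
    stepped <- FALSE
    if (i >= 1L && v != NU) {
      sub <- if (identical(g$labels[v], q[i])) 0 else dx
      for (u in sort(g$pred[[v]])) {
        if (S[u, i] + sub == val) {
          emit(if (sub == 0) 0L else 1L, v, i)
          v <- u; i <- i - 1L; stepped <- TRUE; break
        }
      }
    }
    if (!stepped && v != NU) {
      for (u in sort(g$pred[[v]])) {
        if (S[u, i + 1L] + dg == val) {
          emit(3L, v, NA_integer_)
          v <- u; stepped <- TRUE; break
        }
      }
    }
    if (!stepped) {
      if (i >= 1L && S[v, i] + dg == val || (v == NU && i >= 1L)) {
        emit(2L, NA_integer_, i)
        i <- i - 1L; stepped <- TRUE
      }
    }
    if (!stepped) stop("internal error: DP traceback stuck", call. = FALSE)
  }
  ops_mat <- do.call(rbind, rev(ops))
  if (is.null(ops_mat)) ops_mat <- matrix(integer(0), ncol = 3)
  make_alignment_(ops_mat, cost)
}

dp_affine_ <- function(g, q, m, n, model) {
  dx <- model$dx; go <- model$do; ge <- model$de
  idx <- 0:m
  M <- matrix(DP_INF, n, m + 1L)
  D <- matrix(DP_INF, n, m + 1L)
  I <- matrix(DP_INF, n, m + 1L)
  M[NU, 1L] <- 0
  if (m >= 1L) I[NU, 2:(m + 1L)] <- go + (1:m) * ge
  B <- function(u) pmin(M[u, ], D[u, ], I[u, ])
  for (v in g$topo) {
    if (v == NU || v == TAU) next
    subv <- ifelse(g$labels[v] == q, 0, dx)
    Mrow <- rep.int(DP_INF, m + 1L)
    Drow <- rep.int(DP_INF, m + 1L)
    for (u in g$pred[[v]]) {
      bu <- B(u)
      Mrow <- pmin(Mrow, c(DP_INF, bu[1:m] + subv))
      Drow <- pmin(Drow, bu + go + ge, D[u, ] + ge)
    }
    MD <- pmin(Mrow, Drow)
    Irow <- c(DP_INF, cummin(MD - idx * ge)[1:m]) + idx * ge + go
    M[v, ] <- Mrow; D[v, ] <- Drow; I[v, ] <- Irow
  }
  # tau row: entered free from any predecessor, trailing insertions within
  preds_tau <- sort(g$pred[[TAU]])
  Mtau <- rep.int(DP_INF, m + 1L)
  for (u in preds_tau) Mtau <- pmin(Mtau, B(u))
  M[TAU, ] <- Mtau
  I[TAU, ] <- c(DP_INF, cummin(Mtau - idx * ge)[1:m]) + idx * ge + go
  cost <- min(M[TAU, m + 1L], I[TAU, m + 1L])

  layer_at <- function(v, i) {  # preference M, D, I
    b <- min(M[v, i + 1L], D[v, i + 1L], I[v, i + 1L])
    if (M[v, i + 1L] == b) "M" else if (D[v, i + 1L] == b) "D" else "I"
  }
  ops <- list()
  emit <- function(op, node, qpos) {
    ops[[length(ops) + 1L]] <<- c(op, node, qpos)
  }
  v <- TAU
  i <- m
  layer <- if (M[TAU, m + 1L] <= I[TAU, m + 1L]) "M" else "I"
  while (!(v == NU && i == 0L && layer == "M")) {
    stepped <- FALSE
    if (v == TAU && layer == "M") {
      val <- M[TAU, i + 1L]
      for (u in preds_tau) {
        bu <- min(M[u, i + 1L], D[u, i + 1L], I[u, i + 1L])
        if (bu == val) {
          v <- u
          layer <- layer_at(u, i)
          stepped <- TRUE
          break
        }
      }
    } else if (layer == "M") {
      val <- M[v, i + 1L]
      sub <- if (identical(g$labels[v], q[i])) 0 else dx
      for (u in sort(g$pred[[v]])) {
        bu <- min(M[u, i], D[u, i], I[u, i])
        if (i >= 1L && bu + sub == val) {
          emit(if (sub == 0) 0L else 1L, v, i)
          v <- u; i <- i - 1L; layer <- layer_at(v, i); stepped <- TRUE
          break
        }
      }
    } else if (layer == "D") {
      val <- D[v, i + 1L]
      for (u in sort(g$pred[[v]])) {  # extension preferred
        if (D[u, i + 1L] + ge == val) {
          emit(3L, v, NA_integer_)
          v <- u; layer <- "D"; stepped <- TRUE; break
        }
      }
      if (!stepped) {
        for (u in sort(g$pred[[v]])) {
          bu <- min(M[u, i + 1L], D[u, i + 1L], I[u, i + 1L])
          if (bu + go + ge == val) {
            emit(3L, v, NA_integer_)
            v <- u; layer <- layer_at(v, i); stepped <- TRUE; break
          }
        }
      }
    } else { # I
      val <- I[v, i + 1L]
      if (i >= 1L && I[v, i] + ge == val) {
        emit(2L, NA_integer_, i)
        i <- i - 1L; layer <- "I"; stepped <- TRUE
      } else if (i >= 1L) {
        md <- min(M[v, i], D[v, i])
        if (md + go + ge == val) {
          emit(2L, NA_integer_, i)
          i <- i - 1L
          layer <- if (M[v, i + 1L] <= D[v, i + 1L]) "M" else "D"
          stepped <- TRUE
        }
      }
    }
    if (!stepped) stop("internal error: affine DP traceback stuck", call. = FALSE)
  }
  ops_mat <- do.call(rbind, rev(ops))
  if (is.null(ops_mat)) ops_mat <- matrix(integer(0), ncol = 3)
  make_alignment_(ops_mat, cost)
}
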