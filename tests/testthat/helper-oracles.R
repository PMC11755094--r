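# Independent oracles and generators used across the suite. None of these
# share code with the package's search or index implementations.

degap <- function(x) gsub("-", "", x)

# Random DAG over n labeled nodes: edges only from lower to higher external
# ids, so acyclicity holds by construction.
random_dag <- function(n, edge_p = 0.35) {
  labels <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < edge_p
  edges <- pairs[keep, , drop = FALSE]
  poa_graph_from_edges(labels, if (nrow(edges)) edges else NULL)
}

# All path lengths (edge counts) from internal node v to tau, by enumeration.
all_path_lengths_to_tau <- function(g, v) {
  if (v == 2L) return(0L)
  out <- integer(0)
  for (w in g$succ[[v]]) out <- c(out, 1L + all_path_lengths_to_tau(g, w))
  out
}

# Brute-force superbubble finder straight from the definition: for entrance
# s and candidate exit t, R = nodes reachable from s without passing t;
# (s, t) qualifies iff R has no sink, interior nodes and t have all their
# predecessors inside, and t is the minimal such exit for s.
brute_superbubbles <- function(g) {
  n <- length(g$labels)
  reach_stop <- function(s, t) {
    seen <- logical(n)
    seen[s] <- TRUE
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in g$succ[[v]]) {
        if (w != t && !seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    which(seen)
  }
  valid <- function(s, t) {
    R <- reach_stop(s, t)
    if (t %in% R) return(NULL)
    # every path leaving s must end in t: no sink inside R, and t actually
    # reachable (some edge from R into t)
    if (!any(vapply(R, function(v) t %in% g$succ[[v]], logical(1)))) return(NULL)
    for (v in R) {
      sc <- g$succ[[v]]
      if (length(sc) == 0L) return(NULL)            # dead-end path
      if (!all(sc %in% c(R, t))) return(NULL)       # cannot happen, by def of R
    }
    U <- setdiff(R, s)
    for (u in U) if (!all(g$pred[[u]] %in% R)) return(NULL)  # outside path enters
    if (!all(g$pred[[t]] %in% R)) return(NULL)               # side entry into exit
    list(s = s, t = t, interior = sort(U))
  }
  out <- list()
  for (s in seq_len(n)) {
    if (length(g$succ[[s]]) == 0L) next
    cands <- list()
    for (t in seq_len(n)) {
      if (t == s) next
      b <- valid(s, t)
      if (!is.null(b)) cands[[length(cands) + 1L]] <- b
    }
    if (length(cands)) {
      sizes <- vapply(cands, function(b) length(b$interior), integer(1))
      out[[length(out) + 1L]] <- cands[[which.min(sizes)]]  # minimal exit
    }
  }
  out
}

bubble_key <- function(bubbles) {
  sort(vapply(bubbles, function(b) paste(b$s, b$t, paste(b$interior, collapse = ","),
                                         sep = ":"), character(1)))
}

# Exact remaining cost-to-go for every alignment state, by backward
# relaxation over the alignment graph using the reference edge semantics of
# expand_state(). rem["M", tau, m] = 0.
true_remaining <- function(g, query, model) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  m <- length(q)
  n <- length(g$labels)
  layers <- c("M", "D", "I")
  rem <- array(Inf, dim = c(3L, n, m + 1L), dimnames = list(layers, NULL, NULL))
  rem["M", 2L, m + 1L] <- 0
  for (v in rev(g$topo)) {
    for (i in m:0) {
      for (l in layers) {
        if (model$kind == "linear" && l != "M") next
        sc <- expand_state(g, list(v = v, i = i, layer = l), query, model)
        if (nrow(sc) == 0L) next
        vals <- sc$cost + rem[cbind(match(sc$layer, layers), sc$v, sc$i + 1L)]
        rem[l, v, i + 1L] <- min(vals)
      }
    }
  }
  rem
}

# All states reachable from <nu, 0> via forward search on expand_state().
reachable_states <- function(g, query, model) {
  m <- nchar(query)
  n <- length(g$labels)
  layers <- c("M", "D", "I")
  seen <- array(FALSE, dim = c(3L, n, m + 1L))
  seen[1L, 1L, 1L] <- TRUE
  queue <- list(list(v = 1L, i = 0L, layer = "M"))
  out <- list()
  while (length(queue)) {
    st <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    out[[length(out) + 1L]] <- st
    sc <- expand_state(g, st, query, model)
    for (r in seq_len(nrow(sc))) {
      li <- match(sc$layer[r], layers)
      if (!seen[li, sc$v[r], sc$i[r] + 1L]) {
        seen[li, sc$v[r], sc$i[r] + 1L] <- TRUE
        queue[[length(queue) + 1L]] <- list(v = sc$v[r], i = sc$i[r],
                                            layer = sc$layer[r])
      }
    }
  }
  out
}

# Random progressive-POA instance in the study regime: 2-6 homologs of up to
# `max_len` bp, substitution rate <= 25%, indel rate <= 10%.
random_instance <- function(seed, max_len = 60L) {
  set.seed(seed)
  nseq <- sample(2:6, 1L)
  len <- sample(10:max_len, 1L)
  sub_rate <- runif(1L, 0, 0.25)
  indel_rate <- runif(1L, 0, 0.10)
  seqs <- simulate_homologs(len, nseq, sub_rate = sub_rate,
                            indel_rate = indel_rate, seed = seed + 1000003L)
  if (runif(1L) < 0.5) {
    model <- cost_model("linear", mismatch = sample(1:6, 1L), gap = sample(1:4, 1L))
  } else {
    de <- sample(1:3, 1L)
    model <- cost_model("affine", mismatch = sample(1:6, 1L),
                        gap_open = de + sample(2:6, 1L), gap_extend = de)
  }
  list(seqs = seqs, model = model)
}

# The DAG from the pruning walkthrough: a superbubble whose entrance opens a
# matching T-T-T-C path (the query's offsets 5-8) next to a branch node with
# two paths of lengths 2 and 4 to the exit, followed by a tail in which the
# final two characters mismatch. Returns the graph plus named internal ids.
pruning_example_graph <- function() {
  labels <- c("C", "C", "G", "C",
              "T", "T", "T", "C",       # matching path through the bubble
              "A",                      # branch node ("node 5")
              "G",                      # short path, length 2 to the exit
              "G", "A", "G",            # long path, length 4 to the exit
              "G", "A", "G", "C", "T", "T")  # tail past the exit
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4),
                 c(4, 5), c(5, 6), c(6, 7), c(7, 8),
                 c(4, 9), c(9, 10), c(10, 8),
                 c(9, 11), c(11, 12), c(12, 13), c(13, 8),
                 c(8, 14), c(14, 15), c(15, 16), c(16, 17), c(17, 18), c(18, 19))
  g <- poa_graph_from_edges(labels, edges)
  list(g = g, entrance = g$node_map[4], branch = g$node_map[9],
       exit = g$node_map[8], query = "CCGCTTTCGAGCCC")
}

# All path lengths from v to a target node t, by enumeration (paths that
# dead-end elsewhere contribute nothing).
path_lengths_to_target <- function(g, v, t) {
  if (v == t) return(0L)
  out <- integer(0)
  for (w in g$succ[[v]]) out <- c(out, 1L + path_lengths_to_target(g, w, t))
  out
}
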