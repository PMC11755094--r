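lin <- cost_model("linear", mismatch = 4, gap = 2)
aff <- cost_model("affine", mismatch = 4, gap_open = 6, gap_extend = 2)

test_that("a query identical to the stored sequence aligns at cost zero", {
  g <- poa_graph("ACGTACGT", "s1")
  a <- poa_align(g, "ACGTACGT", lin)
  expect_identical(a$cost, 0L)
  expect_true(all(a$ops$op == "match"))
  expect_identical(alignment_cost(a$ops, lin), 0L)
  # the DFS component consumes the whole chain; no extra queue expansions
  expect_identical(a$stats$states_pruned, 0)
})

test_that("a substituted base aligns at the mismatch cost", {
  g <- poa_graph("AGGT", "s1")
  a <- poa_align(g, "ACGT", lin)
  # one mismatch (4) ties an insertion/deletion pair (2+2); cost is 4 either
  # way and the reported op list must account for it exactly
  expect_identical(a$cost, 4L)
  expect_identical(alignment_cost(a$ops, lin), 4L)
  nmis <- sum(a$ops$op == "mismatch")
  ngap <- sum(a$ops$op %in% c("insert", "delete"))
  expect_true((nmis == 1L && ngap == 0L) || (nmis == 0L && ngap == 2L))
  # with a higher mismatch cost the gap pair wins outright
  a2 <- poa_align(g, "ACGT", cost_model("linear", mismatch = 5, gap = 2))
  expect_identical(a2$cost, 4L)
  expect_identical(sum(a2$ops$op %in% c("insert", "delete")), 2L)
  # with a cheaper mismatch the substitution wins outright
  a3 <- poa_align(g, "ACGT", cost_model("linear", mismatch = 3, gap = 2))
  expect_identical(a3$cost, 3L)
  expect_identical(sum(a3$ops$op == "mismatch"), 1L)
  expect_identical(a3$ops$qpos[a3$ops$op == "mismatch"], 2L)
})

test_that("degenerate inputs are handled explicitly", {
  g <- poa_graph("ACGT", "s1")
  expect_error(poa_align(g, ""), "non-empty")
  # graph with no labeled nodes: trivial all-insert alignment
  g0 <- structure(list(labels = c(NA_character_, NA_character_),
                       succ = list(integer(0), integer(0)),
                       pred = list(integer(0), integer(0)),
                       edge_seqs = list(list(), list()),
                       topo = c(1L, 2L), rank = c(1L, 2L),
                       seq_names = character(0), seq_paths = list(),
                       class_of = c(NA_integer_, NA_integer_),
                       classes = list()), class = "poa_graph")
  a0 <- poa_align(g0, "ACG", lin)
  expect_true(all(a0$ops$op == "insert"))
  expect_identical(a0$cost, 6L)
  # characters outside the graph alphabet are guaranteed mismatches
  an <- poa_align(poa_graph("AAAA", "s"), "ANAA", lin)
  expect_identical(an$cost, 4L)
})

test_that("DFS follows both branches when both successors match", {
  # two arms spelling the same sequence: every state on both arms is a match
  g <- poa_graph_from_edges(c("A", "C", "C", "G"),
                            rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
  a <- poa_align(g, "ACG", lin)
  expect_identical(a$cost, 0L)
  expect_gte(a$stats$dfs_steps, 5)  # nu-side chain plus both arms
})

test_that("recomputing the op-list cost reproduces the reported cost", {
  set.seed(202)
  for (trial in 1:25) {
    inst <- random_instance(3000 + trial, max_len = 40L)
    g <- poa_graph(inst$seqs[[1]], "s1")
    for (k in seq_along(inst$seqs)[-1]) {
      a <- poa_align(g, inst$seqs[[k]], inst$model)
      expect_identical(alignment_cost(a$ops, inst$model), a$cost)
      g <- insert_alignment(g, inst$seqs[[k]], names(inst$seqs)[k], a)
    }
  }
})

test_that("A* cost equals the DP oracle cost across random instances", {
  set.seed(77)
  for (trial in 1:60) {
    inst <- random_instance(5000 + trial, max_len = 40L)
    g <- poa_graph(inst$seqs[[1]], "s1")
    for (k in seq_along(inst$seqs)[-1]) {
      a <- poa_align(g, inst$seqs[[k]], inst$model)
      d <- dp_align(g, inst$seqs[[k]], inst$model)
      expect_identical(a$cost, d$cost)
      g <- insert_alignment(g, inst$seqs[[k]], names(inst$seqs)[k], a)
    }
  }
})

test_that("accelerators change the work done, never the cost", {
  set.seed(99)
  exp_full <- exp_nodfs <- exp_noheur <- 0
  for (trial in 1:40) {
    inst <- random_instance(7000 + trial, max_len = 40L)
    seqs <- inst$seqs
    g <- build_msa(seqs[-length(seqs)], model = inst$model)$graph
    q <- seqs[[length(seqs)]]
    a <- poa_align(g, q, inst$model)
    for (cfg in list(list(use_prune = FALSE), list(use_dfs = FALSE),
                     list(use_heuristic = FALSE),
                     list(use_prune = FALSE, use_dfs = FALSE, use_heuristic = FALSE))) {
      b <- do.call(poa_align, c(list(g = g, query = q, model = inst$model), cfg))
      expect_identical(b$cost, a$cost)
    }
    exp_full <- exp_full + a$stats$states_expanded
    exp_nodfs <- exp_nodfs + poa_align(g, q, inst$model, use_dfs = FALSE)$stats$states_expanded
    exp_noheur <- exp_noheur + poa_align(g, q, inst$model, use_heuristic = FALSE)$stats$states_expanded
  }
  expect_lte(exp_full, exp_nodfs)
  expect_lte(exp_full, exp_noheur)
})

test_that("pruned states never appear on the reported optimal path", {
  set.seed(13)
  checked <- 0L
  for (trial in 1:30) {
    inst <- random_instance(9000 + trial, max_len = 40L)
    seqs <- inst$seqs
    g <- build_msa(seqs[-length(seqs)], model = inst$model)$graph
    a <- poa_align(g, seqs[[length(seqs)]], inst$model, debug = TRUE)
    pr <- a$stats$pruned_states
    if (nrow(pr) == 0L) next
    checked <- checked + 1L
    onpath <- a$ops[a$ops$op %in% c("match", "mismatch"), c("node", "qpos")]
    overlap <- merge(as.data.frame(pr), onpath, by.x = c("node", "qpos"),
                     by.y = c("node", "qpos"))
    expect_identical(nrow(overlap), 0L)
  }
  expect_gt(checked, 0L)
})
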