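lin42 <- cost_model("linear", mismatch = 4, gap = 2)
aff <- cost_model("affine", mismatch = 4, gap_open = 6, gap_extend = 2)

ops_df <- function(kinds) {
  data.frame(op = factor(kinds, levels = c("match", "mismatch", "insert", "delete")),
             node = NA_integer_, qpos = NA_integer_)
}

test_that("cost model validation enforces the sign and affine constraints", {
  expect_error(cost_model("linear", mismatch = -1), "non-negative")
  expect_error(cost_model("affine", gap_open = 2, gap_extend = 2), "gap_open > gap_extend")
  expect_identical(cost_model("linear")$dm, 0L)
})

test_that("alignment_cost applies the linear and affine formulas", {
  expect_identical(alignment_cost(ops_df(rep("match", 4)), lin42), 0L)
  expect_identical(alignment_cost(ops_df(c(rep("match", 3), "mismatch")), lin42), 4L)
  # 2 matches + one gap of length 2: No = 1, Ng = 2 -> 6 + 2*2 = 10
  expect_identical(alignment_cost(ops_df(c("match", "insert", "insert", "match")), aff), 10L)
  # two separate gaps of one position each open twice
  expect_identical(alignment_cost(ops_df(c("insert", "match", "delete")), aff), 16L)
  # direction change splits a run
  expect_identical(alignment_cost(ops_df(c("insert", "delete")), aff), 16L)
  expect_identical(alignment_cost(ops_df(c("insert", "delete")), lin42), 4L)
})

test_that("min_indel_edges follows the three-branch rule", {
  expect_identical(min_indel_edges(2L, 4L, 5L), 2L)  # dmax-1 = 3 < lr
  expect_identical(min_indel_edges(7L, 8L, 4L), 2L)  # dmin-1 = 6 > lr
  for (lr in 2:6) expect_identical(min_indel_edges(3L, 7L, lr), 0L)
})

test_that("min_indel_edges lower-bounds the true indel count over graph paths", {
  # diamond with arms of lengths 2 and 4: path lengths to tau are {3, 5}
  g <- poa_graph_from_edges(c("S", "A", "B", "C", "D", "T"),
                            rbind(c(1, 2), c(2, 6), c(1, 3), c(3, 4), c(4, 5), c(5, 6)))
  v <- g$node_map[1]
  d <- dist_to_tau(g)
  lens <- all_path_lengths_to_tau(g, v)
  for (lr in 0:8) {
    true_min <- min(abs(lr - (lens - 1L)))
    ng <- unname(min_indel_edges(d[v, "dmin"], d[v, "dmax"], lr))
    expect_lte(ng, true_min)
    # equality whenever a path of the implied length exists
    if (lr <= min(lens) - 1L || lr >= max(lens) - 1L) {
      expect_identical(ng, true_min)
    }
  }
})

test_that("the gap heuristic scales indel counts by the model costs", {
  g <- poa_graph("ACGT", "s")
  v1 <- 3L  # the A node: dmin = dmax = 4, so 3 consuming nodes remain
  tb <- heuristic_tables(g, 9L)
  expect_identical(tb$dmin[v1], 4L)
  # lr = 9 against 3 remaining consuming nodes: Ngmin = 6 insertions
  expect_identical(gap_heuristic(v1, 0L, tb, lin42), 12L)
  # Ngmin = 2 with gap cost 2 -> 4
  expect_identical(gap_heuristic(v1, 4L, tb, lin42), 4L)
  # Ngmin = 0 -> 0 for any model
  tb4 <- heuristic_tables(g, 4L)
  expect_identical(gap_heuristic(v1, 1L, tb4, lin42), 0L)
  expect_identical(gap_heuristic(v1, 1L, tb4, aff), 0L)
  # affine from the match layer: Ngmin = 3 costs one opening + 3 extensions
  tb7 <- heuristic_tables(g, 7L)
  expect_identical(gap_heuristic(v1, 1L, tb7, aff), 12L)
  # an open insertion in the required direction has already paid the opening
  expect_identical(gap_heuristic(v1, 1L, tb7, aff, layer = "I"), 6L)
  expect_identical(gap_heuristic(v1, 1L, tb7, aff, layer = "D"), 12L)
  # deletions required instead: lr = 0 with dmin - 1 = 3 -> Ngmin = 3
  tb0 <- heuristic_tables(g, 0L)
  expect_identical(gap_heuristic(v1, 0L, tb0, aff, layer = "D"), 6L)
  expect_identical(gap_heuristic(v1, 0L, tb0, aff, layer = "I"), 12L)
  # tau is free once the query is consumed
  expect_identical(gap_heuristic(2L, 4L, tb4, lin42), 0L)
})

test_that("implicit gap costs are linear per position or opened once", {
  expect_identical(implicit_gap_cost(1L, lin42), 2L)
  expect_identical(implicit_gap_cost(0L, lin42), 0L)
  expect_identical(implicit_gap_cost(0L, aff), 0L)
  expect_identical(implicit_gap_cost(3L, aff), 12L)
  expect_identical(implicit_gap_cost(0:3, lin42), c(0L, 2L, 4L, 6L))
})

test_that("expand_state enumerates (mis)match, indel, and end edges", {
  g <- poa_graph("A", "s")
  sc <- expand_state(g, list(v = 1L, i = 0L), "A", lin42)
  hit <- sc[sc$op == "match", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$v, 3L)
  expect_identical(hit$i, 1L)
  expect_identical(hit$cost, 0L)

  # mismatch position on a chain: successors cost {4, 2, 2}
  g2 <- poa_graph("TT", "s")
  sc2 <- expand_state(g2, list(v = 3L, i = 1L), "AA", lin42)
  expect_setequal(sc2$cost, c(4L, 2L, 2L))
  expect_setequal(as.character(sc2$op), c("mismatch", "delete", "insert"))

  # terminal state has no successors
  expect_identical(nrow(expand_state(g, list(v = 2L, i = 1L), "A", lin42)), 0L)

  # the edge toward tau is always free; leftover query is inserted at tau
  sc3 <- expand_state(g, list(v = 3L, i = 1L), "A", lin42)
  expect_true("end" %in% sc3$op)
  expect_identical(sc3$cost[sc3$op == "end"], 0L)
  sc4 <- expand_state(g, list(v = 2L, i = 0L), "A", lin42)
  expect_identical(as.character(sc4$op), "insert")
  expect_identical(sc4$cost, 2L)

  # affine layers: open from M costs do + de, extension de, close 0
  sc5 <- expand_state(g2, list(v = 3L, i = 0L, layer = "M"), "AA", aff)
  expect_identical(sort(unique(sc5$cost[sc5$op %in% c("insert", "delete")])), 8L)
  sc6 <- expand_state(g2, list(v = 3L, i = 1L, layer = "I"), "AA", aff)
  expect_identical(sc6$cost[sc6$op == "insert"], 2L)
  expect_identical(sc6$cost[sc6$op == "close"], 0L)
})

test_that("DP memory estimates reproduce the dense-table arithmetic", {
  expect_identical(dp_memory_estimate(1, 1, 1, 4), 8)  # m + 1 = 2 offsets
  # 500k nodes x 500 kbp x 3 layers x 4 B is about 3 TB
  est <- dp_memory_estimate(5e5, 5e5, 3, 4)
  expect_lt(abs(est / 1e12 - 3), 0.01)
  # megabase alignment of a graph with ~1e6 nodes: ~13 TB order of magnitude
  est2 <- dp_memory_estimate(1e6, 1e6, 3, 4)
  expect_gt(est2, 1e13)
  expect_lt(est2, 1.5e13)
})
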