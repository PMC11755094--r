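test_that("a single sequence builds a labeled chain with virtual terminals", {
  g <- poa_graph("ACGT", "s1")
  expect_length(g$topo, 6L)
  expect_identical(g$labels[g$seq_paths[[1]]], c("A", "C", "G", "T"))
  expect_identical(poa_msa(g)$rows, c(s1 = "ACGT"))
  expect_error(poa_graph("", "empty"), "non-empty")

  g1 <- poa_graph("A", "one")
  expect_length(g1$topo, 3L)
  expect_identical(g1$labels[3L], "A")
  expect_no_error(validate_poa(g1))
})

test_that("merging an identical sequence reuses every node", {
  g <- poa_graph("ACGT", "s1")
  a <- poa_align(g, "ACGT")
  g2 <- insert_alignment(g, "ACGT", "s2", a)
  expect_identical(length(g2$labels), length(g$labels))
  # every chain edge now carries both sequence ids
  p <- c(1L, g2$seq_paths[[1]], 2L)
  for (j in seq_len(length(p) - 1L)) {
    k <- match(p[j + 1L], g2$succ[[p[j]]])
    expect_setequal(g2$edge_seqs[[p[j]]][[k]], 1:2)
  }
})

test_that("mismatches join the aligned column class; insertions open one", {
  g <- poa_graph("ACGT", "s1")
  g <- add_sequence(g, "AGGT", "s2")
  # exactly one new node, labeled G, in the class of the original C node
  expect_identical(length(g$labels), 7L)
  newnode <- 7L
  expect_identical(g$labels[newnode], "G")
  cnode <- which(g$labels == "C")
  expect_identical(g$class_of[newnode], g$class_of[cnode])
  expect_identical(unname(poa_msa(g)$rows), c("ACGT", "AGGT"))

  g <- add_sequence(g, "ACGGT", "s3")
  msa <- poa_msa(g)
  expect_identical(msa$column_count, 5L)
  expect_identical(unname(degap(msa$rows)), c("ACGT", "AGGT", "ACGGT"))
  # the mismatch column holds two alternative alleles
  expect_identical(substr(msa$rows[["s1"]], 2, 2), "C")
  expect_identical(substr(msa$rows[["s2"]], 2, 2), "G")
  expect_no_error(validate_poa(g))
})

test_that("a one-deletion merge yields the expected two-row MSA", {
  g <- poa_graph("AC", "s1")
  g <- add_sequence(g, "A", "s2")
  expect_identical(unname(poa_msa(g)$rows), c("AC", "A-"))
})

test_that("dist_to_tau matches exhaustive path enumeration", {
  g <- poa_graph("AB", "s")  # chain nu -> a -> b -> tau
  d <- dist_to_tau(g)
  expect_identical(unname(d[3L, ]), c(2L, 2L))
  expect_identical(unname(d[4L, ]), c(1L, 1L))
  expect_identical(unname(d[2L, ]), c(0L, 0L))

  # diamond with unequal arms: s -> a -> t and s -> b -> c -> t
  gd <- poa_graph_from_edges(c("S", "A", "B", "C", "T"),
                             rbind(c(1, 2), c(2, 5), c(1, 3), c(3, 4), c(4, 5)))
  dd <- dist_to_tau(gd)
  expect_identical(unname(dd[gd$node_map[1], ]), c(3L, 4L))

  set.seed(42)
  for (trial in 1:20) {
    g <- random_dag(sample(3:12, 1L))
    d <- dist_to_tau(g)
    for (v in seq_along(g$labels)[-2L]) {
      lens <- all_path_lengths_to_tau(g, v)
      expect_identical(unname(d[v, "dmin"]), min(lens))
      expect_identical(unname(d[v, "dmax"]), max(lens))
      expect_lte(d[v, "dmin"], d[v, "dmax"])
    }
  }
})

test_that("progressive builds stay acyclic and round-trip every sequence", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (trial in 1:5) {
    seqs <- simulate_homologs(sample(20:40, 1L), 20L, sub_rate = runif(1, 0, 0.2),
                              indel_rate = runif(1, 0, 0.08), seed = 100L + trial)
    res <- build_msa(seqs)
    g <- res$graph
    expect_identical(unname(degap(res$msa$rows)), as.character(seqs))
    expect_no_error(validate_poa(g))
    # independent acyclicity check
    el <- do.call(rbind, lapply(seq_along(g$succ), function(v) {
      if (length(g$succ[[v]])) cbind(v, g$succ[[v]]) else NULL
    }))
    ig <- igraph::graph_from_edgelist(el, directed = TRUE)
    expect_true(igraph::is_dag(ig))
    # nodes sharing an alignment class never lie on a common path
    for (cls in res$graph$classes) {
      if (length(cls) < 2L) next
      for (a in cls) for (b in cls) {
        if (a < b) expect_false(exactpoa:::reaches_(g, a, b) ||
                                  exactpoa:::reaches_(g, b, a))
      }
    }
  }
})

test_that("aligning a sequence identical to a graph path adds zero nodes", {
  set.seed(5)
  seqs <- simulate_homologs(30, 3, sub_rate = 0.1, indel_rate = 0.05, seed = 9)
  g <- build_msa(seqs)$graph
  before <- length(g$labels)
  g2 <- add_sequence(g, seqs[[2]], "again")
  expect_identical(length(g2$labels), before)
})

test_that("inconsistent alignments are rejected", {
  g <- poa_graph("ACGT", "s1")
  bad <- data.frame(op = factor("match", levels = OP_NAMES <- c("match", "mismatch", "insert", "delete")),
                    node = 99L, qpos = 1L)
  expect_error(insert_alignment(g, "A", "s2", list(ops = bad)), "unknown")
  a <- poa_align(g, "ACGT")
  expect_error(insert_alignment(g, "ACGT", "s1", a), "duplicate")
})
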