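test_that("tips at branches are removed, chain ends and isolated edges are kept", {
  genome <- repeat_free_genome(40, 5, seed = 21)
  spur_base <- kmer_list(genome, 5)[15]
  spur <- paste0(spur_base,
                 setdiff(c("A", "C", "G", "T"),
                         substr(genome, 20, 20))[1])
  g <- build_graph(c(genome, spur), 5)
  g0 <- build_graph(genome, 5)
  stopifnot(nrow(g$edges) == nrow(g0$edges) + 1L)
  res <- remove_tips(g)
  expect_identical(res$removed, 1L)
  expect_identical(graph_shape(res$graph), graph_shape(g0))

  # isolated short edge: both endpoints terminal, never a tip
  giso <- build_graph("TAGTCG", 5)
  expect_identical(remove_tips(giso)$removed, 0L)
  # chain without branches: unchanged
  expect_identical(remove_tips(g0)$removed, 0L)
  expect_same_graph(remove_tips(g0)$graph, g0)
})

test_that("self-loops merge with a compatible neighbour or are deleted", {
  g <- reduce_graph(worked_graph())$graph
  res <- resolve_self_loops(g)
  expect_identical(res$merged, 1L)
  expect_identical(res$removed, 0L)
  graph_audit(res$graph)
  # (GTC..,TCG,+,+,..G) merged through (TCG,TCG,+,-,A): arrives on TCG-
  e <- res$graph$edges
  hit <- e[e$dto == "-" & (e$to == "TCG" | e$from == "TCG"), , drop = FALSE]
  expect_identical(nrow(hit), 1L)
  expect_true(endsWith(paste0(msgasm:::oriented_key(hit$from, hit$dfrom),
                              hit$label), "TCGA"))

  # the same junction with no neighbour: loop deleted, molecule dropped
  lone <- build_graph("TCGA", 3)
  res2 <- resolve_self_loops(lone)
  expect_identical(res2$removed, 1L)
  expect_identical(nrow(res2$graph$edges), 0L)
  expect_identical(nrow(res2$graph$mol), 0L)

  # no self-loops: identity
  g0 <- chain_graph(5)
  expect_same_graph(resolve_self_loops(g0)$graph, g0)
})

test_that("parallel edges keep the higher coverage, ties keep the smaller label", {
  # two bubble arms reduce to parallel 4-step edges between GTT and TTG
  arms <- build_graph(c("AACCCAA", "AACGCAA"), 3)
  cfg <- extension_config(tips = FALSE, multiple_edges = FALSE,
                          cross = FALSE, virtual_cross = FALSE)
  bub <- assemble_loop(arms, cfg)$graph
  expect_identical(nrow(bub$edges), 2L)

  # higher coverage wins
  g <- bub
  g$edges$coverage <- c(3, 10)
  res <- resolve_multiple_edges(g)
  expect_identical(res$removed, 1L)
  expect_identical(res$graph$edges$coverage, 10)

  # coverage tie: lexicographically smaller stored label wins
  res2 <- resolve_multiple_edges(bub)
  expect_identical(res2$removed, 1L)
  expect_identical(res2$graph$edges$label, min(bub$edges$label))

  # no parallel edges: identity
  g0 <- chain_graph(4)
  expect_same_graph(resolve_multiple_edges(g0)$graph, g0)
})

test_that("cross vertices pair coverage-matched edges and keep the rest", {
  g <- cross_fixture(in_cov = c(100, 10), out_cov = c(98, 11))
  res <- resolve_cross_vertices(g)
  expect_identical(res$merged_pairs, 2L)
  graph_audit(res$graph)
  ct <- emit_contigs(res$graph, 5)
  expect_identical(nrow(ct), 2L)
  expect_setequal(round(ct$coverage, 1), c(99.0, 10.5))
  expect_false("GGCCT" %in% res$graph$mol$rep)  # fully consumed center

  # no pair within 20%: untouched
  g2 <- cross_fixture(in_cov = c(100, 10), out_cov = c(50, 45))
  res2 <- resolve_cross_vertices(g2)
  expect_identical(res2$merged_pairs, 0L)
  expect_same_graph(res2$graph, g2)

  # one edge on a side: not a cross vertex
  g3 <- worked_graph()
  expect_identical(resolve_cross_vertices(g3)$merged_pairs, 0L)
  expect_same_graph(resolve_cross_vertices(g3)$graph, g3)
})

test_that("virtual cross vertices merge outer pairs through the central edge", {
  g <- virtual_cross_fixture(in_cov = c(100, 10), out_cov = c(97, 9))
  res <- resolve_virtual_cross(g)
  expect_identical(res$merged_pairs, 2L)
  graph_audit(res$graph)
  ct <- emit_contigs(res$graph, 5)
  expect_identical(nrow(ct), 2L)
  expect_setequal(ct$sequence, c("CAGGCCAT", canon_seq("TAGGCCAG")))
  # e0 consumed entirely
  expect_identical(nrow(res$graph$edges), 2L)

  g2 <- virtual_cross_fixture(in_cov = c(100, 10), out_cov = c(50, 45))
  res2 <- resolve_virtual_cross(g2)
  expect_identical(res2$merged_pairs, 0L)
  expect_same_graph(res2$graph, g2)

  # a single outer edge on one side: not a virtual cross
  g3 <- reduce_graph(worked_graph())$graph
  expect_same_graph(resolve_virtual_cross(g3)$graph, g3)
})

test_that("the reduce/extend loop assembles the worked reads into the reference", {
  res <- assemble_loop(worked_graph())
  expect_identical(nrow(enumerate_sigma(res$graph)), 0L)
  ct <- emit_contigs(res$graph, 3)
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$sequence, canon_seq(worked_reference))

  # empty graph: zero passes
  expect_identical(assemble_loop(build_graph(character(0), 3))$rounds, 0L)

  # pure chain: extension changes nothing beyond reduction
  g <- chain_graph(20)
  expect_same_graph(assemble_loop(g)$graph, reduce_graph(g)$graph)
})

test_that("with all heuristics disabled the loop equals plain reduction", {
  cfg <- extension_config(tips = FALSE, self_loops = FALSE,
                          multiple_edges = FALSE, cross = FALSE,
                          virtual_cross = FALSE)
  g <- worked_graph()
  expect_same_graph(assemble_loop(g, cfg)$graph, reduce_graph(g)$graph)
})

test_that("extension heuristics preserve all graph invariants", {
  reads <- inject_errors(
    sample_reads(random_genome(600, seed = 40), 60, 10, seed = 41),
    0.01, seed = 42)
  g <- clean_graph(build_graph(reads, 11), 2)
  res <- assemble_loop(g)
  graph_audit(res$graph)
  expect_identical(nrow(enumerate_sigma(res$graph)), 0L)
})

test_that("contig emission filters, orders, and survives dump/reload", {
  g <- reduce_graph(worked_graph())$graph
  ct <- emit_contigs(g, 3)
  expect_identical(ct$length, sort(ct$length, decreasing = TRUE))
  expect_true(all(ct$sequence == canon_seq(ct$sequence)))
  # a single unmerged 1-step edge is dropped by a k+1 length filter
  g1 <- build_graph("TAGT", 3)
  expect_identical(nrow(emit_contigs(g1, 5)), 0L)
  expect_identical(nrow(emit_contigs(g1, 3)), 1L)
  # determinism across dump/reload
  g2 <- graph_load(graph_dump(g))
  expect_identical(emit_contigs(g2, 3), ct)
})
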