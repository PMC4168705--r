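test_that("edge merging concatenates labels and absorbs the zero edge", {
  e1 <- make_edge("TAG", "AGT", "+", "+", "T", coverage = 4)
  e2 <- make_edge("AGT", "GTC", "+", "+", "C", coverage = 2)
  m <- merge_edges(e1, e2)
  expect_identical(m[c("from", "to", "dfrom", "dto", "label", "step")],
                   list(from = "TAG", to = "GTC", dfrom = "+", dto = "+",
                        label = "TC", step = 2L))
  expect_equal(m$coverage, 3)  # label-length-weighted mean

  expect_true(is_zero_edge(merge_edges(zero_edge(), e1)))
  expect_true(is_zero_edge(merge_edges(e1, zero_edge())))
  # direction mismatch at the shared molecule
  expect_true(is_zero_edge(merge_edges(e1, edge_twin(e2))))
  # disconnected endpoints
  expect_true(is_zero_edge(merge_edges(e2, e1)))
})

test_that("edge merging is associative on random consecutive triples", {
  set.seed(11)
  for (rep in 1:40) {
    ch <- random_edge_chain(3, k = 5, seed = rep)
    ch[[1]]$coverage <- runif(1, 1, 50)
    ch[[2]]$coverage <- runif(1, 1, 50)
    ch[[3]]$coverage <- runif(1, 1, 50)
    a <- merge_edges(merge_edges(ch[[1]], ch[[2]]), ch[[3]])
    b <- merge_edges(ch[[1]], merge_edges(ch[[2]], ch[[3]]))
    expect_false(is_zero_edge(a))
    expect_identical(a[c("from", "to", "dfrom", "dto", "label", "step")],
                     b[c("from", "to", "dfrom", "dto", "label", "step")])
    expect_equal(a$coverage, b$coverage)
  }
})

test_that("the operation set contains exactly the degree-2 pass-through centers", {
  g <- worked_graph()
  sig <- enumerate_sigma(g)
  expect_setequal(sig$center, c("AGT", "GTC", "GAG"))  # never TCG (degree 4)
  # a fully reduced chain has an empty operation set
  red <- reduce_graph(chain_graph(6))$graph
  expect_identical(nrow(enumerate_sigma(red)), 0L)
})

test_that("independent selection is conflict-free, maximal, and halves chains", {
  g <- chain_graph(4)
  sig <- enumerate_sigma(g)
  expect_identical(nrow(sig), 3L)
  sel <- select_independent(sig, scheduler_config())
  # at most half of a path's edges merge per round; here exactly half
  expect_identical(sum(sel), 2L)
  picked <- sig[sel, ]
  expect_identical(anyDuplicated(c(picked$e_in, picked$e_out)), 0L)

  one <- sig[2, , drop = FALSE]
  expect_identical(sum(select_independent(one, scheduler_config())), 1L)

  # two operations sharing an edge: exactly one wins, in either mode
  conflicted <- enumerate_sigma(chain_graph(2))
  expect_identical(nrow(conflicted), 1L)
  g3 <- chain_graph(3)
  sig3 <- enumerate_sigma(g3)
  expect_identical(nrow(sig3), 2L)
  expect_identical(sum(select_independent(sig3, scheduler_config())), 1L)
  expect_identical(
    sum(select_independent(sig3, scheduler_config("randomized", seed = 4))),
    1L)
})

test_that("a 5-molecule path collapses to one 4-step edge in 2 rounds", {
  g <- chain_graph(4, k = 7)  # 5 molecules, 4 one-step edges
  res <- reduce_graph(g)
  expect_identical(nrow(res$graph$edges), 1L)
  expect_identical(res$graph$edges$step, 4L)
  expect_identical(res$report$rounds, 2L)
  expect_identical(res$report$operations_applied, 3L)
  expect_identical(sum(res$report$per_round_counts),
                   res$report$operations_applied)
})

test_that("reduction of a pure path takes ceiling(log2(E)) rounds", {
  for (E in c(2L, 3L, 5L, 8L, 13L, 32L, 57L, 100L)) {
    res <- reduce_graph(chain_graph(E))
    expect_identical(res$report$rounds, as.integer(ceiling(log2(E))),
                     label = sprintf("E = %d", E))
    expect_identical(nrow(res$graph$edges), 1L)
  }
  # already reduced: zero rounds, zero operations
  g1 <- reduce_graph(chain_graph(5))$graph
  again <- reduce_graph(g1)
  expect_identical(again$report$rounds, 0L)
  expect_identical(again$report$operations_applied, 0L)
})

test_that("reduction conserves the spelled chain sequence", {
  s <- repeat_free_genome(200, 9, seed = 14)
  res <- reduce_graph(build_graph(tile_reads(s, 40, 7), 9))
  ct <- emit_contigs(res$graph, 9)
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$sequence, canon_seq(s))
})

test_that("a circular chain terminates as a single circular edge", {
  gen <- repeat_free_genome(40, 5, seed = 3)
  circ <- paste0(gen, substr(gen, 1, 5))
  g <- build_graph(tile_reads(circ, 10, 1), 5)
  res <- reduce_graph(g)
  e <- res$graph$edges
  expect_identical(nrow(e), 1L)
  expect_identical(e$from, e$to)
  ct <- emit_contigs(res$graph, 5)
  expect_true(ct$circular)
  expect_identical(nrow(enumerate_sigma(res$graph)), 0L)
})

test_that("the final edge multiset is invariant to scheduling and partitions", {
  for (i in 1:6) {
    reads <- sample_reads(random_genome(250, seed = 100 + i), 40, 6,
                          seed = i)
    g <- build_graph(reads, 9)
    ref <- sort(emit_contigs(reduce_graph(g)$graph, 9)$sequence)
    for (seed in c(1, 2, 3)) {
      alt <- reduce_graph(g, scheduler_config("randomized", seed = seed,
                                              partitions = 8))
      expect_identical(sort(emit_contigs(alt$graph, 9)$sequence), ref)
    }
    p1 <- reduce_graph(g, scheduler_config(partitions = 1))
    p8 <- reduce_graph(g, scheduler_config(partitions = 8))
    expect_same_graph(p1$graph, p8$graph)
  }
})

test_that("run_swap drives the merging activity and caps runaway rounds", {
  g <- worked_graph()
  via_swap <- run_swap(g, enumerate_sigma, msgasm:::apply_merge_pairs,
                       scheduler_config(), max_rounds = 100)
  direct <- reduce_graph(g)
  expect_same_graph(via_swap$state, direct$graph)
  expect_identical(via_swap$report$rounds, direct$report$rounds)
  expect_error(
    run_swap(g, enumerate_sigma, function(state, ops, sel) state,
             scheduler_config(), max_rounds = 3),
    "fixpoint")
  # empty operation set: zero rounds
  empty <- run_swap(direct$graph, enumerate_sigma,
                    msgasm:::apply_merge_pairs, scheduler_config())
  expect_identical(empty$report$rounds, 0L)
})

test_that("schedule costs reproduce the printed path-merging comparison", {
  expect_identical(schedule_cost(c(3, 5), "sequential"), 6L)
  expect_identical(schedule_cost(c(3, 5), "per_path_parallel"), 4L)
  expect_identical(schedule_cost(c(3, 5), "swap"), 2L)
  expect_identical(schedule_cost(5, "sequential"), 4L)
  expect_identical(schedule_cost(3, "sequential"), 2L)
  expect_identical(schedule_cost(2, "swap"), 0L)
  expect_error(schedule_cost(c(3, 1), "swap"), ">= 2")
  expect_error(schedule_cost(integer(0), "sequential"), ">= 2")
})

test_that("chain decomposition matches the brute-force unitig oracle", {
  for (i in 1:20) {
    genome <- random_genome(80 + 7 * i, seed = 500 + i)
    reads <- sample_reads(genome, 20, 6, seed = i, both_strands = TRUE)
    g <- build_graph(reads, 7)
    expect_identical(reduced_contigs(g), oracle_unitigs(reads, 7),
                     label = sprintf("case %d", i))
  }
})
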