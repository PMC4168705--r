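# Shared fixtures built in code.

# The printed worked example: three reads tiling the reference "TAGTCGAGG".
worked_reads <- c("TAGTCG", "AGTCGA", "TCGAGG")
worked_reference <- "TAGTCGAGG"

worked_graph <- function() build_graph(worked_reads, 3)

# A linear chain graph with exactly E one-step edges at word size k,
# built from a repeat-free sequence.
chain_graph <- function(E, k = 7, seed = E) {
  build_graph(repeat_free_genome(k + E, k, seed = seed), k)
}

# Canonical strand of a sequence (larger of the two).
canon_seq <- function(s) {
  rc <- reverse_complement(s)
  ifelse(s >= rc, s, rc)
}

# Set the coverage of the unique edge incident to molecule `far`.
set_arm_coverage <- function(g, far, value) {
  i <- which(g$edges$from == far | g$edges$to == far)
  stopifnot(length(i) == 1L)
  g$edges$coverage[i] <- value
  g
}

# X-shaped fixture: center molecule GGCCT with two in-arms (far molecules
# GCCTT, GCCTC) and two out-arms (TGGCC, GGCCG), with chosen coverages.
cross_fixture <- function(in_cov = c(100, 10), out_cov = c(98, 11)) {
  g <- build_graph(c("AAGGCC", "GAGGCC", "AGGCCA", "AGGCCG"), 5)
  g <- set_arm_coverage(g, "GCCTT", in_cov[1])
  g <- set_arm_coverage(g, "GCCTC", in_cov[2])
  g <- set_arm_coverage(g, "TGGCC", out_cov[1])
  g <- set_arm_coverage(g, "GGCCG", out_cov[2])
  g
}

# H-shaped fixture: central edge e0 between molecules GGCCT and TGGCC, two
# outer in-arms (GCCTG, TAGGC) and two outer out-arms (GCCAT, GCCAG).
virtual_cross_fixture <- function(in_cov = c(100, 10), out_cov = c(97, 9)) {
  g <- build_graph(c("AGGCCA", "CAGGCC", "TAGGCC", "GGCCAT", "GGCCAG"), 5)
  g <- set_arm_coverage(g, "GCCTG", in_cov[1])
  g <- set_arm_coverage(g, "TAGGC", in_cov[2])
  g <- set_arm_coverage(g, "GCCAT", out_cov[1])
  g <- set_arm_coverage(g, "GCCAG", out_cov[2])
  g
}

# Random consecutive bi-edge chains (for associativity and merge checks):
# returns a list of n bi_edge objects forming one traversable path.
random_edge_chain <- function(n, k = 5, seed = 1) {
  s <- repeat_free_genome(k + n, k, seed = seed)
  g <- build_graph(s, k)
  pairsort <- order(g$edges$coverage)  # all 1; keep build order
  # orient every stored edge along the walk of s
  wins <- kmer_list(s, k)
  rep_ <- representative(wins)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    e <- make_edge_search(g, rep_$key[i], rep_$key[i + 1])
    # orient so it runs key[i] -> key[i+1] with the walk orientations
    if (e$from != rep_$key[i] || e$dfrom != rep_$orientation[i]) {
      e <- edge_twin(e)
    }
    stopifnot(e$from == rep_$key[i], e$dfrom == rep_$orientation[i])
    edges[[i]] <- e
  }
  edges
}

make_edge_search <- function(g, a, b) {
  i <- which((g$edges$from == a & g$edges$to == b) |
               (g$edges$from == b & g$edges$to == a))
  stopifnot(length(i) == 1L)
  as_bi_edge_row(g$edges[i, , drop = FALSE])
}

as_bi_edge_row <- function(row) {
  make_edge(row$from, row$to, row$dfrom, row$dto, row$label, row$coverage)
}

expect_same_graph <- function(a, b) {
  expect_identical(graph_dump(a), graph_dump(b))
}

# Sets-only comparison (molecule names and edge identities, not counts).
graph_shape <- function(g) {
  e <- g$edges
  list(mol = sort(g$mol$rep, method = "radix"),
       edges = sort(paste(e$from, e$to, e$dfrom, e$dto, e$label),
                    method = "radix"))
}
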