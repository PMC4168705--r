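# Graph reduction: the edge-merging operation set, round-synchronous
# conflict-free scheduling (an in-process emulation of lock-compute-unlock
# over logical partitions), and the schedule cost model.

#' Scheduler configuration
#'
#' @param mode "deterministic" (pairs walked chain-by-chain with alternating
#'   selection, reproducible and round-optimal on pure paths) or
#'   "randomized" (seeded random priorities emulating backoff winners; the
#'   final graph is identical by associativity, round counts may differ).
#' @param seed Integer seed; ignored in deterministic mode.
#' @param partitions Number of logical partitions the operation set is
#'   hashed over. Affects only per-partition bookkeeping, never results.
#' @return A list of class \code{scheduler_config}.
#' @export
scheduler_config <- function(mode = c("deterministic", "randomized"),
                             seed = 0L, partitions = 1L) {
  mode <- match.arg(mode)
  stopifnot(partitions >= 1L)
  structure(list(mode = mode, seed = as.integer(seed),
                 partitions = as.integer(partitions)),
            class = "scheduler_config")
}

#' Enumerate the edge-merging operation set
#'
#' A merge operation exists at every molecule with exactly two edge
#' attachments from two distinct edges leaving on opposite sides: one edge
#' then enters the molecule in the same orientation in which the other
#' leaves it. Each such center contributes exactly one operation. Molecules
#' touched twice by the same edge (self-loops, palindromic self-twin
#' junctions) and branching molecules contribute none.
#'
#' @param g An \code{msg_graph}.
#' @return A data.frame with one row per operation: \code{center}, row
#'   indices \code{e_in}/\code{e_out} into \code{g$edges}, and the endpoint
#'   roles \code{role_in}/\code{role_out} used to orient the two edges.
#' @export
enumerate_sigma <- function(g) {
  stopifnot(inherits(g, "msg_graph"))
  empty <- data.frame(center = character(0), e_in = integer(0),
                      e_out = integer(0), role_in = character(0),
                      role_out = character(0), stringsAsFactors = FALSE)
  r <- edge_records(g)
  if (nrow(r) == 0L) return(empty)
  r <- r[order(r$mol, method = "radix"), , drop = FALSE]
  rl <- rle(r$mol)
  ends <- cumsum(rl$lengths)
  two <- which(rl$lengths == 2L)
  if (length(two) == 0L) return(empty)
  i2 <- ends[two]          # second record of each degree-2 molecule
  i1 <- i2 - 1L
  ok <- r$edge[i1] != r$edge[i2] & r$side[i1] != r$side[i2]
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(i1) == 0L) return(empty)
  # out = the record leaving on "+", in = the record leaving on "-"
  plus_first <- r$side[i1] == "+"
  out_i <- ifelse(plus_first, i1, i2)
  in_i <- ifelse(plus_first, i2, i1)
  data.frame(center = r$mol[i1],
             e_in = r$edge[in_i], e_out = r$edge[out_i],
             role_in = r$role[in_i], role_out = r$role[out_i],
             stringsAsFactors = FALSE)
}

# Orient an edge row so that it ENTERS the given endpoint role: an edge
# enters its `to` endpoint as stored and its `from` endpoint as its twin.
orient_entering <- function(rows, role) {
  tw <- twin_fields(rows)
  use_twin <- role == "from"
  out <- rows
  out[use_twin, ] <- tw[use_twin, ]
  out
}

# Orient an edge row so that it LEAVES the given endpoint role.
orient_leaving <- function(rows, role) {
  tw <- twin_fields(rows)
  use_twin <- role == "to"
  out <- rows
  out[use_twin, ] <- tw[use_twin, ]
  out
}

#' Select a conflict-free batch of merge operations
#'
#' Two operations conflict exactly when their small worlds intersect, which
#' for degree-2 merge pairs happens exactly when they share an edge; every
#' edge belongs to at most two operations, so the conflict graph is a
#' disjoint union of paths and cycles. Deterministic mode walks each
#' component from a deterministic end and keeps alternate operations, which
#' attains a maximum matching (half the edges of every pure path merge per
#' round). Randomized mode greedily scans a seeded random priority order,
#' emulating backoff winners. Both modes return a maximal conflict-free set.
#'
#' @param pairs Operation set from \code{\link{enumerate_sigma}}, drawn from
#'   one graph snapshot.
#' @param cfg A \code{\link{scheduler_config}}.
#' @return Logical vector marking the selected rows of \code{pairs}.
#' @export
select_independent <- function(pairs, cfg = scheduler_config()) {
  n <- nrow(pairs)
  if (n == 0L) return(logical(0))
  max_edge <- max(pairs$e_in, pairs$e_out)
  edge_used <- logical(max_edge)
  selected <- logical(n)
  take <- function(p) {
    if (!edge_used[pairs$e_in[p]] && !edge_used[pairs$e_out[p]]) {
      edge_used[pairs$e_in[p]] <<- TRUE
      edge_used[pairs$e_out[p]] <<- TRUE
      selected[p] <<- TRUE
    }
  }
  if (cfg$mode == "randomized") {
    ord <- local_seed(cfg$seed, sample.int(n))
    for (p in ord) take(p)
    return(selected)
  }
  # Deterministic: walk the conflict components (paths/cycles of pairs that
  # share an edge) taking alternate pairs.
  owners <- split(rep(seq_len(n), 2L), c(pairs$e_in, pairs$e_out))
  neighbours <- function(p) {
    cand <- c(owners[[as.character(pairs$e_in[p])]],
              owners[[as.character(pairs$e_out[p])]])
    cand[cand != p]
  }
  ord <- order(pairs$center, method = "radix")
  shared <- vapply(owners, length, 0L)
  endpoint <- rep(FALSE, n)
  solo_edges <- as.integer(names(owners)[shared == 1L])
  endpoint[pairs$e_in %in% solo_edges | pairs$e_out %in% solo_edges] <- TRUE
  visited <- logical(n)
  for (start in c(ord[endpoint[ord]], ord)) {
    if (visited[start]) next
    cur <- start
    while (!is.na(cur) && !visited[cur]) {
      visited[cur] <- TRUE
      take(cur)
      nb <- neighbours(cur)
      nb <- nb[!visited[nb]]
      cur <- if (length(nb)) nb[1L] else NA_integer_
    }
  }
  selected
}

# Apply a batch of pairwise-disjoint merges; returns the new graph.
apply_merge_pairs <- function(g, pairs, selected) {
  p <- pairs[selected, , drop = FALSE]
  if (nrow(p) == 0L) return(g)
  left <- orient_entering(g$edges[p$e_in, , drop = FALSE], p$role_in)
  right <- orient_leaving(g$edges[p$e_out, , drop = FALSE], p$role_out)
  merged <- canonicalize_fields(merge_rows(left, right))
  drop <- c(p$e_in, p$e_out)
  edges <- rbind(g$edges[-drop, , drop = FALSE], merged)
  mol <- g$mol[!(g$mol$rep %in% p$center), , drop = FALSE]
  new_msg_graph(g$k, mol, edges)
}

#' Generic round-synchronous scheduler
#'
#' Driver shared by \code{\link{reduce_graph}}: each round it enumerates the
#' pending operations on the current state, selects a maximal conflict-free
#' subset, applies it atomically, and repeats until no operation remains.
#' The caller's operation must be associative on its domain so that the
#' fixpoint is independent of scheduling. Logical partitions only annotate
#' which partition each applied operation hashed to.
#'
#' @param state Initial state (e.g. an \code{msg_graph}).
#' @param ops_fn \code{function(state)} returning the operation set (a
#'   data.frame with a \code{center} key column).
#' @param apply_fn \code{function(state, ops, selected)} applying a selected
#'   batch and returning the new state.
#' @param cfg A \code{\link{scheduler_config}}.
#' @param max_rounds Safety cap; exceeding it is an error.
#' @param select_fn Batch selector, by default
#'   \code{\link{select_independent}}.
#' @return \code{list(state, report)} where \code{report} has
#'   \code{rounds}, \code{operations_applied}, \code{per_round_counts} and
#'   \code{per_partition_counts}.
#' @export
run_swap <- function(state, ops_fn, apply_fn, cfg = scheduler_config(),
                     max_rounds = 1000L, select_fn = select_independent) {
  per_round <- integer(0)
  per_part <- integer(cfg$partitions)
  round <- 0L
  repeat {
    ops <- ops_fn(state)
    if (nrow(ops) == 0L) break
    if (round >= max_rounds) {
      stop("scheduler failed to reach a fixpoint within ", max_rounds,
           " rounds", call. = FALSE)
    }
    sel <- select_fn(ops, cfg)
    part <- (vapply(ops$center[sel],
                    function(x) sum(utf8ToInt(x)), 0) %% cfg$partitions) + 1L
    for (q in part) per_part[q] <- per_part[q] + 1L
    state <- apply_fn(state, ops, sel)
    round <- round + 1L
    per_round <- c(per_round, sum(sel))
  }
  list(state = state,
       report = list(rounds = round,
                     operations_applied = sum(per_round),
                     per_round_counts = per_round,
                     per_partition_counts = per_part))
}

#' One reduction round / full graph reduction
#'
#' \code{reduction_round} applies one maximal conflict-free batch of edge
#' merges: each merged pair replaces its two edges by their merged edge and
#' retires the degree-2 center molecule. \code{reduce_graph} iterates rounds
#' until the operation set is empty, so every unanimous path has collapsed
#' to one full-extended edge; on a pure path of E edges the deterministic
#' scheduler needs ceiling(log2(E)) rounds. A safety cap of
#' 4 * ceiling(log2(edges + 2)) rounds guards against non-termination.
#'
#' @param g An \code{msg_graph}.
#' @param cfg A \code{\link{scheduler_config}}.
#' @return \code{reduction_round}: \code{list(graph, applied)};
#'   \code{reduce_graph}: \code{list(graph, report)} (see
#'   \code{\link{run_swap}}).
#' @export
reduction_round <- function(g, cfg = scheduler_config()) {
  pairs <- enumerate_sigma(g)
  sel <- select_independent(pairs, cfg)
  list(graph = apply_merge_pairs(g, pairs, sel), applied = sum(sel))
}

#' @rdname reduction_round
#' @export
reduce_graph <- function(g, cfg = scheduler_config()) {
  stopifnot(inherits(g, "msg_graph"))
  cap <- 4L * as.integer(ceiling(log2(nrow(g$edges) + 2)))
  res <- run_swap(g, enumerate_sigma, apply_merge_pairs, cfg,
                  max_rounds = max(cap, 1L))
  list(graph = res$state, report = res$report)
}

#' Cost of merging linked paths under three schedules
#'
#' For paths of \code{m} k-molecules (\code{m - 1} one-step edges each):
#' a fully sequential schedule performs one k-mer join at a time, costing
#' the total number of joins; a per-path-parallel schedule advances every
#' path by one join per round, costing the longest path's join count; the
#' pairwise concurrent schedule merges disjoint edge pairs within each path
#' every round, costing \code{ceiling(log2(m - 1))} rounds for the longest
#' path (zero when a path is already a single edge).
#'
#' @param path_node_counts Integer vector of k-molecule counts, each >= 2.
#' @param strategy One of "sequential", "per_path_parallel", "swap".
#' @return Integer operation or round count.
#' @examples
#' schedule_cost(c(3, 5), "sequential")         # 6 operations
#' schedule_cost(c(3, 5), "per_path_parallel")  # 4 rounds
#' schedule_cost(c(3, 5), "swap")               # 2 rounds
#' @export
schedule_cost <- function(path_node_counts,
                          strategy = c("sequential", "per_path_parallel",
                                       "swap")) {
  strategy <- match.arg(strategy)
  m <- path_node_counts
  if (length(m) == 0L || any(is.na(m)) || any(m < 2) || any(m != as.integer(m))) {
    stop("each path must have an integer node count >= 2", call. = FALSE)
  }
  edges <- as.integer(m) - 1L
  switch(strategy,
         sequential = sum(edges),
         per_path_parallel = max(edges),
         swap = max(as.integer(ceiling(log2(edges)))))
}
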