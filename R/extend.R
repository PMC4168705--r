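# Contig extension heuristics: tips, self-loops, parallel (multiple) edges,
# cross vertices and virtual cross vertices, the reduce/extend fixpoint
# loop, and contig emission.

#' Contig-extension configuration
#'
#' @param tip_max_label Tips strictly shorter than this many label bases are
#'   removable; \code{NULL} means the graph's k at use time.
#' @param coverage_tolerance Relative coverage difference
#'   \code{|c1 - c2| / max(c1, c2)} below which two edges at a (virtual)
#'   cross vertex are considered the same genomic path and paired.
#' @param max_rounds Cap on reduce/extend passes.
#' @param tips,self_loops,multiple_edges,cross,virtual_cross Enable flags
#'   for the individual heuristics.
#' @return A list of class \code{extension_config}.
#' @export
extension_config <- function(tip_max_label = NULL, coverage_tolerance = 0.2,
                             max_rounds = 16L, tips = TRUE,
                             self_loops = TRUE, multiple_edges = TRUE,
                             cross = TRUE, virtual_cross = TRUE) {
  stopifnot(coverage_tolerance > 0, coverage_tolerance < 1, max_rounds >= 1)
  structure(list(tip_max_label = tip_max_label,
                 coverage_tolerance = coverage_tolerance,
                 max_rounds = as.integer(max_rounds), tips = tips,
                 self_loops = self_loops, multiple_edges = multiple_edges,
                 cross = cross, virtual_cross = virtual_cross),
            class = "extension_config")
}

# Drop molecules that lost their last attachment relative to `before_reps`
# (molecules that never had an edge are left alone).
drop_newly_isolated <- function(g, before_attached) {
  now <- unique(c(g$edges$from, g$edges$to))
  lost <- g$mol$rep %in% before_attached & !(g$mol$rep %in% now)
  new_msg_graph(g$k, g$mol[!lost, , drop = FALSE], g$edges)
}

#' Remove tip edges
#'
#' A tip is a short dead end hanging off a branch: an edge with exactly one
#' endpoint of degree 1 whose other endpoint branches (degree >= 3), and a
#' label shorter than \code{tip_max_label} (default k). Edges whose far
#' endpoint lies on a plain path (degree <= 2) are chain ends, not tips, and
#' an isolated edge (both endpoints degree 1) is never removed. Molecules
#' stranded by the removal are dropped.
#'
#' @param g An \code{msg_graph}.
#' @param cfg An \code{\link{extension_config}}.
#' @return \code{list(graph, removed)}.
#' @export
remove_tips <- function(g, cfg = extension_config()) {
  stopifnot(inherits(g, "msg_graph"))
  tip_max <- if (is.null(cfg$tip_max_label)) g$k else cfg$tip_max_label
  e <- g$edges
  if (nrow(e) == 0L) return(list(graph = g, removed = 0L))
  r <- edge_records(g)
  degv <- table(r$mol)
  degf <- as.integer(degv[e$from])
  degt <- as.integer(degv[e$to])
  tip <- e$from != e$to & e$step < tip_max &
    ((degf == 1L & degt >= 3L) | (degt == 1L & degf >= 3L))
  if (!any(tip)) return(list(graph = g, removed = 0L))
  before <- unique(c(e$from, e$to))
  g2 <- new_msg_graph(g$k, g$mol, e[!tip, , drop = FALSE])
  list(graph = drop_newly_isolated(g2, before), removed = sum(tip))
}

# Self-loop edges (both endpoints the same molecule, including palindromic
# self-twin junctions) ordered deterministically.
self_loop_rows <- function(e) {
  li <- which(e$from == e$to)
  if (length(li) == 0L) return(integer(0))
  li[order(edge_sortkey(e[li, , drop = FALSE]), method = "radix")]
}

#' Resolve self-loop edges
#'
#' For every edge whose two endpoints are the same molecule: if some other
#' (non-loop) edge at that molecule enters it in an orientation in which the
#' loop leaves it, the highest-coverage such neighbour is merged through the
#' loop (the degree-2 requirement is waived); otherwise the loop is deleted.
#' This is what unblocks palindromic junctions, where a self-twin loop keeps
#' the molecule at degree 4 and ordinary reduction stalls.
#'
#' @param g An \code{msg_graph}.
#' @return \code{list(graph, merged, removed)}.
#' @export
resolve_self_loops <- function(g) {
  stopifnot(inherits(g, "msg_graph"))
  merged <- removed <- 0L
  before <- unique(c(g$edges$from, g$edges$to))
  repeat {
    e <- g$edges
    li <- self_loop_rows(e)
    if (length(li) == 0L) break
    i <- li[1L]
    m <- e$from[i]
    loop <- e[i, , drop = FALSE]
    # orientations in which the loop can be traversed leaving m
    variants <- unique(rbind(loop, twin_fields(loop)))
    r <- edge_records(g)
    nb <- r[r$mol == m & r$edge != i &
              e$from[r$edge] != e$to[r$edge], , drop = FALSE]
    best <- NULL
    if (nrow(nb) > 0L) {
      # neighbour entering m must match a loop variant leaving m
      for (v in seq_len(nrow(variants))) {
        ok <- flip_side(nb$side) == variants$dfrom[v]
        if (!any(ok)) next
        cand <- nb[ok, , drop = FALSE]
        cov <- e$coverage[cand$edge]
        key <- edge_sortkey(e[cand$edge, , drop = FALSE])
        pick <- order(-cov, key, method = "radix")[1L]
        cand <- cand[pick, , drop = FALSE]
        if (is.null(best) || e$coverage[cand$edge] > e$coverage[best$rec$edge]) {
          best <- list(rec = cand, variant = variants[v, , drop = FALSE])
        }
      }
    }
    if (is.null(best)) {
      g <- new_msg_graph(g$k, g$mol, e[-i, , drop = FALSE])
      removed <- removed + 1L
    } else {
      left <- orient_entering(e[best$rec$edge, , drop = FALSE], best$rec$role)
      newrow <- canonicalize_fields(merge_rows(left, best$variant))
      g <- new_msg_graph(g$k, g$mol,
                         rbind(e[-c(i, best$rec$edge), , drop = FALSE],
                               newrow))
      merged <- merged + 1L
    }
  }
  list(graph = drop_newly_isolated(g, before), merged = merged,
       removed = removed)
}

#' Remove parallel (multiple) edges
#'
#' Among edges connecting the same two molecule ends with the same pair of
#' orientations (twin representations identified), only the highest-coverage
#' edge is kept; coverage ties keep the lexicographically smaller stored
#' label. Molecules stranded by the removal are dropped.
#'
#' @param g An \code{msg_graph}.
#' @return \code{list(graph, removed)}.
#' @export
resolve_multiple_edges <- function(g) {
  stopifnot(inherits(g, "msg_graph"))
  e <- g$edges
  if (nrow(e) <= 1L) return(list(graph = g, removed = 0L))
  ka <- paste0(e$from, e$to, ori_letter(e$dfrom), ori_letter(e$dto))
  kb <- paste0(e$to, e$from, ori_letter(flip_side(e$dto)),
               ori_letter(flip_side(e$dfrom)))
  cls <- ifelse(ka <= kb, ka, kb)
  ord <- order(cls, -e$coverage, e$label, edge_sortkey(e), method = "radix")
  keep_first <- !duplicated(cls[ord])
  keep <- logical(nrow(e))
  keep[ord[keep_first]] <- TRUE
  if (all(keep)) return(list(graph = g, removed = 0L))
  before <- unique(c(e$from, e$to))
  g2 <- new_msg_graph(g$k, g$mol, e[keep, , drop = FALSE])
  list(graph = drop_newly_isolated(g2, before), removed = sum(!keep))
}

# Greedy coverage-sorted pairing of two record sets at a (virtual) cross:
# both sides are sorted by descending edge coverage and scanned with two
# pointers; the current tops pair when their relative coverage difference is
# below `tol`, otherwise the larger one is discarded (nothing further down
# the other side can match it). Records whose edge was already consumed, and
# pairings of a record with its own edge, are skipped.
pair_by_coverage <- function(ins, outs, cov, key, tol) {
  oi <- order(-cov[ins$edge], key[ins$edge], method = "radix")
  oj <- order(-cov[outs$edge], key[outs$edge], method = "radix")
  ins <- ins[oi, , drop = FALSE]
  outs <- outs[oj, , drop = FALSE]
  used <- integer(0)
  acc_in <- acc_out <- integer(0)
  i <- j <- 1L
  while (i <= nrow(ins) && j <= nrow(outs)) {
    if (ins$edge[i] %in% used) { i <- i + 1L; next }
    if (outs$edge[j] %in% used) { j <- j + 1L; next }
    if (ins$edge[i] == outs$edge[j]) { i <- i + 1L; next }
    c1 <- cov[ins$edge[i]]; c2 <- cov[outs$edge[j]]
    mx <- max(c1, c2)
    rel <- if (mx == 0) 0 else abs(c1 - c2) / mx
    if (rel < tol) {
      acc_in <- c(acc_in, i); acc_out <- c(acc_out, j)
      used <- c(used, ins$edge[i], outs$edge[j])
      i <- i + 1L; j <- j + 1L
    } else if (c1 >= c2) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  list(ins = ins[acc_in, , drop = FALSE], outs = outs[acc_out, , drop = FALSE])
}

#' Resolve cross vertices
#'
#' A cross vertex carries at least two attachments on each side. Its edges
#' are sorted by descending coverage side by side and greedily paired across
#' the vertex; a pair is accepted when the relative coverage difference is
#' below \code{coverage_tolerance}, on the premise that matching coverage
#' identifies the two halves of one genomic path crossing a repeat. Each
#' accepted pair is merged through a cloned copy of the center (the degree-2
#' requirement is waived); unpaired edges stay attached, and the center is
#' dropped only if everything merged away.
#'
#' @param g An \code{msg_graph}.
#' @param cfg An \code{\link{extension_config}}.
#' @return \code{list(graph, merged_pairs)}.
#' @export
resolve_cross_vertices <- function(g, cfg = extension_config()) {
  stopifnot(inherits(g, "msg_graph"))
  tol <- cfg$coverage_tolerance
  merged_pairs <- 0L
  before <- unique(c(g$edges$from, g$edges$to))
  processed <- character(0)
  repeat {
    e <- g$edges
    r <- edge_records(g)
    if (nrow(r) == 0L) break
    # two distinct edges required on each side (a palindromic self-twin
    # loop leaves two records but is a single edge, not a cross)
    nedges <- function(side) {
      sel <- r$side == side
      tapply(r$edge[sel], r$mol[sel], function(x) length(unique(x)))
    }
    plus <- nedges("+")
    minus <- nedges("-")
    cand <- intersect(names(plus)[plus >= 2L], names(minus)[minus >= 2L])
    cand <- setdiff(cand, processed)
    if (length(cand) == 0L) break
    m <- sort(cand, method = "radix")[1L]
    ins <- r[r$mol == m & r$side == "-", , drop = FALSE]
    outs <- r[r$mol == m & r$side == "+", , drop = FALSE]
    pk <- pair_by_coverage(ins, outs, e$coverage, edge_sortkey(e), tol)
    if (nrow(pk$ins) > 0L) {
      left <- orient_entering(e[pk$ins$edge, , drop = FALSE], pk$ins$role)
      right <- orient_leaving(e[pk$outs$edge, , drop = FALSE], pk$outs$role)
      newrows <- canonicalize_fields(merge_rows(left, right))
      drop <- c(pk$ins$edge, pk$outs$edge)
      g <- new_msg_graph(g$k, g$mol,
                         rbind(e[-drop, , drop = FALSE], newrows))
      merged_pairs <- merged_pairs + nrow(pk$ins)
    }
    processed <- c(processed, m)
  }
  list(graph = drop_newly_isolated(g, before), merged_pairs = merged_pairs)
}

#' Resolve virtual cross vertices
#'
#' An edge e0 whose two endpoints both carry at least two further
#' attachments on their outer sides (the sides from which an edge can merge
#' into, or out of, e0) is treated together with its endpoints as one
#' virtual vertex. Outer edges on the two sides are coverage-ranked and
#' paired under the same relative-difference rule as
#' \code{\link{resolve_cross_vertices}}; each accepted pair is merged with a
#' cloned copy of e0 into a single through edge. e0 itself is removed only
#' when every outer edge on both sides was consumed.
#'
#' @param g An \code{msg_graph}.
#' @param cfg An \code{\link{extension_config}}.
#' @return \code{list(graph, merged_pairs)}.
#' @export
resolve_virtual_cross <- function(g, cfg = extension_config()) {
  stopifnot(inherits(g, "msg_graph"))
  tol <- cfg$coverage_tolerance
  merged_pairs <- 0L
  before <- unique(c(g$edges$from, g$edges$to))
  processed <- character(0)
  repeat {
    e <- g$edges
    if (nrow(e) == 0L) break
    r <- edge_records(g)
    keys <- edge_sortkey(e)
    cand <- which(e$from != e$to & !(keys %in% processed))
    cand <- cand[order(keys[cand], method = "radix")]
    hit <- NULL
    for (i in cand) {
      outer_u <- r[r$mol == e$from[i] & r$side == flip_side(e$dfrom[i]) &
                     r$edge != i, , drop = FALSE]
      outer_v <- r[r$mol == e$to[i] & r$side == e$dto[i] &
                     r$edge != i, , drop = FALSE]
      if (length(unique(outer_u$edge)) >= 2L &&
          length(unique(outer_v$edge)) >= 2L) {
        hit <- list(i = i, outer_u = outer_u, outer_v = outer_v)
        break
      }
    }
    if (is.null(hit)) break
    i <- hit$i
    pk <- pair_by_coverage(hit$outer_u, hit$outer_v, e$coverage, keys, tol)
    if (nrow(pk$ins) == 0L) {
      processed <- c(processed, keys[i])
      next
    }
    left <- orient_entering(e[pk$ins$edge, , drop = FALSE], pk$ins$role)
    right <- orient_leaving(e[pk$outs$edge, , drop = FALSE], pk$outs$role)
    mid <- e[rep(i, nrow(left)), , drop = FALSE]
    newrows <- canonicalize_fields(merge_rows(merge_rows(left, mid), right))
    consumed_all <- nrow(pk$ins) == nrow(hit$outer_u) &&
      nrow(pk$outs) == nrow(hit$outer_v)
    drop <- c(pk$ins$edge, pk$outs$edge, if (consumed_all) i)
    if (!consumed_all) processed <- c(processed, keys[i])
    g <- new_msg_graph(g$k, g$mol, rbind(e[-drop, , drop = FALSE], newrows))
    merged_pairs <- merged_pairs + nrow(pk$ins)
  }
  list(graph = drop_newly_isolated(g, before), merged_pairs = merged_pairs)
}

#' Reduce/extend fixpoint loop
#'
#' Repeats [graph reduction, self-loop resolution, tip removal, multiple
#' edge removal, cross vertices, virtual cross vertices] until one full pass
#' changes nothing or \code{max_rounds} passes have run (then a warning is
#' raised and the current state returned). Self-loops are resolved before
#' tips so that a palindromic junction is unblocked before the short
#' terminal edge it pins down could be mistaken for a tip. With every
#' heuristic disabled the result equals \code{\link{reduce_graph}}.
#'
#' @param g An \code{msg_graph} (typically cleaned).
#' @param cfg An \code{\link{extension_config}}.
#' @param scheduler_cfg A \code{\link{scheduler_config}}.
#' @return \code{list(graph, rounds)} where \code{rounds} counts the passes
#'   that changed the graph.
#' @export
assemble_loop <- function(g, cfg = extension_config(),
                          scheduler_cfg = scheduler_config()) {
  stopifnot(inherits(g, "msg_graph"))
  rounds <- 0L
  repeat {
    before <- graph_dump(g)
    g <- reduce_graph(g, scheduler_cfg)$graph
    if (cfg$self_loops) g <- resolve_self_loops(g)$graph
    if (cfg$tips) g <- remove_tips(g, cfg)$graph
    if (cfg$multiple_edges) g <- resolve_multiple_edges(g)$graph
    if (cfg$cross) g <- resolve_cross_vertices(g, cfg)$graph
    if (cfg$virtual_cross) g <- resolve_virtual_cross(g, cfg)$graph
    if (identical(graph_dump(g), before)) break
    rounds <- rounds + 1L
    if (rounds >= cfg$max_rounds) {
      if (!identical(graph_dump(g), before)) {
        warning("assemble_loop reached max_rounds before the fixpoint",
                call. = FALSE)
      }
      break
    }
  }
  list(graph = g, rounds = rounds)
}

#' Emit contigs from an assembled graph
#'
#' Every remaining edge spells one contig: the traversed source strand
#' concatenated with the label, canonicalized to the lexicographically
#' larger of the two strands. A multi-step self-loop with equal end
#' orientations at an otherwise unattached molecule is an isolated circular
#' chain collapsed onto itself and is flagged \code{circular} (its sequence
#' carries a k-base wrap overlap); loops anchored at a molecule that still
#' has other edges spell ordinary linear contigs.
#' Records shorter than \code{min_length} are dropped; output order is by
#' decreasing length, then sequence.
#'
#' @param g An \code{msg_graph}.
#' @param min_length Minimum contig length to report (default 2k - 1).
#' @return A data.frame with columns \code{id}, \code{sequence},
#'   \code{length}, \code{coverage}, \code{circular}.
#' @export
emit_contigs <- function(g, min_length = 2L * g$k - 1L) {
  stopifnot(inherits(g, "msg_graph"))
  e <- g$edges
  spell <- paste0(oriented_key(e$from, e$dfrom), e$label)
  rcs <- rc_quick(spell)
  seqs <- ifelse(spell >= rcs, spell, rcs)
  r <- edge_records(g)
  degv <- table(r$mol)
  isolated <- as.integer(degv[e$from]) == 2L
  out <- data.frame(sequence = seqs, length = nchar(seqs),
                    coverage = e$coverage,
                    circular = e$from == e$to & e$dfrom == e$dto &
                      e$step > 1L & isolated,
                    stringsAsFactors = FALSE)
  out <- out[out$length >= min_length, , drop = FALSE]
  out <- out[order(-out$length, out$sequence, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  cbind(data.frame(id = sprintf("contig_%d", seq_len(nrow(out))),
                   stringsAsFactors = FALSE),
        out)
}
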