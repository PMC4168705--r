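# The 1-step bi-directed graph: construction from reads, degrees,
# frequency-based cleaning, audits, and a TSV dump/load dialect.
#
# A graph is a plain list:
#   k        odd integer word size
#   mol      data.frame(rep, freq): k-molecules keyed by representative
#   edges    data.frame(from, to, dfrom, dto, label, step, coverage),
#            one row per stored edge, always in canonical (smaller-key)
#            representation; parallel rows are permitted after merging.

new_msg_graph <- function(k, mol, edges) {
  rownames(mol) <- NULL
  rownames(edges) <- NULL
  structure(list(k = as.integer(k), mol = mol, edges = edges),
            class = "msg_graph")
}

empty_graph <- function(k) {
  new_msg_graph(k,
                data.frame(rep = character(0), freq = integer(0),
                           stringsAsFactors = FALSE),
                edge_fields(character(0), character(0), character(0),
                            character(0), character(0), numeric(0)))
}

#' @export
print.msg_graph <- function(x, ...) {
  cat(sprintf("<msg_graph> k=%d, %d k-molecules, %d edges\n",
              x$k, nrow(x$mol), nrow(x$edges)))
  invisible(x)
}

# Attachment records: every edge contributes exactly two, one per endpoint.
# `side` is the orientation in which the edge LEAVES the molecule (for the
# `to` endpoint that is the negated arrival orientation). A self-twin
# palindromic edge yields two coincident records and so counts twice toward
# degree, as does a self-loop.
edge_records <- function(g) {
  e <- g$edges
  n <- nrow(e)
  data.frame(mol = c(e$from, e$to),
             side = c(e$dfrom, flip_side(e$dto)),
             edge = rep(seq_len(n), 2L),
             role = rep(c("from", "to"), each = n),
             stringsAsFactors = FALSE)
}

#' Build the 1-step bi-directed graph from reads
#'
#' Slides a window of length k over every read (split at ambiguous bases),
#' canonicalizes each window into a k-molecule, and connects consecutive
#' windows with 1-step bi-directed edges labelled with the last base of the
#' successor window in its traversal orientation. Molecule frequency counts
#' window occurrences on either strand; edge coverage counts adjacent-pair
#' occurrences. Each distinct edge is stored once in canonical form, so the
#' graph built from reverse-complemented reads is identical.
#'
#' @param reads Character vector (or list) of read sequences.
#' @param k Odd integer word size (>= 3).
#' @return An object of class \code{msg_graph}.
#' @examples
#' g <- build_graph(c("TAGTCG", "AGTCGA", "TCGAGG"), 3)
#' g  # 6 k-molecules, 6 edges
#' @export
build_graph <- function(reads, k) {
  k <- check_odd_k(k)
  reads <- toupper(unlist(reads, use.names = FALSE))
  mols <- vector("list", length(reads))
  efrom <- eto <- edf <- edt <- elab <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    segs <- strsplit(reads[i], "[^ACGT]+")[[1L]]
    segs <- segs[nchar(segs) >= k]
    if (length(segs) == 0L) next
    rm_ <- ef_ <- et_ <- df_ <- dt_ <- lb_ <- vector("list", length(segs))
    for (j in seq_along(segs)) {
      s <- segs[j]
      m <- nchar(s) - k + 1L
      win <- substring(s, seq_len(m), seq_len(m) + k - 1L)
      cn <- canon_kmers(win)
      rm_[[j]] <- cn$key
      if (m >= 2L) {
        ef_[[j]] <- cn$key[-m]
        et_[[j]] <- cn$key[-1L]
        df_[[j]] <- cn$orientation[-m]
        dt_[[j]] <- cn$orientation[-1L]
        lb_[[j]] <- substr(win[-1L], k, k)
      }
    }
    mols[[i]] <- unlist(rm_)
    efrom[[i]] <- unlist(ef_); eto[[i]] <- unlist(et_)
    edf[[i]] <- unlist(df_); edt[[i]] <- unlist(dt_); elab[[i]] <- unlist(lb_)
  }
  mols <- unlist(mols)
  if (is.null(mols) || length(mols) == 0L) return(empty_graph(k))
  freq <- table(mols)
  mol <- data.frame(rep = names(freq), freq = as.integer(freq),
                    stringsAsFactors = FALSE)
  mol <- mol[order(mol$rep, method = "radix"), , drop = FALSE]

  ef <- unlist(efrom)
  if (is.null(ef) || length(ef) == 0L) return(new_msg_graph(k, mol, empty_graph(k)$edges))
  raw <- edge_fields(ef, unlist(eto), unlist(edf), unlist(edt), unlist(elab),
                     1)
  can <- canonicalize_fields(raw)
  key <- edge_sortkey(can)
  cov <- table(key)
  first <- !duplicated(key)
  edges <- can[first, , drop = FALSE]
  edges$coverage <- as.numeric(cov[key[first]])
  edges <- edges[order(edge_sortkey(edges), method = "radix"), , drop = FALSE]
  new_msg_graph(k, mol, edges)
}

#' Molecule degrees
#'
#' \code{mol_degree} counts all edge attachments of a molecule (a self-loop
#' or self-twin edge counts twice); \code{side_degree} counts only the
#' attachments leaving the molecule in the given orientation. The two side
#' degrees always sum to the full degree.
#'
#' @param g An \code{msg_graph}.
#' @param m Representative k-mer of a molecule present in \code{g}.
#' @param side "+" or "-".
#' @return Integer attachment count.
#' @export
mol_degree <- function(g, m) {
  stopifnot(inherits(g, "msg_graph"))
  if (!m %in% g$mol$rep) stop("molecule not in graph: ", m, call. = FALSE)
  r <- edge_records(g)
  sum(r$mol == m)
}

#' @rdname mol_degree
#' @export
side_degree <- function(g, m, side) {
  stopifnot(inherits(g, "msg_graph"), is_side(side))
  if (!m %in% g$mol$rep) stop("molecule not in graph: ", m, call. = FALSE)
  r <- edge_records(g)
  sum(r$mol == m & r$side == side)
}

#' Mean molecule frequency and automatic cleaning threshold
#'
#' The automatic threshold is a fixed fraction of the mean k-molecule
#' frequency (default 5\%, in the customary 3-10\% band), rounded up and
#' clamped below at 2 so that singleton k-mers - the signature of isolated
#' sequencing errors - are always removable. An empty graph yields 0.
#'
#' @param g An \code{msg_graph}.
#' @param fraction Fraction of the mean frequency to use.
#' @return \code{mean_molecule_coverage}: mean frequency;
#'   \code{auto_threshold}: integer threshold.
#' @export
mean_molecule_coverage <- function(g) {
  stopifnot(inherits(g, "msg_graph"))
  if (nrow(g$mol) == 0L) return(NaN)
  mean(g$mol$freq)
}

#' @rdname mean_molecule_coverage
#' @export
auto_threshold <- function(g, fraction = 0.05) {
  stopifnot(inherits(g, "msg_graph"), fraction > 0, fraction < 1)
  if (nrow(g$mol) == 0L) return(0L)
  max(2L, as.integer(ceiling(fraction * mean_molecule_coverage(g))))
}

#' Frequency-based graph cleaning
#'
#' Removes (1) molecules with frequency strictly below
#' \code{molecule_threshold} together with their incident edges, then (2)
#' edges with coverage strictly below \code{edge_threshold}, then (3)
#' molecules that lost their last attachment in steps 1-2. Molecules that
#' never had an edge are kept, so cleaning with both thresholds 0 is the
#' identity, and the operation is idempotent at fixed thresholds.
#'
#' @param g An \code{msg_graph}.
#' @param molecule_threshold,edge_threshold Non-negative integers;
#'   \code{edge_threshold} defaults to \code{molecule_threshold}.
#' @return The cleaned \code{msg_graph}.
#' @export
clean_graph <- function(g, molecule_threshold,
                        edge_threshold = molecule_threshold) {
  stopifnot(inherits(g, "msg_graph"),
            molecule_threshold >= 0, edge_threshold >= 0)
  attached_before <- unique(c(g$edges$from, g$edges$to))
  keep_mol <- g$mol$freq >= molecule_threshold
  mol <- g$mol[keep_mol, , drop = FALSE]
  e <- g$edges
  e <- e[e$from %in% mol$rep & e$to %in% mol$rep, , drop = FALSE]
  e <- e[e$coverage >= edge_threshold, , drop = FALSE]
  attached_after <- unique(c(e$from, e$to))
  newly_isolated <- mol$rep %in% attached_before &
    !(mol$rep %in% attached_after)
  mol <- mol[!newly_isolated, , drop = FALSE]
  new_msg_graph(g$k, mol, e)
}

#' Audit graph invariants
#'
#' Checks that every stored edge satisfies the oriented-string invariant, is
#' stored in canonical (smaller-key) representation, that both endpoints
#' exist in the molecule table, and that step counts equal label lengths.
#' Stops with a message on the first violation.
#'
#' @param g An \code{msg_graph}.
#' @return \code{TRUE}, invisibly.
#' @export
graph_audit <- function(g) {
  stopifnot(inherits(g, "msg_graph"))
  e <- g$edges
  if (nrow(e) == 0L) return(invisible(TRUE))
  if (!all(e$step == nchar(e$label))) stop("step != label length")
  if (!all(edge_invariant_ok(e, g$k))) {
    stop("oriented-string invariant violated in stored edge")
  }
  if (!all(edge_sortkey(e) <= edge_sortkey(twin_fields(e)))) {
    stop("edge stored in non-canonical representation")
  }
  if (!all(c(e$from, e$to) %in% g$mol$rep)) {
    stop("edge endpoint missing from molecule table")
  }
  invisible(TRUE)
}

#' Dump and load graphs in a TSV dialect
#'
#' One line \code{K <k>}, then one line \code{M <rep> <freq>} per molecule
#' and one line \code{E <from> <to> <d_from> <d_to> <label> <coverage>} per
#' stored edge, each block sorted, coverage rendered with round-trip-exact
#' precision. Two graphs are equal exactly when their dumps are equal.
#'
#' @param g An \code{msg_graph}.
#' @param file Optional path; when given the dump is written there.
#' @return \code{graph_dump}: the character vector of lines (invisibly when
#'   \code{file} is given); \code{graph_load}: the reconstructed
#'   \code{msg_graph}.
#' @export
graph_dump <- function(g, file = NULL) {
  stopifnot(inherits(g, "msg_graph"))
  m <- g$mol[order(g$mol$rep, method = "radix"), , drop = FALSE]
  e <- g$edges
  eline <- sprintf("E\t%s\t%s\t%s\t%s\t%s\t%s", e$from, e$to, e$dfrom,
                   e$dto, e$label, fmt_cov(e$coverage))
  lines <- c(sprintf("K\t%d", g$k),
             sprintf("M\t%s\t%d", m$rep, m$freq),
             sort(eline, method = "radix"))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @rdname graph_dump
#' @param x Path to a dump file, or a character vector of dump lines.
#' @export
graph_load <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(parts, `[[`, "", 1L)
  if (tag[1L] != "K") stop("dump must start with a K line", call. = FALSE)
  k <- check_odd_k(as.integer(parts[[1L]][2L]))
  mp <- parts[tag == "M"]
  mol <- data.frame(rep = vapply(mp, `[[`, "", 2L),
                    freq = as.integer(vapply(mp, `[[`, "", 3L)),
                    stringsAsFactors = FALSE)
  ep <- parts[tag == "E"]
  get <- function(i) vapply(ep, `[[`, "", i)
  edges <- if (length(ep)) {
    edge_fields(get(2L), get(3L), get(4L), get(5L), get(6L),
                as.numeric(get(7L)))
  } else {
    empty_graph(k)$edges
  }
  g <- new_msg_graph(k, mol, edges)
  graph_audit(g)
  g
}
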