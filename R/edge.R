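# Bi-directed edges: construction, twin representation, canonical storage
# form, and the associative merging operation.
#
# An edge (from, to, d_from, d_to, label) records that traversing the graph
# from molecule `from` read in orientation d_from and appending `label`
# lands on molecule `to` read in orientation d_to:
#   suffix_k(oriented(from, d_from) o label) == oriented(to, d_to).
# Every edge has exactly one equivalent twin representation seen from the
# other endpoint; graphs store whichever of the two has the smaller sort key.

# The strand of a molecule key actually traversed.
oriented_key <- function(key, side) ifelse(side == "+", key, rc_quick(key))

# All edge fields as parallel vectors; used by the vectorized internals.
edge_fields <- function(from, to, dfrom, dto, label, coverage = 0) {
  data.frame(from = from, to = to, dfrom = dfrom, dto = dto, label = label,
             step = nchar(label), coverage = as.numeric(coverage),
             stringsAsFactors = FALSE)
}

edge_invariant_ok <- function(e, k) {
  full <- paste0(oriented_key(e$from, e$dfrom), e$label)
  n <- nchar(full)
  substr(full, n - k + 1L, n) == oriented_key(e$to, e$dto) &
    nchar(e$from) == k & nchar(e$to) == k & e$step >= 1L
}

# Twin representation of each row (vectorized).
twin_fields <- function(e) {
  full <- paste0(oriented_key(e$from, e$dfrom), e$label)
  lab2 <- rc_quick(substr(full, 1L, e$step))
  edge_fields(e$to, e$from, flip_side(e$dto), flip_side(e$dfrom), lab2,
              e$coverage)
}

# Collation-independent sort key: uppercase letters only (orientations are
# mapped to P/M, fields are fixed-width except the trailing label).
edge_sortkey <- function(e) {
  paste0(e$from, e$to, ori_letter(e$dfrom), ori_letter(e$dto), e$label)
}

# Canonical storage form: the lexicographically smaller of (edge, twin).
canonicalize_fields <- function(e) {
  tw <- twin_fields(e)
  keep <- edge_sortkey(e) <= edge_sortkey(tw)
  out <- e
  out[!keep, ] <- tw[!keep, ]
  out
}

as_bi_edge <- function(row) {
  structure(list(from = row$from, to = row$to, dfrom = row$dfrom,
                 dto = row$dto, label = row$label, step = row$step,
                 coverage = row$coverage), class = "bi_edge")
}

edge_row <- function(e) {
  edge_fields(e$from, e$to, e$dfrom, e$dto, e$label, e$coverage)
}

#' Construct a bi-directed edge
#'
#' Builds and validates a single multi-step bi-directed edge. Endpoints must
#' be canonical representatives (each at least as large as its reverse
#' complement) of equal odd length, and the oriented-string invariant must
#' hold: the length-k suffix of the traversed source strand concatenated
#' with the label equals the traversed target strand.
#'
#' @param from,to Representative k-mers of the two endpoint molecules.
#' @param dfrom,dto Orientations ("+" or "-") at the two endpoints.
#' @param label Edge label; its length is the step count.
#' @param coverage Non-negative observation weight.
#' @return An object of class \code{bi_edge}.
#' @examples
#' make_edge("TAG", "AGT", "+", "+", "T")
#' @export
make_edge <- function(from, to, dfrom, dto, label, coverage = 0) {
  for (x in list(from, to, label)) {
    if (!is.character(x) || length(x) != 1L || !grepl("^[ACGT]+$", x)) {
      stop("edge fields must be single ACGT strings", call. = FALSE)
    }
  }
  if (!is_side(c(dfrom, dto))) stop("orientations must be '+' or '-'",
                                    call. = FALSE)
  k <- check_odd_k(nchar(from))
  if (nchar(to) != k) stop("endpoint k-mers must have equal length",
                           call. = FALSE)
  if (from < rc_quick(from) || to < rc_quick(to)) {
    stop("endpoints must be canonical representatives", call. = FALSE)
  }
  e <- edge_fields(from, to, dfrom, dto, label, coverage)
  if (!edge_invariant_ok(e, k)) {
    stop("oriented-string invariant violated: suffix_k(oriented(from) o ",
         "label) != oriented(to)", call. = FALSE)
  }
  as_bi_edge(e)
}

#' @export
print.bi_edge <- function(x, ...) {
  cat(sprintf("<bi_edge> (%s,%s,%s,%s) label=%s step=%d cov=%g\n",
              x$from, x$to, x$dfrom, x$dto, x$label, x$step, x$coverage))
  invisible(x)
}

#' Twin representation of a bi-directed edge
#'
#' Every bi-directed edge has exactly one equivalent representation from the
#' other endpoint's perspective: endpoints swap, both orientations negate,
#' and the label becomes the reverse complement of the leading step-length
#' prefix of the traversed string. The twin of the twin is the original
#' edge, and some palindromic junction edges are their own twin.
#'
#' @param e A \code{bi_edge} (see \code{\link{make_edge}}).
#' @return The twin \code{bi_edge}.
#' @export
edge_twin <- function(e) {
  stopifnot(inherits(e, "bi_edge"))
  row <- edge_row(e)
  if (!edge_invariant_ok(row, nchar(e$from))) {
    stop("edge violates the oriented-string invariant", call. = FALSE)
  }
  as_bi_edge(twin_fields(row))
}

#' The zero edge
#'
#' Distinguished sentinel standing for every non-existing bi-directed edge.
#' It absorbs merging: merging anything with the zero edge yields the zero
#' edge, which makes the edge set closed under \code{\link{merge_edges}}.
#'
#' @return An object of class \code{msg_zero_edge}.
#' @export
zero_edge <- function() structure(list(), class = "msg_zero_edge")

#' @rdname zero_edge
#' @param x Object to test.
#' @export
is_zero_edge <- function(x) inherits(x, "msg_zero_edge")

# Vectorized merge of aligned edge rows; callers guarantee compatibility
# (left$to == right$from, left$dto == right$dfrom).
merge_rows <- function(left, right) {
  lab <- paste0(left$label, right$label)
  cov <- (left$step * left$coverage + right$step * right$coverage) /
    (left$step + right$step)
  edge_fields(left$from, right$to, left$dfrom, right$dto, lab, cov)
}

#' Merge two bi-directed edges
#'
#' The associative semigroup operation of the assembler. Two edges merge
#' when the first ends where the second starts with the same traversal
#' orientation at the shared molecule; the result concatenates labels, adds
#' step counts and label-length-weights the coverages. All other cases
#' (including either operand being the zero edge) return the zero edge. The
#' degree-2 requirement on the shared molecule is enforced by the graph
#' scheduler, not here: merging is a total function on edge values.
#'
#' @param e1,e2 \code{bi_edge} objects or the \code{\link{zero_edge}}.
#' @return The merged \code{bi_edge}, or the zero edge when the operands do
#'   not connect.
#' @examples
#' e1 <- make_edge("TAG", "AGT", "+", "+", "T")
#' e2 <- make_edge("AGT", "GTC", "+", "+", "C")
#' merge_edges(e1, e2)  # (TAG,GTC,+,+) label "TC"
#' @export
merge_edges <- function(e1, e2) {
  if (is_zero_edge(e1) || is_zero_edge(e2)) return(zero_edge())
  stopifnot(inherits(e1, "bi_edge"), inherits(e2, "bi_edge"))
  if (e1$to != e2$from || e1$dto != e2$dfrom) return(zero_edge())
  as_bi_edge(merge_rows(edge_row(e1), edge_row(e2)))
}
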