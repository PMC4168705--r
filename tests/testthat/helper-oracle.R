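# Independent brute-force unitig decomposition used as an oracle for graph
# reduction. Shares no code with the package: its own reverse complement
# (Biostrings), its own adjacency representation (oriented k-mer arcs), and
# a path-walking algorithm instead of iterated pairwise edge merging.

oracle_rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Maximal unanimous-path decomposition of the k-mer graph of `reads`.
# Returns list(linear = sorted canonical sequences, circular = sorted
# rotation-canonical sequences of isolated cycles).
oracle_unitigs <- function(reads, k) {
  from <- character(0); to <- character(0)
  for (r in reads) {
    for (seg in strsplit(toupper(r), "[^ACGT]+")[[1]]) {
      m <- nchar(seg) - k + 1L
      if (is.na(m) || m < 2L) next
      w <- substring(seg, 1:m, 1:m + k - 1L)
      from <- c(from, w[-m]); to <- c(to, w[-1L])
    }
  }
  if (length(from) == 0L) return(list(linear = character(0),
                                      circular = character(0)))
  # arcs in the doubled (both-strand) representation, deduplicated
  from2 <- c(from, oracle_rc(to)); to2 <- c(to, oracle_rc(from))
  keep <- !duplicated(paste(from2, to2))
  from2 <- from2[keep]; to2 <- to2[keep]

  molec <- function(x) pmax(x, oracle_rc(x))
  # one record per bi-edge endpoint: bi-edge = arc identified with its mirror
  arc_key <- paste(from2, to2)
  mirror_key <- paste(oracle_rc(to2), oracle_rc(from2))
  biedge <- pmin(arc_key, mirror_key)
  first <- !duplicated(biedge)
  bf <- from2[first]; bt <- to2[first]
  side_of <- function(x) ifelse(x == molec(x), "+", "-")
  rec_mol <- c(molec(bf), molec(bt))
  rec_side <- c(side_of(bf), chartr("+-", "-+", side_of(bt)))
  rec_edge <- rep(biedge[first], 2L)
  # internal molecule: exactly two records, distinct bi-edges, opposite sides
  spl <- split(seq_along(rec_mol), rec_mol)
  internal <- vapply(spl, function(i) {
    length(i) == 2L && rec_edge[i[1]] != rec_edge[i[2]] &&
      rec_side[i[1]] != rec_side[i[2]]
  }, TRUE)
  internal_mols <- names(spl)[internal]

  succ <- split(to2, from2)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  see <- function(a, b) assign(paste(a, b), TRUE, envir = visited)
  seen <- function(a, b) exists(paste(a, b), envir = visited)
  spell_step <- function(seq, nxt) paste0(seq, substr(nxt, k, k))

  linear <- character(0)
  starts <- which(!(molec(from2) %in% internal_mols))
  for (i in starts) {
    if (seen(from2[i], to2[i])) next
    cur_from <- from2[i]; cur_to <- to2[i]
    seqs <- spell_step(cur_from, cur_to)
    see(cur_from, cur_to)
    while (molec(cur_to) %in% internal_mols) {
      nxts <- succ[[cur_to]]
      stopifnot(length(nxts) == 1L)
      cur_from <- cur_to; cur_to <- nxts
      see(cur_from, cur_to)
      seqs <- spell_step(seqs, cur_to)
    }
    linear <- c(linear, max(seqs, oracle_rc(seqs)))
  }
  linear <- unique(linear)

  # leftover arcs form isolated cycles; canonicalize by rotation and strand
  circular <- character(0)
  for (i in seq_along(from2)) {
    if (seen(from2[i], to2[i])) next
    start <- from2[i]
    cur_from <- from2[i]; cur_to <- to2[i]
    see(cur_from, cur_to)
    body <- substr(cur_to, k, k)
    while (cur_to != start) {
      nxts <- succ[[cur_to]]
      stopifnot(length(nxts) == 1L)
      cur_from <- cur_to; cur_to <- nxts
      see(cur_from, cur_to)
      body <- paste0(body, substr(cur_to, k, k))
    }
    circular <- c(circular, rotation_canonical(body))
  }
  list(linear = sort(linear, method = "radix"),
       circular = sort(unique(circular), method = "radix"))
}

# Smallest rotation over both strands of a circular sequence.
rotation_canonical <- function(s) {
  rots <- function(x) {
    n <- nchar(x)
    vapply(seq_len(n),
           function(i) paste0(substr(x, i, n), substr(x, 1, i - 1L)), "")
  }
  min(c(rots(s), rots(oracle_rc(s))))
}

# Contigs of the package's reduction, shaped for oracle comparison.
reduced_contigs <- function(g, cfg = scheduler_config()) {
  red <- reduce_graph(g, cfg)
  ct <- emit_contigs(red$graph, min_length = g$k)
  lin <- ct$sequence[!ct$circular]
  # a circular chain's spelled sequence carries a k-base wrap overlap
  circ <- vapply(ct$sequence[ct$circular],
                 function(s) rotation_canonical(substr(s, g$k + 1L, nchar(s))),
                 "", USE.NAMES = FALSE)
  list(linear = sort(lin, method = "radix"),
       circular = sort(unique(circ), method = "radix"))
}
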