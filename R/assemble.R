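# The five-step pipeline (input, construction, cleaning, reduction,
# extension) and assembly statistics.

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L together contain at
#' least half of all assembled bases.
#'
#' @param lengths Vector of positive integer lengths (empty gives 0).
#' @return Integer N50.
#' @examples
#' n50(c(6, 5, 4, 3, 2))  # 5
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("lengths must be positive", call. = FALSE)
  }
  s <- sort(as.integer(lengths), decreasing = TRUE)
  as.integer(s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]])
}

#' Run the full assembly pipeline
#'
#' Reads sequences, builds the 1-step bi-directed graph, cleans it by
#' frequency thresholds, reduces and extends it to the fixpoint, and emits
#' contigs. With \code{output}/\code{stats_path} set, the contig FASTA and a
#' JSON statistics report are written; \code{dump_prefix} additionally dumps
#' the graph after construction, cleaning and assembly.
#'
#' @param inputs Character vector of FASTA/FASTQ paths, or (for programmatic
#'   use) a character vector of raw sequences via \code{reads}.
#' @param reads Optional character vector of in-memory reads (used instead
#'   of \code{inputs}).
#' @param k Odd word size (default 31).
#' @param molecule_threshold "auto" or a non-negative integer; "auto" uses
#'   \code{\link{auto_threshold}} with \code{threshold_fraction}.
#' @param edge_threshold Integer; defaults to the resolved molecule
#'   threshold.
#' @param threshold_fraction Fraction for the automatic threshold.
#' @param min_contig_len Minimum emitted contig length (default 2k - 1).
#' @param extension An \code{\link{extension_config}}; set
#'   \code{extension = NULL} to run reduction only.
#' @param scheduler A \code{\link{scheduler_config}}.
#' @param output Optional contig FASTA path.
#' @param stats_path Optional JSON statistics path.
#' @param dump_prefix Optional path prefix for per-stage graph dumps.
#' @param quiet Suppress progress messages.
#' @return A list of class \code{assembly_stats}: contig counts and sizes
#'   (\code{contig_count}, \code{total_bases}, \code{max_length},
#'   \code{n50}), stage sizes (\code{molecules_before_clean},
#'   \code{molecules_after_clean}, \code{edges_before}, \code{edges_after}),
#'   the scheduler report (\code{rounds}), and the contig table
#'   (\code{contigs}).
#' @export
assemble <- function(inputs = NULL, reads = NULL, k = 31L,
                     molecule_threshold = "auto", edge_threshold = NULL,
                     threshold_fraction = 0.05,
                     min_contig_len = 2L * k - 1L,
                     extension = extension_config(),
                     scheduler = scheduler_config(),
                     output = NULL, stats_path = NULL, dump_prefix = NULL,
                     quiet = TRUE) {
  k <- check_odd_k(k)
  if (is.null(reads)) {
    if (is.null(inputs) || length(inputs) == 0L) {
      stop("no input reads given", call. = FALSE)
    }
    reads <- unlist(lapply(inputs, read_sequences))
  }
  if (length(reads) == 0L) stop("no reads to assemble", call. = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  g <- build_graph(reads, k)
  say("graph construction: %d k-molecules, %d edges from %d reads",
      nrow(g$mol), nrow(g$edges), length(reads))
  if (!is.null(dump_prefix)) graph_dump(g, paste0(dump_prefix, ".built.tsv"))
  molecules_before <- nrow(g$mol)
  edges_before <- nrow(g$edges)

  if (identical(molecule_threshold, "auto")) {
    molecule_threshold <- auto_threshold(g, threshold_fraction)
  }
  if (is.null(edge_threshold)) edge_threshold <- molecule_threshold
  gc_ <- clean_graph(g, molecule_threshold, edge_threshold)
  say("graph cleaning (thresholds %d/%d): removed %.1f%% of k-molecules",
      molecule_threshold, edge_threshold,
      100 * (1 - nrow(gc_$mol) / max(1L, nrow(g$mol))))
  g <- gc_
  if (!is.null(dump_prefix)) graph_dump(g, paste0(dump_prefix, ".cleaned.tsv"))
  molecules_after <- nrow(g$mol)

  red <- reduce_graph(g, scheduler)
  g <- red$graph
  say("graph reduction: %d rounds, %d merges", red$report$rounds,
      red$report$operations_applied)
  if (!is.null(extension)) {
    ext <- assemble_loop(g, extension, scheduler)
    g <- ext$graph
    say("contig extension: %d reduce/extend passes", ext$rounds)
  }
  if (!is.null(dump_prefix)) graph_dump(g, paste0(dump_prefix, ".final.tsv"))

  contigs <- emit_contigs(g, min_contig_len)
  stats <- structure(list(
    contig_count = nrow(contigs),
    total_bases = sum(contigs$length),
    max_length = if (nrow(contigs)) max(contigs$length) else 0L,
    n50 = n50(contigs$length),
    molecules_before_clean = molecules_before,
    molecules_after_clean = molecules_after,
    edges_before = edges_before,
    edges_after = nrow(g$edges),
    molecule_threshold = molecule_threshold,
    edge_threshold = edge_threshold,
    k = k,
    rounds = red$report,
    contigs = contigs), class = "assembly_stats")
  if (!is.null(output)) write_contigs_fasta(contigs, output)
  if (!is.null(stats_path)) {
    jsonlite::write_json(stats[setdiff(names(stats), "contigs")],
                         stats_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  stats
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("<assembly_stats> %d contigs, %d bases, ",
                     "N50=%d, max=%d (k=%d)\n"),
              x$contig_count, x$total_bases, x$n50, x$max_length, x$k))
  invisible(x)
}
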