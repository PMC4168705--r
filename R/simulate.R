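# Seeded synthetic genomes and reads, so every pipeline stage is testable
# without external data: uniform coverage, optional strand symmetry, and a
# substitution-only error model (the cleaning stage targets the
# low-frequency k-mers substitutions create; indels add nothing testable).

#' Random genome sequence
#'
#' Uniform i.i.d. bases; a fixed seed reproduces the sequence exactly.
#'
#' @param length Genome length (>= 1).
#' @param seed Integer RNG seed.
#' @return A single DNA string.
#' @export
random_genome <- function(length, seed = 1L) {
  stopifnot(length >= 1)
  local_seed(seed,
             paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""))
}

#' Repeat-free genome sequence
#'
#' Generates a genome in which every canonical (k-1)-mer window is distinct
#' (reverse-complement collisions included), by seeded random extension with
#' backtracking restarts. Such a genome has a single unanimous path at word
#' size k, so error-free full-coverage reads must assemble back into exactly
#' one contig. Lengths near the 4^(k-1)/2 canonical word capacity are
#' rejected as infeasible, as are runs that exhaust their restart budget.
#'
#' @param length Genome length.
#' @param k Odd word size the genome must be repeat-free for.
#' @param seed Integer RNG seed.
#' @param max_restarts Restart budget for the rejection sampler.
#' @return A single DNA string.
#' @export
repeat_free_genome <- function(length, k, seed = 1L, max_restarts = 50L) {
  k <- check_odd_k(k)
  stopifnot(length >= k)
  wlen <- k - 1L
  capacity <- 4^wlen / 2
  if (length - wlen + 1L > capacity) {
    stop("infeasible: ", length - wlen + 1L, " distinct canonical ", wlen,
         "-mers requested but only ~", capacity, " exist", call. = FALSE)
  }
  local_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      cur <- paste(sample(DNA_BASES, wlen, replace = TRUE), collapse = "")
      rc_cur <- rc_quick(cur)
      seen <- new.env(hash = TRUE, parent = emptyenv())
      assign(max(cur, rc_cur), TRUE, envir = seen)
      out <- character(length)
      out[seq_len(wlen)] <- strsplit(cur, "")[[1L]]
      pos <- wlen
      ok <- TRUE
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      while (pos < length) {
        found <- FALSE
        for (b in sample(DNA_BASES)) {
          nxt <- paste0(substr(cur, 2L, wlen), b)
          rc_nxt <- paste0(comp[[b]], substr(rc_cur, 1L, wlen - 1L))
          key <- if (nxt >= rc_nxt) nxt else rc_nxt
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            pos <- pos + 1L
            out[pos] <- b
            cur <- nxt
            rc_cur <- rc_nxt
            found <- TRUE
            break
          }
        }
        if (!found) { ok <- FALSE; break }
      }
      if (ok) return(paste(out, collapse = ""))
    }
    stop("repeat-free generation failed after ", max_restarts,
         " restarts; length too close to capacity for this k", call. = FALSE)
  })
}

#' Tile reads across a genome
#'
#' Windows of \code{read_length} at offsets 0, step, 2*step, ... plus a
#' final window flush with the genome end.
#'
#' @param genome A single DNA string.
#' @param read_length Window length (<= genome length).
#' @param step Offset between consecutive windows.
#' @return Character vector of reads.
#' @examples
#' tile_reads("TAGTCGAGG", 6, 1)
#' @export
tile_reads <- function(genome, read_length, step = 1L) {
  n <- nchar(genome)
  stopifnot(read_length >= 1, read_length <= n, step >= 1)
  starts <- seq(1L, n - read_length + 1L, by = step)
  last <- n - read_length + 1L
  if (starts[length(starts)] != last) starts <- c(starts, last)
  substring(genome, starts, starts + read_length - 1L)
}

#' Sample reads uniformly from a genome
#'
#' Draws \code{ceiling(coverage * |genome| / read_length)} reads at seeded
#' uniform start positions; with \code{both_strands} each read is
#' independently reverse-complemented with probability 1/2, matching the
#' strand symmetry of real sequencing.
#'
#' @param genome A single DNA string.
#' @param read_length Read length.
#' @param coverage Target mean per-base coverage.
#' @param seed Integer RNG seed.
#' @param both_strands Emit reads from both strands.
#' @return Character vector of reads.
#' @export
sample_reads <- function(genome, read_length, coverage, seed = 1L,
                         both_strands = TRUE) {
  n <- nchar(genome)
  stopifnot(read_length >= 1, read_length <= n, coverage > 0)
  nreads <- as.integer(ceiling(coverage * n / read_length))
  local_seed(seed, {
    starts <- sample.int(n - read_length + 1L, nreads, replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    if (both_strands) {
      fl <- stats::runif(nreads) < 0.5
      reads[fl] <- rc_quick(reads[fl])
    }
    reads
  })
}

#' Inject substitution errors into reads
#'
#' Each base is independently substituted with probability \code{rate} by a
#' uniformly chosen different base.
#'
#' @param reads Character vector of reads.
#' @param rate Per-base substitution probability in [0, 1).
#' @param seed Integer RNG seed.
#' @return Character vector of mutated reads.
#' @export
inject_errors <- function(reads, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(reads)
  local_seed(seed, {
    vapply(reads, function(r) {
      n <- nchar(r)
      hit <- which(stats::runif(n) < rate)
      if (length(hit) == 0L) return(r)
      v <- strsplit(r, "")[[1L]]
      for (i in hit) {
        v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
      }
      paste(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  })
}

#' Write reads as FASTA or FASTQ
#'
#' FASTQ records carry a constant quality 'I'; the assembler ignores
#' qualities either way.
#'
#' @param reads Character vector of reads.
#' @param path Output path (".gz" suffix gzips the file).
#' @param format "fasta" or "fastq".
#' @param prefix Record-name prefix.
#' @return \code{path}, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq"),
                        prefix = "read") {
  format <- match.arg(format)
  ids <- sprintf("%s_%d", prefix, seq_along(reads))
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", ids), reads))
  } else {
    as.vector(rbind(paste0("@", ids), reads, "+",
                    strrep("I", nchar(reads))))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
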