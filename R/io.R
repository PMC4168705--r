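# Sequence file ingestion and contig output.

is_gzipped <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Read sequences from FASTA or FASTQ
#'
#' Auto-detects format (leading '>' vs '@') and gzip compression from the
#' file content. Multi-line FASTA is supported; FASTQ must be strict
#' four-line records and a quality string whose length differs from its
#' sequence is rejected. Qualities and record names are discarded; malformed
#' records raise an error citing the offending line number.
#'
#' @param path Readable file path.
#' @param format "auto", "fasta" or "fastq".
#' @return Character vector of upper-cased sequences in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- if (is_gzipped(path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty sequence file: ", path,
                                   call. = FALSE)
  first <- substr(lines[nonempty[1L]], 1L, 1L)
  if (format == "auto") {
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     stop("cannot detect format of ", path, ": line ",
                          nonempty[1L], " starts with '", first, "'",
                          call. = FALSE))
  }
  if (format == "fasta") {
    headers <- grep("^>", lines)
    if (length(headers) == 0L || nonempty[1L] != headers[1L]) {
      stop("malformed FASTA: line ", nonempty[1L], " is not a header",
           call. = FALSE)
    }
    bounds <- c(headers, length(lines) + 1L)
    seqs <- character(length(headers))
    for (i in seq_along(headers)) {
      lo <- bounds[i] + 1L
      hi <- bounds[i + 1L] - 1L
      body <- if (lo > hi) character(0) else lines[lo:hi]
      body <- body[nzchar(trimws(body))]
      if (length(body) == 0L) {
        stop("malformed FASTA: empty record at line ", headers[i],
             call. = FALSE)
      }
      seqs[i] <- paste(body, collapse = "")
    }
    return(toupper(seqs))
  }
  # FASTQ: strict 4-line records
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: truncated record near line ", length(lines),
         call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  for (i in idx) {
    if (substr(lines[i], 1L, 1L) != "@") {
      stop("malformed FASTQ: line ", i, " does not start with '@'",
           call. = FALSE)
    }
    if (substr(lines[i + 2L], 1L, 1L) != "+") {
      stop("malformed FASTQ: line ", i + 2L, " does not start with '+'",
           call. = FALSE)
    }
    if (nchar(lines[i + 3L]) != nchar(lines[i + 1L])) {
      stop("malformed FASTQ: quality length mismatch at line ", i + 3L,
           call. = FALSE)
    }
  }
  toupper(lines[idx + 1L])
}

#' Write contigs to FASTA
#'
#' Headers are \code{>contig_<n> length=<L> cov=<c>[ circular]}; sequence
#' lines wrap at 80 columns.
#'
#' @param contigs Contig data.frame from \code{\link{emit_contigs}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(contigs))) {
    hdr <- sprintf(">%s length=%d cov=%.4f%s", contigs$id[i],
                   contigs$length[i], contigs$coverage[i],
                   if (contigs$circular[i]) " circular" else "")
    starts <- seq(1L, contigs$length[i], by = 80L)
    writeLines(c(hdr, substring(contigs$sequence[i], starts,
                                pmin(starts + 79L, contigs$length[i]))), con)
  }
  invisible(path)
}
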