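# Sequence primitives: reverse complement, canonical representatives,
# k-mer and k-molecule extraction.

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement without input validation; callers guarantee ACGT.
rc_quick <- function(s) stringi::stri_reverse(chartr("ACGT", "TGCA", s))

#' Reverse complement of DNA strings
#'
#' Reverses each string and complements every base (A<->T, C<->G). Only the
#' unambiguous alphabet A, C, G, T is accepted: graph-side sequences never
#' carry ambiguity codes, and windows containing them are skipped upstream.
#'
#' @param s Character vector of DNA strings over A, C, G, T.
#' @return Character vector of the same length with each element reverse
#'   complemented. The operation is an involution.
#' @examples
#' reverse_complement("TAG")  # "CTA"
#' @export
reverse_complement <- function(s) {
  if (!is.character(s)) stop("s must be a character vector", call. = FALSE)
  bad <- !grepl("^[ACGT]+$", s)
  if (any(bad)) {
    stop("sequence contains a character outside {A,C,G,T}: ",
         s[which(bad)[1L]], call. = FALSE)
  }
  rc_quick(s)
}

# Vectorized canonicalization of clean k-mers. Returns list(key, orientation).
# Comparison is plain lexicographic order on A<C<G<T; the representative is
# the LARGER of the two strands. Uppercase-letter-only strings compare
# identically under any locale collation, so `>=` is safe here.
canon_kmers <- function(kmers) {
  rc <- rc_quick(kmers)
  pos <- kmers >= rc
  list(key = ifelse(pos, kmers, rc), orientation = ifelse(pos, "+", "-"))
}

#' Canonical representative of a k-mer
#'
#' Every k-mer and its reverse complement form one k-molecule, the vertex
#' unit of the bi-directed graph. The representative is the
#' lexicographically larger strand (A < C < G < T); the returned orientation
#' is "+" when the input equals the representative, "-" otherwise. k must be
#' odd, which guarantees no k-mer is its own reverse complement.
#'
#' @param kmer Character vector of k-mers (equal odd length, A/C/G/T only).
#' @return A list with components \code{key} (representative k-mer) and
#'   \code{orientation} ("+" or "-"), each as long as \code{kmer}.
#' @examples
#' representative("TAG")  # key "TAG", orientation "+"
#' representative("CTA")  # key "TAG", orientation "-"
#' @export
representative <- function(kmer) {
  if (!is.character(kmer) || length(kmer) == 0L) {
    stop("kmer must be a non-empty character vector", call. = FALSE)
  }
  bad <- !grepl("^[ACGT]+$", kmer)
  if (any(bad)) stop("k-mer contains non-ACGT character", call. = FALSE)
  n <- nchar(kmer)
  if (length(unique(n)) != 1L) stop("k-mers must share one length", call. = FALSE)
  if (n[1L] %% 2L == 0L) {
    stop("k must be odd: even k-mers can be palindromic", call. = FALSE)
  }
  canon_kmers(kmer)
}

#' Enumerate k-mer windows of a sequence
#'
#' Slides a window of length k along \code{s} and returns the windows in
#' order. Windows containing a non-ACGT character (e.g. N) are skipped, so a
#' read is effectively split at ambiguous bases. A sequence shorter than k
#' yields an empty vector.
#'
#' @param s A single DNA string; may contain ambiguity characters.
#' @param k Odd integer window size (>= 3).
#' @return Character vector of k-mers in positional order.
#' @examples
#' kmer_list("TAGTCG", 3)  # "TAG" "AGT" "GTC" "TCG"
#' @export
kmer_list <- function(s, k) {
  k <- check_odd_k(k)
  if (!is.character(s) || length(s) != 1L) {
    stop("s must be a single string", call. = FALSE)
  }
  s <- toupper(s)
  n <- nchar(s)
  if (k > n) return(character(0))
  starts <- seq_len(n - k + 1L)
  win <- substring(s, starts, starts + k - 1L)
  win[grepl("^[ACGT]+$", win)]
}

#' k-spectrum: the set of k-molecules of a sequence
#'
#' Canonicalizes every k-mer window of \code{s} and returns the distinct
#' representatives. By construction the spectrum of a sequence equals the
#' spectrum of its reverse complement.
#'
#' @inheritParams kmer_list
#' @return Sorted character vector of distinct representative k-mers.
#' @examples
#' kmer_spectrum("TAGTC", 3)  # "AGT" "GTC" "TAG" "TCG"
#' @export
kmer_spectrum <- function(s, k) {
  win <- kmer_list(s, k)
  if (length(win) == 0L) return(character(0))
  sort(unique(canon_kmers(win)$key), method = "radix")
}
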