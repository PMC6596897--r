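DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(seq, allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("sequence must be a single character string")
  s <- toupper(seq)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, s))
    stop("sequence contains symbols outside ",
         if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}")
  s
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence as a 4 x N matrix whose columns are the basis vectors
#' A = (1,0,0,0)', C = (0,1,0,0)', G = (0,0,1,0)', T = (0,0,0,1)'. The fixed
#' A,C,G,T channel order makes reversal of the channel axis coincide with
#' base complementation, which is what every reverse-complement group action
#' in this package relies on.
#'
#' Sequences containing \code{N} are rejected: ambiguous bases must be
#' filtered out upstream (see \code{\link{extract_center}}), mirroring the
#' practice of discarding sequences with unspecified bases when building
#' training data.
#'
#' @param seq A single string over \code{{A,C,G,T}} (case-insensitive).
#' @return A numeric matrix of dimension \code{c(4, nchar(seq))} with rows
#'   named A, C, G, T; every column sums to 1.
#' @examples
#' one_hot_encode("ACGT")  # the 4x4 identity matrix
#' @export
one_hot_encode <- function(seq) {
  s <- .check_dna(seq, allow_n = FALSE)
  n <- nchar(s)
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
  X <- matrix(0, nrow = 4L, ncol = n, dimnames = list(DNA_BASES, NULL))
  if (n > 0L) X[cbind(idx, seq_len(n))] <- 1
  X
}

#' Reverse complement of a DNA string
#'
#' Reverses the sequence and swaps A with T and C with G; \code{N} maps to
#' itself. Applying it twice returns the original string.
#'
#' @param seq A single string over \code{{A,C,G,T,N}} (case-insensitive).
#' @return The reverse-complemented string, uppercase.
#' @examples
#' rc_seq("AACG")  # "CGTT"
#' @export
rc_seq <- function(seq) {
  s <- .check_dna(seq, allow_n = TRUE)
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Reverse-complement action on a one-hot input tensor
#'
#' Implements the input-space group action RC(X)[i, j] = X[-i, -j], where a
#' negative index counts from the opposite end of the axis (paper-style
#' 1-based indexing; internally, entry (i, j) moves to (5 - i, N + 1 - j)).
#' With the A,C,G,T channel order this equals encoding the reverse-complement
#' strand, and the map is an involution.
#'
#' @param X A \code{[4, N]} matrix as returned by \code{\link{one_hot_encode}}.
#' @return A matrix of the same shape with both axes reversed.
#' @export
rc_input <- function(X) {
  if (!is.matrix(X) || nrow(X) != 4L) stop("X must be a [4, N] matrix")
  rc_hidden(X)
}

#' Reverse-complement action on a hidden-layer tensor
#'
#' The group action on any \code{[C, L]} activation tensor: both the
#' channel/filter axis and the spatial axis are reversed. On a \code{[4, N]}
#' one-hot tensor this is identical to \code{\link{rc_input}}.
#'
#' @param T_ A numeric matrix \code{[C, L]}.
#' @return The doubly reversed matrix.
#' @export
rc_hidden <- function(T_) {
  if (!is.matrix(T_)) stop("input must be a matrix")
  out <- T_[rev(seq_len(nrow(T_))), rev(seq_len(ncol(T_))), drop = FALSE]
  dimnames(out) <- NULL
  dimnames(T_) <- NULL
  out
}

#' Read a FASTA file of DNA sequences
#'
#' Multi-record, wrapped-line FASTA; bases are normalized to uppercase.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' GC content of a sequence
#'
#' Fraction of G and C bases. Sequences containing \code{N} are rejected,
#' as the hot/coldspot pipeline only matches GC on fully specified windows.
#'
#' @param seq A non-empty string over \code{{A,C,G,T}}.
#' @return A fraction in \code{[0, 1]}.
#' @export
gc_content <- function(seq) {
  s <- .check_dna(seq, allow_n = FALSE)
  n <- nchar(s)
  if (n == 0L) stop("empty sequence")
  (nchar(gsub("[AT]", "", s))) / n
}
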