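# Circular sequence primitives.
#
# A circular sequence is stored as a plain upper-case character scalar over
# {A,C,G,T,N}; all coordinates are 1-based and inclusive, and position L + 1
# wraps to position 1.

#' Create a circular nucleotide sequence
#'
#' Validates and normalizes a nucleotide string for use with the circular
#' coordinate arithmetic in this package. The sequence is stored upper-case;
#' coordinates into it are 1-based inclusive and wrap past its length.
#'
#' @param residues Character scalar over the alphabet A, C, G, T, N
#'   (case-insensitive).
#' @return A character scalar of class `circular_seq` with the alphabet
#'   checked and case normalized.
#' @examples
#' s <- circular_sequence("ACGTACGT")
#' seq_length(s)
#' @export
circular_sequence <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  residues <- toupper(residues)
  if (nchar(residues) == 0L) {
    stop("circular sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGTN]", residues)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", residues), "")[[1]])
    stop("invalid residues in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(residues, class = "circular_seq")
}

#' Length of a circular sequence in base pairs
#' @param seq A `circular_seq` or plain character scalar.
#' @return Integer length in bp.
#' @export
seq_length <- function(seq) {
  nchar(unclass(seq)[[1]])
}

#' @export
print.circular_seq <- function(x, ...) {
  L <- seq_length(x)
  shown <- if (L > 60L) paste0(substr(x, 1L, 57L), "...") else unclass(x)
  cat(sprintf("<circular_seq> %d bp\n  %s\n", L, shown))
  invisible(x)
}

# Wrap a vector of 1-based positions onto [1, L].
wrap_pos <- function(pos, L) {
  ((pos - 1L) %% L) + 1L
}

#' Extract a (possibly origin-spanning) slice of a circular sequence
#'
#' Returns the residues from `start` to `stop` inclusive, walking forward on
#' the majority strand and wrapping through the origin when `start > stop`.
#'
#' @param seq Circular sequence (or plain string).
#' @param start,stop 1-based inclusive positions in `[1, L]`.
#' @return Character scalar with the slice on the majority strand.
#' @export
circ_substr <- function(seq, start, stop) {
  s <- unclass(seq)[[1]]
  L <- nchar(s)
  stopifnot(start >= 1L, start <= L, stop >= 1L, stop <= L)
  if (start <= stop) {
    substr(s, start, stop)
  } else {
    paste0(substr(s, start, L), substr(s, 1L, stop))
  }
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over A, C, G, T, N.
#' @return The reverse complement, same case.
#' @export
revcomp <- function(x) {
  x <- unclass(x)[[1]]
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Rotate a circular string so that old position (r + 1) becomes position 1.
rotate_string <- function(x, r) {
  L <- nchar(x)
  r <- r %% L
  if (r == 0L) return(x)
  paste0(substr(x, r + 1L, L), substr(x, 1L, r))
}
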