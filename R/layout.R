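# Layout arithmetic on the circular coordinate axis: feature sizes, the
# junction (spacer/overlap) ledger, gene order, and motif occurrence.

#' Length of a feature on a circular genome
#'
#' `stop - start + 1` for an ordinary feature; a wrapping feature
#' (`start > stop`) contributes `(L - start + 1) + stop`.
#'
#' @param feature One row of an annotation's feature table (anything with
#'   `start`, `stop` and `wraps` fields), or a `mito_annotation` whose rows
#'   are all measured.
#' @param L Circular genome length in bp (ignored when `feature` is a
#'   `mito_annotation`).
#' @return Integer length(s) in bp.
#' @examples
#' feature_length(list(start = 273, stop = 1985, wraps = FALSE), 16407)
#' feature_length(list(start = 16381, stop = 41, wraps = TRUE), 16407)
#' @export
feature_length <- function(feature, L = NULL) {
  if (inherits(feature, "mito_annotation")) {
    L <- feature$genome_length
    feature <- feature$features
  }
  stopifnot(!is.null(L))
  start <- as.integer(feature$start)
  stop <- as.integer(feature$stop)
  ifelse(start > stop, (L - start + 1L) + stop, stop - start + 1L)
}

#' Signed gap between two consecutive features on the circle
#'
#' `start(next) - stop(prev) - 1`, evaluated with circular wrap modulo L.
#' Positive values are intergenic spacers, negative values overlaps, zero
#' means abutting features. The wrap is applied so that the result lies in
#' `(-L/2, L/2]`, i.e. the gap is measured along the short way from the end
#' of `prev` to the start of `nxt`.
#'
#' @param prev,nxt Feature rows (fields `start`, `stop`); `nxt` is the next
#'   feature in circular start order.
#' @param L Circular genome length in bp.
#' @return Integer gap in nucleotides (negative = overlap).
#' @export
junction_gap <- function(prev, nxt, L) {
  raw <- (as.integer(nxt$start) - as.integer(prev$stop) - 1L) %% L
  # Map the modular residue to a signed value: overlaps appear as residues
  # close to L, spacers as small non-negative residues.
  ifelse(raw > L / 2, raw - L, raw)
}

#' Build the junction ledger of an annotation
#'
#' One record per adjacent feature pair in start order, including the
#' wrap-around pair from the last feature back to the first. Each gap is
#' attributed to its upstream feature's row. The telescoping identity
#' `sum(length) + sum(gap) == L` holds for every valid annotation.
#'
#' @param ann A `mito_annotation` with at least 2 features.
#' @return data.frame with columns `upstream`, `downstream`, `gap_nt`.
#' @export
build_junction_ledger <- function(ann) {
  f <- ann$features
  if (nrow(f) < 2L) stop("junction ledger needs >= 2 features", call. = FALSE)
  L <- ann$genome_length
  nxt_idx <- c(seq_len(nrow(f))[-1L], 1L)
  data.frame(
    upstream = f$name,
    downstream = f$name[nxt_idx],
    gap_nt = vapply(seq_len(nrow(f)), function(i) {
      junction_gap(f[i, ], f[nxt_idx[i], ], L)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Summarize spacers and overlaps of a junction ledger
#'
#' @param ledger Output of [build_junction_ledger()].
#' @return A list of class `layout_summary`: counts, totals and extremes of
#'   the positive (spacer) and negative (overlap) gaps.
#' @export
layout_summary <- function(ledger) {
  g <- ledger$gap_nt
  pos <- g[g > 0]
  neg <- g[g < 0]
  structure(list(
    n_spacers = length(pos),
    total_spacer_nt = sum(pos),
    min_spacer = if (length(pos)) min(pos) else NA_integer_,
    max_spacer = if (length(pos)) max(pos) else NA_integer_,
    n_overlaps = length(neg),
    total_overlap_nt = sum(-neg),
    largest_overlap = if (length(neg)) max(-neg) else NA_integer_
  ), class = "layout_summary")
}

#' @export
print.layout_summary <- function(x, ...) {
  cat(sprintf(
    "<layout_summary> %d spacers (%d nt, %s..%s), %d overlaps (largest %s nt)\n",
    x$n_spacers, x$total_spacer_nt, x$min_spacer, x$max_spacer,
    x$n_overlaps, x$largest_overlap))
  invisible(x)
}

#' Signed circular gene order of an annotation
#'
#' Tokens in start order, each signed by strand, rotated so the sequence
#' begins at an anchor feature (default: the control region). When the
#' anchor is absent the rotation starts at the lexicographically smallest
#' token.
#'
#' @param ann A `mito_annotation`.
#' @param anchor Token to rotate the circular order to (default `"CR"`).
#' @param include Categories to include (default: all).
#' @return A `gene_order` object: list with `tokens` (signed character
#'   vector like `"+trnM"`, `"-trnQ"`) and `label`.
#' @export
gene_order <- function(ann, anchor = "CR", include = FEATURE_CATEGORIES) {
  f <- ann$features[ann$features$category %in% include, , drop = FALSE]
  if (nrow(f) == 0L) stop("no features selected", call. = FALSE)
  tokens <- paste0(ifelse(f$strand == "+", "+", "-"), f$name)
  names <- f$name
  idx <- if (anchor %in% names) {
    which(names == anchor)[1]
  } else {
    order(names)[1]
  }
  rot <- c(seq(idx, length(tokens)), seq_len(idx - 1L))
  new_gene_order(tokens[rot], label = ann$source_id)
}

new_gene_order <- function(tokens, label = "") {
  stopifnot(length(tokens) >= 1L)
  bare <- sub("^[+-]", "", tokens)
  if (anyDuplicated(bare)) {
    stop("gene order tokens must be unique: ",
         paste(unique(bare[duplicated(bare)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(tokens = as.character(tokens), label = as.character(label)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s(%d tokens)\n  %s\n",
              if (nzchar(x$label)) paste0(x$label, " ") else "",
              length(x$tokens), paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' Scan a circular genome for a motif on both strands
#'
#' Finds every occurrence of `motif` (and of its reverse complement, i.e.
#' hits on the minority strand) across the circular sequence, wrap-aware,
#' and annotates each hit with the features covering any part of it.
#'
#' @param seq A `circular_seq`.
#' @param motif Motif over A, C, G, T.
#' @param ann Optional `mito_annotation` used to annotate hits with
#'   overlapping features.
#' @return data.frame with columns `start`, `end` (1-based inclusive,
#'   majority-strand coordinates; `end` may be < `start` for a hit spanning
#'   the origin), `strand`, and `features` (comma-separated tokens).
#' @export
motif_scan <- function(seq, motif, ann = NULL) {
  motif <- toupper(motif)
  if (nchar(motif) == 0L) stop("motif must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", motif)) stop("motif must be over A,C,G,T",
                                    call. = FALSE)
  L <- seq_length(seq)
  m <- nchar(motif)
  if (m > L) return(motif_hits_frame())
  # Extend the linear text by m - 1 bases so origin-spanning hits are found
  # exactly once.
  text <- paste0(unclass(seq)[[1]],
                 substr(unclass(seq)[[1]], 1L, min(m - 1L, L)))
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else revcomp(motif)
    starts <- gregexpr(pat, text, fixed = TRUE)[[1]]
    starts <- starts[starts > 0 & starts <= L]
    for (s in starts) {
      e <- wrap_pos(s + m - 1L, L)
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, end = e, strand = strand,
        features = if (is.null(ann)) "" else
          paste(features_covering(ann, s, m), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(motif_hits_frame())
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

motif_hits_frame <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             features = character(), stringsAsFactors = FALSE)
}

# Names of features covering any of the m positions starting at s.
features_covering <- function(ann, s, m) {
  L <- ann$genome_length
  pos <- wrap_pos(seq(s, s + m - 1L), L)
  f <- ann$features
  covered <- vapply(seq_len(nrow(f)), function(i) {
    span <- if (f$wraps[i]) {
      c(seq(f$start[i], L), seq_len(f$stop[i]))
    } else {
      seq(f$start[i], f$stop[i])
    }
    any(pos %in% span)
  }, logical(1))
  f$name[covered]
}

#' Export a junction ledger as TSV
#' @param ledger Output of [build_junction_ledger()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_ledger <- function(ledger, path) {
  write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
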