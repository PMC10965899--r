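# Supermatrix preparation: concatenated nucleotide or amino-acid matrices
# of the 13 protein-coding genes across annotated mitogenomes, with a
# partition table. Alignment is deliberately external.

#' Canonical concatenation order of the 13 protein-coding genes
#' @return Character vector of gene tokens.
#' @export
pcg_concatenation_order <- function() {
  c("COI", "COII", "COIII", "CYTB", "ATP6", "ATP8",
    "NADH1", "NADH2", "NADH3", "NADH4", "NADH4L", "NADH5", "NADH6")
}

#' Build a concatenated supermatrix of the 13 PCGs
#'
#' Extracts each protein-coding gene on its coding strand from every
#' genome, strips terminal stop codons (trimming an incomplete terminal
#' codon with a warning), optionally translates under the given code, and
#' concatenates per taxon in a fixed gene order. Per-taxon gene lengths may
#' differ — the matrix is unaligned; the partition table records each
#' gene's offsets per taxon.
#'
#' @param genomes Named list of `list(sequence =, annotation =)` pairs
#'   (as returned by [read_genbank()] or [generate_mitogenome()]); names
#'   are the taxon labels.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param code A [genetic_code()] for translation (default table 5).
#' @param gene_order Concatenation order (default
#'   [pcg_concatenation_order()]).
#' @param gap_fill Replace a missing gene by an empty block instead of
#'   erroring?
#' @return A `supermatrix`: list with `taxa`, `alphabet`, `sequences`
#'   (named character vector) and `partition` (data.frame `gene`, `taxon`,
#'   `start`, `end` offsets into each taxon's concatenation).
#' @export
build_supermatrix <- function(genomes,
                              alphabet = c("amino-acid", "nucleotide"),
                              code = genetic_code(5),
                              gene_order = pcg_concatenation_order(),
                              gap_fill = FALSE) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    stop("genomes must be a named list (taxon labels)", call. = FALSE)
  }
  taxa <- names(genomes)
  seqs <- setNames(character(length(taxa)), taxa)
  parts <- list()
  for (tx in taxa) {
    g <- genomes[[tx]]
    f <- g$annotation$features
    offset <- 0L
    blocks <- character()
    for (gene in gene_order) {
      row <- f[f$name == gene & f$category == "PCG", , drop = FALSE]
      if (nrow(row) == 0L) {
        if (!gap_fill) {
          stop("taxon '", tx, "' is missing PCG '", gene, "'",
               call. = FALSE)
        }
        block <- ""
      } else {
        cds <- extract_cds(g$sequence, row[1, ])
        rem <- nchar(cds) %% 3L
        if (rem != 0L) {
          warning("taxon '", tx, "' gene '", gene,
                  "': trimming incomplete terminal codon (", rem, " nt)",
                  call. = FALSE)
          cds <- substr(cds, 1L, nchar(cds) - rem)
        }
        last <- substr(cds, nchar(cds) - 2L, nchar(cds))
        if (isTRUE(unname(code$codon_to_aa[last]) == "*")) {
          cds <- substr(cds, 1L, nchar(cds) - 3L)
        }
        block <- if (alphabet == "amino-acid") {
          translate_cds(cds, code)
        } else {
          cds
        }
      }
      parts[[length(parts) + 1L]] <- data.frame(
        gene = gene, taxon = tx, start = offset + 1L,
        end = offset + nchar(block), stringsAsFactors = FALSE)
      offset <- offset + nchar(block)
      blocks <- c(blocks, block)
    }
    seqs[tx] <- paste(blocks, collapse = "")
  }
  structure(list(taxa = taxa, alphabet = alphabet, sequences = seqs,
                 partition = do.call(rbind, parts)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa, %s alphabet, %d gene partitions\n",
              length(x$taxa), x$alphabet,
              length(unique(x$partition$gene))))
  invisible(x)
}

#' Export a supermatrix as FASTA plus a partition file
#'
#' Writes the unaligned per-taxon concatenations as multi-FASTA and a
#' RAxML-style partition text (`gene = start-end`, offsets of the first
#' taxon; with unaligned sequences these offsets are per-taxon records in
#' the accompanying TSV).
#'
#' @param m A `supermatrix`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_matrices <- function(m, dir, prefix = "supermatrix") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (m$alphabet == "amino-acid") "aa" else "nt"
  fasta <- file.path(dir, sprintf("%s_%s.fasta", prefix, ext))
  if (m$alphabet == "amino-acid") {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(m$sequences),
                                fasta, width = 70L)
  } else {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(m$sequences),
                                fasta, width = 70L)
  }
  part_file <- file.path(dir, sprintf("%s_%s.partitions.txt", prefix, ext))
  p1 <- m$partition[m$partition$taxon == m$taxa[1], , drop = FALSE]
  writeLines(sprintf("%s = %d-%d", p1$gene, p1$start, p1$end), part_file)
  part_tsv <- file.path(dir, sprintf("%s_%s.partitions.tsv", prefix, ext))
  write.table(m$partition, part_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta, partitions = part_file,
              partitions_tsv = part_tsv))
}
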