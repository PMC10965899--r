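# Pluggable genetic codes and their synonymous-family partitions.
#
# A genetic code is the 64-entry codon -> amino-acid map; the synonymous
# families used for RSCU are derived from the translation product, with
# stop codons forming their own family. The default is NCBI transl_table 5
# (invertebrate mitochondrial): AGA/AGG -> Ser, AUA -> Met, UGA -> Trp.

# 64 codons in the canonical NCBI enumeration order (first base slowest),
# DNA alphabet.
codon_enumeration <- function() {
  bases <- c("T", "C", "A", "G")
  as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
}

# NCBI translation strings in the enumeration order above; '*' = stop.
GENETIC_CODE_STRINGS <- c(
  "1" = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "2" = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
  "5" = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG"
)

#' Genetic code with synonymous-family partition
#'
#' Builds the codon-to-amino-acid map for an NCBI translation table and
#' partitions the 64 codons into synonymous families by translation
#' product; stop codons form their own family. Table 5, the invertebrate
#' mitochondrial code, is the default: relative to the standard code it
#' reassigns AGA/AGG to serine (an 8-codon Ser family), ATA to methionine
#' and TGA to tryptophan.
#'
#' @param table_id NCBI translation table id: 1 (standard), 2 (vertebrate
#'   mitochondrial) or 5 (invertebrate mitochondrial, default).
#' @return A `genetic_code` object: list with `table_id`, `codon_to_aa`
#'   (named character vector, DNA codons, stop = `"*"`), and `families`
#'   (named list of codon vectors, one per product; the stop family is
#'   named `"*"`).
#' @export
genetic_code <- function(table_id = 5) {
  id <- as.character(table_id)
  if (!id %in% names(GENETIC_CODE_STRINGS)) {
    stop("unknown translation table ", table_id, "; available: ",
         paste(names(GENETIC_CODE_STRINGS), collapse = ", "), call. = FALSE)
  }
  codons <- codon_enumeration()
  aa <- strsplit(GENETIC_CODE_STRINGS[[id]], "")[[1]]
  map <- setNames(aa, codons)
  families <- split(codons, aa)
  structure(list(table_id = as.integer(table_id),
                 codon_to_aa = map,
                 families = families),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> transl_table %d: %d synonymous families (stops: %s)\n",
              x$table_id, length(x$families),
              paste(x$families[["*"]], collapse = ", ")))
  invisible(x)
}

#' Translate a coding sequence
#'
#' @param cds DNA string, length divisible by 3, coding strand.
#' @param code A [genetic_code()] (default table 5).
#' @param internal_stop `"error"` (default) to fail on a stop codon before
#'   the final position, or `"mask"` to emit `X` for it.
#' @return Amino-acid string; a terminal stop codon is rendered as `*`.
#' @export
translate_cds <- function(cds, code = genetic_code(5),
                          internal_stop = c("error", "mask")) {
  internal_stop <- match.arg(internal_stop)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length ", n, " not divisible by 3",
                        call. = FALSE)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"  # ambiguous bases
  stops <- which(aa == "*")
  internal <- stops[stops < length(aa)]
  if (length(internal)) {
    if (internal_stop == "error") {
      stop("internal stop codon at codon position ", internal[1],
           " (nt ", (internal[1] - 1) * 3 + 1, ")", call. = FALSE)
    }
    aa[internal] <- "X"
  }
  paste(aa, collapse = "")
}
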