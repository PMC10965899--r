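# Codon usage: CDS extraction, start/stop typing, codon counting, and
# relative synonymous codon usage (RSCU).

#' Extract a CDS on its coding strand
#'
#' Returns the residues of a protein-coding feature read 5' to 3' on its
#' coding strand: the majority-strand slice for `+` features (wrap-aware),
#' reverse-complemented for `-` features.
#'
#' @param seq A `circular_seq`.
#' @param feature A PCG feature row (fields `start`, `stop`, `strand`).
#' @return Coding-strand nucleotide string.
#' @export
extract_cds <- function(seq, feature) {
  s <- circ_substr(seq, feature$start, feature$stop)
  if (feature$strand == "-") s <- revcomp(s)
  if (nchar(s) < 6L) stop("CDS shorter than 6 nt", call. = FALSE)
  s
}

#' Type the start and stop codon of a CDS
#'
#' @param cds Coding-strand nucleotide string, length >= 6. A length not
#'   divisible by 3 is flagged as an incomplete terminator, not an error.
#' @return A list with `start`, `stop` (DNA triplets; for an incomplete
#'   terminator, `stop` is the trailing remainder), and `complete`
#'   (`TRUE` iff length divisible by 3).
#' @export
type_start_stop <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6L) stop("CDS shorter than 6 nt", call. = FALSE)
  rem <- n %% 3L
  list(
    start = substr(cds, 1L, 3L),
    stop = if (rem == 0L) substr(cds, n - 2L, n) else
      substr(cds, n - rem + 1L, n),
    complete = rem == 0L
  )
}

#' Start/stop codon report for all PCGs of an annotation
#'
#' @param seq A `circular_seq`.
#' @param ann A `mito_annotation`.
#' @param check_atn Warn when a start codon is outside the canonical
#'   mitochondrial ATN set (ATT/ATG/ATA/ATC)?
#' @return data.frame with columns `gene`, `start_codon`, `stop_codon`,
#'   `complete`.
#' @export
start_stop_report <- function(seq, ann, check_atn = TRUE) {
  f <- ann$features[ann$features$category == "PCG", , drop = FALSE]
  rows <- lapply(seq_len(nrow(f)), function(i) {
    ts <- type_start_stop(extract_cds(seq, f[i, ]))
    data.frame(gene = f$name[i], start_codon = ts$start,
               stop_codon = ts$stop, complete = ts$complete,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (check_atn) {
    bad <- out$gene[!out$start_codon %in% c("ATT", "ATG", "ATA", "ATC")]
    if (length(bad)) {
      warning("non-ATN start codon in: ", paste(bad, collapse = ", "),
              call. = FALSE)
    }
  }
  out
}

#' Count codons across a set of CDS
#'
#' Tallies every in-frame triplet of each CDS. The initiation codon is
#' excluded from the counts when `exclude_start` (the default); the
#' terminal codon, when it is a stop under `code`, is tallied into the
#' stop family (`stop_policy = "separate"`, default) or dropped
#' (`"exclude"`). `n_analyzed` excludes both initiation and termination
#' codons under either policy. Trailing incomplete triplets (abbreviated
#' terminators) are skipped.
#'
#' @param cds_list Character vector/list of coding-strand CDS (length >= 6
#'   each).
#' @param code A [genetic_code()], used to recognize stop codons.
#' @param exclude_start Drop each CDS's first codon from the counts?
#' @param stop_policy `"separate"` or `"exclude"`.
#' @return A `codon_usage` object: list with `counts` (named integer
#'   vector over the 64 codons, DNA alphabet), `n_analyzed`, `n_ambiguous`.
#' @export
count_codons <- function(cds_list, code = genetic_code(5),
                         exclude_start = TRUE,
                         stop_policy = c("separate", "exclude")) {
  stop_policy <- match.arg(stop_policy)
  codons64 <- codon_enumeration()
  counts <- setNames(integer(64), codons64)
  n_ambiguous <- 0L
  for (cds in cds_list) {
    cds <- toupper(cds)
    n <- nchar(cds)
    if (n < 6L) stop("CDS shorter than 6 nt", call. = FALSE)
    n_full <- n %/% 3L
    codons <- substring(cds, seq(1L, by = 3L, length.out = n_full),
                        seq(3L, by = 3L, length.out = n_full))
    if (exclude_start) codons <- codons[-1L]
    last <- codons[length(codons)]
    terminal_stop <- code$codon_to_aa[last] %in% "*" && !is.na(last)
    if (terminal_stop && stop_policy == "exclude") {
      codons <- codons[-length(codons)]
    }
    ambiguous <- !codons %in% codons64
    if (any(ambiguous)) {
      n_ambiguous <- n_ambiguous + sum(ambiguous)
      warning(sum(ambiguous), " ambiguous (non-ACGT) codon(s) skipped",
              call. = FALSE)
      codons <- codons[!ambiguous]
    }
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  is_stop <- unname(code$codon_to_aa[codons64] == "*")
  structure(list(
    counts = counts,
    n_analyzed = sum(counts[!is_stop]),
    n_ambiguous = n_ambiguous,
    table_id = code$table_id
  ), class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d codons analyzed (transl_table %d), %d stop-codon tallies\n",
              x$n_analyzed, x$table_id, sum(x$counts) - x$n_analyzed))
  invisible(x)
}

#' Codon usage table from a named count vector
#'
#' Wraps externally obtained 64-codon counts (e.g. a published codon-usage
#' table) as a `codon_usage` object for [rscu()]. Codon names may use the
#' RNA (U) or DNA (T) alphabet.
#'
#' @param counts Named numeric vector; missing codons count 0.
#' @param code A [genetic_code()] used to classify stops for `n_analyzed`.
#' @return A `codon_usage` object.
#' @export
codon_usage_from_counts <- function(counts, code = genetic_code(5)) {
  codons64 <- codon_enumeration()
  nm <- chartr("Uu", "Tt", toupper(names(counts)))
  if (!all(nm %in% codons64)) {
    stop("unknown codon name(s): ",
         paste(names(counts)[!nm %in% codons64], collapse = ", "),
         call. = FALSE)
  }
  full <- setNames(integer(64), codons64)
  full[nm] <- as.integer(counts)
  is_stop <- unname(code$codon_to_aa[codons64] == "*")
  structure(list(counts = full, n_analyzed = sum(full[!is_stop]),
                 n_ambiguous = 0L, table_id = code$table_id),
            class = "codon_usage")
}

#' Relative synonymous codon usage
#'
#' For a codon `c` in synonymous family `F`,
#' `RSCU(c) = count(c) * |F| / sum(count over F)`: the observed count
#' relative to the mean of its family, 1.0 meaning unbiased usage.
#' Families follow the genetic code's translation products, with stop
#' codons as their own family; a family with zero total has undefined
#' (`NA`) RSCU.
#'
#' @param usage A `codon_usage` (from [count_codons()] or
#'   [codon_usage_from_counts()]).
#' @param code A [genetic_code()]; defaults to the table the counts were
#'   made with.
#' @return data.frame with one row per codon: `codon` (RNA alphabet, as
#'   conventionally printed), `aa`, `count`, `rscu` (unrounded), `rscu_2dp`.
#' @export
rscu <- function(usage, code = genetic_code(usage$table_id)) {
  counts <- usage$counts
  codons <- names(counts)
  aa <- unname(code$codon_to_aa[codons])
  vals <- rep(NA_real_, length(codons))
  for (fam in code$families) {
    tot <- sum(counts[fam])
    if (tot > 0) {
      vals[match(fam, codons)] <- counts[fam] * length(fam) / tot
    }
  }
  data.frame(
    codon = chartr("T", "U", codons),
    aa = aa,
    count = as.integer(counts),
    rscu = vals,
    rscu_2dp = round(vals, 2),
    stringsAsFactors = FALSE
  )
}

#' Export an RSCU table as TSV
#'
#' Writes the codon/amino-acid/count/RSCU table (RSCU at 2 decimal
#' places, the conventional reporting precision).
#'
#' @param rscu_table Output of [rscu()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rscu_table <- function(rscu_table, path) {
  out <- rscu_table[, c("codon", "aa", "count", "rscu_2dp")]
  names(out)[4] <- "rscu"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
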