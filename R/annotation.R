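# Annotation data model: the in-memory twin of a mitogenome feature table.
#
# A mito_annotation is a list(genome_length, source_id, features) where
# features is a data.frame with columns name, category, strand, start, stop,
# wraps, anticodon, sorted ascending by start. Coordinates are 1-based fully
# inclusive on the majority-strand axis; a feature crossing the origin is
# encoded with start > stop and wraps = TRUE.

FEATURE_CATEGORIES <- c("PCG", "tRNA", "rRNA", "control", "other")

PCG_TOKENS <- c("COI", "COII", "COIII", "CYTB", "ATP6", "ATP8",
                paste0("NADH", 1:6), "NADH4L")

TRNA_TOKENS <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnE", "trnQ",
                 "trnG", "trnH", "trnI", "trnL1", "trnL2", "trnK", "trnM",
                 "trnF", "trnP", "trnS1", "trnS2", "trnT", "trnW", "trnY",
                 "trnV")

RRNA_TOKENS <- c("rrnL", "rrnS")

# Submitter-dialect aliases -> canonical tokens. Keys are matched after
# upper-casing and stripping non-alphanumerics, so "ND5", "nd5" and "ND-5"
# all normalize identically.
GENE_ALIASES <- c(
  ND1 = "NADH1", ND2 = "NADH2", ND3 = "NADH3", ND4 = "NADH4",
  ND4L = "NADH4L", ND5 = "NADH5", ND6 = "NADH6",
  NAD1 = "NADH1", NAD2 = "NADH2", NAD3 = "NADH3", NAD4 = "NADH4",
  NAD4L = "NADH4L", NAD5 = "NADH5", NAD6 = "NADH6",
  COX1 = "COI", COX2 = "COII", COX3 = "COIII",
  CO1 = "COI", CO2 = "COII", CO3 = "COIII",
  COB = "CYTB", CYB = "CYTB", CYTB = "CYTB",
  ATP6 = "ATP6", ATP8 = "ATP8", ATPASE6 = "ATP6", ATPASE8 = "ATP8",
  RRNL = "rrnL", RRNS = "rrnS", "16S" = "rrnL", "12S" = "rrnS",
  "16SRRNA" = "rrnL", "12SRRNA" = "rrnS", LRRNA = "rrnL", SRRNA = "rrnS",
  DLOOP = "DLOOP", CR = "CR", CONTROLREGION = "CR", ATRICHREGION = "CR"
)

# One-letter amino-acid codes for tRNA isotype parsing (trnL1, trnS2, ...).
TRNA_AA <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             E = "Glu", Q = "Gln", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Normalize a gene name to its canonical token
#'
#' Applies a table-driven normalization so that GenBank files from different
#' submitters parse identically: `ND5 -> NADH5`, `COX1 -> COI`,
#' `16S -> rrnL`, `trn-Ser (GCT)` variants to `trnS1`, and so on. Names
#' already canonical pass through unchanged.
#'
#' @param name Character vector of raw gene names.
#' @return Character vector of canonical tokens; names with no known mapping
#'   are returned unchanged (callers decide whether that is an error).
#' @export
normalize_gene_name <- function(name) {
  vapply(name, function(nm) {
    if (nm %in% c(PCG_TOKENS, TRNA_TOKENS, RRNA_TOKENS, "CR", "DLOOP")) {
      return(nm)
    }
    key <- toupper(gsub("[^A-Za-z0-9]", "", nm))
    if (key %in% names(GENE_ALIASES)) return(unname(GENE_ALIASES[key]))
    # tRNA dialects: trnS1, trnS, tRNA-Ser, trn-S ...
    m <- regmatches(nm, regexec("^t[Rr]?[Nn][Aa]?[-_ ]?([A-Za-z]{1,3})([12])?$",
                                nm))[[1]]
    if (length(m) == 3L) {
      aa <- m[2]
      iso <- m[3]
      letter <- if (nchar(aa) == 1L) {
        toupper(aa)
      } else {
        hit <- names(TRNA_AA)[tolower(TRNA_AA) == tolower(aa)]
        if (length(hit) == 1L) hit else NA_character_
      }
      if (!is.na(letter) && letter %in% names(TRNA_AA)) {
        tok <- paste0("trn", letter, iso)
        if (tok %in% TRNA_TOKENS) return(tok)
        if (letter %in% c("L", "S") && iso == "") return(paste0("trn", letter))
      }
    }
    nm
  }, character(1), USE.NAMES = FALSE)
}

# Category implied by a canonical token, or NA if unknown.
category_for_name <- function(name) {
  ifelse(name %in% PCG_TOKENS, "PCG",
  ifelse(name %in% TRNA_TOKENS | grepl("^trn", name), "tRNA",
  ifelse(name %in% RRNA_TOKENS, "rRNA",
  ifelse(name == "CR", "control",
  ifelse(name == "DLOOP", "other", NA_character_)))))
}

empty_features <- function() {
  data.frame(name = character(), category = character(), strand = character(),
             start = integer(), stop = integer(), wraps = logical(),
             anticodon = character(), stringsAsFactors = FALSE)
}

#' Construct a mitogenome annotation
#'
#' Bundles a feature table with the genome length into a validated
#' `mito_annotation`. Features are sorted ascending by start; the wrapping
#' feature (if any) sorts by its start position like any other.
#'
#' @param features data.frame with columns `name`, `category`, `strand`,
#'   `start`, `stop` and optionally `anticodon`. `wraps` is derived
#'   (`start > stop`), never supplied.
#' @param genome_length Circular genome length L in bp.
#' @param source_id Free-text provenance label (e.g. an accession).
#' @return A `mito_annotation` object.
#' @export
mito_annotation <- function(features, genome_length, source_id = "") {
  stopifnot(is.numeric(genome_length), length(genome_length) == 1L,
            genome_length >= 1)
  L <- as.integer(genome_length)
  if (nrow(features) == 0L) {
    features <- empty_features()
  } else {
    if (!all(c("name", "category", "strand", "start", "stop") %in%
             names(features))) {
      stop("features must have columns name, category, strand, start, stop",
           call. = FALSE)
    }
    if (is.null(features$anticodon)) features$anticodon <- NA_character_
    features$anticodon[!is.na(features$anticodon) &
                         features$anticodon == ""] <- NA_character_
    features <- data.frame(
      name = as.character(features$name),
      category = as.character(features$category),
      strand = as.character(features$strand),
      start = as.integer(features$start),
      stop = as.integer(features$stop),
      wraps = as.integer(features$start) > as.integer(features$stop),
      anticodon = tolower(as.character(features$anticodon)),
      stringsAsFactors = FALSE
    )
  }
  ann <- structure(
    list(genome_length = L,
         source_id = as.character(source_id),
         features = features),
    class = "mito_annotation"
  )
  validate_annotation(ann)
  ann$features <- ann$features[order(ann$features$start,
                                     ann$features$name), , drop = FALSE]
  rownames(ann$features) <- NULL
  ann
}

validate_annotation <- function(ann) {
  f <- ann$features
  L <- ann$genome_length
  if (nrow(f) == 0L) return(invisible(ann))
  if (anyDuplicated(f$name)) {
    stop("duplicate feature names: ",
         paste(unique(f$name[duplicated(f$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(f$start < 1L | f$start > L | f$stop < 1L | f$stop > L)
  if (length(bad)) {
    stop("feature position out of range [1, ", L, "]: ",
         paste(sprintf("%s (%d..%d)", f$name[bad], f$start[bad], f$stop[bad]),
               collapse = ", "),
         call. = FALSE)
  }
  if (!all(f$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (!all(f$category %in% FEATURE_CATEGORIES)) {
    stop("unknown category: ",
         paste(setdiff(f$category, FEATURE_CATEGORIES), collapse = ", "),
         call. = FALSE)
  }
  implied <- category_for_name(f$name)
  clash <- which(!is.na(implied) & implied != f$category)
  if (length(clash)) {
    stop("category inconsistent with name for: ",
         paste(sprintf("%s (%s, expected %s)", f$name[clash],
                       f$category[clash], implied[clash]), collapse = ", "),
         call. = FALSE)
  }
  invisible(ann)
}

#' Check for a complete animal mitogenome gene set
#'
#' A complete animal mitogenome carries exactly 13 protein-coding genes,
#' 22 tRNAs and 2 rRNAs.
#'
#' @param ann A `mito_annotation`.
#' @return Logical scalar; attributes `missing` and `extra` list deviations
#'   from the canonical 37-gene set.
#' @export
is_complete_mitogenome <- function(ann) {
  canon <- c(PCG_TOKENS, TRNA_TOKENS, RRNA_TOKENS)
  have <- ann$features$name
  missing <- setdiff(canon, have)
  extra <- setdiff(have[ann$features$category %in% c("PCG", "tRNA", "rRNA")],
                   canon)
  structure(length(missing) == 0L && length(extra) == 0L,
            missing = missing, extra = extra)
}

#' @export
print.mito_annotation <- function(x, ...) {
  f <- x$features
  cat(sprintf("<mito_annotation> %s%d features on a %d bp circle\n",
              if (nzchar(x$source_id)) paste0(x$source_id, ": ") else "",
              nrow(f), x$genome_length))
  tab <- table(factor(f$category, levels = FEATURE_CATEGORIES))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a feature table (tab- or comma-separated)
#'
#' Reads the plain feature-table dialect with header columns `name`,
#' `category`, `strand`, `start`, `stop` and optional `anticodon`; extra
#' columns are ignored. Wrapping is inferred from `start > stop`.
#'
#' @param path Path to the table.
#' @param genome_length Circular genome length L in bp.
#' @param source_id Optional provenance label; defaults to the file name.
#' @return A `mito_annotation`.
#' @export
read_feature_table <- function(path, genome_length,
                               source_id = basename(path)) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("name", "category", "strand", "start", "stop")
  if (!all(need %in% names(tab))) {
    stop("feature table ", path, " must have header columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  mito_annotation(tab, genome_length, source_id = source_id)
}

#' Write a feature table
#'
#' Writes the annotation in the same dialect [read_feature_table()] reads,
#' so that a read of the written file reproduces the annotation exactly.
#'
#' @param ann A `mito_annotation`.
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ann, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- ann$features[, c("name", "category", "strand", "start", "stop",
                          "anticodon")]
  out$anticodon[is.na(out$anticodon)] <- ""
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
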