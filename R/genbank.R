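# Minimal GenBank flat-file support for annotated mitogenomes.
#
# Covers the subset of the format mitogenome submissions actually use:
# LOCUS topology, gene/CDS/tRNA/rRNA/D-loop/misc_feature keys, simple and
# complement() locations, join() across the origin, /gene //product //note
# qualifiers, and the ORIGIN sequence block. Locations such as
# join(16381..16407,1..41) on a circular record map to a wrapping feature
# (start > stop).

parse_genbank_location <- function(loc, L) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    body <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(body, ",")[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
    # Origin-spanning join: last bases of the circle followed by the first.
    if (length(rng) == 2L && rng[[1]][2] == L && rng[[2]][1] == 1L) {
      return(list(start = rng[[1]][1], stop = rng[[2]][2], strand = strand))
    }
    stop("unsupported join() location: ", loc, call. = FALSE)
  }
  ends <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  if (length(ends) == 1L) ends <- c(ends, ends)
  list(start = ends[1], stop = ends[2], strand = strand)
}

#' Read a GenBank flat file
#'
#' Parses an annotated mitogenome record: features become a
#' [mito_annotation()] (CDS to PCG, tRNA to tRNA, rRNA to rRNA, and
#' D-loop/misc_feature entries naming the control region to the control
#' category), and the ORIGIN block, when present, becomes a
#' [circular_sequence()]. Gene names are normalized via
#' [normalize_gene_name()]; names with no known mapping keep category
#' `other` with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @param allow_linear Parse records whose LOCUS line does not say
#'   `circular`? Default `FALSE` (error), because every coordinate
#'   computation in this package assumes a circular topology.
#' @return A list with elements `sequence` (a `circular_seq`, or `NULL` when
#'   the record has no ORIGIN block) and `annotation` (a `mito_annotation`).
#' @export
read_genbank <- function(path, allow_linear = FALSE) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file: ", path,
                                call. = FALSE)
  locus <- locus[1]
  if (!grepl("circular", locus, ignore.case = TRUE) && !allow_linear) {
    stop("GenBank record is not circular; pass allow_linear = TRUE to ",
         "override", call. = FALSE)
  }
  lm <- regmatches(locus, regexec("\\s(\\d+)\\s+bp", locus))[[1]]
  if (length(lm) != 2L) stop("cannot read genome length from LOCUS line",
                             call. = FALSE)
  L <- as.integer(lm[2])
  accession <- sub("^LOCUS\\s+(\\S+).*$", "\\1", locus)

  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  terminator <- grep("^//", lines)
  feat_end <- min(c(origin, terminator, length(lines) + 1L))
  feats <- if (length(feat_start)) {
    lines[(feat_start[1] + 1L):(feat_end - 1L)]
  } else {
    character()
  }

  # Split the feature block into (key, location, qualifiers) entries; a new
  # entry starts at column 6 with a non-blank key.
  entries <- list()
  cur <- NULL
  for (ln in feats) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- sub("^ {5}\\S+\\s+", "", ln)
      cur <- list(key = key, loc = loc, quals = character())
    } else if (!is.null(cur)) {
      txt <- sub("^\\s+", "", ln)
      if (grepl("^/", txt)) {
        cur$quals <- c(cur$quals, txt)
      } else if (length(cur$quals) == 0L) {
        cur$loc <- paste0(cur$loc, txt)  # continuation of a long location
      } else {
        cur$quals[length(cur$quals)] <- paste(cur$quals[length(cur$quals)],
                                              txt)
      }
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

  qual_value <- function(quals, name) {
    hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
  }

  rows <- list()
  for (e in entries) {
    if (!e$key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    loc <- parse_genbank_location(e$loc, L)
    raw <- qual_value(e$quals, "gene")
    if (is.na(raw)) raw <- qual_value(e$quals, "product")
    if (is.na(raw)) raw <- qual_value(e$quals, "note")
    if (is.na(raw)) raw <- if (e$key == "D-loop") "DLOOP" else "unnamed"
    name <- normalize_gene_name(raw)
    category <- switch(e$key,
      CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
      `D-loop` = , misc_feature = {
        if (name == "CR" ||
            grepl("control region|A\\+?T[- ]rich", raw, ignore.case = TRUE)) {
          name <- "CR"
          "control"
        } else if (name == "DLOOP" ||
                   grepl("d-?loop", raw, ignore.case = TRUE)) {
          name <- "DLOOP"
          "other"
        } else {
          "other"
        }
      })
    implied <- category_for_name(name)
    if (is.na(implied) && category %in% c("PCG", "tRNA", "rRNA")) {
      warning("unknown gene name '", raw, "'; keeping category 'other'",
              call. = FALSE)
      category <- "other"
    }
    anticodon <- qual_value(e$quals, "anticodon")
    if (is.na(anticodon)) {
      m <- regmatches(name, regexec("^trn([A-Z])[12]?$", name))[[1]]
      anticodon <- NA_character_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, category = category, strand = loc$strand,
      start = loc$start, stop = loc$stop, anticodon = anticodon,
      stringsAsFactors = FALSE)
  }
  features <- if (length(rows)) do.call(rbind, rows) else empty_features()

  sequence <- NULL
  if (length(origin)) {
    seq_lines <- lines[(origin[1] + 1L):(terminator[1] - 1L)]
    res <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    sequence <- circular_sequence(res)
    if (seq_length(sequence) != L) {
      stop("ORIGIN block length ", seq_length(sequence),
           " disagrees with LOCUS length ", L, call. = FALSE)
    }
  }

  list(sequence = sequence,
       annotation = mito_annotation(features, L, source_id = accession))
}

format_genbank_location <- function(start, stop, strand, L) {
  loc <- if (start > stop) {
    sprintf("join(%d..%d,1..%d)", start, L, stop)
  } else {
    sprintf("%d..%d", start, stop)
  }
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}

#' Write a GenBank flat file
#'
#' Emits a circular GenBank record for an annotation plus sequence, using
#' standard feature keys (CDS, tRNA, rRNA, misc_feature) and
#' origin-spanning `join()` locations for wrapping features. A read of the
#' written file reproduces the annotation and sequence.
#'
#' @param seq A `circular_seq`.
#' @param ann A `mito_annotation` on the same circle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(seq, ann, path) {
  L <- seq_length(seq)
  stopifnot(L == ann$genome_length)
  name <- if (nzchar(ann$source_id)) ann$source_id else "mitogenome"
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular INV 01-JAN-2026",
            gsub("\\s", "_", name), L),
    sprintf("DEFINITION  %s, complete circular mitochondrial genome.", name),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    "                     /organism=\"synthetic construct\"")
  for (i in seq_len(nrow(ann$features))) {
    f <- ann$features[i, ]
    key <- switch(f$category, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control = "misc_feature", other = "misc_feature")
    loc <- format_genbank_location(f$start, f$stop, f$strand, L)
    out <- c(out, sprintf("     %-15s %s", key, loc),
             sprintf("                     /gene=\"%s\"", f$name))
    if (f$category == "control") {
      out <- c(out, "                     /note=\"control region\"")
    }
    if (f$name == "DLOOP") {
      out <- c(out, "                     /note=\"D-loop\"")
    }
    if (!is.na(f$anticodon)) {
      out <- c(out, sprintf("                     /anticodon=\"%s\"",
                            f$anticodon))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(unclass(seq)[[1]])
  starts <- seq(1L, L, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a single-record FASTA file as a circular sequence
#' @param path Path to a FASTA file with one record.
#' @return A `circular_seq`.
#' @export
read_fasta_circular <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop("expected exactly one FASTA record", call. = FALSE)
  circular_sequence(as.character(x[[1]]))
}

#' Write a circular sequence as FASTA
#' @param seq A `circular_seq`.
#' @param path Output path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
write_fasta_circular <- function(seq, path, name = "mitogenome") {
  x <- Biostrings::DNAStringSet(setNames(unclass(seq)[[1]], name))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
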