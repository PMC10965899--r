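# Control-region mining: tandem repeats, microsatellites, homopolymer
# stretches, replication-origin motifs, and stem-loop (inverted repeat)
# candidates. All finders are deterministic; positions are 1-based within
# the region.

repeat_hits_frame <- function() {
  data.frame(start = integer(), unit_length = integer(),
             copy_number = numeric(), unit_sequence = character(),
             identity = numeric(), stringsAsFactors = FALSE)
}

#' Find maximal tandem repeat arrays
#'
#' Deterministic search for tandem arrays: a unit of `min_unit` to
#' `max_unit` bp repeated at least `min_copies` times in direct succession
#' (the final copy may be fractional). Arrays are maximal in both
#' directions, reported longest-unit-first; reports of the same array at
#' multiple phases are collapsed to the leftmost phase, and arrays nested
#' inside an already-reported span of a longer unit are dropped.
#' `min_identity < 1` lets the array extension run through isolated
#' mismatches while the running identity stays at or above the threshold
#' (the array still ends on a match).
#'
#' @param region Nucleotide string (e.g. the control region).
#' @param min_unit,max_unit Unit length bounds in bp.
#' @param min_copies Minimum copy number (>= 2).
#' @param min_identity Minimum fraction of matching positions in the
#'   repeated extension; 1.0 (default) = perfect arrays only.
#' @return data.frame of repeat hits: `start`, `unit_length`,
#'   `copy_number`, `unit_sequence`, `identity`.
#' @export
find_tandem_repeats <- function(region, min_unit = 6L, max_unit = 300L,
                                min_copies = 2.0, min_identity = 1.0) {
  if (min_unit > max_unit) stop("min_unit > max_unit", call. = FALSE)
  stopifnot(min_copies >= 2, min_identity > 0, min_identity <= 1)
  region <- toupper(region)
  n <- nchar(region)
  if (n < 2L * min_unit) {
    stop("region shorter than two units of min_unit", call. = FALSE)
  }
  chars <- strsplit(region, "")[[1]]
  cand <- list()
  for (u in seq(min(max_unit, n %/% 2L), min_unit)) {
    # match[t] is TRUE when position t repeats the base one unit earlier
    match_u <- c(rep(FALSE, u), chars[(u + 1L):n] == chars[1:(n - u)])
    s <- 1L
    while (s <= n - 2L * u + 1L) {
      # leftmost phase only: the array must not extend to the left
      if (s > 1L && chars[s - 1L] == chars[s - 1L + u]) {
        s <- s + 1L
        next
      }
      # extend to the right from s + u while identity holds
      t <- s + u
      mism <- 0L
      last_ok <- s + u - 1L  # end of a valid (possibly fractional) array
      while (t <= n) {
        if (!match_u[t]) mism <- mism + 1L
        ext_len <- t - (s + u) + 1L
        if ((ext_len - mism) / ext_len < min_identity) break
        if (match_u[t]) last_ok <- t
        t <- t + 1L
      }
      ext <- last_ok - (s + u) + 1L
      span <- u + max(ext, 0L)
      copies <- span / u
      if (copies >= min_copies) {
        ext_pos <- if (ext > 0L) match_u[(s + u):last_ok] else logical()
        ident <- if (length(ext_pos)) mean(ext_pos) else 1
        cand[[length(cand) + 1L]] <- data.frame(
          start = s, unit_length = u, copy_number = copies,
          unit_sequence = substr(region, s, s + u - 1L),
          identity = ident, end = s + span - 1L,
          stringsAsFactors = FALSE)
      }
      # always advance by one: an overlapping array in a different phase
      # can reach beyond this span; the leftmost-phase check above keeps
      # reports unique
      s <- s + 1L
    }
  }
  if (length(cand) == 0L) return(repeat_hits_frame())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$unit_length, cand$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1L]) {
    prior <- which(keep[seq_len(i - 1L)])
    nested <- any(cand$start[prior] <= cand$start[i] &
                    cand$end[prior] >= cand$end[i])
    if (nested) keep[i] <- FALSE
  }
  out <- cand[keep, c("start", "unit_length", "copy_number",
                      "unit_sequence", "identity")]
  rownames(out) <- NULL
  out
}

#' Find perfect microsatellite runs of a fixed unit
#'
#' Maximal perfect `(unit)n` runs with `n >= min_repeats`; only whole-unit
#' copies count.
#'
#' @param region Nucleotide string.
#' @param unit Repeat unit (default `"TA"`).
#' @param min_repeats Minimum whole copies.
#' @return data.frame of repeat hits (as [find_tandem_repeats()]).
#' @export
find_microsatellites <- function(region, unit = "TA", min_repeats = 5L) {
  if (nchar(unit) < 1L) stop("unit must be non-empty", call. = FALSE)
  region <- toupper(region)
  unit <- toupper(unit)
  pat <- sprintf("(?:%s){%d,}", unit, min_repeats)
  m <- gregexpr(pat, region, perl = TRUE)[[1]]
  if (m[1] == -1L) return(repeat_hits_frame())
  len <- attr(m, "match.length")
  copies <- len %/% nchar(unit)
  data.frame(start = as.integer(m), unit_length = nchar(unit),
             copy_number = as.numeric(copies),
             unit_sequence = unit, identity = 1,
             stringsAsFactors = FALSE)
}

#' Find homopolymer stretches
#'
#' Maximal single-base runs meeting a per-base length threshold.
#'
#' @param region Nucleotide string.
#' @param base_thresholds Named integer vector, e.g. `c(T = 7, A = 5)`:
#'   minimum run length per base.
#' @return data.frame with columns `base`, `start`, `length`.
#' @export
find_homopolymers <- function(region, base_thresholds = c(T = 7L, A = 5L)) {
  if (any(base_thresholds < 2)) stop("thresholds must be >= 2",
                                     call. = FALSE)
  chars <- strsplit(toupper(region), "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (b in names(base_thresholds)) {
    hit <- which(r$values == b & r$lengths >= base_thresholds[[b]])
    for (i in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        base = b, start = starts[i], length = r$lengths[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(base = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find replication-origin motifs
#'
#' Exact occurrences of candidate origin-of-replication motifs (default:
#' the `ATAGT` motif and its `ATAGA` variant) on the given strand, with an
#' option to scan the reverse complement as well.
#'
#' @param region Nucleotide string.
#' @param motifs Character vector of motifs.
#' @param both_strands Also report reverse-complement occurrences?
#' @return data.frame with columns `motif`, `start`, `strand`.
#' @export
find_ori_motif <- function(region, motifs = c("ATAGT", "ATAGA"),
                           both_strands = FALSE) {
  if (length(motifs) == 0L) stop("motifs must be non-empty", call. = FALSE)
  region <- toupper(region)
  rows <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (mot in toupper(motifs)) {
    for (st in strands) {
      pat <- if (st == "+") mot else revcomp(mot)
      m <- gregexpr(pat, region, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (s in as.integer(m)) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = mot, start = s, strand = st, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(motif = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Find stem-loop (hairpin) candidates
#'
#' Inverted-repeat detection: a 5' arm and a 3' arm separated by a loop of
#' `loop_range` bases, the arms reverse-complementary with at most
#' `max_mismatch` mismatched pairs (arms always end on a matching pair).
#' Hits are ranked by stem length, then fewest mismatches; with
#' `prune = TRUE` (default), hits overlapping an already-accepted better
#' hit are dropped, leaving local maxima.
#'
#' @param region Nucleotide string.
#' @param min_stem Minimum paired stem length in bp.
#' @param max_mismatch Mismatch budget within the stem.
#' @param loop_range Length-2 vector: allowed loop lengths (inclusive).
#' @param prune Prune overlapping hits to local maxima?
#' @return data.frame with columns `stem_start5`, `stem_start3`,
#'   `stem_length`, `loop_length`, `mismatches`.
#' @export
find_stem_loops <- function(region, min_stem = 6L, max_mismatch = 1L,
                            loop_range = c(3L, 30L), prune = TRUE) {
  region <- toupper(region)
  n <- nchar(region)
  if (n < 2L * min_stem + loop_range[1]) {
    return(data.frame(stem_start5 = integer(), stem_start3 = integer(),
                      stem_length = integer(), loop_length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  chars <- strsplit(region, "")[[1]]
  comp <- unname(complement_base[chars])
  rows <- list()
  for (l in seq(loop_range[1], loop_range[2])) {
    # e5 = last base of the 5' arm; 3' arm starts at e5 + l + 1. The
    # innermost pair must match: a mismatch at the loop boundary is the
    # same hairpin with a wider loop, and is reported at that center.
    for (e5 in seq(min_stem, n - l - min_stem)) {
      if (chars[e5] != comp[e5 + l + 1L] || chars[e5] == "N") next
      k <- 0L
      mism <- 0L
      best_k <- 0L
      best_mism <- 0L
      while (e5 - k >= 1L && e5 + l + k + 1L <= n) {
        pair_ok <- chars[e5 - k] == comp[e5 + l + k + 1L] &&
          chars[e5 - k] != "N"
        if (!pair_ok) {
          mism <- mism + 1L
          if (mism > max_mismatch) break
        }
        k <- k + 1L
        if (pair_ok) {
          best_k <- k
          best_mism <- mism
        }
      }
      if (best_k >= min_stem) {
        rows[[length(rows) + 1L]] <- data.frame(
          stem_start5 = e5 - best_k + 1L,
          stem_start3 = e5 + l + 1L,
          stem_length = best_k,
          loop_length = l,
          mismatches = best_mism,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(stem_start5 = integer(), stem_start3 = integer(),
                      stem_length = integer(), loop_length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$stem_length, out$mismatches, out$stem_start5,
                   out$loop_length), , drop = FALSE]
  # drop sub-hairpins: same 3' arm start with a shorter stem, etc.
  if (prune && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    span_start <- out$stem_start5
    span_end <- out$stem_start3 + out$stem_length - 1L
    for (i in seq_len(nrow(out))[-1L]) {
      prior <- which(keep[seq_len(i - 1L)])
      overlaps <- any(span_start[prior] <= span_end[i] &
                        span_end[prior] >= span_start[i])
      if (overlaps) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Mine a control region end to end
#'
#' Runs every control-region finder on one region of an annotated genome
#' and assembles the report: region length and A+T content, tandem
#' repeats, `(TA)n` microsatellites, homopolymer stretches, origin motifs
#' and stem-loop candidates. Positions are reported relative to the region
#' start; `abs_start` columns give the corresponding absolute
#' majority-strand genome positions (wrap-aware).
#'
#' @param seq A `circular_seq`.
#' @param ann A `mito_annotation` containing the region feature.
#' @param region_name Feature to mine (default `"CR"`).
#' @param min_unit,max_unit,min_copies,min_identity Passed to
#'   [find_tandem_repeats()].
#' @param microsat_unit,microsat_min_repeats Passed to
#'   [find_microsatellites()].
#' @param homopolymer_thresholds Passed to [find_homopolymers()].
#' @param ori_motifs Passed to [find_ori_motif()].
#' @param min_stem,max_mismatch,loop_range Passed to [find_stem_loops()].
#' @return A list of class `control_region_report`.
#' @export
control_region_report <- function(seq, ann, region_name = "CR",
                                  min_unit = 6L, max_unit = 300L,
                                  min_copies = 2.0, min_identity = 1.0,
                                  microsat_unit = "TA",
                                  microsat_min_repeats = 5L,
                                  homopolymer_thresholds = c(T = 7L, A = 5L),
                                  ori_motifs = c("ATAGT", "ATAGA"),
                                  min_stem = 6L, max_mismatch = 1L,
                                  loop_range = c(3L, 30L)) {
  f <- ann$features[ann$features$name == region_name, , drop = FALSE]
  if (nrow(f) != 1L) stop("region feature '", region_name,
                          "' not found in annotation", call. = FALSE)
  region <- feature_residues(seq, f[1, ])
  L <- ann$genome_length
  abs_pos <- function(rel) wrap_pos(f$start[1] + rel - 1L, L)
  add_abs <- function(df, col = "start") {
    if (nrow(df)) df$abs_start <- abs_pos(df[[col]])
    df
  }
  counts <- count_bases(region)
  rep_hits <- find_tandem_repeats(region, min_unit, max_unit, min_copies,
                                  min_identity)
  structure(list(
    region_name = region_name,
    region_length = nchar(region),
    pct_AT = 100 * (counts[["A"]] + counts[["T"]]) / sum(counts),
    tandem_repeats = add_abs(rep_hits),
    microsatellites = add_abs(
      find_microsatellites(region, microsat_unit, microsat_min_repeats)),
    homopolymers = add_abs(
      find_homopolymers(region, homopolymer_thresholds)),
    ori_motifs = add_abs(find_ori_motif(region, ori_motifs)),
    stem_loops = add_abs(
      find_stem_loops(region, min_stem, max_mismatch, loop_range),
      col = "stem_start5")
  ), class = "control_region_report")
}

#' @export
print.control_region_report <- function(x, ...) {
  cat(sprintf(
    "<control_region_report> %s: %d bp, %.1f%% A+T\n  %d tandem repeat(s), %d microsatellite run(s), %d homopolymer(s), %d origin motif(s), %d stem-loop(s)\n",
    x$region_name, x$region_length, x$pct_AT, nrow(x$tandem_repeats),
    nrow(x$microsatellites), nrow(x$homopolymers), nrow(x$ori_motifs),
    nrow(x$stem_loops)))
  invisible(x)
}

#' Write a control-region report as JSON
#' @param report A `control_region_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_control_region_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
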