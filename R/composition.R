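# Base composition and strand-asymmetry (AT/GC skew) statistics, per
# feature class and genome-wide.

#' AT skew
#'
#' `(A - T) / (A + T)`, computable from raw counts or from printed
#' percentages (the ratio is scale-free).
#'
#' @param a,t Counts or percentages of A and T.
#' @return Dimensionless skew in `[-1, 1]`.
#' @examples
#' at_skew(41.4, 40.5)  # 0.011 at 3 dp
#' @export
at_skew <- function(a, t) {
  if (any(a + t <= 0)) stop("AT skew undefined: A + T must be > 0",
                            call. = FALSE)
  (a - t) / (a + t)
}

#' GC skew
#'
#' `(G - C) / (G + C)`, from counts or percentages.
#'
#' @param g,c Counts or percentages of G and C.
#' @return Dimensionless skew in `[-1, 1]`.
#' @examples
#' gc_skew(7.5, 10.6)  # -0.171 at 3 dp
#' @export
gc_skew <- function(g, c) {
  if (any(g + c <= 0)) stop("GC skew undefined: G + C must be > 0",
                            call. = FALSE)
  (g - c) / (g + c)
}

count_bases <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  counts <- table(factor(chars, levels = c("A", "C", "G", "T", "N")))
  as.integer(counts)[c(1, 4, 3, 2)] |>
    setNames(c("A", "T", "G", "C"))
}

profile_from_counts <- function(counts, class_label) {
  n <- sum(counts)
  pct <- 100 * counts / n
  structure(list(
    class_label = class_label,
    n_bases = n,
    counts = counts,
    pct_A = unname(pct["A"]), pct_T = unname(pct["T"]),
    pct_G = unname(pct["G"]), pct_C = unname(pct["C"]),
    pct_AT = unname(pct["A"] + pct["T"]),
    at_skew = if (counts[["A"]] + counts[["T"]] > 0) {
      at_skew(counts[["A"]], counts[["T"]])
    } else {
      NA_real_
    },
    gc_skew = if (counts[["G"]] + counts[["C"]] > 0) {
      gc_skew(counts[["G"]], counts[["C"]])
    } else {
      NA_real_
    }
  ), class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "<composition_profile> %s: %d bp | A %.1f T %.1f G %.1f C %.1f | AT%% %.1f | AT skew %.3f GC skew %.3f\n",
    x$class_label, x$n_bases, x$pct_A, x$pct_T, x$pct_G, x$pct_C,
    x$pct_AT, x$at_skew, x$gc_skew))
  invisible(x)
}

# Coding-strand residues of one feature.
feature_residues <- function(seq, feature) {
  s <- circ_substr(seq, feature$start, feature$stop)
  if (feature$strand == "-") revcomp(s) else s
}

#' Base composition and skews of a feature class
#'
#' Concatenates every member feature's residues read on its coding strand
#' (reverse complement for minority-strand features), counts bases, and
#' derives percentages and AT/GC skews. `class_label = "genome"` counts the
#' full majority strand instead. Overlapping features contribute their full
#' spans, so bases shared by two features of the same class are counted
#' twice — classes are reported independently.
#'
#' @param seq A `circular_seq`.
#' @param ann A `mito_annotation`.
#' @param class_label One of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`,
#'   `"other"`, or `"genome"`.
#' @return A `composition_profile`.
#' @export
class_composition <- function(seq, ann, class_label) {
  stopifnot(seq_length(seq) == ann$genome_length)
  if (class_label == "genome") {
    return(profile_from_counts(count_bases(unclass(seq)[[1]]), "genome"))
  }
  f <- ann$features[ann$features$category == class_label, , drop = FALSE]
  if (nrow(f) == 0L) stop("no features in class '", class_label, "'",
                          call. = FALSE)
  residues <- paste(vapply(seq_len(nrow(f)), function(i) {
    feature_residues(seq, f[i, ])
  }, character(1)), collapse = "")
  profile_from_counts(count_bases(residues), class_label)
}

#' Full composition table across feature classes
#'
#' Computes [class_composition()] for every class present in the
#' annotation plus the whole genome, shaped like a per-class base
#' composition report (percentages at 1 decimal place, skews at 3).
#'
#' @param seq A `circular_seq`.
#' @param ann A `mito_annotation`.
#' @param classes Classes to report (default: those present, plus genome).
#' @param digits Use `NULL` to suppress report rounding.
#' @return data.frame with one row per class.
#' @export
composition_table <- function(seq, ann,
                              classes = intersect(
                                c("PCG", "tRNA", "rRNA", "control"),
                                unique(ann$features$category)),
                              digits = TRUE) {
  profs <- lapply(c(classes, "genome"), function(cl) {
    p <- class_composition(seq, ann, cl)
    data.frame(class = p$class_label, size_bp = p$n_bases,
               pct_A = p$pct_A, pct_T = p$pct_T, pct_G = p$pct_G,
               pct_C = p$pct_C, pct_AT = p$pct_AT,
               at_skew = p$at_skew, gc_skew = p$gc_skew,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, profs)
  if (isTRUE(digits)) {
    pc <- c("pct_A", "pct_T", "pct_G", "pct_C", "pct_AT")
    out[pc] <- lapply(out[pc], round, 1)
    out[c("at_skew", "gc_skew")] <- lapply(out[c("at_skew", "gc_skew")],
                                           round, 3)
  }
  out
}

#' Skews recomputed from printed composition percentages
#'
#' Evaluates AT and GC skew directly from a table of per-class base
#' percentages (columns `class`, `pct_A`, `pct_T`, `pct_G`, `pct_C`), the
#' path used when only a published composition table — not the sequence —
#' is available. Percentages rounded to 1 decimal place propagate an
#' uncertainty of up to about 0.002 into a skew near zero denominator 80;
#' agreement with skews computed from raw counts is therefore expected only
#' within that tolerance.
#'
#' @param percent data.frame with columns `class`, `pct_A`, `pct_T`,
#'   `pct_G`, `pct_C`.
#' @param digits Round skews to 3 decimal places (default) or `NULL`.
#' @return data.frame with columns `class`, `at_skew`, `gc_skew`.
#' @export
skews_from_percentages <- function(percent, digits = 3) {
  out <- data.frame(
    class = percent$class,
    at_skew = at_skew(percent$pct_A, percent$pct_T),
    gc_skew = gc_skew(percent$pct_G, percent$pct_C),
    stringsAsFactors = FALSE
  )
  if (!is.null(digits)) {
    out$at_skew <- round(out$at_skew, digits)
    out$gc_skew <- round(out$gc_skew, digits)
  }
  out
}
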