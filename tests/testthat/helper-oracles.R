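# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own arithmetic: they walk the
# circle position by position, compare substrings directly, or enumerate
# exhaustively.

# Signed gap between two features by literally walking forward around the
# circle from the base after prev's stop until reaching next's start.
oracle_junction_gap <- function(prev_stop, next_start, L) {
  steps <- 0L
  p <- prev_stop
  repeat {
    p <- p + 1L
    if (p > L) p <- 1L
    if (p == next_start) break
    steps <- steps + 1L
    if (steps > L) stop("walked the whole circle")
  }
  d <- steps
  if (d > L / 2) d - L else d
}

# Feature length by walking start -> stop inclusively.
oracle_feature_length <- function(start, stop, L) {
  n <- 1L
  p <- start
  while (p != stop) {
    p <- p + 1L
    if (p > L) p <- 1L
    n <- n + 1L
  }
  n
}

# Per-position base tally of a feature class, complementing minus-strand
# positions one by one.
oracle_class_counts <- function(seq_str, features, L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  tally <- c(A = 0L, T = 0L, G = 0L, C = 0L)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    pos <- f$start
    repeat {
      b <- substr(seq_str, pos, pos)
      if (f$strand == "-") b <- comp[[b]]
      if (b %in% names(tally)) tally[[b]] <- tally[[b]] + 1L
      if (pos == f$stop) break
      pos <- pos + 1L
      if (pos > L) pos <- 1L
    }
  }
  tally
}

# Sliding-triplet codon tally: first codon dropped, terminal stop kept
# aside, everything counted into an environment.
oracle_codon_counts <- function(cds_list, stop_codons = c("TAA", "TAG")) {
  counts <- new.env()
  for (cds in cds_list) {
    i <- 4L
    while (i + 2L <= nchar(cds)) {
      cod <- substr(cds, i, i + 2L)
      key <- cod
      prev <- if (is.null(counts[[key]])) 0L else counts[[key]]
      counts[[key]] <- prev + 1L
      i <- i + 3L
    }
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

# Breakpoint distance by exhaustively matching each adjacency of `a`
# against every adjacency of `b` in both reading directions.
oracle_breakpoint_distance <- function(tokens_a, tokens_b) {
  flip <- function(t) {
    ifelse(startsWith(t, "-"), sub("^-", "+", t),
           paste0("-", sub("^\\+", "", t)))
  }
  adj <- function(tokens) {
    n <- length(tokens)
    lapply(seq_len(n), function(i) c(tokens[i], tokens[i %% n + 1L]))
  }
  aa <- adj(tokens_a)
  bb <- adj(tokens_b)
  missing <- 0L
  for (p in aa) {
    found <- FALSE
    for (q in bb) {
      if (identical(p, q) ||
          identical(p, c(flip(q[2]), flip(q[1])))) {
        found <- TRUE
        break
      }
    }
    if (!found) missing <- missing + 1L
  }
  missing
}

# Quadratic exact tandem-array scanner: every (start, unit) pair tried by
# direct substring comparison; same reporting semantics (leftmost phase,
# maximal span, longest-unit-first, nested spans dropped).
oracle_tandem_repeats <- function(region, min_unit = 6L, max_unit = 300L,
                                  min_copies = 2.0) {
  n <- nchar(region)
  cand <- list()
  for (u in seq(min(max_unit, n %/% 2L), min_unit)) {
    for (s in seq_len(n - 2L * u + 1L)) {
      if (s > 1L && substr(region, s - 1L, s - 1L) ==
          substr(region, s - 1L + u, s - 1L + u)) next
      unit <- substr(region, s, s + u - 1L)
      e <- s + u - 1L
      # whole-unit extensions
      while (e + u <= n && substr(region, e + 1L, e + u) == unit) {
        e <- e + u
      }
      # partial final copy
      k <- 0L
      while (e + k + 1L <= n &&
             substr(region, e + k + 1L, e + k + 1L) ==
             substr(region, s + k, s + k)) {
        k <- k + 1L
      }
      e <- e + k
      copies <- (e - s + 1L) / u
      if (copies >= min_copies) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = s, unit_length = u, copy_number = copies, end = e)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(), unit_length = integer(),
                      copy_number = numeric()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[c("start", "unit_length")]), , drop = FALSE]
  cand <- cand[order(-cand$unit_length, cand$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1L]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(cand$start[prior] <= cand$start[i] &
            cand$end[prior] >= cand$end[i])) keep[i] <- FALSE
  }
  out <- cand[keep, c("start", "unit_length", "copy_number")]
  rownames(out) <- NULL
  out
}

# Random dense circular annotation: features laid head to tail with small
# spacers/overlaps; the telescoping identity holds by construction.
random_annotation <- function(n_features = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(5:60, n_features, replace = TRUE)
  gaps <- sample(-3:20, n_features, replace = TRUE)
  gaps <- pmax(gaps, -(pmin(lens, c(lens[-1], lens[1])) - 2L))
  L <- sum(lens + gaps)
  start <- 1L
  rows <- list()
  for (i in seq_len(n_features)) {
    stop_pos <- start + lens[i] - 1L
    rows[[i]] <- data.frame(
      name = sprintf("F%02d", i), category = "other",
      strand = sample(c("+", "-"), 1L),
      start = ((start - 1L) %% L) + 1L,
      stop = ((stop_pos - 1L) %% L) + 1L,
      stringsAsFactors = FALSE)
    start <- stop_pos + 1L + gaps[i]
  }
  mito_annotation(do.call(rbind, rows), L, source_id = "random")
}

# Random AT-rich region string.
random_region <- function(n, seed = NULL,
                          probs = c(A = 0.42, T = 0.44, G = 0.05,
                                    C = 0.09)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Build a gene_order from a token vector via the file round-trip.
read_order_tokens <- function(tokens) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(tokens, tmp)
  read_gene_order(tmp, label = "tokens")
}
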