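# Gene-order comparison: signed circular permutations over the 37-gene
# mitochondrial alphabet, breakpoint distance, and per-gene classification.

# Ancestral gene-order registries, anchored at the control region. The
# lepidopteran ancestor differs from the insect ancestor exactly by the
# I-Q-M -> M-I-Q block change between the control region and NADH2; the
# rest of the arrangement (including the A-R-N-S1-E-F block between NADH3
# and NADH5) is shared.
ORDER_REGISTRY <- list(
  insect_ancestor = c(
    "+CR", "+trnI", "-trnQ", "+trnM",
    "+NADH2", "+trnW", "-trnC", "-trnY", "+COI", "+trnL2", "+COII",
    "+trnK", "+trnD", "+ATP8", "+ATP6", "+COIII", "+trnG", "+NADH3",
    "+trnA", "+trnR", "+trnN", "+trnS1", "+trnE", "-trnF", "-NADH5",
    "-trnH", "-NADH4", "-NADH4L", "+trnT", "-trnP", "+NADH6", "+CYTB",
    "+trnS2", "-NADH1", "-trnL1", "-rrnL", "-trnV", "-rrnS"),
  lepidoptera_ancestor = c(
    "+CR", "+trnM", "+trnI", "-trnQ",
    "+NADH2", "+trnW", "-trnC", "-trnY", "+COI", "+trnL2", "+COII",
    "+trnK", "+trnD", "+ATP8", "+ATP6", "+COIII", "+trnG", "+NADH3",
    "+trnA", "+trnR", "+trnN", "+trnS1", "+trnE", "-trnF", "-NADH5",
    "-trnH", "-NADH4", "-NADH4L", "+trnT", "-trnP", "+NADH6", "+CYTB",
    "+trnS2", "-NADH1", "-trnL1", "-rrnL", "-trnV", "-rrnS")
)

#' Reference ancestral gene orders
#'
#' Returns a registry gene order: the insect ancestral arrangement or the
#' lepidopteran ancestral arrangement, which carries the derived
#' trnM-trnI-trnQ (MIQ) block between the control region and NADH2 in
#' place of the ancestral trnI-trnQ-trnM. Both registries contain the 37
#' genes plus the control region token, signed by strand and anchored at
#' the control region.
#'
#' @param name `"insect_ancestor"` or `"lepidoptera_ancestor"`.
#' @return A `gene_order`.
#' @export
reference_order <- function(name) {
  if (!name %in% names(ORDER_REGISTRY)) {
    stop("unknown reference order '", name, "'; registry: ",
         paste(names(ORDER_REGISTRY), collapse = ", "), call. = FALSE)
  }
  new_gene_order(ORDER_REGISTRY[[name]], label = name)
}

order_signs <- function(tokens) {
  ifelse(grepl("^-", tokens), -1L, 1L)
}

order_names <- function(tokens) {
  sub("^[+-]", "", tokens)
}

# Canonical signed adjacency set of a circular order. Each adjacency
# (a, b) is orientation-aware: reading the circle in the opposite
# direction gives (-b, -a), which is the same physical adjacency, so the
# canonical form is the lexicographically smaller of the two renderings.
adjacency_set <- function(order) {
  tokens <- order$tokens
  n <- length(tokens)
  nxt <- c(tokens[-1L], tokens[1L])
  vapply(seq_len(n), function(i) {
    a <- tokens[i]
    b <- nxt[i]
    flip <- function(t) {
      if (grepl("^-", t)) sub("^-", "+", t) else paste0("-", sub("^\\+", "", t))
    }
    fwd <- paste(a, b, sep = "|")
    rev <- paste(flip(b), flip(a), sep = "|")
    min(fwd, rev)
  }, character(1))
}

check_same_tokens <- function(a, b) {
  na <- order_names(a$tokens)
  nb <- order_names(b$tokens)
  if (!setequal(na, nb)) {
    stop("gene orders have different token sets; only in first: {",
         paste(setdiff(na, nb), collapse = ", "), "}, only in second: {",
         paste(setdiff(nb, na), collapse = ", "), "}", call. = FALSE)
  }
  invisible(TRUE)
}

#' Breakpoint distance between two signed circular gene orders
#'
#' The number of signed, orientation-aware adjacencies of `a` absent from
#' `b`. Zero iff the two circular orders are equivalent up to rotation
#' (and whole-circle reflection with all signs flipped). The count is
#' symmetric in its arguments because both orders have the same number of
#' adjacencies.
#'
#' @param a,b `gene_order` objects over the same token set.
#' @return Non-negative integer.
#' @export
breakpoint_distance <- function(a, b) {
  check_same_tokens(a, b)
  sum(!adjacency_set(a) %in% adjacency_set(b))
}

#' Classify each gene's status between two orders
#'
#' Per-gene comparison of `a` against reference `b`: a gene is `inverted`
#' when its strand sign differs, `translocated` when its signed left
#' neighbor (the preceding token in circular order) differs,
#' `translocated+inverted` when both, otherwise `kept`.
#'
#' @param a,b `gene_order` objects over the same token set.
#' @return A list of class `order_comparison`: `identical` (logical),
#'   `breakpoint_count`, and `per_gene` (named character vector of
#'   statuses).
#' @export
classify_genes <- function(a, b) {
  check_same_tokens(a, b)
  left_of <- function(order) {
    tokens <- order$tokens
    nm <- order_names(tokens)
    setNames(tokens[c(length(tokens), seq_len(length(tokens) - 1L))], nm)
  }
  la <- left_of(a)
  lb <- left_of(b)
  sa <- setNames(order_signs(a$tokens), order_names(a$tokens))
  sb <- setNames(order_signs(b$tokens), order_names(b$tokens))
  genes <- order_names(a$tokens)
  status <- vapply(genes, function(g) {
    inv <- sa[[g]] != sb[[g]]
    trans <- la[[g]] != lb[[g]]
    if (inv && trans) "translocated+inverted"
    else if (inv) "inverted"
    else if (trans) "translocated"
    else "kept"
  }, character(1))
  bp <- breakpoint_distance(a, b)
  structure(list(
    identical = bp == 0L && all(status == "kept"),
    breakpoint_count = bp,
    per_gene = status
  ), class = "order_comparison")
}

#' @export
print.order_comparison <- function(x, ...) {
  moved <- names(x$per_gene)[x$per_gene != "kept"]
  cat(sprintf("<order_comparison> %s; %d breakpoint(s)%s\n",
              if (x$identical) "identical" else "rearranged",
              x$breakpoint_count,
              if (length(moved)) paste0("; affected: ",
                                        paste(moved, collapse = ", "))
              else ""))
  invisible(x)
}

#' Read a gene order from a one-token-per-line file
#'
#' Lines hold `+`/`-`-prefixed tokens (an unprefixed token is taken as
#' `+`); blank lines and `#` comments are skipped.
#'
#' @param path Input path.
#' @param label Order label; defaults to the file name.
#' @return A `gene_order`.
#' @export
read_gene_order <- function(path, label = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tokens <- ifelse(grepl("^[+-]", lines), lines, paste0("+", lines))
  new_gene_order(tokens, label = label)
}

#' Write a gene order, one token per line
#' @param order A `gene_order`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_order <- function(order, path) {
  writeLines(order$tokens, path)
  invisible(path)
}
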