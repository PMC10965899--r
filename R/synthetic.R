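# Synthetic mitogenome generator: emits an annotated, AT-rich ~16 kb
# circular genome shaped like a lepidopteran mitogenome -- 13 PCGs with
# biased codon usage and fixed start/stop codons, 22 tRNAs, 2 rRNAs, a
# control region with planted repeat/motif/hairpin features, one gene
# spanning the origin, and one planted 7 bp gene overlap -- together with
# an exact ground-truth manifest.

#' Generator specification
#'
#' Bundles every tunable of the synthetic mitogenome. The defaults emulate
#' the L. coffeella study genome: the lepidopteran ancestral gene order,
#' the published per-gene lengths and start/stop codons, codon-usage
#' weights taken from the published 64-codon counts, per-class base
#' composition targets from the published composition table, a 1363 bp
#' control region with two planted tandem arrays (57 and 159 bp units,
#' two copies each), four (TA)n microsatellite runs, five poly-T(7) and
#' five poly-A(5) stretches, one ATAGT replication-origin motif and one
#' stem-loop, a 7 bp ATGATAA overlap between ATP8 and ATP6, and the
#' trnN gene spanning the origin.
#'
#' @param order_template Registry name of the gene-order template.
#' @param pcg_lengths Named integer vector of PCG lengths (bp, multiples
#'   of 3, including start and stop codons).
#' @param start_codons,stop_codons Named character vectors per PCG.
#' @param codon_weights Named non-negative weights over the 64 codons
#'   (RNA or DNA names) driving internal-codon sampling.
#' @param trna_length_range,rrn_lengths tRNA length bounds; rRNA lengths.
#' @param class_probs List of per-class base probabilities (named numeric
#'   over A, T, G, C) for `tRNA`, `rRNA`, `control`, `spacer`.
#' @param cr_length Control-region length (bp).
#' @param cr_tandem list of `c(unit, copies)` tandem arrays to plant.
#' @param cr_microsat_reps Copy numbers of the planted (TA)n runs.
#' @param cr_polyT,cr_polyA Counts of planted poly-T(7) / poly-A(5) runs.
#' @param cr_ori_motif Origin motif to plant.
#' @param cr_stem,cr_loop Stem and loop lengths of the planted hairpin.
#' @param gap_range Intergenic spacer range (bp) for unplanned junctions.
#' @param overlap_atp Plant the 7 bp ATGATAA ATP8/ATP6 overlap?
#' @param wrap_gene Gene placed across the origin.
#' @param wrap_offset Bases of `wrap_gene` before the origin.
#' @param genetic_code_id Translation table for CDS validity.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(
    order_template = "lepidoptera_ancestor",
    pcg_lengths = c(COI = 1542, COII = 714, COIII = 789, CYTB = 1155,
                    ATP6 = 678, ATP8 = 162, NADH1 = 933, NADH2 = 1008,
                    NADH3 = 354, NADH4 = 1341, NADH4L = 279, NADH5 = 1713,
                    NADH6 = 504),
    start_codons = c(COI = "ATT", COII = "ATG", COIII = "ATG",
                     CYTB = "ATG", ATP6 = "ATG", ATP8 = "ATT",
                     NADH1 = "ATA", NADH2 = "ATT", NADH3 = "ATT",
                     NADH4 = "ATG", NADH4L = "ATG", NADH5 = "ATT",
                     NADH6 = "ATT"),
    stop_codons = c(COI = "TAA", COII = "TAA", COIII = "TAA",
                    CYTB = "TAA", ATP6 = "TAA", ATP8 = "TAA",
                    NADH1 = "TAA", NADH2 = "TAA", NADH3 = "TAG",
                    NADH4 = "TAA", NADH4L = "TAA", NADH5 = "TAA",
                    NADH6 = "TAA"),
    codon_weights = NULL,
    trna_length_range = c(61L, 71L),
    rrn_lengths = c(rrnL = 1346L, rrnS = 762L),
    class_probs = list(
      tRNA = c(A = 0.411, T = 0.398, G = 0.108, C = 0.083),
      rRNA = c(A = 0.429, T = 0.418, G = 0.102, C = 0.051),
      control = c(A = 0.462, T = 0.494, G = 0.013, C = 0.031),
      spacer = c(A = 0.414, T = 0.405, G = 0.075, C = 0.106)),
    cr_length = 1363L,
    cr_tandem = list(c(unit = 57L, copies = 2L),
                     c(unit = 159L, copies = 2L)),
    cr_microsat_reps = c(6L, 7L, 8L, 6L),
    cr_polyT = 5L, cr_polyA = 5L,
    cr_ori_motif = "ATAGT",
    cr_stem = 24L, cr_loop = 8L,
    gap_range = c(0L, 25L),
    overlap_atp = TRUE,
    wrap_gene = "trnN",
    wrap_offset = 27L,
    genetic_code_id = 5) {
  if (is.null(codon_weights)) {
    cu <- lcoffeella_codon_usage()
    codon_weights <- setNames(cu$count + 0.1, cu$codon)
  }
  spec <- list(order_template = order_template, pcg_lengths = pcg_lengths,
               start_codons = start_codons, stop_codons = stop_codons,
               codon_weights = codon_weights,
               trna_length_range = trna_length_range,
               rrn_lengths = rrn_lengths, class_probs = class_probs,
               cr_length = cr_length, cr_tandem = cr_tandem,
               cr_microsat_reps = cr_microsat_reps,
               cr_polyT = cr_polyT, cr_polyA = cr_polyA,
               cr_ori_motif = cr_ori_motif,
               cr_stem = cr_stem, cr_loop = cr_loop,
               gap_range = gap_range, overlap_atp = overlap_atp,
               wrap_gene = wrap_gene, wrap_offset = wrap_offset,
               genetic_code_id = genetic_code_id)
  class(spec) <- "generator_spec"
  validate_generator_spec(spec)
  spec
}

validate_generator_spec <- function(spec) {
  if (any(spec$pcg_lengths %% 3L != 0L)) {
    stop("PCG lengths must be multiples of 3", call. = FALSE)
  }
  if (any(spec$pcg_lengths < 9L)) {
    stop("PCG lengths must be >= 9 (start + one codon + stop)",
         call. = FALSE)
  }
  planted <- sum(vapply(spec$cr_tandem,
                        function(x) x[["unit"]] * x[["copies"]], numeric(1))) +
    sum(2L * spec$cr_microsat_reps) +
    spec$cr_polyT * 7L + spec$cr_polyA * 5L +
    nchar(spec$cr_ori_motif) + 2L * spec$cr_stem + spec$cr_loop
  n_elements <- length(spec$cr_tandem) + length(spec$cr_microsat_reps) +
    spec$cr_polyT + spec$cr_polyA + 2L
  # each planted element carries two breaker bases and needs a little
  # filler around it
  if (planted + 4L * n_elements > spec$cr_length) {
    stop("planted control-region features exceed the region length (",
         planted, " + padding > ", spec$cr_length, ")", call. = FALSE)
  }
  invisible(spec)
}

# Sample filler bases from `probs`, optionally under run constraints that
# prevent accidental homopolymer / (TA)n / origin-motif hits: no A run
# >= 5, no T run >= 7, no alternating TA/AT stretch >= 9 bases, and no
# ATAG (the G is flipped to T).
sample_filler <- function(n, probs, constrained = FALSE) {
  if (n <= 0L) return("")
  bases <- names(probs)
  out <- sample(bases, n, replace = TRUE, prob = probs)
  if (!constrained) return(paste(out, collapse = ""))
  fix_runs <- function(x) {
    n <- length(x)
    for (i in seq_len(n)) {
      # homopolymer caps
      if (i >= 5L && all(x[(i - 4L):i] == "A")) x[i] <- "T"
      if (i >= 7L && all(x[(i - 6L):i] == "T")) x[i] <- "A"
      # alternating TA/AT cap at 8
      if (i >= 9L) {
        w <- x[(i - 8L):i]
        if (all(w %in% c("T", "A")) && all(w[-1L] != w[-9L])) {
          x[i] <- if (x[i] %in% c("T", "A")) "C" else x[i]
        }
      }
      # no ATAG seed for the origin motif
      if (i >= 4L && x[i] == "G" &&
          identical(x[(i - 3L):(i - 1L)], c("A", "T", "A"))) {
        x[i] <- "T"
      }
    }
    x
  }
  paste(fix_runs(out), collapse = "")
}

# Sample one CDS as a codon vector: fixed start and stop, internal codons
# drawn from the weight table restricted to non-stop codons.
sample_cds <- function(len, start_codon, stop_codon, weights_dna, code) {
  n_codons <- len %/% 3L
  pool <- names(weights_dna)
  is_stop <- unname(code$codon_to_aa[pool] == "*")
  pool <- pool[!is_stop]
  w <- weights_dna[pool]
  internal <- sample(pool, n_codons - 2L, replace = TRUE, prob = w)
  c(start_codon, internal, stop_codon)
}

# Assemble the control region and its ground-truth plan. Planted elements
# are separated by constrained filler and flanked by breaker bases so
# that each is maximal exactly as planted.
build_control_region <- function(spec) {
  probs <- spec$class_probs$control
  elements <- list()
  add <- function(kind, string, breaker_l, breaker_r, meta) {
    elements[[length(elements) + 1L]] <<- list(
      kind = kind, string = string, breaker_l = breaker_l,
      breaker_r = breaker_r, meta = meta)
  }
  # a planted element must not itself contain (or create, across copy
  # boundaries) a homopolymer, microsatellite or origin-motif hit
  clean_element <- function(x) {
    !grepl("A{5}", x) && !grepl("T{7}", x) &&
      !grepl("(?:TA){5}|(?:AT){5}", x) && !grepl("ATAG", x)
  }
  for (td in spec$cr_tandem) {
    u <- td[["unit"]]
    copies <- td[["copies"]]
    repeat {
      unit <- sample_filler(u, probs, constrained = TRUE)
      arr <- paste(rep(unit, copies), collapse = "")
      # aperiodic unit, and no secondary features across copy boundaries
      if (!grepl("^(.+?)\\1+$", unit) && clean_element(arr)) break
    }
    # breakers block left/right extension of the array
    bl <- setdiff(c("C", "G"), substr(unit, u, u))[1]
    br <- setdiff(c("C", "G"), substr(unit, 1L, 1L))[1]
    add("tandem", arr, bl, br,
        list(unit_length = u, copy_number = as.numeric(copies),
             unit_sequence = unit))
  }
  for (reps in spec$cr_microsat_reps) {
    add("microsat", paste(rep("TA", reps), collapse = ""), "C", "C",
        list(copy_number = as.numeric(reps)))
  }
  for (i in seq_len(spec$cr_polyT)) {
    add("polyT", strrep("T", 7L), "C", "C", list(base = "T", length = 7L))
  }
  for (i in seq_len(spec$cr_polyA)) {
    add("polyA", strrep("A", 5L), "C", "C", list(base = "A", length = 5L))
  }
  add("ori", spec$cr_ori_motif, "C", "C", list(motif = spec$cr_ori_motif))
  # hairpin: GC-reinforced arm so the planted stem dominates the AT-rich
  # background; double non-pairing breakers on both sides and non-pairing
  # loop ends keep the detected stem exactly as planted
  # an all-C loop cannot pair with itself, so the detected stem cannot
  # creep into the loop even through the mismatch budget
  loop <- strrep("C", spec$cr_loop)
  repeat {
    # G/C-anchored arm ends keep the stem distinct from the breakers and
    # the AT-rich filler on both sides
    core <- sample(c(rep(c("G", "C"), 3L),
                     sample(c("A", "T", "G", "C"),
                            spec$cr_stem - 8L, replace = TRUE,
                            prob = c(0.35, 0.35, 0.15, 0.15))))
    arm <- paste(c("G", core, "C"), collapse = "")
    hairpin <- paste0(arm, loop, revcomp(arm))
    if (clean_element(hairpin)) break
  }
  # CA/AC breakers: neither extension step can pair, and the C side faces
  # the filler so no A run can form across the boundary
  add("stem", hairpin, "CA", "AC",
      list(stem_length = spec$cr_stem, loop_length = spec$cr_loop))

  # shuffle the planting order deterministically, then interleave filler
  elements <- elements[sample(length(elements))]
  planted_len <- sum(vapply(elements, function(e) {
    nchar(e$string) + nchar(e$breaker_l) + nchar(e$breaker_r)
  }, integer(1)))
  n_gaps <- length(elements) + 1L
  filler_total <- spec$cr_length - planted_len
  base_fill <- filler_total %/% n_gaps
  extra <- filler_total %% n_gaps
  fill_lens <- rep(base_fill, n_gaps) + c(rep(1L, extra),
                                          rep(0L, n_gaps - extra))

  region <- ""
  truth <- list(tandem = list(), microsat = list(), polyT = list(),
                polyA = list(), ori = list(), stem = list())
  for (i in seq_along(elements)) {
    region <- paste0(region, sample_filler(fill_lens[i], probs, TRUE))
    e <- elements[[i]]
    region <- paste0(region, e$breaker_l)
    start <- nchar(region) + 1L  # first base of the planted element
    region <- paste0(region, e$string, e$breaker_r)
    rec <- c(list(start = start), e$meta)
    slot <- switch(e$kind, tandem = "tandem", microsat = "microsat",
                   polyT = "polyT", polyA = "polyA", ori = "ori",
                   stem = "stem")
    truth[[slot]][[length(truth[[slot]]) + 1L]] <- rec
  }
  region <- paste0(region, sample_filler(fill_lens[n_gaps], probs, TRUE))
  stopifnot(nchar(region) == spec$cr_length)
  list(region = region, truth = truth)
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Deterministic for a fixed seed. The emitted genome satisfies the spec
#' by construction: every CDS starts and stops with its configured codons
#' and contains no internal stop under the chosen code, the control
#' region carries the planted features at recorded coordinates, the
#' ATGATAA overlap joins ATP8 and ATP6, and the wrap gene spans the
#' origin. The truth manifest records realized (recounted) quantities,
#' not targets.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_mitogenome`: `sequence`
#'   (`circular_seq`), `annotation` (`mito_annotation`), and `truth` (a
#'   list: per-class base counts, codon counts, start/stop codons, gene
#'   order tokens, junction gaps, control-region plantings with
#'   region-relative and absolute coordinates, and the wrap gene).
#' @export
generate_mitogenome <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(as.integer(seed))
  code <- genetic_code(spec$genetic_code_id)
  weights_dna <- spec$codon_weights
  names(weights_dna) <- chartr("Uu", "Tt", toupper(names(weights_dna)))

  template <- reference_order(spec$order_template)
  tokens <- template$tokens
  nm <- order_names(tokens)
  strand <- ifelse(order_signs(tokens) > 0, "+", "-")
  category <- ifelse(nm %in% PCG_TOKENS, "PCG",
              ifelse(nm %in% TRNA_TOKENS, "tRNA",
              ifelse(nm %in% RRNA_TOKENS, "rRNA",
              ifelse(nm == "CR", "control", "other"))))

  # --- per-feature coding-strand strings -------------------------------
  cr <- build_control_region(spec)
  cds_codons <- list()
  strings <- setNames(vector("list", length(nm)), nm)
  for (i in seq_along(nm)) {
    g <- nm[i]
    strings[[g]] <- switch(category[i],
      control = cr$region,
      PCG = {
        len <- spec$pcg_lengths[[g]]
        codons <- sample_cds(len, spec$start_codons[[g]],
                             spec$stop_codons[[g]], weights_dna, code)
        cds_codons[[g]] <- codons
        paste(codons, collapse = "")
      },
      tRNA = sample_filler(
        sample(seq(spec$trna_length_range[1], spec$trna_length_range[2]), 1L),
        spec$class_probs$tRNA),
      rRNA = sample_filler(spec$rrn_lengths[[g]], spec$class_probs$rRNA))
  }

  if (spec$overlap_atp) {
    # ATP6 begins ATG ATA A.. and ATP8 ends ..A TGA TAA so that the two
    # share the 7 bp ATGATAA across a -7 junction
    atp6 <- cds_codons[["ATP6"]]
    atp6[2L] <- "ATA"
    third <- atp6[3L]
    if (substr(third, 1L, 1L) != "A" ||
        isTRUE(code$codon_to_aa[paste0("A", substr(third, 2L, 3L))] == "*")) {
      atp6[3L] <- "AAT"
    }
    cds_codons[["ATP6"]] <- atp6
    strings[["ATP6"]] <- paste(atp6, collapse = "")
    atp8 <- cds_codons[["ATP8"]]
    n8 <- length(atp8)
    pool <- names(weights_dna)
    endA <- pool[substr(pool, 3L, 3L) == "A" &
                   unname(code$codon_to_aa[pool] != "*")]
    atp8[n8 - 2L] <- sample(endA, 1L, prob = weights_dna[endA])
    atp8[n8 - 1L] <- "TGA"
    atp8[n8] <- "TAA"
    cds_codons[["ATP8"]] <- atp8
    strings[["ATP8"]] <- paste(atp8, collapse = "")
    stopifnot(substr(strings[["ATP8"]],
                     nchar(strings[["ATP8"]]) - 6L,
                     nchar(strings[["ATP8"]])) == "ATGATAA",
              substr(strings[["ATP6"]], 1L, 7L) == "ATGATAA")
  }

  # --- linear assembly in template order -------------------------------
  lens <- vapply(nm, function(g) nchar(strings[[g]]), integer(1))
  gaps <- sample(seq(spec$gap_range[1], spec$gap_range[2]),
                 length(nm), replace = TRUE)
  if (spec$overlap_atp) {
    i8 <- which(nm == "ATP8")
    if (nm[wrap_pos(i8 + 1L, length(nm))] == "ATP6") gaps[i8] <- -7L
  }
  starts <- integer(length(nm))
  pos <- 1L
  genome <- ""
  for (i in seq_along(nm)) {
    starts[i] <- pos
    s <- strings[[nm[i]]]
    placed <- if (strand[i] == "-") revcomp(s) else s
    # planted overlap with the previous feature: shared bases must agree
    if (starts[i] <= nchar(genome)) {
      overlap_nt <- nchar(genome) - starts[i] + 1L
      stopifnot(substr(placed, 1L, overlap_nt) ==
                  substr(genome, starts[i], nchar(genome)))
      placed <- substr(placed, overlap_nt + 1L, nchar(placed))
    }
    genome <- paste0(genome, placed)
    gap_fill <- if (i < length(nm)) {
      sample_filler(max(gaps[i], 0L), spec$class_probs$spacer)
    } else {
      ""
    }
    genome <- paste0(genome, gap_fill)
    pos <- starts[i] + lens[i] + gaps[i]
  }
  # final junction: spacer between the last feature and the first
  gaps[length(nm)] <- max(gaps[length(nm)], 0L)
  genome <- paste0(genome,
                   sample_filler(gaps[length(nm)], spec$class_probs$spacer))
  L <- nchar(genome)
  stopifnot(L == sum(lens) + sum(gaps))

  # --- rotate so the wrap gene spans the origin ------------------------
  wi <- which(nm == spec$wrap_gene)
  stopifnot(length(wi) == 1L, lens[wi] > spec$wrap_offset)
  # put wrap_offset bases of the wrap gene before the origin:
  # its new start becomes L - wrap_offset + 1
  r <- (starts[wi] - (L - spec$wrap_offset + 1L)) %% L
  genome_rot <- rotate_string(genome, r)
  new_pos <- function(p) wrap_pos(p - r, L)
  features <- data.frame(
    name = nm, category = category, strand = strand,
    start = vapply(starts, new_pos, integer(1)),
    stop = vapply(starts + lens - 1L, new_pos, integer(1)),
    anticodon = NA_character_, stringsAsFactors = FALSE)
  seq_obj <- circular_sequence(genome_rot)
  ann <- mito_annotation(features, L, source_id = sprintf("synthetic_seed%d",
                                                          as.integer(seed)))

  # --- ground truth ----------------------------------------------------
  count_class <- function(cl) {
    members <- nm[category == cl]
    count_bases(paste(vapply(members, function(g) strings[[g]],
                             character(1)), collapse = ""))
  }
  cr_start_abs <- new_pos(starts[which(nm == "CR")])
  abs_of_rel <- function(rel) wrap_pos(cr_start_abs + rel - 1L, L)
  cr_truth <- cr$truth
  for (slot in names(cr_truth)) {
    cr_truth[[slot]] <- lapply(cr_truth[[slot]], function(rec) {
      rec$abs_start <- abs_of_rel(rec$start)
      rec
    })
  }
  truth <- list(
    genome_length = L,
    wrap_gene = spec$wrap_gene,
    gene_order = tokens,
    junction_gaps = setNames(as.integer(gaps), nm),
    class_counts = list(PCG = count_class("PCG"),
                        tRNA = count_class("tRNA"),
                        rRNA = count_class("rRNA"),
                        control = count_class("control"),
                        genome = count_bases(genome)),
    codon_counts = count_codons(
      vapply(names(cds_codons), function(g)
        paste(cds_codons[[g]], collapse = ""), character(1)),
      code = code),
    start_codons = spec$start_codons,
    stop_codons = spec$stop_codons,
    feature_lengths = setNames(as.integer(lens), nm),
    control_region = cr_truth,
    seed = as.integer(seed)
  )
  structure(list(sequence = seq_obj, annotation = ann, truth = truth),
            class = "synthetic_mitogenome")
}

#' @export
print.synthetic_mitogenome <- function(x, ...) {
  cat(sprintf("<synthetic_mitogenome> seed %d: %d bp, %d features (wrap: %s)\n",
              x$truth$seed, x$truth$genome_length,
              nrow(x$annotation$features), x$truth$wrap_gene))
  invisible(x)
}

#' Write a synthetic mitogenome to disk
#'
#' Emits GenBank, FASTA and a JSON truth manifest.
#'
#' @param sim A `synthetic_mitogenome`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_mitogenome <- function(sim, dir, prefix = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genbank = file.path(dir, paste0(prefix, ".gb")),
             fasta = file.path(dir, paste0(prefix, ".fasta")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_genbank(sim$sequence, sim$annotation, paths["genbank"])
  write_fasta_circular(sim$sequence, paths["fasta"],
                       name = sim$annotation$source_id)
  truth <- sim$truth
  truth$codon_counts <- as.list(unclass(truth$codon_counts))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
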